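test_that("embedded construct fixtures have their designated lengths", {
  rep <- validate_fixture_lengths()
  expect_true(all(rep$ok))
  expect_equal(rep$length, c(167L, 208L, 208L))
})

test_that("enzyme scans on the constructs match the brute-force oracle", {
  cs <- widom_601_constructs()
  for (nm in names(cs)) {
    for (enz in c("HinfI", "NsiI")) {
      motif <- c(HinfI = "GANTC", NsiI = "ATGCAT")[[enz]]
      got <- scan_sites(cs[[nm]], enz)
      expect_equal(got$start, brute_force_scan(cs[[nm]]$sequence, motif),
                   info = paste(nm, enz))
    }
  }
  ## the NsiI site exists only in the mutagenized 208-bp repeat
  expect_equal(nrow(scan_sites(cs$`601_208`, "NsiI")), 0L)
  expect_gt(nrow(scan_sites(cs$`601_208_NsiI`, "NsiI")), 0L)
  expect_equal(nrow(scan_sites(cs$`601_167`, "HinfI")), 1L)
})

test_that("random-sequence scans equal the oracle for random IUPAC motifs", {
  set.seed(601)
  iupac <- names(IUPAC_SETS)
  for (i in 1:200) {
    n <- sample(30:120, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    motif <- paste(sample(iupac, sample(4:8, 1), replace = TRUE,
                          prob = c(rep(4, 4), rep(1, 11))),
                   collapse = "")
    got <- scan_sites(construct_sequence("rnd", seq), motif)
    expect_equal(got$start[got$strand == "+"], brute_force_scan(seq, motif),
                 info = paste(i, motif))
    ## minus-strand hits (non-palindromic motifs) equal the oracle on the
    ## reverse complement motif
    if (any(got$strand == "-"))
      expect_equal(got$start[got$strand == "-"],
                   brute_force_scan(seq, revcomp(motif)))
  }
})

test_that("palindromic motifs give mirror-consistent positions", {
  for (motif in c("GANTC", "ATGCAT")) {
    s <- widom_601_constructs("601_208_NsiI")
    top <- scan_sites(s, motif)$start
    bottom <- brute_force_scan(revcomp(s$sequence), motif)
    ## a palindromic hit at top-strand position p appears at
    ## L - (p + k - 1) + 1 on the reverse complement
    expect_equal(sort(s$length - (top + nchar(motif) - 1) + 1), sort(bottom))
  }
})

test_that("scan inputs are validated", {
  expect_error(scan_sites(construct_sequence("x", "ACGT"), "GAXTC"),
               "IUPAC")
  expect_error(scan_sites(construct_sequence("x", "ACGT"), ""), "IUPAC")
  empty <- construct_sequence("empty", "")
  expect_equal(nrow(scan_sites(empty, "GANTC")), 0L)
  expect_error(construct_sequence("bad", "ACGU"), "A/C/G/T")
})

test_that("core-edge distances classify sites by accessibility context", {
  seq <- construct_sequence("toy", paste(rep("A", 200), collapse = ""),
                            core = c(31, 177))
  mk <- function(s, e) {
    df <- data.frame(enzyme = "custom", motif = "X", start = s, end = e,
                     strand = "+", stringsAsFactors = FALSE)
    class(df) <- c("restriction_sites", "data.frame")
    df
  }
  ## motif starting exactly at the core edge
  expect_equal(site_accessibility_context(mk(31, 36), seq)$dist_to_core, 0L)
  expect_equal(site_accessibility_context(mk(31, 36), seq)$class, "edge")
  ## 6 bp inside the core end
  expect_equal(site_accessibility_context(mk(37, 42), seq)$dist_to_core, -6L)
  expect_equal(site_accessibility_context(mk(37, 42), seq)$class, "edge")
  ## deep inside a centered core
  expect_equal(site_accessibility_context(mk(100, 105), seq)$class,
               "internal")
  ## outside the core
  expect_equal(site_accessibility_context(mk(5, 10), seq)$dist_to_core, 21L)
  expect_equal(site_accessibility_context(mk(5, 10), seq)$class,
               "outside-core")
  nocore <- construct_sequence("toy2", "ACGTACGT")
  expect_error(site_accessibility_context(mk(1, 4), nocore), "core")
})

test_that("the assay constructs place both enzyme sites at the core edge", {
  s208 <- widom_601_constructs("601_208")
  hinf <- site_accessibility_context(scan_sites(s208, "HinfI"), s208)
  expect_equal(hinf$class, "edge")
  smod <- widom_601_constructs("601_208_NsiI")
  nsi <- site_accessibility_context(scan_sites(smod, "NsiI"), smod)
  expect_equal(nsi$class, "edge")
})
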