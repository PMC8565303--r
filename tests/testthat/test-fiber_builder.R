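test_that("builder/estimator duality holds over random parameter sets", {
  set.seed(2024)
  for (i in 1:25) {
    ps <- c(x = runif(1, 8, 20), beta = runif(1, 0, 40),
            d = runif(1, 30, 80), gamma = runif(1, 0, 40))
    n <- sample(c(8L, 12L, 16L), 1)
    m <- suppressWarnings(build_fiber(
      fiber_build_spec(n = n, x = ps["x"], beta = ps["beta"], d = ps["d"],
                       gamma = ps["gamma"])))
    fp <- summarize_parameters(m$frames, m$linkers)
    expect_equal(fp$summary$mean, unname(ps), tolerance = 1e-6)
  }
})

test_that("beta = 0 gives collinear unit centers at spacing d", {
  m <- suppressWarnings(build_fiber(
    fiber_build_spec(n = 4, x = 14.9, beta = 0, d = 100, gamma = 0)))
  u <- partition_units(m$frames)
  c1 <- u[[1]]$center; c2 <- u[[2]]$center
  expect_equal(c2 - c1, c(0, 0, 100), tolerance = 1e-9)
})

test_that("tight packing triggers the steric warning but still builds", {
  expect_warning(m <- build_fiber(
    fiber_build_spec(n = 8, x = 10, beta = 5, d = 31, gamma = 0)),
    "steric")
  expect_s3_class(m, "fiber_model")
})

test_that("decoration places template copies exactly on their frames", {
  tpl <- path_to_duplex_model(make_ideal_ncp_path(), source = "tpl")
  m <- build_fiber(h2az_spec(n = 6))
  dec <- decorate(m, tpl, dyad = c("I", 74))
  expect_equal(n_atoms(dec),
               6L * n_atoms(tpl) + 5L * 2L * 10L)  # copies + linker bp

  ## per-copy Kabsch RMSD against the intended placement is ~0
  tf <- assign_frame(extract_dna_duplex(tpl, dyad = c("I", 74)))
  loc <- sweep(as.matrix(tpl$atoms[, c("x", "y", "z")]), 2, tf$center) %*% tf$R
  chains <- unique(dec$atoms$chain)
  for (k in 1:6) {
    want <- sweep(loc %*% t(m$frames[[k]]$R), 2, m$frames[[k]]$center, `+`)
    got <- as.matrix(dec$atoms[dec$atoms$chain %in%
                                 chains[c(2 * k - 1, 2 * k)],
                               c("x", "y", "z")])
    expect_lt(kabsch_rmsd(want, got), 1e-6)
    expect_lt(max(abs(want - got)), 1e-6)
  }

  ## a template placed on its own frame is the identity transform
  one <- build_fiber(h2az_spec(n = 2))
  one$frames <- list(tf, tf)
  one$linkers <- NULL
  self <- decorate(one, tpl, dyad = c("I", 74))
  got1 <- as.matrix(self$atoms[seq_len(n_atoms(tpl)), c("x", "y", "z")])
  expect_lt(max(abs(got1 - as.matrix(tpl$atoms[, c("x", "y", "z")]))), 1e-9)

  prot <- structure_model(data.frame(chain = "A", resno = 1:5, resid = "ALA",
                                     elety = "CA", x = 1:5, y = 0, z = 0))
  expect_error(decorate(m, prot), "underivable")
})

test_that("dimension measurement matches closed-form envelopes", {
  ## single nucleosome, disc face-on to the axis: length = thickness
  d1 <- measure_dimensions(frames = list(frame_at(c(0, 0, 0))),
                           axis = list(direction = c(0, 0, 1)))
  expect_equal(unname(d1["length_nm"]), 5.5, tolerance = 1e-9)
  expect_equal(unname(d1["width_nm"]), 11, tolerance = 1e-4)

  ## 12 stacked units at d = 59.5 A, discs edge-on: 11 steps + disc diameter
  fr <- lapply(0:11, function(i) frame_at(c(0, 0, i * 59.5),
                                          normal = c(1, 0, 0),
                                          dyad = c(0, 1, 0)))
  d2 <- measure_dimensions(frames = fr, axis = list(direction = c(0, 0, 1)))
  expect_equal(unname(d2["length_nm"]), 11 * 5.95 + 11, tolerance = 1e-9)
})

test_that("fiber length grows with n and with d, and is rigid-motion invariant", {
  len <- function(n, d) {
    m <- build_fiber(fiber_build_spec(n = n, x = 14.9, beta = 19.7, d = d,
                                      gamma = 27.5))
    unname(measure_dimensions(m)["length_nm"])
  }
  expect_lt(len(8, 59.5), len(12, 59.5))
  expect_lt(len(12, 59.5), len(12, 70))

  m <- build_fiber(h2az_spec(n = 8))
  ref <- measure_dimensions(m)
  set.seed(5)
  for (i in 1:5) {
    mo <- random_rigid_motion()
    fr <- lapply(m$frames, transform_frame, motion = mo)
    got <- measure_dimensions(frames = fr,
                              axis = list(direction = as.numeric(
                                mo$R %*% m$axis$direction)))
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("24-mer fiber lengths order H2A.Z below H2A", {
  lz <- measure_dimensions(build_fiber(h2az_spec(n = 24)))
  la <- measure_dimensions(build_fiber(h2a_spec(n = 24)))
  expect_lt(lz["length_nm"], la["length_nm"])
})

test_that("frames CSV round-trips and feeds the estimator identically", {
  m <- build_fiber(h2az_spec(n = 8))
  f <- tempfile(fileext = ".csv")
  write_frames_csv(m$frames, f)
  back <- read_frames_csv(f)
  expect_length(back, 8)
  for (k in 1:8) {
    expect_equal(back[[k]]$center, m$frames[[k]]$center, tolerance = 1e-9)
    expect_equal(back[[k]]$normal, m$frames[[k]]$normal, tolerance = 1e-9)
  }
  fp1 <- summarize_parameters(m$frames)
  fp2 <- summarize_parameters(back)
  expect_equal(fp2$summary$mean[1:3], fp1$summary$mean[1:3],
               tolerance = 1e-9)
  unlink(f)
})
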