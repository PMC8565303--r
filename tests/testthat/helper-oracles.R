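# Independent oracles and small fixture builders used across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force IUPAC sliding-window scan (independent of Biostrings)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

brute_force_scan <- function(seq, motif) {
  s <- strsplit(seq, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  n <- length(s); k <- length(m)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[i + j - 1] %in% IUPAC_SETS[[m[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

## brute-force count of mutually nearest inter-strand reference-atom pairs
## within the pairing cutoff
brute_force_pair_count <- function(x1, x2, cutoff = 12) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  d <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    d[i, j] <- sqrt(sum((x1[i, ] - x2[j, ])^2))
  cnt <- 0L
  for (i in seq_len(n1)) {
    j <- which.min(d[i, ])
    if (which.min(d[, j]) == i && d[i, j] <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

## Kabsch superposition RMSD oracle (closed-form SVD solution)
kabsch_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv <- svd(t(Ac) %*% Bc)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fit <- sweep(Bc %*% R, 2, ca, `+`)  # B mapped onto A
  fitB <- sweep(Ac %*% t(R), 2, cb, `+`)
  sqrt(mean(rowSums((fitB - B)^2)))
}

## quick frame builder for hand-constructed fibers
frame_at <- function(center, normal = c(0, 0, 1), dyad = c(1, 0, 0)) {
  nucleosome_frame(center, normal, dyad)
}

h2az_spec <- function(n = 12L, nrl = 167L)
  fiber_build_spec(n = n, x = 14.9, beta = 19.7, d = 59.5, gamma = 27.5,
                   nrl = nrl)

h2a_spec <- function(n = 12L, nrl = 167L)
  fiber_build_spec(n = n, x = 14.3, beta = 12, d = 61, gamma = 9.7,
                   nrl = nrl)
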