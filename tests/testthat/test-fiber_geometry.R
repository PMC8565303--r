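test_that("di-nucleosome partitioning pairs consecutive nucleosomes", {
  m8 <- build_fiber(h2az_spec(n = 8))
  u <- partition_units(m8$frames)
  expect_length(u, 4)
  expect_equal(u[[3]]$members, c(5L, 6L))
  expect_equal(u[[1]]$center,
               (m8$frames[[1]]$center + m8$frames[[2]]$center) / 2)
  ## unit frame is orthonormal
  expect_equal(crossprod(u[[1]]$frame), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)

  u4 <- partition_units(build_fiber(h2az_spec(n = 4))$frames)
  expect_length(u4, 2)
  expect_warning(u5 <- partition_units(build_fiber(h2az_spec(n = 5))$frames),
                 "ordinal 5")
  expect_length(u5, 2)
  expect_equal(attr(u5, "excluded"), 5L)
  expect_error(partition_units(build_fiber(h2az_spec(n = 3))$frames[1:3]),
               ">= 4")
})

test_that("fiber axis estimation: construction axis, closed form, equivariance", {
  m <- build_fiber(h2az_spec(n = 12))
  u <- partition_units(m$frames)
  ax <- estimate_fiber_axis(u)
  expect_lt(angle_between(ax$direction, c(0, 0, 1)) * pi / 180, 1e-6)

  ## two units: axis is the normalized center difference
  u2 <- u[1:2]
  ax2 <- estimate_fiber_axis(u2)
  expect_equal(ax2$direction,
               (u[[2]]$center - u[[1]]$center) /
                 sqrt(sum((u[[2]]$center - u[[1]]$center)^2)),
               tolerance = 1e-9)

  set.seed(3)
  mo <- random_rigid_motion()
  ut <- lapply(u, function(x) { x$center <- as.numeric(mo$R %*% x$center + mo$t)
                                x$pair_dir <- as.numeric(mo$R %*% x$pair_dir); x })
  axt <- estimate_fiber_axis(ut)
  expect_equal(axt$direction, as.numeric(mo$R %*% ax$direction),
               tolerance = 1e-9)

  uc <- lapply(u, function(x) { x$center <- c(0, 0, 0); x })
  expect_error(estimate_fiber_axis(uc), "coincide")
})

test_that("x is the intra-unit center distance in nm", {
  m <- build_fiber(h2az_spec(n = 12))
  u <- partition_units(m$frames)
  expect_equal(compute_x(u[[1]]), 14.9, tolerance = 1e-9)
  ## independent two-point distance oracle
  expect_equal(compute_x(u[[2]]),
               sqrt(sum((m$frames[[4]]$center - m$frames[[3]]$center)^2)) / 10,
               tolerance = 1e-12)
  uc <- u[[1]]; uc$member_centers <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_warning(x0 <- compute_x(uc), "coincident")
  expect_equal(x0, 0)
})

test_that("beta and d recover a known screw relation", {
  base <- list(members = c(1L, 2L), member_centers = rbind(c(-70, 0, 0), c(70, 0, 0)),
               center = c(0, 0, 0), pair_dir = c(1, 0, 0))
  ax <- list(direction = c(0, 0, 1), point = c(0, 0, 0))
  Rz <- rotation_about(c(0, 0, 1), 23.3)
  nxt <- base
  nxt$center <- c(0, 0, 38.9)
  nxt$pair_dir <- as.numeric(Rz %*% base$pair_dir)
  bd <- compute_beta_d(base, nxt, ax)
  expect_equal(bd$beta, 23.3, tolerance = 1e-9)
  expect_equal(bd$d, 38.9, tolerance = 1e-9)

  ## pure translation: beta = 0
  tr <- base; tr$center <- c(5, -3, 50)
  bd0 <- compute_beta_d(base, tr, ax)
  expect_equal(bd0$beta, 0, tolerance = 1e-9)
  expect_equal(bd0$d, 50, tolerance = 1e-12)

  ## degenerate: pair direction along the axis
  dg <- base; dg$pair_dir <- c(0, 0, 1)
  expect_error(compute_beta_d(dg, nxt, ax), "parallel")
})

test_that("gamma round-trips through the builder and tracks jittered linkers", {
  for (g in c(0, 27.5, 9.7)) {
    m <- build_fiber(fiber_build_spec(n = 6, x = 14.9, beta = 19.7, d = 59.5,
                                      gamma = g))
    got <- compute_gamma(m$frames[[3]], entry = m$linkers[[2]]$entry,
                         exit = m$linkers[[3]]$exit)
    expect_equal(got$gamma, g, tolerance = 1e-6)
    expect_equal(got$raw_angle, reference_entry_exit_angle() + g,
                 tolerance = 1e-6)
  }
  expect_error(compute_gamma(build_fiber(h2az_spec(6))$frames[[2]],
                             entry = matrix(0, 3, 3), exit = matrix(1, 5, 3)),
               "too short")

  ## Monte-Carlo: 1 A Gaussian linker noise, mean within 2 SE of truth
  vals <- vapply(1:100, function(s) {
    m <- make_synthetic_fiber(h2az_spec(n = 6),
                              jitter_spec(linker_sd = 1, seed = 1000 + s))
    compute_gamma(m$frames[[3]], entry = m$linkers[[2]]$entry,
                  exit = m$linkers[[3]]$exit)$gamma
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 27.5), 2 * se + 1e-12)
})

test_that("summarize_parameters reproduces both reference parameter sets", {
  for (ps in list(c(14.9, 19.7, 59.5, 27.5), c(14.3, 12, 61, 9.7))) {
    m <- build_fiber(fiber_build_spec(n = 12, x = ps[1], beta = ps[2],
                                      d = ps[3], gamma = ps[4]))
    fp <- summarize_parameters(m$frames, m$linkers)
    expect_equal(fp$summary$mean, ps, tolerance = 1e-6)
    expect_true(all(fp$summary$sd < 1e-6))
    expect_equal(fp$summary$n, c(6, 5, 5, 10))
  }
})

test_that("packing parameters are rigid-motion invariant and scale correctly", {
  m <- build_fiber(h2az_spec(n = 8))
  ref <- summarize_parameters(m$frames, m$linkers)
  set.seed(99)
  for (i in 1:25) {
    mo <- random_rigid_motion()
    fr <- lapply(m$frames, transform_frame, motion = mo)
    lk <- lapply(m$linkers, function(l) list(exit = apply_rigid(l$exit, mo),
                                             entry = apply_rigid(l$entry, mo)))
    got <- summarize_parameters(fr, lk)
    expect_equal(got$summary$mean, ref$summary$mean, tolerance = 1e-6)
  }
  ## uniform scaling: x and d scale, beta and gamma do not
  s <- 1.7
  frs <- lapply(m$frames, function(f)
    nucleosome_frame(f$center * s, f$normal, f$dyad_dir))
  lks <- lapply(m$linkers, function(l) list(exit = l$exit * s,
                                            entry = l$entry * s))
  sc <- summarize_parameters(frs, lks)
  expect_equal(sc$summary$mean[sc$summary$parameter %in% c("x", "d")],
               ref$summary$mean[ref$summary$parameter %in% c("x", "d")] * s,
               tolerance = 1e-9)
  expect_equal(sc$summary$mean[sc$summary$parameter %in% c("beta", "gamma")],
               ref$summary$mean[ref$summary$parameter %in% c("beta", "gamma")],
               tolerance = 1e-9)
})

test_that("jittered fibers recover construction parameters within 2 SE", {
  truth <- c(14.9, 19.7, 59.5, 27.5)
  means <- t(vapply(1:60, function(s) {
    m <- make_synthetic_fiber(h2az_spec(n = 12),
                              jitter_spec(center_sd = 2, orient_sd = 2,
                                          seed = 5000 + s))
    summarize_parameters(m$frames, m$linkers)$summary$mean
  }, numeric(4)))
  for (j in 1:4) {
    se <- sd(means[, j]) / sqrt(nrow(means))
    expect_lt(abs(mean(means[, j]) - truth[j]), 2 * se + 0.02)
  }
})
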