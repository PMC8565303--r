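test_that("noise-free exponential data are recovered exactly", {
  for (ps in list(c(C = 0, A = 1, k = 0.05), c(C = 0.1, A = 0.7, k = 0.012),
                  c(C = 0.02, A = 0.9, k = 0.2))) {
    tc <- make_timecourse(ps["C"], ps["A"], ps["k"])
    fit <- fit_exponential(tc)
    expect_equal(c(C = fit$C, A = fit$A, k = fit$k), ps, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("degenerate time courses are rejected", {
  expect_error(fit_exponential(digestion_timecourse(c(0, 15, 30, 45),
                                                    rep(0.5, 4))),
               "unidentifiable")
  expect_error(digestion_timecourse(c(0, 15, 15, 45), c(0, .1, .2, .3)),
               "increasing")
  expect_error(digestion_timecourse(c(0, 15, 30), c(0, .1, .2)), ">= 4")
})

test_that("k scales inversely with the time unit and C absorbs y offsets", {
  tc <- make_timecourse(0.05, 0.85, 0.046)
  f0 <- fit_exponential(tc)
  ## minutes -> seconds
  fs <- fit_exponential(digestion_timecourse(tc$t * 60, tc$y))
  expect_equal(fs$k * 60, f0$k, tolerance = 1e-9)
  expect_equal(c(fs$C, fs$A), c(f0$C, f0$A), tolerance = 1e-9)
  ## y offset
  fo <- fit_exponential(digestion_timecourse(tc$t, tc$y + 0.07))
  expect_equal(fo$C, f0$C + 0.07, tolerance = 1e-8)
  expect_equal(c(fo$A, fo$k), c(f0$A, f0$k), tolerance = 1e-8)
})

test_that("noisy rate constants are recovered without systematic bias", {
  ks <- vapply(1:200, function(s)
    fit_exponential(make_timecourse(0, 1, 0.05, noise_sd = 0.02,
                                    seed = s))$k,
    numeric(1))
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.05), 2 * se)
})

test_that("relative rates behave as exact fold changes", {
  a <- kinetics_fit_from_k(c(0.05, 0.05))
  expect_equal(relative_rate(a, a)$fold, 1)
  expect_equal(relative_rate(kinetics_fit_from_k(0.10),
                             kinetics_fit_from_k(0.05))$fold, 2)
  ## noise-free datasets with rates k and c*k give fold exactly c
  f1 <- fit_exponential(make_timecourse(0, 1, 0.02))
  f2 <- fit_exponential(make_timecourse(0, 1, 0.02 * 2.31))
  expect_equal(relative_rate(list(f2), list(f1))$fold, 2.31,
               tolerance = 1e-6)
  expect_error(relative_rate(a, kinetics_fit_from_k(c(-1, -2))), "positive")
})

test_that("group comparison gates the t test on the variance F test", {
  g <- kinetics_fit_from_k(c(0.05, 0.06, 0.055, 0.052))
  res <- compare_groups(list(a = g, b = g))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_true(res$var_equal)

  set.seed(8)
  g1 <- kinetics_fit_from_k(rnorm(6, 0.05, 0.002))
  g2 <- kinetics_fit_from_k(rnorm(6, 0.05, 0.02))
  res2 <- compare_groups(list(ctrl = g1, wide = g2))
  expect_false(res2$var_equal)

  expect_error(compare_groups(list(g)), ">= 2 groups")
  expect_error(compare_groups(list(a = g, b = kinetics_fit_from_k(0.05))),
               ">= 2 fits")
})

test_that("strongly separated groups are detected with high power", {
  set.seed(21)
  hits <- mean(vapply(1:300, function(i) {
    g1 <- kinetics_fit_from_k(rnorm(5, 0.05, 0.005))
    g2 <- kinetics_fit_from_k(rnorm(5, 0.05 + 3 * 0.005, 0.005))
    compare_groups(list(a = g1, b = g2))$p.value < 0.05
  }, logical(1)))
  expect_gte(hits, 0.95)
})

test_that("time-course CSV IO round-trips and the file pipeline fits it", {
  courses <- list(make_timecourse(0, 1, 0.05, condition = "H2A",
                                  replicate = "r1"),
                  make_timecourse(0, 1, 0.05, condition = "H2A",
                                  replicate = "r2"),
                  make_timecourse(0, 1, 0.115, condition = "H2A.Z",
                                  replicate = "r1"),
                  make_timecourse(0, 1, 0.115, condition = "H2A.Z",
                                  replicate = "r2"))
  f <- tempfile(fileext = ".csv")
  write_timecourses(courses, f)
  back <- read_timecourses(f)
  expect_named(back, c("H2A", "H2A.Z"))
  expect_equal(back$H2A$r1$y, courses[[1]]$y)

  res <- fit_kinetics_file(f, control = "H2A")
  expect_equal(res$folds$fold, 2.3, tolerance = 1e-6)
  expect_equal(res$rates$H2A$mean_k, 0.05, tolerance = 1e-6)
  expect_error(fit_kinetics_file(f, control = "nope"), "not found")
  unlink(f)
})
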