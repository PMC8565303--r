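#' Restriction-digestion time course
#'
#' One replicate of a digestion assay: fraction digested as a function of
#' time.  Fractions may slightly exceed 1 from gel quantification noise.
#'
#' @param t time in minutes, non-negative, strictly increasing, >= 4 points.
#' @param y fraction digested.
#' @param condition condition label (e.g. "H2A", "H2A.Z").
#' @param replicate replicate id.
#' @return object of class \code{digestion_timecourse} (a data.frame with
#'   columns \code{t}, \code{y} and attributes \code{condition},
#'   \code{replicate}).
#' @export
digestion_timecourse <- function(t, y, condition = "unknown",
                                 replicate = "r1") {
  if (length(t) < 4) stop("need >= 4 time points", call. = FALSE)
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  if (any(t < 0) || any(diff(t) <= 0))
    stop("t must be non-negative and strictly increasing", call. = FALSE)
  out <- data.frame(t = as.numeric(t), y = as.numeric(y))
  attr(out, "condition") <- as.character(condition)
  attr(out, "replicate") <- as.character(replicate)
  class(out) <- c("digestion_timecourse", "data.frame")
  out
}

#' Fit the saturating exponential digestion model
#'
#' Nonlinear least-squares fit of y = C + A (1 - exp(-k t)) with k > 0.
#' Initialization is deterministic: C0 = min(y), A0 = max(y) - min(y), k0
#' log-linearized from the first two informative points, then a bounded
#' multi-start over the fixed grid k0 x \{0.2, 0.5, 1, 2, 5\}; the lowest
#' residual sum of squares wins, so the fit is a deterministic function of
#' the data.
#'
#' @param tc a \code{\link{digestion_timecourse}} (or data.frame with
#'   \code{t}, \code{y}).
#' @return object of class \code{kinetics_fit}: list with \code{C},
#'   \code{A}, \code{k} (per minute), \code{rss}, \code{fitted},
#'   \code{condition}, \code{replicate}.
#' @export
fit_exponential <- function(tc) {
  t <- tc$t; y <- tc$y
  if (length(t) < 4) stop("need >= 4 time points", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("flat time course (zero variance): k is unidentifiable",
         call. = FALSE)
  C0 <- min(y); A0 <- max(y) - min(y)
  ## log-linearized k from the first two informative points:
  ## 1 - (y - C0)/A0 = exp(-k t)  =>  k = -log(z)/t
  z <- 1 - (y - C0) / A0
  ok <- which(t > 0 & z > 1e-6 & z < 1 - 1e-6)
  k0 <- if (length(ok) >= 1) {
    stats::median(-log(z[utils::head(ok, 2)]) / t[utils::head(ok, 2)])
  } else 1 / stats::median(t[t > 0])
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / stats::median(t[t > 0])
  best <- NULL
  df <- data.frame(t = t, y = y)
  for (mult in c(0.2, 0.5, 1, 2, 5)) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ C + A * (1 - exp(-k * t)), data = df,
      start = list(C = C0, A = A0, k = k0 * mult),
      lower = c(C = -Inf, A = -Inf, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("exponential fit failed to converge from all restarts (n = ",
         length(t), " points, k0 = ", signif(k0, 3), ")", call. = FALSE)
  cf <- stats::coef(best$fit)
  fitted_y <- cf[["C"]] + cf[["A"]] * (1 - exp(-cf[["k"]] * t))
  if (any(fitted_y < min(y) - 0.2) || any(fitted_y > max(y) + 0.2))
    warning("fitted curve strays > 0.2 beyond the observed y range")
  structure(list(C = cf[["C"]], A = cf[["A"]], k = cf[["k"]],
                 rss = best$rss, fitted = fitted_y,
                 condition = attr(tc, "condition") %||% "unknown",
                 replicate = attr(tc, "replicate") %||% "r1"),
            class = "kinetics_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s/%s: C = %.4f, A = %.4f, k = %.5f /min (RSS %.2e)\n",
              x$condition, x$replicate, x$C, x$A, x$k, x$rss))
  invisible(x)
}

#' Wrap bare rate constants as minimal fit objects
#'
#' Convenience for simulation studies that operate on rate constants
#' directly (e.g. type-I-error or power studies of
#' \code{\link{compare_groups}}): each k becomes a degenerate
#' \code{kinetics_fit} carrying only the rate.
#'
#' @param k numeric vector of rate constants.
#' @param condition condition label.
#' @return list of \code{kinetics_fit} objects.
#' @export
kinetics_fit_from_k <- function(k, condition = "sim") {
  lapply(seq_along(k), function(i)
    structure(list(C = 0, A = 1, k = k[i], rss = NA_real_, fitted = NULL,
                   condition = condition, replicate = paste0("r", i)),
              class = "kinetics_fit"))
}

.k_of <- function(fits) vapply(fits, `[[`, numeric(1), "k")

#' Mean rate constant and SEM of a group of fits
#' @param fits list of \code{kinetics_fit}.
#' @return list with \code{mean_k}, \code{sem_k}, \code{n}.
#' @export
group_rate <- function(fits) {
  k <- .k_of(fits)
  list(mean_k = mean(k),
       sem_k = if (length(k) > 1) stats::sd(k) / sqrt(length(k)) else NA_real_,
       n = length(k))
}

#' Relative digestion rate (fold change) between two groups
#'
#' fold = mean(k_test) / mean(k_control); its uncertainty comes from
#' first-order propagation of the two SEMs:
#' se = fold * sqrt((sem_t/mean_t)^2 + (sem_c/mean_c)^2).
#'
#' @param test_fits,control_fits lists of \code{kinetics_fit} (>= 1 each).
#' @return list with \code{fold}, \code{se}, and the two group summaries.
#' @export
relative_rate <- function(test_fits, control_fits) {
  gt <- group_rate(test_fits); gc_ <- group_rate(control_fits)
  if (gc_$mean_k <= 0)
    stop("control mean rate constant must be positive", call. = FALSE)
  fold <- gt$mean_k / gc_$mean_k
  se <- if (is.na(gt$sem_k) || is.na(gc_$sem_k)) NA_real_ else
    fold * sqrt((gt$sem_k / gt$mean_k)^2 + (gc_$sem_k / gc_$mean_k)^2)
  list(fold = fold, se = se, test = gt, control = gc_)
}

#' Compare rate constants between groups
#'
#' For each non-control group versus the control (first) group: an F test
#' for equality of variances at the 0.05 level decides between the pooled-
#' and unequal-variance (Welch) two-sample t test on the rate constants.
#'
#' @param groups named list of >= 2 groups, each a list of >= 2
#'   \code{kinetics_fit}; the first group is the control.
#' @return data.frame with one row per comparison: group, control, n,
#'   var_equal, f_p, statistic (t), df, p.value.
#' @export
compare_groups <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs >= 2 fits", call. = FALSE)
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  kc <- .k_of(groups[[1]])
  out <- lapply(seq_along(groups)[-1], function(i) {
    kt <- .k_of(groups[[i]])
    fp <- suppressWarnings(stats::var.test(kt, kc)$p.value)
    veq <- is.na(fp) || fp >= 0.05
    tt <- tryCatch(stats::t.test(kt, kc, var.equal = veq),
                   error = function(e) {
                     ## both groups (near-)constant: the t statistic is 0 for
                     ## equal means and unbounded otherwise
                     dm <- mean(kt) - mean(kc)
                     if (abs(dm) < 1e-12)
                       list(statistic = c(t = 0),
                            parameter = c(df = length(kt) + length(kc) - 2),
                            p.value = 1)
                     else
                       list(statistic = c(t = sign(dm) * Inf),
                            parameter = c(df = length(kt) + length(kc) - 2),
                            p.value = 0)
                   })
    data.frame(group = nm[i], control = nm[1], n_group = length(kt),
               n_control = length(kc), var_equal = veq, f_p = fp,
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p.value = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read digestion time courses from CSV
#'
#' Expected columns: \code{condition}, \code{replicate}, \code{t_min},
#' \code{fraction_digested}.
#'
#' @param path CSV file.
#' @return named list (by condition) of lists of
#'   \code{digestion_timecourse} objects.
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "t_min", "fraction_digested")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$condition), function(dc) {
    lapply(split(dc, dc$replicate), function(dr) {
      dr <- dr[order(dr$t_min), ]
      digestion_timecourse(dr$t_min, dr$fraction_digested,
                           condition = dc$condition[1],
                           replicate = dr$replicate[1])
    })
  })
  out
}

#' Write digestion time courses to CSV
#'
#' @param courses list of \code{digestion_timecourse} objects (flat list).
#' @param path CSV file.
#' @export
write_timecourses <- function(courses, path) {
  df <- do.call(rbind, lapply(courses, function(tc)
    data.frame(condition = attr(tc, "condition"),
               replicate = attr(tc, "replicate"),
               t_min = tc$t, fraction_digested = tc$y,
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Fit all time courses in a CSV and compare against a control
#'
#' Pipeline wrapper: reads the CSV, fits every replicate, computes each
#' condition's mean rate and fold change versus the control, and runs the
#' variance-gated t test.
#'
#' @param path CSV of time courses (see \code{\link{read_timecourses}}).
#' @param control control condition label (default "H2A").
#' @param json_path,tsv_path optional report outputs.
#' @return list with \code{fits}, \code{folds} (data.frame), \code{tests}
#'   (from \code{\link{compare_groups}}).
#' @export
fit_kinetics_file <- function(path, control = "H2A", json_path = NULL,
                              tsv_path = NULL) {
  courses <- read_timecourses(path)
  if (!control %in% names(courses))
    stop("control condition '", control, "' not found in ", path,
         call. = FALSE)
  fits <- lapply(courses, function(reps) lapply(reps, fit_exponential))
  others <- setdiff(names(fits), control)
  folds <- do.call(rbind, lapply(others, function(cn) {
    rr <- relative_rate(fits[[cn]], fits[[control]])
    data.frame(condition = cn, control = control, fold = rr$fold,
               se = rr$se, mean_k = rr$test$mean_k,
               control_mean_k = rr$control$mean_k,
               stringsAsFactors = FALSE)
  }))
  tests <- if (all(lengths(fits) >= 2) && length(fits) >= 2)
    compare_groups(c(fits[control], fits[others])) else NULL
  res <- list(folds = folds, tests = tests,
              rates = lapply(fits, group_rate))
  if (!is.null(json_path))
    jsonlite::write_json(res, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(tsv_path))
    utils::write.table(folds, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  c(list(fits = fits), res)
}
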