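#' Nucleosome reference frame
#'
#' Local rigid frame of one nucleosome: disc center, disc normal, dyad
#' direction (center toward dyad bp, in the disc plane) and handedness.
#' The rotation matrix \code{R} has columns (dyad direction, normal x dyad,
#' normal), so \code{R} maps frame-local coordinates to the global frame.
#'
#' @param center 3-vector, Angstrom.
#' @param normal unit 3-vector, disc normal.
#' @param dyad_dir unit 3-vector in the disc plane.
#' @param handedness -1 for the left-handed nucleosomal superhelix.
#' @return object of class \code{nucleosome_frame}.
#' @export
nucleosome_frame <- function(center, normal, dyad_dir, handedness = -1L) {
  center <- unname(as.numeric(center))
  normal <- unname(unit_vec(as.numeric(normal)))
  dyad_dir <- unname(unit_vec(as.numeric(dyad_dir)))
  if (abs(sum(normal * dyad_dir)) > 1e-8)
    stop("disc normal and dyad direction must be orthonormal", call. = FALSE)
  if (!handedness %in% c(-1L, 1L)) stop("handedness must be +/-1",
                                        call. = FALSE)
  structure(list(center = as.numeric(center), normal = normal,
                 dyad_dir = dyad_dir, handedness = as.integer(handedness),
                 R = cbind(dyad_dir, cross3(normal, dyad_dir), normal,
                           deparse.level = 0)),
            class = "nucleosome_frame")
}

#' @export
print.nucleosome_frame <- function(x, ...) {
  cat(sprintf("<nucleosome_frame> center (%.1f, %.1f, %.1f) A, normal (%.3f, %.3f, %.3f)\n",
              x$center[1], x$center[2], x$center[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Apply a rigid motion to a nucleosome frame
#' @param frame a \code{nucleosome_frame}.
#' @param motion list with \code{R}, \code{t}.
#' @return transformed frame.
#' @export
transform_frame <- function(frame, motion) {
  nucleosome_frame(center = as.numeric(motion$R %*% frame$center + motion$t),
                   normal = as.numeric(motion$R %*% frame$normal),
                   dyad_dir = as.numeric(motion$R %*% frame$dyad_dir),
                   handedness = frame$handedness)
}

#' Assign the nucleosome reference frame from a base-pair path
#'
#' The disc normal is the best-fit plane normal of the core base pairs
#' (|SHL| <= 5, so disordered termini do not bias the frame), oriented so
#' that the DNA wrap runs left-handed about it (clockwise when viewed down
#' the normal).  The center is the center of the best-fit circle of those
#' core base pairs in the disc plane -- i.e. the superhelix axis, not the
#' DNA centroid, so it sits on the disc axis and is insensitive to
#' terminal truncation.  The dyad direction points from the center to the
#' dyad base pair, projected into the disc plane.
#'
#' @param path a \code{\link{basepair_path}} with >= 60 resolved bp.
#' @return a \code{\link{nucleosome_frame}}.
#' @export
assign_frame <- function(path) {
  stopifnot(inherits(path, "basepair_path"))
  res <- path[path$resolved, , drop = FALSE]
  if (nrow(res) < 60)
    stop("need >= 60 resolved bp to assign a frame", call. = FALSE)
  core <- res[abs(res$index) <= 50, , drop = FALSE]
  if (nrow(core) < 30)
    stop("too few core (|SHL| <= 5) bp to assign a frame", call. = FALSE)
  core <- core[order(core$index), , drop = FALSE]
  P <- as.matrix(core[, c("x", "y", "z")])
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  ## The disc normal is the superhelix axis.  For a uniformly sampled
  ## helix the second differences of consecutive bp centers point exactly
  ## toward the axis (the pitch drops out), so the axis is the smallest
  ## right-singular direction of the second-difference matrix.
  dstep <- diff(core$index)
  consec <- which(dstep[-length(dstep)] == 1L & dstep[-1] == 1L)
  if (length(consec) < 10)
    stop("too few consecutive core bp to assign a frame", call. = FALSE)
  D2 <- P[consec + 2L, , drop = FALSE] - 2 * P[consec + 1L, , drop = FALSE] +
    P[consec, , drop = FALSE]
  sv2 <- svd(D2)
  if (sv2$d[1] < 1e-8 || sv2$d[2] < 1e-6 * sv2$d[1])
    stop("degenerate (collinear) base-pair path", call. = FALSE)
  nrm <- sv2$v[, 3]
  ## in-plane basis for the circle fit
  e1 <- orthonormalize_to(if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0),
                          nrm)
  e2 <- cross3(nrm, e1)
  ## circle fit (Kasa) in the plane basis
  u <- Pc %*% e1; v <- Pc %*% e2
  A <- cbind(2 * u, 2 * v, 1)
  sol <- qr.solve(A, u^2 + v^2)
  center <- ctr + sol[1] * e1 + sol[2] * e2
  ## orient the normal so the wrap is left-handed (clockwise looking down n)
  Q <- sweep(as.matrix(res[order(res$index), c("x", "y", "z")]), 2, center)
  sweep_sum <- colSums(do.call(rbind, lapply(seq_len(nrow(Q) - 1), function(i)
    cross3(Q[i, ], Q[i + 1, ]))))
  if (sum(sweep_sum * nrm) > 0) nrm <- -nrm
  ## dyad direction: toward the bp nearest index 0, in-plane
  k <- which.min(abs(res$index))
  vd <- as.numeric(res[k, c("x", "y", "z")]) - center
  vd <- vd - sum(vd * nrm) * nrm
  nucleosome_frame(center, nrm, unit_vec(vd), handedness = -1L)
}

#' Superhelical location of each base pair
#'
#' SHL is the position along the wrap in double-helix turns from the dyad,
#' with the standard 10 bp per turn: SHL(i) = i / 10 for bp index i.
#'
#' @param path a \code{\link{basepair_path}} containing the dyad (index 0).
#' @return data.frame with columns \code{index}, \code{shl} for resolved bp.
#' @export
assign_shl <- function(path) {
  stopifnot(inherits(path, "basepair_path"))
  if (!0L %in% path$index)
    stop("no dyad: path does not contain bp index 0", call. = FALSE)
  res <- path[path$resolved, , drop = FALSE]
  data.frame(index = res$index, shl = res$index / 10)
}

#' Wrapped-DNA accounting against a reference wrap length
#'
#' Counts resolved base pairs and, per terminus, how many base pairs are
#' missing relative to a reference wrap (default 147 bp, the canonical
#' nucleosome core).  Missing stretches are reported as SHL intervals.
#' Disc-face labels follow the convention that DF1 carries the larger
#' terminal deficit (the flexible side); ties assign DF1 to the positive-
#' index terminus.
#'
#' @param path a \code{\link{basepair_path}} indexed relative to the dyad.
#' @param reference reference wrap length in bp (odd; default 147).
#' @param model_id label carried into reports.
#' @return object of class \code{wrap_report}: list with \code{n_resolved},
#'   \code{reference}, \code{missing} (data.frame: terminus, side,
#'   n_missing, shl_from, shl_to), \code{shl}, \code{model_id}.
#' @export
count_wrapped_bp <- function(path, reference = 147L, model_id = "model") {
  stopifnot(inherits(path, "basepair_path"))
  reference <- as.integer(reference)
  if (reference %% 2L != 1L)
    stop("reference wrap length must be odd (dyad-centered)", call. = FALSE)
  half <- (reference - 1L) %/% 2L
  res_idx <- path$index[path$resolved]
  n_resolved <- length(res_idx)
  if (n_resolved > reference)
    stop("resolved bp exceed the reference wrap length: register mis-set",
         call. = FALSE)
  if (max(res_idx) > half || min(res_idx) < -half)
    stop("bp indices extend beyond the reference wrap: register mis-set",
         call. = FALSE)
  miss_plus <- half - max(res_idx)
  miss_minus <- half + min(res_idx)
  n_interior <- (max(res_idx) - min(res_idx) + 1L) - n_resolved
  sides <- data.frame(
    side = c("plus", "minus"),
    n_missing = c(miss_plus, miss_minus),
    shl_from = c(if (miss_plus > 0) (max(res_idx) + 1L) / 10 else NA_real_,
                 if (miss_minus > 0) -half / 10 else NA_real_),
    shl_to = c(if (miss_plus > 0) half / 10 else NA_real_,
               if (miss_minus > 0) (min(res_idx) - 1L) / 10 else NA_real_),
    stringsAsFactors = FALSE)
  df1 <- if (sides$n_missing[2] > sides$n_missing[1]) "minus" else "plus"
  sides$terminus <- ifelse(sides$side == df1, "DF1-side", "DF2-side")
  sides <- sides[order(sides$terminus),
                 c("terminus", "side", "n_missing", "shl_from", "shl_to")]
  rownames(sides) <- NULL
  structure(list(n_resolved = n_resolved,
                 reference = reference,
                 n_interior_unresolved = n_interior,
                 missing = sides,
                 shl = assign_shl(path),
                 model_id = model_id),
            class = "wrap_report")
}

#' @export
print.wrap_report <- function(x, ...) {
  cat(sprintf("<wrap_report> %s: %d/%d bp resolved\n", x$model_id,
              x$n_resolved, x$reference))
  m <- x$missing[x$missing$n_missing > 0, , drop = FALSE]
  if (nrow(m) == 0) cat("  no missing terminal bp\n")
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s: %d bp missing, SHL [%.1f, %.1f]\n", m$terminus[i],
                m$n_missing[i], m$shl_from[i], m$shl_to[i]))
  invisible(x)
}

#' Serialize a wrap report
#'
#' @param report a \code{wrap_report}.
#' @param json_path,tsv_path optional output paths; either may be NULL.
#' @return invisibly, the one-line TSV summary string.
#' @export
write_wrap_report <- function(report, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(report, "wrap_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  m <- report$missing
  fmt_iv <- function(i) if (m$n_missing[i] > 0)
    sprintf("[%.1f,%.1f]", m$shl_from[i], m$shl_to[i]) else "-"
  line <- paste(report$model_id, report$n_resolved,
                m$n_missing[m$terminus == "DF1-side"],
                m$n_missing[m$terminus == "DF2-side"],
                fmt_iv(which(m$terminus == "DF1-side")),
                fmt_iv(which(m$terminus == "DF2-side")), sep = "\t")
  header <- paste("model_id", "resolved_bp", "missing_DF1", "missing_DF2",
                  "shl_DF1", "shl_DF2", sep = "\t")
  if (!is.null(tsv_path)) writeLines(c(header, line), tsv_path)
  invisible(line)
}
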