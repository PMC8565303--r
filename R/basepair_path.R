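#' Base-pair path of a nucleosomal or linker DNA duplex
#'
#' A \code{basepair_path} holds the ordered base-pair centers of a DNA
#' duplex, indexed relative to the dyad (index 0 at the dyad base pair,
#' negative and positive toward the two termini).  It is the common
#' currency between structure reading, superhelical-location (SHL)
#' assignment and fiber geometry.
#'
#' @param centers numeric n x 3 matrix of bp centers, Angstrom.
#' @param index integer vector of bp indices relative to the dyad,
#'   consecutive over the resolved span.
#' @param resolved logical vector, one flag per bp (default all TRUE).
#' @param check validate spacing/index invariants (default TRUE).  Spacing
#'   between consecutive resolved centers must fall in 2--6 Angstrom, the
#'   B-DNA rise range with curvature tolerance; disable for deliberately
#'   jittered synthetic paths.
#'
#' @return object of class \code{basepair_path}: a data.frame with columns
#'   \code{index}, \code{x}, \code{y}, \code{z}, \code{resolved}.
#' @export
basepair_path <- function(centers, index, resolved = rep(TRUE, nrow(centers)),
                          check = TRUE) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (ncol(centers) != 3L) stop("centers must be n x 3", call. = FALSE)
  if (length(index) != nrow(centers) || length(resolved) != nrow(centers))
    stop("index/resolved length must match number of centers", call. = FALSE)
  if (any(!is.finite(centers))) stop("non-finite bp coordinates", call. = FALSE)
  index <- as.integer(index)
  if (check) {
    if (any(diff(index) != 1L))
      stop("bp indices must be consecutive integers", call. = FALSE)
    if (sum(index == 0L) > 1L)
      stop("more than one dyad (index 0) base pair", call. = FALSE)
    res <- which(resolved)
    if (length(res) > 1) {
      d <- sqrt(rowSums((centers[res[-1], , drop = FALSE] -
                         centers[res[-length(res)], , drop = FALSE])^2))
      step <- diff(res)
      bad <- step == 1L & (d < 2 | d > 6)
      if (any(bad))
        stop(sprintf("%d consecutive bp spacing(s) outside 2-6 Angstrom",
                     sum(bad)), call. = FALSE)
    }
  }
  out <- data.frame(index = index, x = centers[, 1], y = centers[, 2],
                    z = centers[, 3], resolved = as.logical(resolved))
  class(out) <- c("basepair_path", "data.frame")
  out
}

#' @export
print.basepair_path <- function(x, ...) {
  cat(sprintf("<basepair_path> %d bp (index %d..%d), %d resolved\n",
              nrow(x), min(x$index), max(x$index), sum(x$resolved)))
  invisible(x)
}

bp_centers <- function(path, resolved_only = TRUE) {
  stopifnot(inherits(path, "basepair_path"))
  if (resolved_only) path <- path[path$resolved, , drop = FALSE]
  as.matrix(path[, c("x", "y", "z")])
}

#' Apply a rigid motion to a base-pair path
#'
#' @param path a \code{basepair_path}.
#' @param motion list with rotation \code{R} and translation \code{t}
#'   (e.g. from \code{\link{random_rigid_motion}}).
#' @return transformed \code{basepair_path}.
#' @export
transform_path <- function(path, motion) {
  xyz <- apply_rigid(as.matrix(path[, c("x", "y", "z")]), motion)
  basepair_path(xyz, path$index, path$resolved, check = FALSE)
}
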