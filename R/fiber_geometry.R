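## Two-start fiber packing parameters.
##
## The di-nucleosome is the structural unit of the two-start zigzag fiber:
## nucleosomes (1,2), (3,4), ... along the DNA path form units; consecutive
## units are related by a rotation beta about the fiber axis and an axial
## shift d; the two members of a unit sit x apart; gamma measures how far
## each nucleosome's linker entry/exit geometry is opened relative to the
## fully wrapped straight-linker reference.

.IDEAL_NCP <- list(n_bp = 147L, radius = 41.9, pitch = 25.9, turns = 1.65)

## analytic tangent of the ideal left-handed superhelix at parameter theta
.superhelix_tangent <- function(theta, radius, pitch) {
  unit_vec(c(-radius * sin(theta), -radius * cos(theta), pitch / (2 * pi)))
}

#' Reference DNA entry/exit angle of the fully wrapped nucleosome
#'
#' Angle between the entering and exiting linker directions (each oriented
#' away from the nucleosome) for a canonical, fully wrapped core with
#' straight tangential linkers.  This is the gamma = 0 baseline: reported
#' entry/exit angles are measured relative to it.
#'
#' @param radius,pitch,turns superhelix constants (Angstrom, Angstrom per
#'   turn, turns); defaults are the canonical nucleosome-core geometry.
#' @return angle in degrees.
#' @export
reference_entry_exit_angle <- function(radius = .IDEAL_NCP$radius,
                                       pitch = .IDEAL_NCP$pitch,
                                       turns = .IDEAL_NCP$turns) {
  th <- turns * pi  # half the total wrap angle
  exit_away <- .superhelix_tangent(th, radius, pitch)
  entry_away <- -.superhelix_tangent(-th, radius, pitch)
  angle_between(entry_away, exit_away)
}

#' Partition an ordered fiber into di-nucleosome units
#'
#' Units are consecutive pairs (1,2), (3,4), ... in DNA-path order.  An odd
#' trailing nucleosome is excluded from unit statistics and reported via a
#' warning and the \code{excluded} attribute.
#'
#' @param frames ordered list of \code{\link{nucleosome_frame}}s (>= 4).
#' @return list of units, each with \code{members} (ordinals),
#'   \code{member_centers} (2 x 3), \code{center}, \code{pair_dir} (unit
#'   vector member 1 -> member 2) and \code{frame} (orthonormal 3 x 3 built
#'   from pair direction, mean disc normal, and their cross product).
#'   Attribute \code{excluded} lists any excluded ordinal.
#' @export
partition_units <- function(frames) {
  n <- length(frames)
  if (n < 4)
    stop("need >= 4 nucleosomes for inter-unit statistics", call. = FALSE)
  excluded <- integer(0)
  if (n %% 2L == 1L) {
    excluded <- n
    warning(sprintf("odd nucleosome count: ordinal %d excluded from units", n))
  }
  m <- n %/% 2L
  units <- vector("list", m)
  for (i in seq_len(m)) {
    f1 <- frames[[2 * i - 1]]; f2 <- frames[[2 * i]]
    pc <- rbind(f1$center, f2$center)
    e1 <- unit_vec(f2$center - f1$center)
    nbar <- f1$normal + f2$normal
    e2 <- orthonormalize_to(nbar, e1)
    units[[i]] <- list(members = c(2L * i - 1L, 2L * i),
                       member_centers = pc,
                       center = colMeans(pc),
                       pair_dir = e1,
                       frame = cbind(e1, e2, cross3(e1, e2),
                                     deparse.level = 0))
  }
  attr(units, "excluded") <- excluded
  units
}

#' Estimate the fiber axis from di-nucleosome unit centers
#'
#' First principal direction of the unit centers, oriented from the first
#' toward the last unit; the axis point is the centroid of unit centers.
#'
#' @param units output of \code{\link{partition_units}} (>= 2 units).
#' @return list with \code{direction} (unit 3-vector) and \code{point}.
#' @export
estimate_fiber_axis <- function(units) {
  if (length(units) < 2) stop("need >= 2 units to estimate an axis",
                              call. = FALSE)
  C <- do.call(rbind, lapply(units, `[[`, "center"))
  ctr <- colMeans(C)
  Cc <- sweep(C, 2, ctr)
  if (max(abs(Cc)) < 1e-9)
    stop("unit centers coincide: fiber axis undefined", call. = FALSE)
  dir <- svd(Cc)$v[, 1]
  span <- units[[length(units)]]$center - units[[1]]$center
  if (sum(dir * span) < 0) dir <- -dir
  list(direction = unit_vec(dir), point = ctr)
}

#' Intra-unit inter-nucleosome distance x
#'
#' Center-to-center distance between the two nucleosomes of a unit,
#' reported in nm.
#'
#' @param unit one element of \code{\link{partition_units}} output.
#' @param frames unused; accepted for call-site symmetry.
#' @return distance in nm.
#' @export
compute_x <- function(unit, frames = NULL) {
  d <- sqrt(sum((unit$member_centers[2, ] - unit$member_centers[1, ])^2))
  if (d < 1e-9) warning("coincident unit members: x = 0 violates x > 0")
  d / 10
}

#' Inter-unit rotation beta and axial shift d
#'
#' d is the magnitude of the center displacement between consecutive units
#' projected on the fiber axis (Angstrom).  beta is the angle between the
#' two units' intra-unit (member 1 -> member 2) directions after projecting
#' both onto the plane perpendicular to the axis (degrees, [0, 180)).
#'
#' @param unit_a,unit_b consecutive units.
#' @param axis output of \code{\link{estimate_fiber_axis}}.
#' @return list with \code{beta} (degrees) and \code{d} (Angstrom).
#' @export
compute_beta_d <- function(unit_a, unit_b, axis) {
  a <- axis$direction
  d_val <- abs(sum((unit_b$center - unit_a$center) * a))
  proj <- function(v) {
    p <- v - sum(v * a) * a
    if (sqrt(sum(p^2)) < 1e-8)
      stop("unit pair direction parallel to the fiber axis: beta undefined",
           call. = FALSE)
    unit_vec(p)
  }
  beta <- angle_between(proj(unit_a$pair_dir), proj(unit_b$pair_dir))
  if (beta >= 180) beta <- 0
  list(beta = beta, d = d_val)
}

## least-squares direction through a linker segment, oriented away from the
## nucleosome center
.linker_direction <- function(seg, center) {
  xyz <- if (inherits(seg, "basepair_path")) bp_centers(seg) else as.matrix(seg)
  if (nrow(xyz) < 4)
    stop("linker segment too short (< 4 bp) to fit a direction",
         call. = FALSE)
  d <- fit_line_direction(xyz)
  dist2 <- rowSums(sweep(xyz, 2, center)^2)
  far <- xyz[which.max(dist2), ] - xyz[which.min(dist2), ]
  if (sum(d * far) < 0) d <- -d
  d
}

#' DNA entry/exit angle gamma of one nucleosome
#'
#' The raw angle between the entering and exiting linker directions (each a
#' least-squares line through its segment's bp centers, oriented away from
#' the nucleosome) minus the fully wrapped straight-linker reference angle
#' (\code{\link{reference_entry_exit_angle}}), clipped to [0, 180).  A
#' canonical full 147-bp wrap with straight tangential linkers therefore
#' scores gamma = 0.
#'
#' @param frame the nucleosome's \code{\link{nucleosome_frame}}.
#' @param entry,exit linker segments (n x 3 matrices or
#'   \code{basepair_path}s of >= 4 bp) entering and leaving the nucleosome.
#' @param reference_angle baseline angle in degrees (default the canonical
#'   full-wrap value).
#' @return list with \code{gamma} (degrees, relative) and \code{raw_angle}
#'   (degrees, absolute inter-linker angle).
#' @export
compute_gamma <- function(frame, entry, exit,
                          reference_angle = reference_entry_exit_angle()) {
  de <- .linker_direction(entry, frame$center)
  dx <- .linker_direction(exit, frame$center)
  raw <- angle_between(de, dx)
  gamma <- min(max(raw - reference_angle, 0), 180 - 1e-12)
  list(gamma = gamma, raw_angle = raw)
}

#' Packing-parameter summary of a fiber
#'
#' Computes per-sample values and mean/SD (n - 1 denominator) of the four
#' packing parameters: x per di-nucleosome unit (nm), beta and d per
#' consecutive unit pair (degrees, Angstrom), and gamma per interior
#' nucleosome (degrees; terminal nucleosomes lack one linker and carry no
#' gamma sample).  gamma is omitted when no linker paths are available
#' (e.g. frames read from a bare frames CSV).
#'
#' @param frames ordered list of \code{\link{nucleosome_frame}}s (>= 4).
#' @param linkers optional list of n - 1 linkers as produced by
#'   \code{\link{build_fiber}}: each a list with straight half-segments
#'   \code{exit} (leaving nucleosome i) and \code{entry} (entering i + 1).
#' @param reference_angle baseline for gamma, degrees.
#' @return object of class \code{fiber_parameters}: per-sample vectors
#'   \code{x}, \code{beta}, \code{d}, \code{gamma}, a \code{summary}
#'   data.frame (parameter, n, mean, sd, units) and \code{excluded}
#'   ordinals.
#' @export
summarize_parameters <- function(frames, linkers = NULL,
                                 reference_angle = reference_entry_exit_angle()) {
  units <- partition_units(frames)
  axis <- estimate_fiber_axis(units)
  x <- vapply(units, compute_x, numeric(1))
  m <- length(units)
  beta <- numeric(0); d <- numeric(0)
  if (m >= 2) {
    bd <- lapply(seq_len(m - 1), function(i)
      compute_beta_d(units[[i]], units[[i + 1]], axis))
    beta <- vapply(bd, `[[`, numeric(1), "beta")
    d <- vapply(bd, `[[`, numeric(1), "d")
  }
  gamma <- NULL
  n <- length(frames)
  if (!is.null(linkers)) {
    if (length(linkers) != n - 1)
      stop("expected ", n - 1, " linkers, got ", length(linkers),
           call. = FALSE)
    gamma <- vapply(seq(2, n - 1), function(j)
      compute_gamma(frames[[j]], entry = linkers[[j - 1]]$entry,
                    exit = linkers[[j]]$exit,
                    reference_angle = reference_angle)$gamma,
      numeric(1))
  }
  summ <- function(v) c(n = length(v), mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  tab <- rbind(x = summ(x), beta = summ(beta), d = summ(d),
               gamma = if (!is.null(gamma)) summ(gamma) else
                 c(n = 0, mean = NA_real_, sd = NA_real_))
  summary <- data.frame(parameter = rownames(tab), tab,
                        units = c("nm", "deg", "A", "deg"),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(x = x, beta = beta, d = d, gamma = gamma,
                 summary = summary,
                 excluded = attr(units, "excluded")),
            class = "fiber_parameters")
}

#' @export
print.fiber_parameters <- function(x, ...) {
  cat("<fiber_parameters>\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    if (s$n[i] == 0) next
    cat(sprintf("  %-5s mean %8.3f %s  (sd %s, n = %d)\n", s$parameter[i],
                s$mean[i], s$units[i],
                ifelse(is.na(s$sd[i]), "NA", sprintf("%.3f", s$sd[i])),
                s$n[i]))
  }
  if (length(x$excluded))
    cat("  excluded trailing nucleosome(s):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize fiber parameters
#'
#' @param fp a \code{fiber_parameters} object.
#' @param json_path,tsv_path optional output paths.
#' @return invisibly, \code{fp}.
#' @export
write_fiber_parameters <- function(fp, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fp, "fiber_parameters"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(fp), json_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (!is.null(tsv_path))
    utils::write.table(fp$summary, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fp)
}
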