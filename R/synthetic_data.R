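## Synthetic-data generators.  These produce idealized inputs with known
## ground truth -- superhelical nucleosome DNA paths, two-start fibers with
## optional Gaussian jitter, and saturating-exponential digestion time
## courses -- so every analysis stage can be exercised and its estimators
## validated without any external data.

## evaluate expr with a temporary RNG seed, restoring global RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Ideal nucleosomal DNA path
#'
#' Base-pair centers on an ideal left-handed superhelix (canonical
#' nucleosome-core geometry by default: 41.9 Angstrom radius, 25.9
#' Angstrom pitch per turn, 1.65 turns over 147 bp), uniformly spaced in
#' arc angle, dyad at the midpoint (bp index 0).  Optional truncation
#' removes terminal bp from one side, emulating a disordered terminus.
#'
#' @param n_bp number of base pairs (default 147; odd values keep the dyad
#'   exactly central).
#' @param radius superhelix radius, Angstrom (> 0).
#' @param pitch superhelix pitch, Angstrom per turn (> 0).
#' @param turns number of superhelical turns.
#' @param truncation NULL or list(side = "plus"/"minus", n_bp = count) --
#'   bp removed from the positive- or negative-index terminus.
#' @return a \code{\link{basepair_path}}.
#' @export
make_ideal_ncp_path <- function(n_bp = 147L, radius = 41.9, pitch = 25.9,
                                turns = 1.65, truncation = NULL) {
  n_bp <- as.integer(n_bp)
  if (n_bp < 10) stop("need >= 10 bp", call. = FALSE)
  if (radius <= 0 || pitch <= 0) stop("radius and pitch must be positive",
                                      call. = FALSE)
  delta <- turns * 2 * pi / (n_bp - 1)
  c_ <- pitch / (2 * pi)
  spacing <- delta * sqrt(radius^2 + c_^2)
  if (spacing < 2 || spacing > 6)
    stop(sprintf("turns/n_bp give %.2f Angstrom bp spacing, outside 2-6",
                 spacing), call. = FALSE)
  index <- seq_len(n_bp) - 1L - (n_bp - 1L) %/% 2L
  theta <- (seq_len(n_bp) - 1 - (n_bp - 1) / 2) * delta
  xyz <- cbind(radius * cos(theta), -radius * sin(theta), c_ * theta)
  if (!is.null(truncation)) {
    side <- match.arg(truncation$side, c("plus", "minus"))
    k <- as.integer(truncation$n_bp)
    if (k < 0 || k >= n_bp) stop("invalid truncation count", call. = FALSE)
    keep <- if (side == "plus") seq_len(n_bp - k) else (k + 1L):n_bp
    xyz <- xyz[keep, , drop = FALSE]
    index <- index[keep]
  }
  basepair_path(xyz, index)
}

#' Jitter specification for synthetic fibers
#'
#' @param center_sd Gaussian SD on nucleosome centers, Angstrom.
#' @param orient_sd Gaussian SD on nucleosome orientations, degrees
#'   (rotation by N(0, sd) about a uniformly random axis).
#' @param linker_sd Gaussian SD on linker bp centers, Angstrom.
#' @param seed integer seed; all draws are a deterministic function of it.
#' @return object of class \code{jitter_spec}.
#' @export
jitter_spec <- function(center_sd = 0, orient_sd = 0, linker_sd = 0,
                        seed = 1L) {
  if (center_sd < 0 || orient_sd < 0 || linker_sd < 0)
    stop("jitter SDs must be >= 0", call. = FALSE)
  structure(list(center_sd = center_sd, orient_sd = orient_sd,
                 linker_sd = linker_sd, seed = as.integer(seed)),
            class = "jitter_spec")
}

#' Synthetic two-start fiber with known ground truth
#'
#' Noise-free placement is identical to \code{\link{build_fiber}}; jitter
#' is applied after placement and is a deterministic function of the seed.
#' The ground-truth build spec stays attached as \code{$spec}.
#'
#' @param build a \code{\link{fiber_build_spec}}.
#' @param jitter NULL (bitwise-identical to \code{build_fiber}) or a
#'   \code{\link{jitter_spec}}.
#' @return a \code{fiber_model}.
#' @export
make_synthetic_fiber <- function(build, jitter = NULL) {
  model <- build_fiber(build)
  if (is.null(jitter)) return(model)
  stopifnot(inherits(jitter, "jitter_spec"))
  .with_seed(jitter$seed, {
    model$frames <- lapply(model$frames, function(f) {
      ctr <- f$center + stats::rnorm(3, 0, jitter$center_sd)
      nrm <- f$normal; dyd <- f$dyad_dir
      if (jitter$orient_sd > 0) {
        ax <- unit_vec(stats::rnorm(3))
        Rp <- rotation_about(ax, stats::rnorm(1, 0, jitter$orient_sd))
        nrm <- as.numeric(Rp %*% nrm)
        dyd <- as.numeric(Rp %*% dyd)
      }
      nucleosome_frame(ctr, nrm, dyd, f$handedness)
    })
    if (!is.null(model$linkers) && jitter$linker_sd > 0) {
      model$linkers <- lapply(model$linkers, function(l) {
        l$exit <- l$exit + matrix(stats::rnorm(length(l$exit), 0,
                                               jitter$linker_sd),
                                  nrow(l$exit))
        l$entry <- l$entry + matrix(stats::rnorm(length(l$entry), 0,
                                                 jitter$linker_sd),
                                    nrow(l$entry))
        l
      })
    }
  })
  model$provenance <- sprintf("synthetic (jitter: %.2g A / %.2g deg / %.2g A, seed %d)",
                              jitter$center_sd, jitter$orient_sd,
                              jitter$linker_sd, jitter$seed)
  model
}

#' Synthetic digestion time course
#'
#' Saturating exponential y = C + A (1 - exp(-k t)) with optional seeded
#' Gaussian noise, clipped to [0, 1.1] (gel quantification can slightly
#' exceed full digestion).
#'
#' @param C baseline fraction.
#' @param A amplitude fraction.
#' @param k rate constant, per minute (> 0).
#' @param times sampling times in minutes, strictly increasing (default
#'   every 15 min to 90 min).
#' @param noise_sd Gaussian noise SD on y.
#' @param seed integer seed (NULL = use current RNG state).
#' @param condition,replicate labels carried on the result.
#' @return a \code{\link{digestion_timecourse}}.
#' @export
make_timecourse <- function(C, A, k, times = seq(0, 90, by = 15),
                            noise_sd = 0, seed = NULL,
                            condition = "synthetic", replicate = "r1") {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  y <- C + A * (1 - exp(-k * times))
  if (noise_sd > 0)
    y <- .with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  y <- pmin(pmax(y, 0), 1.1)
  digestion_timecourse(times, y, condition = condition,
                       replicate = replicate)
}
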