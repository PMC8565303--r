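#' Reference packing-parameter sets
#'
#' Packing parameters used throughout examples and tests: the H2A.Z
#' 12 x 167-bp fiber, the canonical H2A fiber (twisted conformation) and
#' the tetra-nucleosome crystal geometry (beta/d only; its x and gamma are
#' not part of the set).
#'
#' @return data.frame with columns \code{set}, \code{x_nm},
#'   \code{beta_deg}, \code{d_A}, \code{gamma_deg}.
#' @export
fiber_parameter_sets <- function() {
  data.frame(set = c("H2A.Z", "H2A", "tetra"),
             x_nm = c(14.9, 14.3, NA),
             beta_deg = c(19.7, 12, 23.3),
             d_A = c(59.5, 61, 38.9),
             gamma_deg = c(27.5, 9.7, NA),
             stringsAsFactors = FALSE)
}

#' Fiber build specification
#'
#' Parameters of an idealized two-start zigzag fiber: \code{n} nucleosomes
#' at nucleosome repeat length \code{nrl}, intra-unit center distance
#' \code{x} (nm), per-unit-step rotation \code{beta} (degrees) and axial
#' shift \code{d} (Angstrom), and DNA entry/exit angle \code{gamma}
#' (degrees, relative to the fully wrapped straight-linker reference).
#'
#' @param n number of nucleosomes (>= 2).
#' @param x intra-unit inter-nucleosome distance, nm.
#' @param beta inter-unit rotation, degrees.
#' @param d inter-unit axial shift, Angstrom.
#' @param gamma DNA entry/exit angle, degrees.
#' @param nrl nucleosome repeat length, bp (>= 147; default 167).
#' @param template optional \code{structure_model} of one nucleosome used
#'   to decorate the frames.
#' @param linker_style only \code{"straight"} is supported.
#' @return object of class \code{fiber_build_spec}.
#' @export
fiber_build_spec <- function(n, x, beta, d, gamma, nrl = 167L,
                             template = NULL, linker_style = "straight") {
  linker_style <- match.arg(linker_style, "straight")
  n <- as.integer(n); nrl <- as.integer(nrl)
  if (n < 2) stop("need n >= 2 nucleosomes", call. = FALSE)
  if (nrl < 147) stop("NRL must be >= 147 bp", call. = FALSE)
  if (x <= 0) stop("x must be positive", call. = FALSE)
  if (beta < 0 || beta >= 180) stop("beta must lie in [0, 180)", call. = FALSE)
  if (d < 0) stop("d must be non-negative", call. = FALSE)
  if (gamma < 0 || gamma >= 120)
    stop("gamma must lie in [0, 120)", call. = FALSE)
  structure(list(n = n, nrl = nrl, x = x, beta = beta, d = d, gamma = gamma,
                 template = template, linker_style = linker_style),
            class = "fiber_build_spec")
}

## local (frame-relative) geometry of one idealized wrapped nucleosome:
## wrap path in frame coordinates plus entry/exit stub anchors and
## away-directions opened by gamma about the fully wrapped baseline
.local_nucleosome_geometry <- function(gamma) {
  g <- .IDEAL_NCP
  path <- make_ideal_ncp_path()
  f0 <- assign_frame(path)
  xyz <- bp_centers(path)
  q <- sweep(xyz, 2, f0$center) %*% f0$R  # local coords (rows)
  th <- g$turns * pi
  exit_away_g <- .superhelix_tangent(th, g$radius, g$pitch)
  entry_away_g <- -.superhelix_tangent(-th, g$radius, g$pitch)
  ## to local frame
  a0 <- as.numeric(t(f0$R) %*% entry_away_g)
  b0 <- as.numeric(t(f0$R) %*% exit_away_g)
  w <- cross3(a0, b0)
  if (sqrt(sum(w^2)) < 1e-9) w <- c(0, 0, 1)
  a <- as.numeric(rotation_about(w, -gamma / 2) %*% a0)
  b <- as.numeric(rotation_about(w, +gamma / 2) %*% b0)
  list(path_local = q,
       index = path$index,
       entry_anchor = q[1, ], exit_anchor = q[nrow(q), ],
       entry_away = a, exit_away = b)
}

#' Build an idealized two-start zigzag fiber
#'
#' Di-nucleosome units are placed by a screw operation: unit i + 1 is unit
#' i rotated by beta about the fiber axis and shifted d along it.  Within
#' each unit the two members sit x apart, disc normals along the fiber
#' axis, odd ordinals forming one stack and even ordinals the other.
#' Linkers are straight bp paths: each inter-nucleosome linker is stored as
#' two half-segments leaving/entering the flanking nucleosomes along
#' entry/exit directions opened by gamma relative to the fully wrapped
#' baseline, so the parameter estimator recovers the build parameters
#' exactly in the noise-free case.
#'
#' @param spec a \code{\link{fiber_build_spec}}.
#' @return object of class \code{fiber_model}: list with \code{frames}
#'   (ordered \code{nucleosome_frame}s), \code{linkers} (n - 1 lists with
#'   \code{exit}/\code{entry} bp matrices), \code{axis}, \code{spec},
#'   \code{provenance}, and the local wrap geometry used for decoration.
#'   If non-neighboring discs come closer than 60 Angstrom a steric
#'   warning is raised (the model is still returned).
#' @export
build_fiber <- function(spec) {
  stopifnot(inherits(spec, "fiber_build_spec"))
  loc <- .local_nucleosome_geometry(spec$gamma)
  x_A <- spec$x * 10
  frames <- vector("list", spec$n)
  for (j in seq_len(spec$n)) {
    i <- (j + 1L) %/% 2L
    s <- if (j %% 2L == 1L) -1 else 1
    phi <- (i - 1) * spec$beta
    Rz <- rotation_about(c(0, 0, 1), phi)
    u <- as.numeric(Rz %*% c(1, 0, 0))
    center <- c(0, 0, (i - 1) * spec$d) + s * (x_A / 2) * u
    Rj <- Rz %*% (if (s > 0) diag(3) else rotation_about(c(0, 0, 1), 180))
    frames[[j]] <- nucleosome_frame(center, normal = Rj[, 3],
                                    dyad_dir = Rj[, 1])
  }
  ## straight linker half-segments (3.4 A rise per bp)
  n_half <- (spec$nrl - 147L) %/% 2L
  linkers <- NULL
  if (n_half >= 4) {
    linkers <- vector("list", spec$n - 1L)
    place <- function(frame, pt) as.numeric(frame$R %*% pt + frame$center)
    dirg <- function(frame, v) as.numeric(frame$R %*% v)
    for (j in seq_len(spec$n - 1L)) {
      f1 <- frames[[j]]; f2 <- frames[[j + 1]]
      a1 <- place(f1, loc$exit_anchor); b1 <- dirg(f1, loc$exit_away)
      a2 <- place(f2, loc$entry_anchor); b2 <- dirg(f2, loc$entry_away)
      ex <- t(sapply(seq_len(n_half), function(k) a1 + 3.4 * k * b1))
      en <- t(sapply(rev(seq_len(n_half)), function(k) a2 + 3.4 * k * b2))
      linkers[[j]] <- list(exit = ex, entry = en)
    }
  } else if (spec$nrl > 147L) {
    warning("linker shorter than 8 bp: gamma is not encoded in the model")
  }
  ## steric check between non-neighboring discs
  C <- do.call(rbind, lapply(frames, `[[`, "center"))
  if (spec$n >= 3) {
    D <- as.matrix(stats::dist(C))
    off <- abs(row(D) - col(D)) > 1
    if (any(D[off] < 60))
      warning("steric overlap: non-neighboring nucleosome centers < 60 A apart")
  }
  structure(list(frames = frames, linkers = linkers,
                 axis = list(direction = c(0, 0, 1), point = c(0, 0, 0)),
                 spec = spec, provenance = "built", local = loc),
            class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat(sprintf("<fiber_model> %d nucleosomes, %d linkers (%s)\n",
              length(x$frames),
              if (is.null(x$linkers)) 0L else length(x$linkers),
              x$provenance))
  invisible(x)
}

## disc envelope half-extent along direction w for a nucleosome with unit
## normal nrm: cylinder of radius r, half-thickness h
.disc_extent <- function(nrm, w, r = 55, h = 27.5) {
  cth <- abs(sum(nrm * w))
  h * cth + r * sqrt(max(0, 1 - cth^2))
}

#' Fiber length and width from the disc envelope
#'
#' Each nucleosome is modeled as a disc of 11 nm diameter and 5.5 nm
#' thickness in its frame.  Length is the extent of the disc envelopes
#' projected on the fiber axis; width is the maximal envelope extent over
#' directions perpendicular to the axis (sampled at 0.5 degree steps).
#'
#' @param model a \code{fiber_model}, or any list of
#'   \code{nucleosome_frame}s via \code{frames}.
#' @param frames alternative direct input: list of frames.
#' @param axis optional axis (list with \code{direction}); defaults to the
#'   model's stored axis or, failing that, the estimated axis.
#' @return named numeric vector \code{c(length_nm, width_nm)}.
#' @export
measure_dimensions <- function(model = NULL, frames = NULL, axis = NULL) {
  if (is.null(frames)) {
    stopifnot(inherits(model, "fiber_model"))
    frames <- model$frames
    if (is.null(axis)) axis <- model$axis
  }
  if (is.null(axis)) {
    axis <- if (length(frames) >= 4) estimate_fiber_axis(partition_units(frames))
            else list(direction = c(0, 0, 1))
  }
  a <- unit_vec(axis$direction)
  C <- do.call(rbind, lapply(frames, `[[`, "center"))
  N <- do.call(rbind, lapply(frames, `[[`, "normal"))
  proj_extent <- function(w) {
    cw <- C %*% w
    e <- vapply(seq_len(nrow(N)), function(j) .disc_extent(N[j, ], w),
                numeric(1))
    max(cw + e) - min(cw - e)
  }
  len <- proj_extent(a)
  ## perpendicular basis
  seed_v <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- orthonormalize_to(seed_v, a)
  e2 <- cross3(a, e1)
  phis <- seq(0, pi, by = pi / 360)
  wid <- max(vapply(phis, function(p)
    proj_extent(cos(p) * e1 + sin(p) * e2), numeric(1)))
  c(length_nm = len / 10, width_nm = wid / 10)
}

## derive the nucleosome frame of a template structure (via its DNA duplex)
.template_frame <- function(template, dyad = "auto") {
  fr <- try(assign_frame(extract_dna_duplex(template, dyad = dyad)),
            silent = TRUE)
  if (inherits(fr, "try-error"))
    stop("template frame underivable: template must contain one nucleosome's DNA duplex",
         call. = FALSE)
  fr
}

.CHAIN_POOL <- c(LETTERS, letters, as.character(0:9))

#' Decorate fiber frames with a template nucleosome structure
#'
#' Rigidly maps a single-nucleosome template onto every frame of the fiber
#' (frame-to-frame superposition: atoms are expressed in the template's own
#' nucleosome frame, then re-expressed in each target frame).  Chains are
#' relabeled from a 62-letter pool so that (chain, resno, atom) triples
#' stay unique; linker bp are appended as P pseudo-atoms on a final chain.
#'
#' @param model a \code{fiber_model}.
#' @param template a \code{structure_model} of one nucleosome with a
#'   derivable frame (its DNA duplex is used).
#' @param dyad dyad locator passed to \code{\link{extract_dna_duplex}} for
#'   the template.
#' @param include_linkers append linker pseudo-atoms (default TRUE).
#' @return a \code{structure_model} of the whole fiber.
#' @export
decorate <- function(model, template, dyad = "auto", include_linkers = TRUE) {
  stopifnot(inherits(model, "fiber_model"),
            inherits(template, "structure_model"))
  tf <- .template_frame(template, dyad = dyad)
  ta <- template$atoms
  loc_xyz <- sweep(as.matrix(ta[, c("x", "y", "z")]), 2, tf$center) %*% tf$R
  tpl_chains <- unique(ta$chain)
  n_cp <- length(model$frames)
  need <- n_cp * length(tpl_chains) + as.integer(include_linkers)
  if (need > length(.CHAIN_POOL))
    stop("too many chains to relabel uniquely (", need, " needed)",
         call. = FALSE)
  pieces <- vector("list", n_cp)
  ci <- 0L
  for (k in seq_len(n_cp)) {
    fr <- model$frames[[k]]
    g <- sweep(loc_xyz %*% t(fr$R), 2, fr$center, `+`)
    at <- ta
    at$x <- g[, 1]; at$y <- g[, 2]; at$z <- g[, 3]
    map <- stats::setNames(.CHAIN_POOL[ci + seq_along(tpl_chains)],
                           tpl_chains)
    at$chain <- unname(map[at$chain])
    ci <- ci + length(tpl_chains)
    pieces[[k]] <- at
  }
  if (include_linkers && !is.null(model$linkers)) {
    lk <- do.call(rbind, lapply(model$linkers, function(l)
      rbind(l$exit, l$entry)))
    pieces[[n_cp + 1]] <- data.frame(chain = .CHAIN_POOL[ci + 1L],
                                     resno = seq_len(nrow(lk)),
                                     resid = "DA", elety = "P",
                                     x = lk[, 1], y = lk[, 2], z = lk[, 3],
                                     stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, pieces),
                  source = paste0("decorated fiber (", n_cp, " copies of ",
                                  template$source, ")"))
}

#' Write a fiber as an atomic structure
#'
#' Without a template, each nucleosome is represented by the synthetic
#' duplex of its wrapped DNA path (two C1' pseudo-strands per nucleosome,
#' register preserved); with a template, \code{\link{decorate}} is used.
#'
#' @param model a \code{fiber_model}.
#' @param template optional single-nucleosome \code{structure_model}.
#' @param include_linkers append linker pseudo-atoms.
#' @return a \code{structure_model}.
#' @export
fiber_to_structure <- function(model, template = NULL,
                               include_linkers = TRUE) {
  stopifnot(inherits(model, "fiber_model"))
  if (!is.null(template))
    return(decorate(model, template, include_linkers = include_linkers))
  if (is.null(model$local))
    stop("model carries no local wrap geometry to place", call. = FALSE)
  n_cp <- length(model$frames)
  if (2L * n_cp + 1L > length(.CHAIN_POOL))
    stop("too many nucleosomes for unique chain labels", call. = FALSE)
  pieces <- vector("list", n_cp)
  for (k in seq_len(n_cp)) {
    fr <- model$frames[[k]]
    g <- sweep(model$local$path_local %*% t(fr$R), 2, fr$center, `+`)
    pth <- basepair_path(g, model$local$index, check = FALSE)
    dm <- path_to_duplex_model(pth,
                               chains = .CHAIN_POOL[c(2L * k - 1L, 2L * k)],
                               source = "fiber nucleosome")
    pieces[[k]] <- dm$atoms
  }
  if (include_linkers && !is.null(model$linkers)) {
    lk <- do.call(rbind, lapply(model$linkers, function(l)
      rbind(l$exit, l$entry)))
    pieces[[n_cp + 1]] <- data.frame(chain = .CHAIN_POOL[2L * n_cp + 1L],
                                     resno = seq_len(nrow(lk)),
                                     resid = "DA", elety = "P",
                                     x = lk[, 1], y = lk[, 2], z = lk[, 3],
                                     stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, pieces),
                  source = sprintf("synthetic fiber (%d nucleosomes)", n_cp))
}

#' Recover nucleosome frames from a fiber structure file
#'
#' Groups DNA chains in order of appearance into consecutive strand pairs
#' (the layout written by \code{\link{fiber_to_structure}}), extracts each
#' pair's duplex and assigns its frame.
#'
#' @param model a \code{structure_model} of a fiber.
#' @return ordered list of \code{nucleosome_frame}s.
#' @export
fiber_frames_from_structure <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  ref <- a[a$elety %in% c("C1'", "C1*") & a$resid %in% .DNA_RESIDUES, ,
           drop = FALSE]
  chains <- unique(ref$chain)  # order of appearance
  if (length(chains) < 2 || length(chains) %% 2L != 0L)
    stop("expected an even number of DNA strand chains", call. = FALSE)
  lapply(seq_len(length(chains) / 2), function(k) {
    assign_frame(extract_dna_duplex(model,
                                    chains = chains[c(2 * k - 1, 2 * k)]))
  })
}

#' Read/write nucleosome frames as CSV
#'
#' Plain CSV interchange for frames: columns \code{ordinal}, \code{cx},
#' \code{cy}, \code{cz} (Angstrom), \code{nx}, \code{ny}, \code{nz} (disc
#' normal), \code{dx}, \code{dy}, \code{dz} (dyad direction).
#'
#' @param frames ordered list of \code{nucleosome_frame}s.
#' @param path CSV path.
#' @return \code{read_frames_csv} returns the list of frames;
#'   \code{write_frames_csv} returns the path invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  df <- do.call(rbind, lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    data.frame(ordinal = i, cx = f$center[1], cy = f$center[2],
               cz = f$center[3], nx = f$normal[1], ny = f$normal[2],
               nz = f$normal[3], dx = f$dyad_dir[1], dy = f$dyad_dir[2],
               dz = f$dyad_dir[3])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$ordinal), , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    nucleosome_frame(center = c(df$cx[i], df$cy[i], df$cz[i]),
                     normal = c(df$nx[i], df$ny[i], df$nz[i]),
                     dyad_dir = c(df$dx[i], df$dy[i], df$dz[i])))
}
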