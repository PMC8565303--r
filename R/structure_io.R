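#' Atomic structure container
#'
#' Minimal atom-table container used throughout the package.  Atoms are a
#' data.frame with columns \code{chain}, \code{resno}, \code{resid},
#' \code{elety} (atom name), \code{x}, \code{y}, \code{z} (Angstrom).
#' Hetero atoms, waters and non-first alternate locations are dropped on
#' reading; geometry downstream uses backbone reference atoms only.
#'
#' @param atoms data.frame with the columns above.
#' @param source free-text label recording where the model came from.
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(atoms, source = "unknown") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  atoms <- atoms[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom name) triples in model",
         call. = FALSE)
  structure(list(atoms = atoms, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s) [%s] (source: %s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              paste(sort(unique(x$atoms$chain)), collapse = ","), x$source))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model a \code{structure_model}.
#' @export
n_atoms <- function(model) nrow(model$atoms)

.guess_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(format, c("pdb", "mmcif"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
}

#' Read an atomic structure (PDB or mmCIF)
#'
#' Thin wrapper over \code{bio3d} readers that normalizes both formats to a
#' \code{\link{structure_model}}.  Chain and residue identifiers are kept
#' verbatim; HETATM records, waters and alternate locations other than the
#' first are discarded.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"mmcif"}, or NULL to guess from the
#'   file extension.
#' @return a \code{structure_model}.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- .guess_format(path, format)
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, verbose = FALSE)
  } else {
    ## read.cif warns about its beta status and absent helix/sheet records
    ## on every call; neither concerns coordinate reading
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A", ".", "?")) &
    !(at$resid %in% c("HOH", "WAT"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path, call. = FALSE)
  at$chain[is.na(at$chain)] <- " "
  structure_model(
    data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
               elety = at$elety, x = at$x, y = at$y, z = at$z,
               stringsAsFactors = FALSE),
    source = basename(path))
}

#' Write an atomic structure (PDB or mmCIF)
#'
#' PDB output goes through \code{bio3d::write.pdb} (fixed-width, 3-decimal
#' Angstrom); mmCIF output is a minimal \code{atom_site} loop that
#' round-trips through \code{read_structure}.
#'
#' @param model a \code{structure_model}.
#' @param path output file path.
#' @param format \code{"pdb"}, \code{"mmcif"}, or NULL to guess from the
#'   extension.
#' @export
write_structure <- function(model, path, format = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (n_atoms(model) == 0) stop("refusing to write an empty model",
                                call. = FALSE)
  format <- .guess_format(path, format)
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety)
  } else {
    elem <- sub("^([0-9]*)([A-Za-z]).*", "\\2", a$elety)
    ## canonical RCSB atom_site column layout (fixed-position parsers rely
    ## on it)
    hdr <- paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num"))
    rows <- sprintf(
      "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
      seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, a$resno,
      a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
    writeLines(c("data_chromfiber", "#", "loop_", hdr, rows, "#"), path)
  }
  invisible(path)
}

.DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DU", "DI",
                   "A", "C", "G", "T", "U", "I")

#' Extract an ordered DNA base-pair path from a structure
#'
#' Base pairing is geometric, not by residue numbering: each strand's
#' C1'-equivalent reference atoms are paired with the mutually nearest
#' opposite-strand atom within 12 Angstrom (deposited models renumber DNA
#' inconsistently, so numbering is never trusted for pairing).  Base-pair
#' centers are midpoints of the paired reference atoms.  Indices are
#' assigned relative to the dyad base pair: index 0 at the dyad, one unit
#' per base pair toward either terminus.
#'
#' @param model a \code{structure_model} containing exactly two
#'   complementary DNA strands (restrict with \code{chains} otherwise).
#' @param dyad either \code{"auto"} (dyad = base pair at the midpoint of
#'   the longest contiguous resolved span; the even-length case takes the
#'   lower-middle base pair) or a length-2 vector \code{c(chain, resno)}
#'   naming the dyad residue on either strand.  An explicit dyad always
#'   wins and is required for exact register reproduction.
#' @param chains optional character vector restricting which chains are
#'   considered.
#' @return a \code{\link{basepair_path}}; interior pairing gaps are carried
#'   as interpolated centers flagged unresolved.
#' @export
extract_dna_duplex <- function(model, dyad = "auto", chains = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  ref <- a[a$elety %in% c("C1'", "C1*") & a$resid %in% .DNA_RESIDUES, ,
           drop = FALSE]
  if (nrow(ref) == 0) stop("no DNA found in model", call. = FALSE)
  dna_chains <- unique(ref$chain)
  if (length(dna_chains) != 2)
    stop(sprintf("expected exactly 2 DNA strands, found %d (%s); restrict with chains=",
                 length(dna_chains), paste(dna_chains, collapse = ",")),
         call. = FALSE)
  s1 <- ref[ref$chain == dna_chains[1], , drop = FALSE]
  s1 <- s1[order(s1$resno), , drop = FALSE]
  s2 <- ref[ref$chain == dna_chains[2], , drop = FALSE]
  s2 <- s2[order(s2$resno), , drop = FALSE]
  x1 <- as.matrix(s1[, c("x", "y", "z")])
  x2 <- as.matrix(s2[, c("x", "y", "z")])
  dmat <- outer(rowSums(x1^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x1)), rowSums(x2^2)) - 2 * x1 %*% t(x2)
  dmat <- sqrt(pmax(dmat, 0))
  j_of_i <- apply(dmat, 1, which.min)
  i_of_j <- apply(dmat, 2, which.min)
  mutual <- which(i_of_j[j_of_i] == seq_len(nrow(x1)) &
                  dmat[cbind(seq_len(nrow(x1)), j_of_i)] <= 12)
  if (length(mutual) < 2) stop("no base pairs found within pairing cutoff",
                               call. = FALSE)
  i <- sort(mutual)
  resno1 <- s1$resno[i]
  centers <- (x1[i, , drop = FALSE] + x2[j_of_i[i], , drop = FALSE]) / 2

  ## dyad register
  if (identical(dyad, "auto")) {
    runs <- split(seq_along(resno1), cumsum(c(1L, diff(resno1) != 1L)))
    lens <- lengths(runs)
    run <- runs[[which.max(lens)]]
    if (length(run) < 20)
      stop("longest contiguous span too short to locate a dyad; pass an explicit dyad = c(chain, resno)",
           call. = FALSE)
    dyad_resno <- resno1[run[floor((length(run) + 1) / 2)]]
  } else {
    if (length(dyad) != 2)
      stop("dyad must be \"auto\" or c(chain, resno)", call. = FALSE)
    dch <- as.character(dyad[1]); drn <- as.integer(dyad[2])
    if (dch == dna_chains[1]) {
      if (!drn %in% resno1) stop("dyad residue is not part of a base pair",
                                 call. = FALSE)
      dyad_resno <- drn
    } else if (dch == dna_chains[2]) {
      k <- which(s2$resno[j_of_i[i]] == drn)
      if (length(k) != 1) stop("dyad residue is not part of a base pair",
                               call. = FALSE)
      dyad_resno <- resno1[k]
    } else stop("dyad chain not found among DNA strands", call. = FALSE)
  }
  index <- resno1 - dyad_resno

  ## fill interior gaps with interpolated, unresolved placeholders
  full_index <- seq(min(index), max(index))
  pos <- match(full_index, index)
  resolved <- !is.na(pos)
  full_centers <- matrix(NA_real_, length(full_index), 3)
  full_centers[resolved, ] <- centers[pos[resolved], , drop = FALSE]
  if (any(!resolved)) {
    for (k in 1:3) {
      full_centers[, k] <- stats::approx(full_index[resolved],
                                         full_centers[resolved, k],
                                         xout = full_index)$y
    }
  }
  basepair_path(full_centers, full_index, resolved, check = FALSE)
}

#' Build a synthetic two-strand duplex model around a base-pair path
#'
#' Places one C1' pseudo-atom per strand at +/- \code{half_width} Angstrom
#' from each resolved bp center, perpendicular to the local path tangent
#' (the perpendicular is parallel-transported along the path so strands are
#' smooth).  Strand 1 residue numbers encode the register as
#' \code{index - min_index + 1} against \code{register_offset}, so the
#' dyad residue is recoverable after truncation.  Useful for writing
#' generator output as PDB/mmCIF files that re-extract exactly.
#'
#' @param path a \code{\link{basepair_path}}.
#' @param half_width strand half-separation, Angstrom (default 5).
#' @param chains two chain ids (default \code{c("I","J")}).
#' @param register_offset resno assigned to the dyad bp on strand 1
#'   (default 74, the canonical-147 bp register).
#' @param source label for the resulting model.
#' @return a \code{structure_model} with two DNA strands.
#' @export
path_to_duplex_model <- function(path, half_width = 5,
                                 chains = c("I", "J"),
                                 register_offset = 74L,
                                 source = "synthetic duplex") {
  p <- path[path$resolved, , drop = FALSE]
  xyz <- as.matrix(p[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2) stop("need >= 2 resolved bp", call. = FALSE)
  ## tangents by central differences
  tg <- t(apply(rbind(xyz[2, ] - xyz[1, ],
                      if (n > 2) xyz[3:n, , drop = FALSE] - xyz[1:(n - 2), , drop = FALSE],
                      xyz[n, ] - xyz[n - 1, ]), 1, unit_vec))
  ## parallel-transported perpendicular
  w <- matrix(0, n, 3)
  seed_w <- c(0, 0, 1)
  if (abs(sum(seed_w * tg[1, ])) > 0.9) seed_w <- c(1, 0, 0)
  w[1, ] <- unit_vec(seed_w - sum(seed_w * tg[1, ]) * tg[1, ])
  if (n > 1) for (k in 2:n) {
    w[k, ] <- unit_vec(w[k - 1, ] - sum(w[k - 1, ] * tg[k, ]) * tg[k, ])
  }
  resno1 <- as.integer(p$index + register_offset)
  resno2 <- as.integer(register_offset - p$index)  # antiparallel numbering
  atoms <- data.frame(
    chain = rep(chains, each = n),
    resno = c(resno1, resno2),
    resid = "DA",
    elety = "C1'",
    x = c(xyz[, 1] + half_width * w[, 1], xyz[, 1] - half_width * w[, 1]),
    y = c(xyz[, 2] + half_width * w[, 2], xyz[, 2] - half_width * w[, 2]),
    z = c(xyz[, 3] + half_width * w[, 3], xyz[, 3] - half_width * w[, 3]),
    stringsAsFactors = FALSE)
  structure_model(atoms, source = source)
}
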