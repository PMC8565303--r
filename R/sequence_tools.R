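## 601 nucleosome-positioning constructs and restriction-site mapping.
## Coordinates are 1-based inclusive throughout (restriction-map
## convention).

.SEQ_167 <- paste0(
  "ATCCCGCCCTGGAGAATCCCGGTGCCGAGGCCGCTCAATTGGTCGTAGACAGCTCTAGCA",
  "CCGCTTAAACGCACGTACGCGCTGTCCCCCGCGTTTTAACCGCCAAGGGGATTACTCCCT",
  "AGTCTCCAGGCACGTGTCAGATATATACATCCTGTGCATGACTAGAT")

.SEQ_208 <- paste0(
  "ACTTATGTGATGGACCCTATACGCGGCCGCCCTGGAGAATCCCGGTGCCGAGGCCGCTCA",
  "ATTGGTCGTAGACAGCTCTAGCACCGCTTAAACGCACGTACGCGCTGTCCCCCGCGTTTT",
  "AACCGCCAAGGGGATTACTCCCTAGTCTCCAGGCACGTGTCAGATATATACATCCTGTGC",
  "ATGTATTGAACAGCGACCTTGCCGGAGT")

.SEQ_208_NSI <- paste0(
  "ACTTATGTGATGGACCCTATACGCGGCCGCCCTGGAGAATCCCGGTGCCGAGGCCGCTCA",
  "ATTGGTCGTAGACAGCTCTAGCACCGCTTAAACGCACGTACGCGCTGTCCCCCGCGTTTT",
  "AACCGCCAAGGGGATTACTCCCTAGTCTCCAGGCACGTGTCAGATATATGCATCCTGTGC",
  "ATGTATTGAACAGCGACCTTGCCGGAGT")

## recognition motifs of the two enzymes used in the accessibility assay;
## both are their own reverse complements
.ENZYMES <- c(HinfI = "GANTC", NsiI = "ATGCAT")

#' 601 construct sequence
#'
#' A named DNA construct with an optional positioned 147-bp core interval.
#'
#' @param name construct name.
#' @param sequence DNA string over A/C/G/T.
#' @param core optional 1-based inclusive c(start, end) of the positioned
#'   147-bp nucleosome core; must span exactly 147 bp within the sequence.
#' @return object of class \code{construct_sequence}.
#' @export
construct_sequence <- function(name, sequence, core = NULL) {
  sequence <- toupper(sequence)
  if (nchar(sequence) > 0 && grepl("[^ACGT]", sequence))
    stop("sequence must contain only A/C/G/T", call. = FALSE)
  if (!is.null(core)) {
    core <- as.integer(core)
    if (length(core) != 2 || core[2] - core[1] + 1L != 147L ||
        core[1] < 1 || core[2] > nchar(sequence))
      stop("core must be a 147-bp interval within the sequence",
           call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), core = core),
            class = "construct_sequence")
}

#' @export
print.construct_sequence <- function(x, ...) {
  cat(sprintf("<construct_sequence> %s: %d bp%s\n", x$name, x$length,
              if (is.null(x$core)) "" else
                sprintf(", core %d..%d", x$core[1], x$core[2])))
  invisible(x)
}

#' Built-in 601 constructs
#'
#' The three repeats used for reconstitution: the 167-bp repeat, the
#' 208-bp repeat, and the 208-bp repeat with an NsiI site introduced by
#' mutagenesis (a single A->G change creating ATGCAT).  The default core
#' interval places the 147-bp positioned core at the start of the shared
#' 601 region (the \code{CTGGAGA...} anchor common to both backbones);
#' pass \code{core} explicitly to override the register.
#'
#' @param name one of \code{"601_167"}, \code{"601_208"},
#'   \code{"601_208_NsiI"}; NULL returns all three as a named list.
#' @param core optional core interval override, c(start, end).
#' @return a \code{\link{construct_sequence}} or named list of them.
#' @export
widom_601_constructs <- function(name = NULL, core = NULL) {
  default_core <- function(seq) {
    anchor <- regexpr("CTGGAGA", seq, fixed = TRUE)[1]
    if (anchor < 1 || anchor + 146L > nchar(seq)) NULL
    else c(anchor, anchor + 146L)
  }
  mk <- function(nm, s) construct_sequence(nm, s, core %||% default_core(s))
  all <- list(`601_167` = mk("601_167", .SEQ_167),
              `601_208` = mk("601_208", .SEQ_208),
              `601_208_NsiI` = mk("601_208_NsiI", .SEQ_208_NSI))
  if (is.null(name)) return(all)
  if (!name %in% names(all))
    stop("unknown construct: ", name, call. = FALSE)
  all[[name]]
}

#' Check embedded construct lengths
#'
#' Asserts that the embedded construct strings have their designated
#' lengths (167, 208, 208 bp); any mismatch means the fixtures were
#' corrupted.
#'
#' @return data.frame with columns \code{name}, \code{length},
#'   \code{expected}, \code{ok} (invisibly errors if any mismatch).
#' @export
validate_fixture_lengths <- function() {
  expected <- c(`601_167` = 167L, `601_208` = 208L, `601_208_NsiI` = 208L)
  got <- vapply(widom_601_constructs(), `[[`, integer(1), "length")
  rep <- data.frame(name = names(expected), length = got[names(expected)],
                    expected = expected, ok = got[names(expected)] == expected,
                    row.names = NULL)
  if (!all(rep$ok))
    stop("embedded construct length mismatch: ",
         paste(rep$name[!rep$ok], collapse = ", "), call. = FALSE)
  rep
}

.IUPAC <- Biostrings::IUPAC_CODE_MAP

#' Scan a construct for a restriction motif
#'
#' IUPAC-aware scanning via \code{Biostrings::matchPattern}.  Both HinfI
#' (GANTC) and NsiI (ATGCAT) motifs are their own reverse complements, so
#' a top-strand scan is complete for them; non-palindromic custom motifs
#' are scanned on both strands and the strand recorded.  Positions are
#' 1-based motif starts on the top strand.
#'
#' @param seq a \code{\link{construct_sequence}} (or plain DNA string).
#' @param motif IUPAC motif string, or an enzyme name ("HinfI", "NsiI").
#' @return data.frame of class \code{restriction_sites}: columns
#'   \code{enzyme}, \code{motif}, \code{start}, \code{end}, \code{strand};
#'   plus \code{dist_to_core}, \code{class} after
#'   \code{\link{site_accessibility_context}}.
#' @export
scan_sites <- function(seq, motif) {
  if (!inherits(seq, "construct_sequence"))
    seq <- construct_sequence("query", seq)
  enzyme <- "custom"
  if (motif %in% names(.ENZYMES)) {
    enzyme <- motif
    motif <- .ENZYMES[[motif]]
  }
  motif <- toupper(motif)
  if (nchar(motif) == 0 || grepl(paste0("[^", paste(names(.IUPAC),
                                                    collapse = ""), "]"),
                                 motif))
    stop("invalid IUPAC motif: ", motif, call. = FALSE)
  subject <- Biostrings::DNAString(seq$sequence)
  pat <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(rc) == as.character(pat)
  hit_df <- function(p, strand) {
    if (nchar(seq$sequence) < nchar(motif))
      return(NULL)
    m <- Biostrings::matchPattern(p, subject, fixed = FALSE)
    if (length(m) == 0) return(NULL)
    data.frame(enzyme = enzyme, motif = motif,
               start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand, stringsAsFactors = FALSE)
  }
  out <- hit_df(pat, "+")
  if (!palindromic) out <- rbind(out, hit_df(rc, "-"))
  if (is.null(out))
    out <- data.frame(enzyme = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "construct") <- seq$name
  class(out) <- c("restriction_sites", "data.frame")
  out
}

#' Distance of restriction sites to the nucleosome core edge
#'
#' Annotates each site with its signed distance to the nearest core edge
#' (negative = inside the core) and a class: \code{outside-core},
#' \code{edge} (on the edge or within 10 bp inside it) or
#' \code{internal}.  Distances use the motif extent: the motif base
#' closest to the relevant core edge.
#'
#' @param sites output of \code{\link{scan_sites}}.
#' @param seq the \code{\link{construct_sequence}} with its core interval
#'   set.
#' @return the sites data.frame with \code{dist_to_core} and \code{class}
#'   columns added.
#' @export
site_accessibility_context <- function(sites, seq) {
  stopifnot(inherits(seq, "construct_sequence"))
  if (is.null(seq$core))
    stop("construct has no core interval set", call. = FALSE)
  cs <- seq$core[1]; ce <- seq$core[2]
  ann <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites$start[i]; e <- sites$end[i]
    if (e < cs) {            # fully left of core
      d <- cs - e
    } else if (s > ce) {     # fully right of core
      d <- s - ce
    } else {                 # overlapping or inside: depth of the motif
      d <- -max(0L, min(s - cs, ce - e))
    }
    cls <- if (d > 0) "outside-core"
           else if (-d <= 10) "edge"
           else "internal"
    c(d = d, cls = cls)
  })
  sites$dist_to_core <- as.integer(vapply(ann, `[[`, character(1), "d"))
  sites$class <- vapply(ann, `[[`, character(1), "cls")
  sites
}
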