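## Pipeline entry points: one function per analysis stage, file in /
## files out, suitable for scripting.  The command-line wrapper in
## inst/cli/chromfiber.R delegates to these.

.out_path <- function(out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(out_dir, name)
}

## record the run configuration (with seed) next to the outputs, so a run
## is reproducible from its config file alone
.log_config <- function(out_dir, stage, config) {
  p <- .out_path(out_dir, paste0(stage, "_config.json"))
  if (is.null(p)) return(invisible(NULL))
  jsonlite::write_json(c(list(stage = stage,
                              package_version = as.character(
                                utils::packageVersion("chromfiber"))),
                         config),
                       p, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(p)
}

#' Wrap accounting for one nucleosome structure
#'
#' Reads a structure, extracts its DNA duplex, counts wrapped vs missing
#' base pairs and writes JSON/TSV reports.
#'
#' @param structure_path PDB or mmCIF file.
#' @param dyad dyad locator (see \code{\link{extract_dna_duplex}}).
#' @param reference reference wrap length, bp.
#' @param out_dir optional output directory for the reports.
#' @param model_id label for reports (default: file name).
#' @return the \code{wrap_report}, invisibly.
#' @export
analyze_nucleosome <- function(structure_path, dyad = "auto",
                               reference = 147L, out_dir = NULL,
                               model_id = basename(structure_path)) {
  model <- read_structure(structure_path)
  path <- extract_dna_duplex(model, dyad = dyad)
  rep <- count_wrapped_bp(path, reference = reference, model_id = model_id)
  write_wrap_report(rep, json_path = .out_path(out_dir, "wrap_report.json"),
                    tsv_path = .out_path(out_dir, "wrap_report.tsv"))
  .log_config(out_dir, "analyze_nucleosome",
              list(structure = structure_path,
                   dyad = if (identical(dyad, "auto")) "auto"
                          else paste(dyad, collapse = ":"),
                   reference = reference))
  invisible(rep)
}

#' Packing parameters of a fiber structure or frames CSV
#'
#' @param path a fiber structure file (PDB/mmCIF written by
#'   \code{\link{fiber_to_structure}}) or a frames CSV
#'   (\code{\link{write_frames_csv}} layout).  Entry/exit angles require
#'   linker geometry and are only reported for in-memory
#'   \code{fiber_model}s; file-based input summarizes x, beta, d.
#' @param out_dir optional output directory.
#' @return the \code{fiber_parameters}, invisibly.
#' @export
analyze_fiber <- function(path, out_dir = NULL) {
  frames <- if (tolower(tools::file_ext(path)) == "csv") {
    read_frames_csv(path)
  } else {
    fiber_frames_from_structure(read_structure(path))
  }
  fp <- summarize_parameters(frames)
  write_fiber_parameters(fp,
                         json_path = .out_path(out_dir, "fiber_parameters.json"),
                         tsv_path = .out_path(out_dir, "fiber_parameters.tsv"))
  .log_config(out_dir, "analyze_fiber", list(input = path))
  invisible(fp)
}

#' Build a fiber model and write its files
#'
#' @param n,x,beta,d,gamma,nrl build parameters (see
#'   \code{\link{fiber_build_spec}}).
#' @param template_path optional single-nucleosome structure to decorate
#'   the frames with.
#' @param out_dir output directory; writes \code{fiber.pdb},
#'   \code{frames.csv} and \code{dimensions.json}.
#' @return the \code{fiber_model}, invisibly.
#' @export
build_fiber_files <- function(n, x, beta, d, gamma, nrl = 167L,
                              template_path = NULL, out_dir = ".") {
  spec <- fiber_build_spec(n = n, x = x, beta = beta, d = d, gamma = gamma,
                           nrl = nrl)
  model <- build_fiber(spec)
  template <- if (!is.null(template_path)) read_structure(template_path)
  write_structure(fiber_to_structure(model, template = template),
                  .out_path(out_dir, "fiber.pdb"))
  write_frames_csv(model$frames, .out_path(out_dir, "frames.csv"))
  dims <- measure_dimensions(model)
  jsonlite::write_json(as.list(dims), .out_path(out_dir, "dimensions.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_config(out_dir, "build_fiber",
              list(n = n, nrl = nrl, x = x, beta = beta, d = d,
                   gamma = gamma, template = template_path))
  invisible(model)
}

#' Scan a construct (built-in or FASTA) for restriction sites
#'
#' @param input a built-in construct name (see
#'   \code{\link{widom_601_constructs}}) or a FASTA file path (first
#'   record used).
#' @param motif IUPAC motif or enzyme name ("HinfI", "NsiI").
#' @param core optional core interval c(start, end) override.
#' @param out_dir optional output directory (writes \code{sites.tsv}).
#' @return annotated sites data.frame, invisibly.
#' @export
scan_sites_file <- function(input, motif, core = NULL, out_dir = NULL) {
  seq <- if (file.exists(input)) {
    ss <- Biostrings::readDNAStringSet(input)
    construct_sequence(names(ss)[1] %||% basename(input),
                       as.character(ss[[1]]), core = core)
  } else {
    widom_601_constructs(input, core = core)
  }
  sites <- scan_sites(seq, motif)
  if (!is.null(seq$core)) sites <- site_accessibility_context(sites, seq)
  tsv <- .out_path(out_dir, "sites.tsv")
  if (!is.null(tsv))
    utils::write.table(sites, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  .log_config(out_dir, "scan_sites",
              list(input = input, motif = motif, core = core))
  invisible(sites)
}

#' Write synthetic datasets for the full pipeline
#'
#' Generates (a) a full and a truncated synthetic nucleosome structure,
#' (b) a synthetic fiber (structure + frames CSV) for a parameter set and
#' (c) noisy digestion time courses for two conditions, all deterministic
#' functions of \code{seed}.
#'
#' @param out_dir output directory.
#' @param seed integer seed for all random draws.
#' @param params named list with fiber build parameters \code{n},
#'   \code{x}, \code{beta}, \code{d}, \code{gamma} (defaults: the H2A.Z
#'   set, 12 nucleosomes).
#' @return named list of written file paths, invisibly.
#' @export
simulate_inputs <- function(out_dir = ".", seed = 1L, params = NULL) {
  ps <- fiber_parameter_sets()
  z <- as.list(ps[ps$set == "H2A.Z", ])
  p <- utils::modifyList(list(n = 12L, x = z$x_nm, beta = z$beta_deg,
                              d = z$d_A, gamma = z$gamma_deg), params %||% list())
  files <- list()
  ## nucleosome structures: full and 11-bp-truncated
  full <- path_to_duplex_model(make_ideal_ncp_path(),
                               source = "synthetic full NCP")
  trunc <- path_to_duplex_model(
    make_ideal_ncp_path(truncation = list(side = "plus", n_bp = 11L)),
    source = "synthetic truncated NCP")
  files$ncp_full <- .out_path(out_dir, "ncp_full.pdb")
  files$ncp_truncated <- .out_path(out_dir, "ncp_truncated.pdb")
  write_structure(full, files$ncp_full)
  write_structure(trunc, files$ncp_truncated)
  ## fiber
  model <- make_synthetic_fiber(
    fiber_build_spec(n = p$n, x = p$x, beta = p$beta, d = p$d,
                     gamma = p$gamma),
    jitter_spec(center_sd = 2, orient_sd = 2, seed = seed))
  files$fiber_pdb <- .out_path(out_dir, "fiber.pdb")
  files$frames_csv <- .out_path(out_dir, "frames.csv")
  write_structure(fiber_to_structure(model), files$fiber_pdb)
  write_frames_csv(model$frames, files$frames_csv)
  ## digestion time courses: control and 2.31-fold faster variant
  courses <- list()
  for (i in 1:5) {
    courses <- c(courses,
                 list(make_timecourse(0.05, 0.85, 0.02, noise_sd = 0.02,
                                      seed = seed * 1000L + i,
                                      condition = "H2A",
                                      replicate = paste0("r", i)),
                      make_timecourse(0.05, 0.85, 0.02 * 2.31,
                                      noise_sd = 0.02,
                                      seed = seed * 1000L + 500L + i,
                                      condition = "H2A.Z",
                                      replicate = paste0("r", i))))
  }
  files$timecourses_csv <- .out_path(out_dir, "timecourses.csv")
  write_timecourses(courses, files$timecourses_csv)
  .log_config(out_dir, "simulate", c(list(seed = seed), p))
  invisible(files)
}
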