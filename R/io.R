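# File input/output and run provenance.

#' Read a FASTA file as a named character vector
#'
#' Record IDs are truncated at the first whitespace.  Gzipped input is
#' handled transparently.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @param uppercase Uppercase the sequences (default `TRUE`; set to
#'   `FALSE` to preserve soft-masking for [scan_fasta()]'s
#'   `respect_softmask`).
#' @return A named character vector of sequences (possibly empty strings
#'   for empty records).
#' @export
read_fasta <- function(path, uppercase = TRUE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  if (uppercase) seqs <- toupper(seqs)
  seqs
}

#' Read a (multi-model) structure file
#'
#' Parses PDB or mmCIF coordinates into a light multi-model container.
#' Heteroatoms and waters are excluded; models are indexed from 1.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return An object of class `g4_structure`: list with `atom` (data frame
#'   with `eleno`, `elety`, `resid`, `chain`, `resno`), `xyz` (matrix,
#'   one row per model, 3 columns per atom) and `n_models`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) {
    bio3d::read.cif(path, multi = TRUE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  }
  keep <- pdb$atom$type == "ATOM" & !(pdb$atom$resid %in% c("HOH", "WAT"))
  atom <- pdb$atom[keep, c("eleno", "elety", "resid", "chain", "resno"),
                   drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  idx <- as.vector(t(outer(which(keep), 0:2, function(i, j) 3 * (i - 1) + 1 + j)))
  xyz <- xyz[, idx, drop = FALSE]
  nuc <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "U", "T")
  if (!any(atom$resid %in% nuc)) {
    stop("no nucleic-acid residues found in ", path)
  }
  g4_structure(atom, xyz)
}

#' Construct a g4_structure from an atom table and coordinates
#'
#' Low-level constructor shared by [read_structure()] and
#' [build_ideal_g4()].
#'
#' @param atom Data frame with columns `eleno`, `elety`, `resid`, `chain`,
#'   `resno` (one row per atom).
#' @param xyz Numeric matrix, one row per model and `3 * nrow(atom)`
#'   columns (x, y, z per atom).
#' @return An object of class `g4_structure`.
#' @export
g4_structure <- function(atom, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  stopifnot(ncol(xyz) == 3L * nrow(atom), all(is.finite(xyz)))
  rownames(atom) <- NULL
  out <- list(atom = atom, xyz = xyz, n_models = nrow(xyz))
  class(out) <- "g4_structure"
  out
}

#' @export
print.g4_structure <- function(x, ...) {
  cat(sprintf("g4_structure: %d model(s), %d atoms, %d residue(s)\n",
              x$n_models, nrow(x$atom),
              nrow(unique(x$atom[, c("chain", "resno")]))))
  invisible(x)
}

# natoms x 3 coordinate matrix of one model
model_coords <- function(st, model = 1L) {
  stopifnot(inherits(st, "g4_structure"),
            model >= 1L, model <= st$n_models)
  matrix(st$xyz[model, ], ncol = 3L, byrow = TRUE)
}

#' Write motif hits as a BED6 file
#'
#' Deterministic, sorted, newline-terminated BED6 output (0-based
#' half-open; `name` = query label, `score` = 0).
#'
#' @param hits A hits data frame from [scan_sequence()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits)) {
    hits <- hits[order(hits$sequence_id, hits$start, hits$query_label), ,
                 drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", hits$sequence_id, hits$start,
                     hits$end, hits$query_label, hits$strand)
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file written by [write_bed()]
#'
#' @param path Path to a BED6 file.
#' @return A hits-style data frame (without `matched_text`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    out <- .empty_hits()
    return(out[, setdiff(names(out), "matched_text")])
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(sequence_id = vapply(f, `[[`, "", 1L),
             start = as.integer(vapply(f, `[[`, "", 2L)),
             end = as.integer(vapply(f, `[[`, "", 3L)),
             strand = vapply(f, `[[`, "", 6L),
             query_label = vapply(f, `[[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Write a JSON report
#'
#' @param x A list (or other jsonlite-serialisable object).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Build a run manifest
#'
#' Records the operation name, parameters, input checksums, package
#' version and timestamp; sufficient to reproduce a deterministic run.
#'
#' @param operation Name of the operation (e.g. `"scan"`).
#' @param parameters Named list of parameters (cutoffs, policies, seeds).
#' @param inputs Character vector of input file paths (checksummed when
#'   they exist).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(operation, parameters = list(), inputs = character(0)) {
  sums <- if (length(inputs)) {
    ex <- file.exists(inputs)
    s <- rep(NA_character_, length(inputs))
    s[ex] <- unname(tools::md5sum(inputs[ex]))
    stats::setNames(as.list(s), inputs)
  } else {
    list()
  }
  out <- list(operation = operation, parameters = parameters,
              input_md5 = sums,
              tool = "quadlock",
              version = as.character(utils::packageVersion("quadlock")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(out) <- "run_manifest"
  out
}
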