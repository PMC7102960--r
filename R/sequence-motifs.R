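# Enumeration and exact-match scanning of irregular PQS query families.
#
# A query describes an ordered series of G-tracts separated by short non-G
# loops.  Tracts are either "full" (G{m,}, m >= 2 by default) or "isolated"
# (G{1,}).  Scanning is exact: N matches neither a tract nor a loop
# character.

.valid_dna_chars <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, arg = "seq") {
  if (length(seq) != 1L || !is.character(seq)) {
    stop(sprintf("`%s` must be a single character string", arg), call. = FALSE)
  }
  if (!nzchar(seq)) stop(sprintf("`%s` is empty", arg), call. = FALSE)
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .valid_dna_chars)
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d of `%s`",
                 chars[bad[1L]], bad[1L], arg), call. = FALSE)
  }
  up
}

#' Decompose a DNA sequence into maximal G-runs and non-G runs
#'
#' Splits a sequence into alternating maximal runs of guanine and
#' non-guanine characters, the elementary bookkeeping behind G-tract
#' counting (e.g. AT26 contains seven G2 tracts and two isolated guanines).
#'
#' @param seq A DNA string over `A`, `C`, `G`, `T`, `N` (case-insensitive).
#' @return An object of class `tract_decomposition`: a list with `runs`
#'   (data frame with columns `base` (`"G"`/`"other"`), `length` and
#'   0-based `start`), `g_run_lengths` (integer vector of G-run lengths in
#'   order) and `n_g` (total guanine count).
#' @examples
#' d <- decompose_tracts(at26_sequence())
#' table(d$g_run_lengths)
#' @export
decompose_tracts <- function(seq) {
  up <- .check_dna(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  r <- rle(chars == "G")
  len <- r$lengths
  runs <- data.frame(
    base = ifelse(r$values, "G", "other"),
    length = as.integer(len),
    start = as.integer(cumsum(c(0L, len[-length(len)]))),
    stringsAsFactors = FALSE)
  out <- list(runs = runs,
              g_run_lengths = as.integer(len[r$values]),
              n_g = as.integer(sum(len[r$values])))
  class(out) <- "tract_decomposition"
  out
}

#' @export
print.tract_decomposition <- function(x, ...) {
  tab <- table(x$g_run_lengths)
  cat(sprintf("Tract decomposition: %d G-run(s), %d guanine(s) total\n",
              length(x$g_run_lengths), x$n_g))
  if (length(tab)) {
    cat("  G-run lengths:",
        paste(sprintf("%sx len %s", tab, names(tab)), collapse = ", "), "\n")
  }
  invisible(x)
}

.motif_query <- function(tract_min, open_ended, loop_min, loop_max, label) {
  q <- list(
    tracts = lapply(seq_along(tract_min), function(i) {
      list(min_len = as.integer(tract_min[i]), open_ended = open_ended[i])
    }),
    loop_min = as.integer(loop_min), loop_max = as.integer(loop_max),
    label = label)
  class(q) <- "motif_query"
  q
}

#' Enumerate an irregular PQS query family
#'
#' Builds the family of queries with `n_tracts` ordered G-tracts separated
#' by loops of `loop_min`..`loop_max` non-G nucleotides, where exactly
#' `n_isolated` tract positions are relaxed from `G{2,}` to `G{1,}`
#' (isolated-guanine) semantics.  One query is emitted per choice of the
#' isolated positions, `choose(n_tracts, n_isolated)` in total; the family
#' with nine tracts and two isolated positions comprises 36 queries.
#'
#' @param n_tracts Number of G-tracts (>= 2).
#' @param n_isolated Number of tract positions relaxed to isolated-G
#'   semantics (0 <= `n_isolated` <= `n_tracts`).
#' @param loop_min,loop_max Loop length bounds in nucleotides
#'   (`1 <= loop_min <= loop_max` unless `allow_zero_loop`).
#' @param tract_min Minimum guanine count of a non-isolated tract
#'   (default 2).
#' @param allow_zero_loop Permit `loop_min = 0` (disallowed by default).
#' @return A `query_set`: list with `queries` (list of `motif_query`) and
#'   `family_name` (e.g. `"8G2"`, `"7G2+2G1"`).  Labels are unique and in
#'   deterministic lexicographic order.
#' @examples
#' length(enumerate_queries(9, 2)$queries)  # 36
#' @export
enumerate_queries <- function(n_tracts, n_isolated = 0L, loop_min = 1L,
                              loop_max = 2L, tract_min = 2L,
                              allow_zero_loop = FALSE) {
  n_tracts <- as.integer(n_tracts); n_isolated <- as.integer(n_isolated)
  if (is.na(n_tracts) || n_tracts < 2L) stop("`n_tracts` must be >= 2")
  if (is.na(n_isolated) || n_isolated < 0L || n_isolated > n_tracts) {
    stop("`n_isolated` must satisfy 0 <= n_isolated <= n_tracts")
  }
  lo <- as.integer(loop_min); hi <- as.integer(loop_max)
  min_lo <- if (allow_zero_loop) 0L else 1L
  if (is.na(lo) || is.na(hi) || lo < min_lo || hi < 1L || lo > hi) {
    stop("loop bounds must satisfy ", min_lo, " <= loop_min <= loop_max")
  }
  n_full <- n_tracts - n_isolated
  family <- if (n_isolated == 0L) {
    paste0(n_tracts, "G", tract_min)
  } else {
    paste0(n_full, "G", tract_min, "+", n_isolated, "G1")
  }
  sets <- if (n_isolated == 0L) {
    list(integer(0))
  } else {
    asplit(utils::combn(n_tracts, n_isolated), 2L)
  }
  queries <- lapply(sets, function(pos) {
    mins <- rep(as.integer(tract_min), n_tracts)
    mins[pos] <- 1L
    label <- if (!length(pos)) family else {
      paste0(family, "_", paste(sprintf("i%02d", pos), collapse = ""))
    }
    .motif_query(mins, rep(TRUE, n_tracts), lo, hi, label)
  })
  labels <- vapply(queries, `[[`, "", "label")
  stopifnot(!anyDuplicated(labels))
  queries <- queries[order(labels)]
  out <- list(queries = queries, family_name = family)
  class(out) <- "query_set"
  out
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("Query set '%s': %d quer%s\n", x$family_name,
              length(x$queries), if (length(x$queries) == 1) "y" else "ies"))
  labs <- vapply(x$queries, `[[`, "", "label")
  show <- utils::head(labs, 8L)
  cat("  ", paste(show, collapse = ", "),
      if (length(labs) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Compile a motif query to a scanning pattern
#'
#' Translates a `motif_query` into a PCRE pattern over `{G, A, C, T}`.
#' Open-ended tracts compile to `G{m,}` (greedy, consuming a maximal
#' G-run); in strict mode every tract matches exactly its minimum length
#' and may not be flanked by further guanines, so the whole match is not
#' embedded in longer G-runs.
#'
#' @param q A `motif_query` (see [enumerate_queries()]).
#' @param strict_tracts Logical; require each tract to be exactly its
#'   minimum length, unflanked by G.
#' @return A `compiled_query`: list with `pattern` (PCRE string), `label`
#'   and `strict`.
#' @examples
#' q <- enumerate_queries(8, 0)$queries[[1]]
#' compile_query(q)$pattern
#' @export
compile_query <- function(q, strict_tracts = FALSE) {
  stopifnot(inherits(q, "motif_query"))
  loop <- sprintf("[ACT]{%d,%d}", q$loop_min, q$loop_max)
  tract <- vapply(q$tracts, function(tr) {
    if (strict_tracts) {
      sprintf("(?<!G)G{%d}(?!G)", tr$min_len)
    } else {
      sprintf("G{%d,}", tr$min_len)
    }
  }, "")
  out <- list(pattern = paste(tract, collapse = loop),
              label = q$label, strict = isTRUE(strict_tracts))
  class(out) <- "compiled_query"
  out
}

.as_query_list <- function(qs) {
  if (inherits(qs, "motif_query")) return(list(qs))
  if (inherits(qs, "query_set")) return(qs$queries)
  if (is.list(qs) && all(vapply(qs, inherits, TRUE, "motif_query"))) return(qs)
  stop("`qs` must be a query_set, a motif_query, or a list of motif_query")
}

.empty_hits <- function() {
  data.frame(sequence_id = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             query_label = character(0), matched_text = character(0),
             stringsAsFactors = FALSE)
}

# one strand, one query, prepared (uppercased/masked) sequence
.scan_one <- function(prep, cq, policy) {
  pat <- cq$pattern
  if (policy == "all_overlapping") {
    m <- gregexpr(paste0("(?=(", pat, "))"), prep, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1L]
  } else if (policy == "leftmost_nonoverlap") {
    m <- gregexpr(pat, prep, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
  } else { # grep_line: the record counts as a single matching line
    m <- regexpr(pat, prep, perl = TRUE)
    if (m == -1L) return(NULL)
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
  }
  data.frame(start = starts - 1L, len = as.integer(lens),
             text = substring(prep, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

.prep_seq <- function(seq, respect_softmask) {
  if (respect_softmask) {
    # masked (lowercase) bases match nothing, like N
    chartr("acgtn", "NNNNN", seq)
  } else {
    toupper(seq)
  }
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a DNA sequence for exact query matches
#'
#' Matches every query of a query set against a sequence and reports hits
#' as 0-based half-open intervals.  Matching is exact: loops admit only
#' `A`/`C`/`T`, and `N` (or soft-masked lowercase when
#' `respect_softmask = TRUE`) matches nothing.
#'
#' @param seq DNA string.
#' @param qs A `query_set`, single `motif_query`, or list of queries.
#' @param overlap_policy `"leftmost_nonoverlap"` (default; greedy
#'   non-overlapping matches, grep `-o`-like), `"grep_line"` (at most one
#'   hit per record and query, the record counted as one matching line) or
#'   `"all_overlapping"` (every distinct match start).
#' @param strand `"fwd"`, `"rev"` or `"both"`.  Reverse-strand hits are
#'   found on the reverse complement and reported in forward coordinates,
#'   with `matched_text` giving the matched-strand text.
#' @param sequence_id Identifier used in the output.
#' @param strict_tracts Passed to [compile_query()].
#' @param respect_softmask Treat lowercase bases as masked (never match).
#' @return A data frame of hits with columns `sequence_id`, `start`, `end`
#'   (0-based half-open), `strand`, `query_label`, `matched_text`, sorted
#'   by (`sequence_id`, `start`, `query_label`).
#' @examples
#' qs <- enumerate_queries(9, 2)
#' scan_sequence(at26_sequence(), qs, overlap_policy = "all_overlapping")
#' @export
scan_sequence <- function(seq, qs,
                          overlap_policy = c("leftmost_nonoverlap",
                                             "grep_line", "all_overlapping"),
                          strand = c("fwd", "rev", "both"),
                          sequence_id = "seq", strict_tracts = FALSE,
                          respect_softmask = FALSE) {
  overlap_policy <- match.arg(overlap_policy)
  strand <- match.arg(strand)
  if (!nzchar(seq)) return(.empty_hits())
  .check_dna(seq)
  queries <- .as_query_list(qs)
  if (!length(queries)) stop("`qs` is empty")
  n <- nchar(seq)
  strands <- switch(strand, fwd = "+", rev = "-", both = c("+", "-"))
  res <- list()
  for (sd in strands) {
    s <- if (sd == "+") seq else .revcomp(seq)
    prep <- .prep_seq(s, respect_softmask)
    for (q in queries) {
      cq <- compile_query(q, strict_tracts)
      h <- .scan_one(prep, cq, overlap_policy)
      if (is.null(h)) next
      if (sd == "+") {
        start <- h$start; end <- h$start + h$len
      } else {
        start <- n - (h$start + h$len); end <- n - h$start
      }
      res[[length(res) + 1L]] <- data.frame(
        sequence_id = sequence_id, start = start, end = end, strand = sd,
        query_label = q$label, matched_text = h$text,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.empty_hits())
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$sequence_id, hits$start, hits$query_label), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan a FASTA file and summarise hits per query
#'
#' Applies [scan_sequence()] to every record of a (possibly gzipped)
#' multi-record FASTA file.
#'
#' @param fasta_path Path to a FASTA file.
#' @param qs,overlap_policy,strand,strict_tracts,respect_softmask As in
#'   [scan_sequence()].
#' @param bed_path Optional path; when given, hits are written as BED6.
#' @return An object of class `scan_result`: list with `hits` (BED-like
#'   data frame), `summary` (data frame `query_label`, `n_hits`, including
#'   zero-hit queries), `total` hit count, and `manifest` recording the
#'   scan parameters.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">AT26", at26_sequence()), fa)
#' scan_fasta(fa, enumerate_queries(9, 2))$total
#' @export
scan_fasta <- function(fasta_path, qs,
                       overlap_policy = c("leftmost_nonoverlap", "grep_line",
                                          "all_overlapping"),
                       strand = c("fwd", "rev", "both"),
                       strict_tracts = FALSE, respect_softmask = FALSE,
                       bed_path = NULL) {
  overlap_policy <- match.arg(overlap_policy)
  strand <- match.arg(strand)
  seqs <- read_fasta(fasta_path)
  if (anyDuplicated(names(seqs))) {
    stop("duplicated FASTA record IDs: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  queries <- .as_query_list(qs)
  all_hits <- .empty_hits()
  for (id in names(seqs)) {
    if (!nzchar(seqs[[id]])) next
    h <- scan_sequence(seqs[[id]], queries, overlap_policy, strand,
                       sequence_id = id, strict_tracts = strict_tracts,
                       respect_softmask = respect_softmask)
    all_hits <- rbind(all_hits, h)
  }
  labels <- sort(vapply(queries, `[[`, "", "label"))
  counts <- table(factor(all_hits$query_label, levels = labels))
  summary <- data.frame(query_label = labels,
                        n_hits = as.integer(counts[labels]),
                        stringsAsFactors = FALSE)
  if (!is.null(bed_path)) write_bed(all_hits, bed_path)
  out <- list(
    hits = all_hits, summary = summary, total = nrow(all_hits),
    manifest = run_manifest("scan",
                            parameters = list(overlap_policy = overlap_policy,
                                              strand = strand,
                                              strict_tracts = strict_tracts,
                                              respect_softmask = respect_softmask,
                                              n_queries = length(queries)),
                            inputs = fasta_path))
  class(out) <- "scan_result"
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("G4 motif scan: %d hit(s) over %d quer%s\n", x$total,
              nrow(x$summary), if (nrow(x$summary) == 1) "y" else "ies"))
  hit <- x$summary[x$summary$n_hits > 0L, , drop = FALSE]
  if (nrow(hit)) print(hit, row.names = FALSE)
  invisible(x)
}
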