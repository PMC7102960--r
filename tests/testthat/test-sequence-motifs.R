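test_that("tract decomposition reports maximal G-runs and counts", {
  d <- decompose_tracts(at26_sequence())
  expect_equal(nchar(at26_sequence()), 28L)
  expect_equal(d$n_g, 16L)
  expect_equal(sum(d$g_run_lengths == 2L), 7L)
  expect_equal(sum(d$g_run_lengths == 1L), 2L)
  expect_equal(d$g_run_lengths, c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 1L))

  d2 <- decompose_tracts("GGGG")
  expect_equal(d2$g_run_lengths, 4L)
  expect_equal(nrow(d2$runs), 1L)

  d3 <- decompose_tracts("TTTT")
  expect_equal(length(d3$g_run_lengths), 0L)
  expect_equal(d3$runs$length, 4L)
  expect_equal(d3$runs$base, "other")

  # runs concatenate back to the input and alternate base class
  d4 <- decompose_tracts("ggTGGNgtA")
  expect_equal(sum(d4$runs$length), 9L)
  expect_true(all(diff(as.integer(d4$runs$base == "G")) != 0L))
})

test_that("tract decomposition rejects bad input with positions", {
  expect_error(decompose_tracts(""), "empty")
  expect_error(decompose_tracts("ACGTX"), "position 5")
})

test_that("query enumeration counts follow the binomial coefficient", {
  expect_equal(length(enumerate_queries(8, 0)$queries), 1L)
  expect_equal(enumerate_queries(8, 0)$queries[[1]]$label, "8G2")
  expect_equal(length(enumerate_queries(9, 2)$queries), 36L)
  expect_equal(length(enumerate_queries(10, 4)$queries), 210L)
  for (n in 2:12) {
    for (m in 0:n) {
      expect_equal(length(enumerate_queries(n, m)$queries), choose(n, m),
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
})

test_that("query labels are unique and deterministically ordered", {
  qs <- enumerate_queries(9, 2)
  labs <- vapply(qs$queries, `[[`, "", "label")
  expect_false(anyDuplicated(labs) > 0L)
  expect_equal(labs, sort(labs))
  expect_equal(qs$family_name, "7G2+2G1")
})

test_that("query enumeration rejects invalid bounds", {
  expect_error(enumerate_queries(1, 0))
  expect_error(enumerate_queries(8, 9))
  expect_error(enumerate_queries(8, 0, loop_min = 0))
  expect_error(enumerate_queries(8, 0, loop_min = 3, loop_max = 2))
  expect_silent(enumerate_queries(8, 0, loop_min = 0, allow_zero_loop = TRUE))
})

test_that("compiled patterns match the intended language", {
  q8 <- enumerate_queries(8, 0)$queries[[1]]
  eight <- paste(rep("GG", 8), collapse = "T")
  h <- scan_sequence(eight, q8, overlap_policy = "all_overlapping")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 0L)
  expect_equal(h$end, nchar(eight))

  # the isolated G of AGRO100 interrupts the 8-tract run
  agro <- "GGTGGTGGTGGTTGTGGTGGTGGTGG"
  expect_equal(nrow(scan_sequence(agro, q8,
                                  overlap_policy = "all_overlapping")), 0L)
  expect_equal(nrow(oracle_scan(agro, q8)), 0L)

  # open-ended tracts admit longer runs, strict mode does not; with
  # overlapping reporting a match may also start inside the long first run
  s3 <- paste0("GGG", substring(eight, 3))
  h3 <- scan_sequence(s3, q8, overlap_policy = "all_overlapping")
  expect_equal(nrow(h3), nrow(oracle_scan(s3, q8)))
  expect_equal(h3$start, c(0L, 1L))
  expect_equal(nrow(scan_sequence(s3, q8,
                                  overlap_policy = "leftmost_nonoverlap")), 1L)
  expect_equal(nrow(scan_sequence(s3, q8, overlap_policy = "all_overlapping",
                                  strict_tracts = TRUE)), 0L)
  expect_equal(nrow(scan_sequence(eight, q8,
                                  overlap_policy = "all_overlapping",
                                  strict_tracts = TRUE)), 1L)
})

test_that("AT26 matches exactly one of the 36 relaxed queries", {
  qs <- enumerate_queries(9, 2)
  h <- scan_sequence(at26_sequence(), qs, overlap_policy = "all_overlapping")
  expect_equal(nrow(h), 1L)
  # the isolated guanines sit at tract positions 5 and 9 (5'->3')
  expect_equal(h$query_label, "7G2+2G1_i05i09")
  # cross-checked with the brute-force oracle for every query
  for (q in qs$queries) {
    or <- oracle_scan(at26_sequence(), q)
    expected <- if (q$label == "7G2+2G1_i05i09") 1L else 0L
    expect_equal(nrow(or), expected, info = q$label)
  }
})

test_that("every hit round-trips through its own compiled pattern", {
  qs <- enumerate_queries(9, 2)
  h <- scan_sequence(at26_sequence(), qs, overlap_policy = "all_overlapping")
  for (i in seq_len(nrow(h))) {
    q <- Filter(function(q) q$label == h$query_label[i], qs$queries)[[1]]
    pat <- compile_query(q)$pattern
    expect_true(grepl(paste0("^(?:", pat, ")$"), h$matched_text[i],
                      perl = TRUE))
  }
})

test_that("scanner agrees with the brute-force oracle on random strings", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(20:200, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.15, 0.10, 0.60, 0.15)), collapse = "")
    nt <- sample(2:4, 1)
    ni <- sample(0:nt, 1)
    qs <- enumerate_queries(nt, ni)
    q <- qs$queries[[sample(length(qs$queries), 1)]]
    strict <- runif(1) < 0.25
    h <- scan_sequence(s, q, overlap_policy = "all_overlapping",
                       strict_tracts = strict)
    or <- oracle_scan(s, q, strict = strict)
    expect_equal(nrow(h), nrow(or), info = paste(i, q$label, s))
    if (nrow(h)) {
      expect_equal(h$start, unname(or[, "start"]))
      expect_equal(h$end - h$start, unname(or[, "len"]))
    }
  }
})

test_that("strand handling reflects coordinates and preserves counts", {
  s <- "GGAGGAGGAGGAGGAGGAGGAGG"     # 8 G2-tracts with 1-nt loops
  q8 <- enumerate_queries(8, 0)
  fwd <- scan_sequence(s, q8, overlap_policy = "all_overlapping",
                       strand = "fwd")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- scan_sequence(rc, q8, overlap_policy = "all_overlapping",
                       strand = "rev")
  expect_equal(nrow(fwd), nrow(rev))
  # reflection: a fwd hit [s, e) corresponds to a rev-strand hit at the
  # mirrored coordinates of the reverse complement
  expect_equal(sort(fwd$start), sort(nchar(s) - rev$end))
  # the reverse complement of s is C-rich and cannot match a G query
  both <- scan_sequence(s, q8, overlap_policy = "all_overlapping",
                        strand = "both")
  expect_equal(nrow(both), nrow(fwd))
  expect_true(all(both$strand == "+"))
})

test_that("N matches neither tracts nor loops; softmask is honoured", {
  q8 <- enumerate_queries(8, 0)
  s <- "GGTGGTGGTGGTGGTGGTGGTGG"
  sN <- sub("^GGT", "GGN", s)
  expect_equal(nrow(scan_sequence(s, q8)), 1L)
  expect_equal(nrow(scan_sequence(sN, q8)), 0L)
  s_mask <- tolower(substr(s, 1, 2))
  s_masked <- paste0(s_mask, substring(s, 3))
  expect_equal(nrow(scan_sequence(s_masked, q8)), 1L)
  expect_equal(nrow(scan_sequence(s_masked, q8, respect_softmask = TRUE)), 0L)
})

test_that("overlap policies report the expected hit multiplicities", {
  # two-tract toy query over a G-rich run: overlapping starts differ
  q <- enumerate_queries(2, 0)$queries[[1]]
  s <- "GGGTGGG"
  all_h <- scan_sequence(s, q, overlap_policy = "all_overlapping")
  lmo <- scan_sequence(s, q, overlap_policy = "leftmost_nonoverlap")
  grl <- scan_sequence(s, q, overlap_policy = "grep_line")
  expect_equal(nrow(all_h), 2L)   # starts 0 and 1
  expect_equal(nrow(lmo), 1L)
  expect_equal(nrow(grl), 1L)
  expect_equal(lmo$start, 0L)
  # empty input and no-hit input give empty results, not errors
  expect_equal(nrow(scan_sequence("", q)), 0L)
  expect_equal(nrow(scan_sequence("ATATAT", q)), 0L)
})

test_that("FASTA scanning summarises per query and writes BED", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">AT26 some description", at26_sequence(),
               ">empty", "",
               ">bg", "ATATATATAT"), fa)
  qs <- enumerate_queries(9, 2)
  res <- scan_fasta(fa, qs, overlap_policy = "all_overlapping")
  expect_equal(res$total, 1L)
  expect_equal(nrow(res$summary), 36L)
  expect_equal(sum(res$summary$n_hits), 1L)
  expect_equal(res$summary$n_hits[res$summary$query_label ==
                                    "7G2+2G1_i05i09"], 1L)
  expect_equal(res$hits$sequence_id, "AT26")

  bed <- tempfile(fileext = ".bed")
  res2 <- scan_fasta(fa, qs, overlap_policy = "all_overlapping",
                     bed_path = bed)
  hits <- read_bed(bed)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, res2$hits$start)

  # duplicated record IDs are refused
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), fa2)
  expect_error(scan_fasta(fa2, qs), "duplicated")
})
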