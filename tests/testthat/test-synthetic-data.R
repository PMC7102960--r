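test_that("planted-motif FASTA is reproducible and truthful", {
  motif <- paste(rep("GG", 8), collapse = "T")
  a <- plant_motifs_fasta(20000, 10, motif, seed = 7, label = "8G2")
  b <- plant_motifs_fasta(20000, 10, motif, seed = 7, label = "8G2")
  expect_identical(a, b)
  c2 <- plant_motifs_fasta(20000, 10, motif, seed = 8, label = "8G2")
  expect_equal(nrow(c2$bed), nrow(a$bed))
  expect_false(identical(a$bed$start, c2$bed$start))
  # planted instances are non-overlapping and separated by the minimum gap
  expect_true(all(diff(a$bed$start) >= nchar(motif) + 10L))
  # the planted substring is really there
  for (i in seq_len(nrow(a$bed))) {
    expect_equal(substr(a$sequences[[1]], a$bed$start[i] + 1L, a$bed$end[i]),
                 motif)
  }
})

test_that("scanner recall is 100% with zero false positives on plants", {
  motif <- paste(rep("GG", 8), collapse = "T")
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  fx <- plant_motifs_fasta(100000, 25, motif, seed = 7, label = "8G2",
                           fasta_path = fa, bed_path = bed)
  res <- scan_fasta(fa, enumerate_queries(8, 0),
                    overlap_policy = "all_overlapping")
  expect_equal(res$total, 25L)
  expect_equal(res$hits$start, fx$bed$start)
  expect_equal(res$hits$end, fx$bed$end)
  # count 0 gives a background-only record with no hits
  none <- plant_motifs_fasta(5000, 0, motif, seed = 1)
  h0 <- scan_sequence(none$sequences[[1]], enumerate_queries(8, 0))
  expect_equal(nrow(h0), 0L)
  expect_equal(nrow(none$bed), 0L)
})

test_that("infeasible packing is refused", {
  expect_error(plant_motifs_fasta(100, 10, strrep("GGT", 8), seed = 1),
               "cannot fit")
})

test_that("fixture plans validate their slot grids", {
  expect_error(g4_plan(c(1, 1), list(plan_g(1, 1), plan_g(1, 1))),
               "duplicate")
  expect_error(g4_plan(1, list(plan_g(1, 1), plan_g(2, 1), plan_g(3, 1))),
               "4 columns")
  expect_error(g4_plan(1, list(plan_g(1, 2))), "layer")
})

test_that("coordinate fixtures are bit-reproducible given a seed", {
  a <- build_ideal_g4(plan_parallel(3), n_models = 2, jitter = 0.1,
                      random_orientation = TRUE, seed = 5)
  b <- build_ideal_g4(plan_parallel(3), n_models = 2, jitter = 0.1,
                      random_orientation = TRUE, seed = 5)
  expect_identical(a$structure$xyz, b$structure$xyz)
  c2 <- build_ideal_g4(plan_parallel(3), n_models = 2, jitter = 0.1,
                       random_orientation = TRUE, seed = 6)
  expect_false(identical(a$structure$xyz, c2$structure$xyz))
})

test_that("generator geometry always satisfies the analyzer's detectors", {
  # closed loop between generator and analyzer under default cutoffs
  for (pl in list(plan_parallel(2), plan_parallel(3), plan_at26_like(),
                  plan_two_block(), plan_vs_loops())) {
    fx <- build_ideal_g4(pl, jitter = 0.12, random_orientation = TRUE,
                         seed = 99)
    tets <- assemble_tetrads(fx$structure)
    expect_equal(length(tets), pl$n_layers)
    got <- lapply(tets, function(t) sort(t$labels))
    expect_setequal(got, lapply(fx$truth$tetrads, sort))
  }
})

test_that("fixture truth matches the analyzer on the AT26 twin", {
  fx <- build_ideal_g4(plan_at26_like(), n_models = 2, jitter = 0.05,
                       seed = 41)
  topo <- g4_topology(fx$structure, rmsd = FALSE)
  expect_equal(lapply(topo$tetrads, sort), lapply(fx$truth$tetrads, sort))
  expect_equal(unname(topo$relative_polarity),
               unname(fx$truth$relative_polarity))
  expect_equal(topo$intra_locked, fx$truth$intra_locked)
  expect_equal(loop_kinds(topo$loops),
               loop_kinds(fx$truth$loops[, c("flank5", "flank3", "kind",
                                             "loop_len", "span_layers")]))
})

test_that("simulated melting curves hit theta = 0.5 at Tm by construction", {
  cv <- simulate_melting_curve(40, noise_sd = 0, seed = 1)
  th <- attr(cv, "theta_true")
  expect_equal(th[cv$temperature == 40], 0.5, tolerance = 1e-12)
  # deterministic given seed
  c1 <- simulate_melting_curve(40.8, noise_sd = 0.01, seed = 3)
  c2 <- simulate_melting_curve(40.8, noise_sd = 0.01, seed = 3)
  expect_identical(c1$signal, c2$signal)
  expect_error(simulate_melting_curve(10, t_range = c(15, 90)))
  expect_error(simulate_melting_curve(40, dH = 45))
})

test_that("overwhelming noise leaves the fit flagged as unreliable", {
  cv <- simulate_melting_curve(45, noise_sd = 1, seed = 12)
  fit <- tryCatch(suppressWarnings(fit_two_state(cv)),
                  error = function(e) e)
  if (inherits(fit, "tm_fit")) {
    expect_gt(fit$tm_uncertainty, 1)
  } else {
    expect_match(conditionMessage(fit), "transition")
  }
})
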