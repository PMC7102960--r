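at26_fx <- build_ideal_g4(plan_at26_like(), n_models = 3, jitter = 0.05,
                          seed = 101)
at26_truth_tetrads <- list(c("G2", "G6", "G9", "G12"),
                           c("G15", "G5", "G8", "G11"),
                           c("G20", "G23", "G3", "G17"),
                           c("G21", "G24", "G27", "G18"))

test_that("glycosidic angle computation matches planted targets", {
  ct <- chi_table(at26_fx$structure)
  planted <- at26_fx$truth$chi_target
  for (lab in ct$label) {
    resno <- sub("^G", "", lab)
    expect_equal(ct$chi_mean[ct$label == lab], unname(planted[resno]),
                 tolerance = 0.05, info = lab)
  }
})

test_that("chi is invariant under rotation and antisymmetric under mirror", {
  st <- at26_fx$structure
  chi0 <- compute_chi(st, models = 1L)
  set.seed(5)
  R <- random_rotation_matrix()
  chi_rot <- compute_chi(transform_structure(st, R, c(3, -7, 11)),
                         models = 1L)
  expect_equal(chi_rot$chi_deg, chi0$chi_deg, tolerance = 1e-6)
  # mirror reflection (improper transform) maps chi -> 360 - chi
  M <- diag(c(-1, 1, 1))
  chi_mir <- compute_chi(transform_structure(st, M), models = 1L)
  expect_equal(chi_mir$chi_deg, (360 - chi0$chi_deg) %% 360,
               tolerance = 1e-6)
})

test_that("own torsion agrees with the bio3d torsion on random atoms", {
  set.seed(9)
  for (i in 1:25) {
    p <- matrix(rnorm(12, sd = 3), 4L, 3L)
    ours <- chi_torsion(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p))) %% 360
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("chi classification uses open syn/anti intervals", {
  expect_equal(classify_chi(75.2), "syn")       # measured syn 5'-dG values
  expect_equal(classify_chi(319.4), "undefined")
  expect_equal(classify_chi(155.4), "undefined")
  expect_equal(classify_chi(317.0), "undefined")
  expect_equal(classify_chi(210), "anti")
  expect_equal(classify_chi(c(0, 90, 180, 240)),
               rep("undefined", 4))             # boundaries are open
  # exhaustive scan: the three classes partition [0, 360)
  grid <- seq(0, 359.9, by = 0.1)
  cls <- classify_chi(grid)
  expect_equal(sort(unique(cls)), c("anti", "syn", "undefined"))
  expect_equal(cls == "syn", grid > 0 & grid < 90)
  expect_equal(cls == "anti", grid > 180 & grid < 240)
})

test_that("Hoogsteen edges form one directed 4-cycle per planted tetrad", {
  single <- build_ideal_g4(plan_single_tetrad(), seed = 3)
  e <- detect_hoogsteen_edges(single$structure)
  expect_equal(nrow(e), 4L)
  expect_setequal(e$donor, e$acceptor)   # closed cycle
  expect_true(all(e$d_N2_N7 < 3.1 & e$d_N1_O6 < 3.1))

  e4 <- detect_hoogsteen_edges(at26_fx$structure)
  expect_equal(nrow(e4), 16L)

  tets <- assemble_tetrads(at26_fx$structure)
  expect_equal(length(tets), 4L)
  got <- lapply(tets, function(t) sort(t$labels))
  expect_setequal(got, lapply(at26_truth_tetrads, sort))
  expect_true(all(vapply(tets, `[[`, 0, "planarity_rmsd") < 0.2))
})

test_that("distant guanines yield no edge and open chains no tetrad", {
  single <- build_ideal_g4(plan_single_tetrad(), seed = 3)
  st <- single$structure
  # move one tetrad guanine far away: the 4-cycle breaks into a chain
  res7 <- which(st$atom$resno == 7L)
  xyz <- st$xyz
  cols <- as.vector(t(outer(res7, 0:2, function(i, j) 3 * (i - 1) + 1 + j)))
  xyz[, cols] <- xyz[, cols] + 50
  broken <- g4_structure(st$atom, xyz)
  e <- detect_hoogsteen_edges(broken)
  expect_lt(nrow(e), 4L)
  expect_equal(length(suppressWarnings(assemble_tetrads(broken))), 0L)
})

test_that("stack ordering and polarity detect the reversal between blocks", {
  tets <- assemble_tetrads(at26_fx$structure)
  stack <- order_stack_and_polarity(tets)
  expect_equal(unname(stack$relative_polarity), c("same", "reverse", "same"))
  # bottom-to-top compositions follow the planted layer order
  ordered <- lapply(tets[stack$order], function(t) sort(t$labels))
  expect_equal(ordered, lapply(at26_truth_tetrads, sort))

  par3 <- build_ideal_g4(plan_parallel(3), seed = 4)
  s3 <- order_stack_and_polarity(assemble_tetrads(par3$structure))
  expect_equal(unname(s3$relative_polarity), c("same", "same"))
})

test_that("polarity signs flip under mirror reflection, relative ones do not", {
  tets <- assemble_tetrads(at26_fx$structure)
  stack <- order_stack_and_polarity(tets)
  mir <- transform_structure(at26_fx$structure, diag(c(-1, 1, 1)))
  stack_m <- order_stack_and_polarity(assemble_tetrads(mir))
  expect_equal(stack_m$polarity_sign, -stack$polarity_sign)
  expect_equal(stack_m$relative_polarity, stack$relative_polarity)
})

test_that("relative polarity is invariant to flipping the stack direction", {
  flipped <- transform_structure(at26_fx$structure,
                                 diag(c(1, -1, -1)))  # proper 180 deg flip
  stack_f <- order_stack_and_polarity(assemble_tetrads(flipped))
  stack <- order_stack_and_polarity(assemble_tetrads(at26_fx$structure))
  expect_equal(unname(stack_f$relative_polarity),
               rev(unname(stack$relative_polarity)))
  expect_equal(sort(unique(stack_f$relative_polarity)), c("reverse", "same"))
})

test_that("separated blocks are refused with a diagnostic", {
  # pull the top two layers of a parallel 4-layer fold far from the rest
  st <- build_ideal_g4(plan_parallel(4), seed = 17)$structure
  top_res <- c(3, 4, 8, 9, 13, 14, 18, 19)       # layer 3-4 tract guanines
  rows <- which(st$atom$resno %in% top_res)
  zcols <- 3L * (rows - 1L) + 3L
  xyz <- st$xyz
  xyz[, zcols] <- xyz[, zcols] + 30
  apart <- g4_structure(st$atom, xyz)
  tets <- assemble_tetrads(apart)
  expect_equal(length(tets), 4L)
  expect_error(order_stack_and_polarity(tets), "blocks")
})

test_that("loop taxonomy reproduces the planted intra-locked loop set", {
  loops <- classify_loops(at26_fx$structure)
  expect_equal(loop_kinds(loops), loop_kinds(at26_fx$truth$loops[,
    c("flank5", "flank3", "kind", "loop_len", "span_layers")]))
  lk <- loops[loops$is_loop, ]
  expect_equal(sum(lk$kind == "propeller"), 4L)
  expect_equal(sum(lk$kind == "edgewise"), 1L)
  expect_equal(sum(lk$kind == "bulge"), 2L)
  expect_equal(lk$span_layers[lk$kind == "V_S"], 2L)
  expect_equal(lk$span_layers[lk$kind == "V_R"], 3L)
  expect_equal(lk$loop_len[lk$kind == "V_R"], 0L)
})

test_that("parallel and V-loop fixtures classify as planted", {
  par3 <- build_ideal_g4(plan_parallel(3), seed = 6)
  lp <- classify_loops(par3$structure)
  lp <- lp[lp$is_loop, ]
  expect_equal(nrow(lp), 3L)
  expect_true(all(lp$kind == "propeller"))

  vs <- build_ideal_g4(plan_vs_loops(), seed = 6)
  lv <- classify_loops(vs$structure)
  lv <- lv[lv$is_loop, ]
  expect_equal(sort(lv$span_layers[lv$kind == "V_S"]), c(2L, 3L))
})

test_that("intra-lock requires two blocks and two or more bridges", {
  topo <- g4_topology(at26_fx$structure, rmsd = FALSE)
  expect_equal(length(topo$blocks), 2L)
  expect_equal(topo$blocks[[1]], 1:2)
  expect_equal(nrow(topo$bridging), 3L)
  expect_true(topo$intra_locked)
  expect_setequal(paste(topo$bridging$flank5, topo$bridging$flank3),
                  c("G2 G3", "G3 G5", "G15 G17"))

  tb <- build_ideal_g4(plan_two_block(), seed = 8)
  topo_tb <- g4_topology(tb$structure, rmsd = FALSE)
  expect_equal(length(topo_tb$blocks), 2L)
  expect_equal(nrow(topo_tb$bridging), 1L)
  expect_false(topo_tb$intra_locked)

  par4 <- build_ideal_g4(plan_parallel(4), seed = 8)
  topo_p <- g4_topology(par4$structure, rmsd = FALSE)
  expect_equal(length(topo_p$blocks), 1L)
  expect_false(topo_p$intra_locked)
})

test_that("ensemble RMSD is zero for identical or rigidly moved models", {
  base <- build_ideal_g4(plan_parallel(3), seed = 12)$structure
  dup <- g4_structure(base$atom, rbind(base$xyz, base$xyz))
  r <- ensemble_rmsd(dup, "all_heavy")
  expect_equal(r$mean, 0, tolerance = 1e-6)

  set.seed(13)
  moved <- transform_structure(base, random_rotation_matrix(), c(5, 6, -7))
  pair <- g4_structure(base$atom, rbind(base$xyz, moved$xyz))
  r2 <- ensemble_rmsd(pair, "tetrad_core_heavy")
  expect_equal(r2$mean, 0, tolerance = 1e-6)
  expect_error(ensemble_rmsd(base), "2 models")
})

test_that("ensemble RMSD is invariant under a common rigid transform", {
  fx <- build_ideal_g4(plan_parallel(3), n_models = 4, jitter = 0.1,
                       seed = 21)
  r0 <- ensemble_rmsd(fx$structure, "tetrad_core_heavy")
  set.seed(22)
  moved <- transform_structure(fx$structure, random_rotation_matrix(),
                               c(-4, 2, 9))
  r1 <- ensemble_rmsd(moved, "tetrad_core_heavy")
  expect_equal(r0$mean, r1$mean, tolerance = 1e-6)
  expect_equal(r0$sd, r1$sd, tolerance = 1e-6)
  expect_gt(r0$mean, 0)
  expect_equal(r0$n_pairs, 6L)
})

test_that("the ensemble topology report carries consensus features", {
  topo <- g4_topology(at26_fx$structure)
  expect_equal(topo$n_models, 3L)
  expect_equal(lapply(topo$tetrads, sort),
               lapply(at26_truth_tetrads, sort))
  expect_equal(sort(topo$chi$label[topo$chi$class == "syn"]),
               c("G15", "G2", "G27"))
  expect_equal(topo$chi$class[topo$chi$label == "G3"], "undefined")
  expect_equal(topo$chi$chi_mean[topo$chi$label == "G3"], 317,
               tolerance = 0.05)
  expect_true(topo$intra_locked)
  expect_lt(topo$rmsd$tetrad_core_heavy$mean, 0.2)
  expect_output(print(topo), "intra-locked: TRUE")
})

test_that("single-tetrad structures degrade gracefully", {
  single <- build_ideal_g4(plan_single_tetrad(), seed = 30)
  topo <- g4_topology(single$structure, rmsd = FALSE)
  expect_equal(length(topo$tetrads), 1L)
  expect_equal(length(topo$relative_polarity), 0L)
  expect_false(topo$intra_locked)
  lp <- topo$loops[topo$loops$is_loop, ]
  expect_true(all(lp$kind == "edgewise"))
})
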