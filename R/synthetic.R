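# Synthetic benchmark generators: planted-motif FASTA with truth BED,
# idealized multi-layer G4 coordinate sets with known topology, and
# simulated two-state melting curves.

# evaluate expr with a temporarily seeded RNG (restores the global state)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a FASTA benchmark with planted motif instances
#'
#' Plants `count` copies of a motif at random non-overlapping positions
#' (separated by at least `min_gap` nucleotides) in each record.  The
#' background is drawn from `{A, C, T}` only, so it can never contain a
#' G-tract and the planted instances are the only matches; the true
#' coordinates are returned as a BED-style data frame.
#'
#' @param record_length Length of each record (nt).
#' @param count Number of planted instances per record (0 allowed).
#' @param motif The motif instance to plant (DNA string).
#' @param n_records Number of records.
#' @param min_gap Minimum background gap between planted instances.
#' @param seed Integer seed; the output is reproducible given
#'   (parameters, seed).
#' @param label Name used in the truth BED.
#' @param fasta_path,bed_path Optional output paths (FASTA / BED6).
#' @return List with `sequences` (named character vector) and `bed` (truth
#'   data frame with `sequence_id`, `start`, `end`, `strand`,
#'   `query_label`).
#' @examples
#' fx <- plant_motifs_fasta(5000, 5, motif = strrep("GGT", 8), seed = 7)
#' nrow(fx$bed)
#' @export
plant_motifs_fasta <- function(record_length, count, motif, n_records = 1L,
                               min_gap = 10L, seed = NULL, label = "motif",
                               fasta_path = NULL, bed_path = NULL) {
  motif <- .check_dna(motif, "motif")
  len <- nchar(motif)
  count <- as.integer(count)
  stopifnot(count >= 0L, record_length >= 1L, min_gap >= 0L)
  spare <- record_length - count * len - max(0L, count - 1L) * min_gap
  if (spare < 0L) {
    stop(sprintf(
      "cannot fit %d instances of a %d-nt motif with gap >= %d in %d nt",
      count, len, min_gap, record_length))
  }
  .with_seed(seed, {
    seqs <- character(n_records)
    beds <- list()
    for (r in seq_len(n_records)) {
      id <- if (n_records == 1L) "synth1" else paste0("synth", r)
      starts <- integer(0)
      if (count > 0L) {
        extra <- sort(sample.int(spare + 1L, count, replace = TRUE) - 1L)
        starts <- extra + (seq_len(count) - 1L) * (len + min_gap)
      }
      bg <- function(n) {
        if (n <= 0L) return("")
        paste(sample(c("A", "C", "T"), n, replace = TRUE), collapse = "")
      }
      pieces <- character(0)
      at <- 0L
      for (s in starts) {
        pieces <- c(pieces, bg(s - at), motif)
        at <- s + len
      }
      pieces <- c(pieces, bg(record_length - at))
      seqs[r] <- paste(pieces, collapse = "")
      stopifnot(nchar(seqs[r]) == record_length)
      names(seqs)[r] <- id
      if (count > 0L) {
        beds[[r]] <- data.frame(sequence_id = id, start = starts,
                                end = starts + len, strand = "+",
                                query_label = label,
                                stringsAsFactors = FALSE)
      }
    }
    bed <- if (length(beds)) do.call(rbind, beds) else {
      data.frame(sequence_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 query_label = character(0), stringsAsFactors = FALSE)
    }
    if (!is.null(fasta_path)) {
      writeLines(paste0(">", names(seqs), "\n", seqs), fasta_path)
    }
    if (!is.null(bed_path)) write_bed(bed, bed_path)
    list(sequences = seqs, bed = bed)
  })
}

# ---------------------------------------------------------------------------
# Idealized G4 coordinate fixtures

#' Specify a G4 fixture topology plan
#'
#' A plan is a strand program: an ordered path of tetrad-guanine slots
#' (`corner column` 1..4, `layer` 1..n) and loop segments, together with
#' the per-layer stacking polarity.  Every layer must have all four columns
#' occupied exactly once, so that each layer forms a complete G-tetrad.
#'
#' @param polarity Numeric vector of +1/-1 per layer (bottom to top).
#' @param path List of elements from [plan_g()] / [plan_loop()].
#' @param chi Optional named numeric vector of glycosidic chi targets in
#'   degrees, keyed by residue number; guanines default to 210 (anti).
#' @param rise Inter-layer rise in angstrom (default 3.3).
#' @param twist Helical twist per layer in degrees (default 30).
#' @return An object of class `g4_plan`.
#' @seealso [plan_parallel()], [plan_at26_like()], [plan_two_block()],
#'   [plan_vs_loops()], [build_ideal_g4()]
#' @export
g4_plan <- function(polarity, path, chi = NULL, rise = 3.3, twist = 30) {
  stopifnot(all(polarity %in% c(-1, 1)), length(polarity) >= 1L)
  n_layers <- length(polarity)
  gs <- Filter(function(e) e$type == "G", path)
  slots <- vapply(gs, function(e) paste(e$column, e$layer), "")
  if (anyDuplicated(slots)) stop("duplicate (column, layer) slot in plan")
  cols <- vapply(gs, `[[`, 0, "column")
  lays <- vapply(gs, `[[`, 0, "layer")
  if (any(cols < 1 | cols > 4)) stop("columns must be in 1..4")
  if (any(lays < 1 | lays > n_layers)) stop("layer outside polarity vector")
  for (l in seq_len(n_layers)) {
    if (!setequal(cols[lays == l], 1:4)) {
      stop(sprintf("layer %d does not have all 4 columns occupied", l))
    }
  }
  out <- list(polarity = polarity, path = path, chi = chi, rise = rise,
              twist = twist, n_layers = n_layers)
  class(out) <- "g4_plan"
  out
}

#' @rdname g4_plan
#' @param column,layer Slot of a tetrad guanine.
#' @export
plan_g <- function(column, layer) {
  list(type = "G", column = as.integer(column), layer = as.integer(layer))
}

#' @rdname g4_plan
#' @param len Number of loop (thymine) residues.
#' @export
plan_loop <- function(len) list(type = "loop", len = as.integer(len))

#' Canned fixture plans
#'
#' * `plan_parallel(n_layers, loop_len)`: all-parallel G4; four tracts run
#'   up the four corner columns, connected by `loop_len`-nt propeller
#'   loops.  One block, no lock.
#' * `plan_at26_like()`: structural twin of the intra-locked AT26 fold:
#'   four layers with polarity (+,+,-,-), two bi-layered blocks bridged by
#'   a 0-nt V_R loop spanning three layers, two 1-nt bulges, plus four
#'   propeller loops, one 2-nt V_S loop and one 2-nt edgewise loop; syn
#'   guanines at residues 2, 15 and 27 and an undefined glycosidic angle
#'   (317 degrees) at residue 3.
#' * `plan_two_block(bridge_len)`: two independent bi-layered blocks of
#'   opposite polarity joined by a single linker -- two blocks but only one
#'   bridging point, hence not intra-locked.
#' * `plan_vs_loops()`: three same-polarity layers with a same-column V_S
#'   loop spanning three layers and a second V_S loop spanning two.
#' * `plan_single_tetrad()`: one tetrad connected by edgewise loops.
#'
#' @param n_layers Number of layers for `plan_parallel`.
#' @param loop_len Propeller loop length (nt).
#' @return A `g4_plan`.
#' @export
plan_parallel <- function(n_layers = 3L, loop_len = 1L) {
  path <- list()
  for (col in 1:4) {
    if (col > 1L) path <- c(path, list(plan_loop(loop_len)))
    for (l in seq_len(n_layers)) path <- c(path, list(plan_g(col, l)))
  }
  g4_plan(rep(1, n_layers), path)
}

#' @rdname plan_parallel
#' @export
plan_at26_like <- function() {
  path <- list(
    plan_loop(1L), plan_g(1, 1), plan_g(2, 3), plan_loop(1L),
    plan_g(2, 2), plan_g(2, 1), plan_loop(1L), plan_g(3, 2), plan_g(3, 1),
    plan_loop(1L), plan_g(4, 2), plan_g(4, 1), plan_loop(2L), plan_g(1, 2),
    plan_loop(1L), plan_g(1, 3), plan_g(1, 4), plan_loop(1L), plan_g(4, 3),
    plan_g(4, 4), plan_loop(1L), plan_g(3, 3), plan_g(3, 4), plan_loop(2L),
    plan_g(2, 4), plan_loop(1L))
  chi <- c("2" = 60, "15" = 60, "27" = 60, "3" = 317)
  g4_plan(c(1, 1, -1, -1), path, chi = chi)
}

#' @rdname plan_parallel
#' @param bridge_len Length (nt) of the single block-connecting linker.
#' @export
plan_two_block <- function(bridge_len = 2L) {
  path <- list(
    plan_g(1, 1), plan_g(1, 2), plan_loop(1L), plan_g(2, 2), plan_g(2, 1),
    plan_loop(1L), plan_g(3, 1), plan_g(3, 2), plan_loop(1L), plan_g(4, 2),
    plan_g(4, 1), plan_loop(bridge_len),
    plan_g(1, 3), plan_g(1, 4), plan_loop(1L), plan_g(2, 4), plan_g(2, 3),
    plan_loop(1L), plan_g(3, 3), plan_g(3, 4), plan_loop(1L), plan_g(4, 4),
    plan_g(4, 3))
  g4_plan(c(1, 1, -1, -1), path)
}

#' @rdname plan_parallel
#' @export
plan_vs_loops <- function() {
  path <- list(
    plan_g(1, 1), plan_g(1, 3), plan_loop(1L), plan_g(2, 3), plan_g(2, 2),
    plan_g(2, 1), plan_loop(1L), plan_g(3, 1), plan_g(3, 2), plan_g(3, 3),
    plan_loop(1L), plan_g(4, 3), plan_g(4, 2), plan_g(4, 1), plan_loop(2L),
    plan_g(1, 2))
  g4_plan(c(1, 1, 1), path)
}

#' @rdname plan_parallel
#' @export
plan_single_tetrad <- function() {
  path <- list(plan_g(1, 1), plan_loop(1L), plan_g(2, 1), plan_loop(1L),
               plan_g(3, 1), plan_loop(1L), plan_g(4, 1))
  g4_plan(1, path)
}

# residue layout of a plan: one row per residue
.plan_residues <- function(plan) {
  rows <- list()
  resno <- 0L
  for (e in plan$path) {
    if (e$type == "G") {
      resno <- resno + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        resno = resno, resid = "DG", column = e$column, layer = e$layer,
        stringsAsFactors = FALSE)
    } else {
      for (i in seq_len(e$len)) {
        resno <- resno + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          resno = resno, resid = "DT", column = NA_integer_,
          layer = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# plan-level truth: loop kinds, blocks, lock -- derived from slots and
# sequence adjacency only (no geometry)
.plan_truth <- function(plan) {
  res <- .plan_residues(plan)
  g <- res[res$resid == "DG", , drop = FALSE]
  pol <- plan$polarity
  tetrads <- lapply(seq_len(plan$n_layers), function(l) {
    gl <- g[g$layer == l, , drop = FALSE]
    gl$resno[order(gl$column)]
  })
  supported <- function(resno) {
    me <- g[g$resno == resno, ]
    for (nb in c(resno - 1L, resno + 1L)) {
      o <- g[g$resno == nb, , drop = FALSE]
      if (nrow(o) && o$column == me$column && abs(o$layer - me$layer) == 1L) {
        return(TRUE)
      }
    }
    FALSE
  }
  cons <- list()
  for (p in seq_len(nrow(g) - 1L)) {
    r5 <- g$resno[p]; r3 <- g$resno[p + 1L]
    r <- r3 - r5 - 1L
    a <- g$layer[p]; b <- g$layer[p + 1L]
    ca <- g$column[p]; cb <- g$column[p + 1L]
    pol_same <- pol[a] == pol[b]
    if (a == b) {
      dc <- abs(ca - cb)
      kind <- if (dc %in% c(1L, 3L)) "edgewise" else "diagonal"
    } else if (ca == cb) {
      if (abs(a - b) == 1L) {
        kind <- if (r == 0L) "tract" else "bulge"
      } else {
        kind <- if (pol_same) "V_S" else "V_R"
      }
    } else if (!supported(r5) || !supported(r3)) {
      kind <- if (pol_same) "V_S" else "V_R"
    } else {
      kind <- if (pol_same) "propeller" else "linker"
    }
    cons[[length(cons) + 1L]] <- data.frame(
      flank5 = paste0("G", r5), flank3 = paste0("G", r3), kind = kind,
      loop_len = r, span_layers = abs(a - b) + 1L, layer5 = a, layer3 = b,
      stringsAsFactors = FALSE)
  }
  connectors <- do.call(rbind, cons)
  block_of <- cumsum(c(1, as.integer(pol[-1L] != pol[-length(pol)])))
  bridging <- connectors[block_of[connectors$layer5] !=
                           block_of[connectors$layer3], , drop = FALSE]
  chi <- stats::setNames(rep(210, nrow(g)), g$resno)
  if (!is.null(plan$chi)) chi[names(plan$chi)] <- plan$chi
  list(
    tetrads = lapply(tetrads, function(t) paste0("G", t)),
    polarity_sign = pol,
    relative_polarity = ifelse(pol[-1L] == pol[-length(pol)],
                               "same", "reverse"),
    loops = connectors[connectors$kind != "tract", , drop = FALSE],
    connectors = connectors,
    n_blocks = max(block_of), n_bridging = nrow(bridging),
    intra_locked = max(block_of) >= 2L && nrow(bridging) >= 2L,
    chi_target = chi,
    chi_class = stats::setNames(classify_chi(chi %% 360), paste0("G", g$resno)))
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' Build an idealized multi-model G4 coordinate fixture
#'
#' Realizes a [g4_plan()] as atomic coordinates: guanine bases are placed
#' as planar cyclic Hoogsteen quartets (N2-N7 and N1-O6 distances of
#' 2.90 angstrom), layers are stacked at the plan's rise and twist,
#' reverse-polarity layers are built with the opposite cycle circulation,
#' sugar O4'/C1' atoms realize the planned glycosidic chi per residue, and
#' loop thymines are placed as non-clashing spacers outside the core.  The
#' returned truth records the planted tetrads, polarities, loop kinds and
#' chi classes.
#'
#' @param plan A `g4_plan`.
#' @param n_models Number of models (replicates with independent jitter).
#' @param jitter Maximum per-atom displacement (angstrom): each atom is
#'   displaced in a uniformly random direction by a uniformly random
#'   amount up to `jitter`.  Bounded displacements keep every planted
#'   Hoogsteen distance within the detection cutoff by construction.
#' @param random_orientation Apply a random global rotation and translation
#'   per model.
#' @param seed Integer seed (reproducible output).
#' @param pdb_path Optional path; coordinates are written as multi-model
#'   PDB.
#' @param truth_path Optional path; truth is written as JSON.
#' @return List of class `g4_fixture` with `structure` (a
#'   [g4_structure()]), `truth` and `plan`.
#' @examples
#' fx <- build_ideal_g4(plan_at26_like(), n_models = 2, jitter = 0.05,
#'                      seed = 1)
#' fx$truth$intra_locked
#' @export
build_ideal_g4 <- function(plan, n_models = 1L, jitter = 0,
                           random_orientation = FALSE, seed = NULL,
                           pdb_path = NULL, truth_path = NULL) {
  stopifnot(inherits(plan, "g4_plan"))
  res <- .plan_residues(plan)
  truth <- .plan_truth(plan)
  unit <- .guanine_tetrad_unit()
  base_names <- rownames(unit)
  cent0 <- colMeans(unit[.base_atom_names(), , drop = FALSE])
  beta0 <- atan2(cent0[2L], cent0[1L]) * 180 / pi
  mirr <- unit; mirr[, 2L] <- -mirr[, 2L]
  atom_rows <- list()
  coords <- list()
  corner_angle <- function(col, layer) {
    (col - 1L) * 90 + (layer - 1L) * plan$twist
  }
  g_idx <- which(res$resid == "DG")
  # guanine atoms
  for (i in g_idx) {
    col <- res$column[i]; lay <- res$layer[i]
    delta <- corner_angle(col, lay)
    X <- if (plan$polarity[lay] > 0) {
      unit %*% t(.rotz(delta))
    } else {
      mirr %*% t(.rotz(delta + 2 * beta0))
    }
    X[, 3L] <- X[, 3L] + (lay - 1L) * plan$rise
    chi <- truth$chi_target[[as.character(res$resno[i])]]
    o4 <- .place_atom(X["C4", ], X["N9", ], X["C1'", ],
                      bond = 1.42, angle_deg = 108.2, torsion_deg = chi)
    X <- rbind(X, "O4'" = o4)
    atom_rows[[length(atom_rows) + 1L]] <- data.frame(
      elety = rownames(X), resid = "DG", chain = "A", resno = res$resno[i],
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- X
  }
  # loop thymines: arcs at a radius outside the core
  r_loop <- 11.5
  g_pos <- function(i) {   # corner anchor of a guanine residue (angle, z)
    c(angle = beta0 + corner_angle(res$column[i], res$layer[i]),
      z = (res$layer[i] - 1L) * plan$rise)
  }
  t_idx <- which(res$resid == "DT")
  if (length(t_idx)) {
    runs <- split(t_idx, cumsum(c(1L, diff(t_idx) != 1L)))
    for (run in runs) {
      before <- run[1L] - 1L; after <- run[length(run)] + 1L
      has_b <- before >= 1L; has_a <- after <= nrow(res)
      if (has_b && has_a) {
        pb <- g_pos(before); pa <- g_pos(after)
        dang <- ((pa["angle"] - pb["angle"] + 180) %% 360) - 180
        anchors <- lapply(seq_along(run), function(k) {
          tf <- k / (length(run) + 1)
          c(angle = unname(pb["angle"] + tf * dang),
            z = unname(pb["z"] + tf * (pa["z"] - pb["z"])))
        })
      } else if (has_a) {        # 5' terminal tail: below and outside
        pa <- g_pos(after)
        anchors <- lapply(rev(seq_along(run)), function(k) {
          c(angle = unname(pa["angle"] - 30 * k),
            z = unname(pa["z"] - 2.5 * k), radius = r_loop + 2.5)
        })
      } else if (has_b) {        # 3' terminal tail: above and outside
        pb <- g_pos(before)
        anchors <- lapply(seq_along(run), function(k) {
          c(angle = unname(pb["angle"] + 30 * k),
            z = unname(pb["z"] + 2.5 * k), radius = r_loop + 2.5)
        })
      } else {
        stop("plan contains a loop with no flanking guanines")
      }
      for (k in seq_along(run)) {
        an <- anchors[[k]]
        rr <- if ("radius" %in% names(an)) an[["radius"]] else r_loop
        rad <- an["angle"] * pi / 180
        u <- c(cos(rad), sin(rad), 0)        # radial
        v <- c(-sin(rad), cos(rad), 0)       # tangential
        p <- rr * u + c(0, 0, an["z"])
        X <- rbind("C1'" = p, N1 = p + 1.4 * v + c(0, 0, 0.4),
                   C2 = p + 1.2 * u + c(0, 0, -0.4))
        atom_rows[[length(atom_rows) + 1L]] <- data.frame(
          elety = rownames(X), resid = "DT", chain = "A",
          resno = res$resno[run[k]], stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- X
      }
    }
  }
  blk_resno <- vapply(atom_rows, function(a) a$resno[1L], 0L)
  ord <- order(blk_resno)
  atom <- do.call(rbind, atom_rows[ord])
  xyz0 <- do.call(rbind, coords[ord])
  atom$eleno <- seq_len(nrow(atom))
  atom <- atom[, c("eleno", "elety", "resid", "chain", "resno")]
  # steric sanity: non-bonded (inter-residue) contacts >= 1.5 A
  dm <- as.matrix(stats::dist(xyz0))
  same_res <- outer(atom$resno, atom$resno, "==")
  dm[same_res] <- Inf
  if (min(dm) < 1.5) {
    w <- which(dm == min(dm), arr.ind = TRUE)[1L, ]
    stop(sprintf("steric clash: %s/%s%d and %s/%s%d at %.2f A",
                 atom$elety[w[1L]], atom$resid[w[1L]], atom$resno[w[1L]],
                 atom$elety[w[2L]], atom$resid[w[2L]], atom$resno[w[2L]],
                 min(dm)))
  }
  st <- .with_seed(seed, {
    xyz <- matrix(0, n_models, 3L * nrow(atom))
    for (m in seq_len(n_models)) {
      X <- xyz0
      if (jitter > 0) {
        dir <- matrix(stats::rnorm(length(xyz0)), nrow(xyz0), 3L)
        dir <- dir / sqrt(rowSums(dir^2))
        X <- X + dir * stats::runif(nrow(xyz0), 0, jitter)
      }
      if (random_orientation) {
        X <- X %*% t(.random_rotation())
        X <- sweep(X, 2L, stats::runif(3L, -20, 20), "+")
      }
      xyz[m, ] <- as.vector(t(X))
    }
    g4_structure(atom, xyz)
  })
  if (!is.null(pdb_path)) write_g4_pdb(st, pdb_path)
  if (!is.null(truth_path)) write_report(truth, truth_path)
  out <- list(structure = st, truth = truth, plan = plan)
  class(out) <- "g4_fixture"
  out
}

#' Write a g4_structure as a (multi-model) PDB file
#'
#' @param st A `g4_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_g4_pdb <- function(st, path) {
  stopifnot(inherits(st, "g4_structure"))
  bio3d::write.pdb(file = path, xyz = st$xyz, resno = st$atom$resno,
                   resid = st$atom$resid, chain = st$atom$chain,
                   eleno = st$atom$eleno, elety = st$atom$elety)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Simulated melting curves

#' Simulate a two-state van't Hoff melting curve
#'
#' The true fraction folded follows the van't Hoff two-state model
#' `theta(T) = 1 / (1 + exp((dH / R) (1/T - 1/Tm)))` with absolute
#' temperatures, so `theta(Tm) = 0.5` exactly.  The observed signal is
#' `theta * baseF(T) + (1 - theta) * baseU(T)` plus Gaussian noise.
#'
#' @param tm Melting temperature (degrees Celsius); must lie inside
#'   `t_range`.
#' @param dH van't Hoff folding enthalpy in kcal/mol (negative for
#'   folding; default -45).
#' @param t_range Temperature range (degrees Celsius).
#' @param step Sampling interval (degrees Celsius).
#' @param folded_baseline,unfolded_baseline Linear baselines
#'   `c(intercept, slope)` in signal units.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed Integer seed.
#' @param branch `"heating"` (ascending temperatures) or `"cooling"`.
#' @return A data frame of class `melting_curve` with columns
#'   `temperature`, `signal`, `branch` and an attribute `theta_true`.
#' @examples
#' cv <- simulate_melting_curve(40.8, noise_sd = 0.01, seed = 2)
#' fit_two_state(cv)$tm
#' @export
simulate_melting_curve <- function(tm, dH = -45, t_range = c(15, 90),
                                   step = 0.5,
                                   folded_baseline = c(1, 0),
                                   unfolded_baseline = c(0, 0),
                                   noise_sd = 0, seed = NULL,
                                   branch = c("heating", "cooling")) {
  branch <- match.arg(branch)
  stopifnot(tm > t_range[1L], tm < t_range[2L], dH < 0)
  R <- 0.0019872           # kcal mol^-1 K^-1
  tt <- seq(t_range[1L], t_range[2L], by = step)
  if (branch == "cooling") tt <- rev(tt)
  tk <- tt + 273.15
  theta <- 1 / (1 + exp((dH / R) * (1 / tk - 1 / (tm + 273.15))))
  s_f <- folded_baseline[1L] + folded_baseline[2L] * tt
  s_u <- unfolded_baseline[1L] + unfolded_baseline[2L] * tt
  signal <- theta * s_f + (1 - theta) * s_u
  signal <- .with_seed(seed, signal + stats::rnorm(length(tt), 0, noise_sd))
  out <- data.frame(temperature = tt, signal = signal, branch = branch,
                    stringsAsFactors = FALSE)
  attr(out, "theta_true") <- theta
  class(out) <- c("melting_curve", "data.frame")
  out
}
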