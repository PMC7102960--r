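# Topology analysis of G-quadruplex coordinates: glycosidic angles,
# Hoogsteen tetrad detection, stacking polarity, loop taxonomy, intra-lock
# architecture and ensemble RMSD.

.gua_resids <- c("DG", "G", "GUA")

# unique residues in (chain, resno) order
.residue_table <- function(st) {
  res <- unique(st$atom[, c("chain", "resno", "resid")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  res$key <- paste(res$chain, res$resno, sep = ":")
  res$label <- paste0(sub("^D", "", res$resid), res$resno)
  rownames(res) <- NULL
  res
}

# coordinates of one named atom for a set of residues; NA rows if absent
.atom_coords <- function(st, model, keys, elety) {
  xyz <- model_coords(st, model)
  akey <- paste(st$atom$chain, st$atom$resno, sep = ":")
  out <- matrix(NA_real_, length(keys), 3L)
  sel <- which(st$atom$elety == elety)
  m <- match(keys, akey[sel])
  ok <- !is.na(m)
  out[ok, ] <- xyz[sel[m[ok]], , drop = FALSE]
  out
}

# guanine geometry of one model: one row per guanine with key atoms and the
# base-plane centroid
.guanine_geometry <- function(st, model = 1L) {
  res <- .residue_table(st)
  gua <- res[res$resid %in% .gua_resids, , drop = FALSE]
  if (!nrow(gua)) stop("structure contains no guanine residues")
  geo <- list(res = gua)
  for (a in c("N1", "N2", "N7", "O6", "N9")) {
    geo[[a]] <- .atom_coords(st, model, gua$key, a)
  }
  xyz <- model_coords(st, model)
  akey <- paste(st$atom$chain, st$atom$resno, sep = ":")
  base <- .base_atom_names()
  geo$base_centroid <- t(vapply(gua$key, function(k) {
    rows <- which(akey == k & st$atom$elety %in% base)
    colMeans(xyz[rows, , drop = FALSE])
  }, numeric(3L)))
  geo$base_xyz <- lapply(gua$key, function(k) {
    rows <- which(akey == k & st$atom$elety %in% base)
    xyz[rows, , drop = FALSE]
  })
  names(geo$base_xyz) <- gua$key
  geo
}

#' Glycosidic torsion angle from four atom positions
#'
#' Computes the guanine glycosidic angle chi, the torsion defined by the
#' O4'-C1'-N9-C4 atoms, mapped to `[0, 360)` degrees.
#'
#' @param o4,c1,n9,c4 Numeric length-3 position vectors (angstrom).
#' @return Angle in degrees in `[0, 360)`.
#' @examples
#' chi_torsion(c(1, 1, 1), c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
#' @export
chi_torsion <- function(o4, c1, n9, c4) {
  stopifnot(length(o4) == 3L, length(c1) == 3L, length(n9) == 3L,
            length(c4) == 3L,
            all(is.finite(c(o4, c1, n9, c4))))
  .torsion_deg(o4, c1, n9, c4) %% 360
}

#' Glycosidic angles of all guanines in a structure
#'
#' @param st A `g4_structure`.
#' @param models Model indices (default all).
#' @return Data frame with columns `model`, `chain`, `resno`, `label`,
#'   `chi_deg` (degrees in `[0, 360)`).
#' @export
compute_chi <- function(st, models = seq_len(st$n_models)) {
  res <- .residue_table(st)
  gua <- res[res$resid %in% .gua_resids, , drop = FALSE]
  if (!nrow(gua)) stop("structure contains no guanine residues")
  out <- list()
  for (m in models) {
    ats <- lapply(c("O4'", "C1'", "N9", "C4"), function(a) {
      .atom_coords(st, m, gua$key, a)
    })
    names(ats) <- c("O4'", "C1'", "N9", "C4")
    for (a in names(ats)) {
      miss <- which(!stats::complete.cases(ats[[a]]))
      if (length(miss)) {
        stop(sprintf("residue %s is missing atom %s", gua$label[miss[1L]], a))
      }
    }
    chi <- vapply(seq_len(nrow(gua)), function(i) {
      chi_torsion(ats[["O4'"]][i, ], ats[["C1'"]][i, ],
                  ats[["N9"]][i, ], ats[["C4"]][i, ])
    }, 0)
    out[[length(out) + 1L]] <- data.frame(
      model = m, chain = gua$chain, resno = gua$resno, label = gua$label,
      chi_deg = chi, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify a glycosidic angle as syn, anti or undefined
#'
#' Uses open-interval class boundaries: syn for `0 < chi < 90`, anti for
#' `180 < chi < 240`, otherwise undefined (boundary values included in
#' undefined).
#'
#' @param chi_deg Numeric vector of angles in `[0, 360)` degrees.
#' @return Character vector in `{"syn", "anti", "undefined"}`.
#' @examples
#' classify_chi(c(75.2, 319.4, 210, 90))
#' @export
classify_chi <- function(chi_deg) {
  stopifnot(is.numeric(chi_deg), all(is.finite(chi_deg)),
            all(chi_deg >= 0 & chi_deg < 360))
  ifelse(chi_deg > 0 & chi_deg < 90, "syn",
         ifelse(chi_deg > 180 & chi_deg < 240, "anti", "undefined"))
}

# circular mean and sd (degrees)
.circ_stats <- function(deg) {
  rad <- deg * pi / 180
  s <- mean(sin(rad)); cc <- mean(cos(rad))
  mu <- (atan2(s, cc) * 180 / pi) %% 360
  rbar <- min(1, sqrt(s^2 + cc^2))
  sd <- if (rbar <= 0) Inf else sqrt(-2 * log(rbar)) * 180 / pi
  c(mean = mu, sd = sd)
}

#' Ensemble glycosidic-angle table
#'
#' Circular mean and circular standard deviation of chi per guanine across
#' models, with the syn/anti/undefined class of the mean.
#'
#' @param st A `g4_structure`.
#' @return Data frame with `label`, `chi_mean`, `chi_sd`, `class`.
#' @export
chi_table <- function(st) {
  chi <- compute_chi(st)
  labs <- unique(chi$label)
  stats <- t(vapply(labs, function(l) {
    .circ_stats(chi$chi_deg[chi$label == l])
  }, c(mean = 0, sd = 0)))
  data.frame(label = labs, chi_mean = stats[, "mean"], chi_sd = stats[, "sd"],
             class = classify_chi(stats[, "mean"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect directed Hoogsteen guanine-guanine edges
#'
#' A directed edge donor -> acceptor is recorded when both heavy-atom
#' hydrogen-bond distances N2(donor)-N7(acceptor) and N1(donor)-O6(acceptor)
#' are within `cutoff`.  Each guanine keeps at most one outgoing and one
#' incoming edge (closest total distance wins).
#'
#' @param st A `g4_structure`.
#' @param model Model index.
#' @param cutoff Distance cutoff in angstrom (default 3.5, the restraint
#'   target 2.9 plus two tolerances).
#' @return Data frame with `donor`, `acceptor` (residue keys
#'   `"chain:resno"`), `donor_label`, `acceptor_label`, `d_N2_N7`,
#'   `d_N1_O6`.
#' @export
detect_hoogsteen_edges <- function(st, model = 1L, cutoff = 3.5) {
  geo <- .guanine_geometry(st, model)
  n <- nrow(geo$res)
  ok <- stats::complete.cases(geo$N1) & stats::complete.cases(geo$N2) &
    stats::complete.cases(geo$N7) & stats::complete.cases(geo$O6)
  idx <- which(ok)
  cand <- NULL
  if (length(idx) >= 2L) {
    pd <- function(A, B) {
      # cross pairwise distances between row sets
      out <- matrix(0, length(idx), length(idx))
      for (i in seq_along(idx)) {
        d <- sweep(B[idx, , drop = FALSE], 2L, A[idx[i], ])
        out[i, ] <- sqrt(rowSums(d^2))
      }
      out
    }
    d1 <- pd(geo$N2, geo$N7)   # donor N2 -> acceptor N7
    d2 <- pd(geo$N1, geo$O6)   # donor N1 -> acceptor O6
    hit <- which(d1 <= cutoff & d2 <= cutoff, arr.ind = TRUE)
    hit <- hit[hit[, 1L] != hit[, 2L], , drop = FALSE]
    if (nrow(hit)) {
      cand <- data.frame(di = idx[hit[, 1L]], ai = idx[hit[, 2L]],
                         d1 = d1[hit], d2 = d2[hit])
      cand <- cand[order(cand$d1 + cand$d2), , drop = FALSE]
      used_out <- used_in <- logical(n)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!used_out[cand$di[i]] && !used_in[cand$ai[i]]) {
          keep[i] <- TRUE
          used_out[cand$di[i]] <- TRUE
          used_in[cand$ai[i]] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(cand) || !nrow(cand)) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      donor_label = character(0), acceptor_label = character(0),
                      d_N2_N7 = numeric(0), d_N1_O6 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(donor = geo$res$key[cand$di],
                    acceptor = geo$res$key[cand$ai],
                    donor_label = geo$res$label[cand$di],
                    acceptor_label = geo$res$label[cand$ai],
                    d_N2_N7 = cand$d1, d_N1_O6 = cand$d2,
                    stringsAsFactors = FALSE)
  out[order(out$donor), , drop = FALSE]
}

#' Assemble G-tetrads from Hoogsteen edges
#'
#' Every simple directed 4-cycle of Hoogsteen edges becomes a tetrad whose
#' cyclic member order is the donor-to-acceptor order.  Cycles of other
#' lengths are reported as warnings.  Tetrads whose base heavy atoms
#' deviate from their least-squares plane by more than `planarity_max`
#' (RMSD) are dropped with a warning.
#'
#' @param st A `g4_structure`.
#' @param model Model index.
#' @param edges Optional precomputed edge table from
#'   [detect_hoogsteen_edges()].
#' @param cutoff Passed to [detect_hoogsteen_edges()] when `edges` is NULL.
#' @param planarity_max Maximum allowed planarity RMSD in angstrom.
#' @return A list of class `g4_tetrads`; each element has `members` (keys
#'   in cyclic order), `labels`, `planarity_rmsd`, `centroid`, `normal`,
#'   `base_centroids` (4 x 3), `n9` (4 x 3).
#' @export
assemble_tetrads <- function(st, model = 1L, edges = NULL, cutoff = 3.5,
                             planarity_max = 0.75) {
  if (is.null(edges)) edges <- detect_hoogsteen_edges(st, model, cutoff)
  geo <- .guanine_geometry(st, model)
  succ <- stats::setNames(edges$acceptor, edges$donor)
  nodes <- unique(c(edges$donor, edges$acceptor))
  seen <- character(0)
  tetrads <- list()
  for (start in nodes) {
    if (start %in% seen) next
    path <- start
    cur <- start
    repeat {
      nxt <- succ[cur]
      if (is.na(nxt)) break
      if (nxt == start) {
        if (length(path) == 4L) {
          seen <- c(seen, path)
          # canonical rotation: start at lexicographically smallest key
          k <- which(path == sort(path)[1L])[1L]
          cyc <- path[((seq_len(4L) + k - 2L) %% 4L) + 1L]
          i <- match(cyc, geo$res$key)
          bx <- do.call(rbind, geo$base_xyz[cyc])
          pr <- .plane_rmsd(bx)
          if (pr > planarity_max) {
            warning(sprintf("dropping non-planar 4-cycle %s (rmsd %.2f A)",
                            paste(geo$res$label[i], collapse = "."), pr))
          } else {
            tetrads[[length(tetrads) + 1L]] <- list(
              members = cyc, labels = geo$res$label[i],
              planarity_rmsd = pr, centroid = colMeans(bx),
              normal = .plane_normal(bx),
              base_centroids = geo$base_centroid[i, , drop = FALSE],
              n9 = geo$N9[i, , drop = FALSE])
          }
        } else {
          seen <- c(seen, path)
          warning(sprintf("Hoogsteen cycle of length %d ignored (%s)",
                          length(path), paste(path, collapse = " -> ")))
        }
        break
      }
      if (nxt %in% path) break     # cycle not through start
      path <- c(path, nxt)
      cur <- nxt
      if (length(path) > length(nodes)) break
    }
  }
  class(tetrads) <- "g4_tetrads"
  tetrads
}

#' @export
print.g4_tetrads <- function(x, ...) {
  cat(sprintf("%d G-tetrad(s)\n", length(x)))
  for (t in x) {
    cat("  ", paste(t$labels, collapse = "."),
        sprintf("  (planarity rmsd %.2f A)\n", t$planarity_rmsd), sep = "")
  }
  invisible(x)
}

#' Order tetrads along the stacking axis and assign polarities
#'
#' The stack axis is the first principal direction of the tetrad centroids,
#' oriented bottom to top.  Adjacent centroids must be separated by
#' `sep_range` angstrom, otherwise the tetrads do not form a single stack
#' and an error lists the detected blocks.  The polarity sign of a layer is
#' the orientation of its donor-to-acceptor cycle viewed along the axis
#' (sign of the summed cross products of successive centroid-to-N9
#' vectors); `relative_polarity[i]` is `"same"` when layers i and i+1 agree.
#'
#' @param tetrads A `g4_tetrads` list (>= 2 tetrads).
#' @param sep_range Allowed adjacent-centroid separation (angstrom).
#' @return A list of class `g4_stack`: `order` (indices into `tetrads`,
#'   bottom to top), `axis`, `polarity_sign` (per layer), and
#'   `relative_polarity` (`"same"`/`"reverse"`, length layers - 1).
#' @export
order_stack_and_polarity <- function(tetrads, sep_range = c(2.5, 5.0)) {
  if (length(tetrads) < 2L) stop("need at least 2 tetrads to order a stack")
  cent <- t(vapply(tetrads, `[[`, numeric(3L), "centroid"))
  pc <- stats::prcomp(cent, center = TRUE)
  axis <- pc$rotation[, 1L]
  proj <- drop(cent %*% axis)
  ord <- order(proj)
  # the global orientation of a stack is arbitrary; adopt the convention
  # that the layer holding the lowest-numbered guanine lies in the bottom
  # half (the customary way these structures are drawn and numbered)
  resno_min <- vapply(tetrads, function(t) {
    min(as.integer(sub("^.*:", "", t$members)))
  }, 0L)
  anchor_layer <- which(ord == which.min(resno_min))
  if (anchor_layer > (length(ord) + 1) / 2) {
    axis <- -axis
    ord <- rev(ord)
  }
  seps <- sqrt(rowSums((cent[ord[-1L], , drop = FALSE] -
                          cent[ord[-length(ord)], , drop = FALSE])^2))
  if (any(seps < sep_range[1L] | seps > sep_range[2L])) {
    grp <- cumsum(c(1, seps > sep_range[2L]))
    blocks <- split(vapply(tetrads[ord], function(t) {
      paste(t$labels, collapse = ".")
    }, ""), grp)
    stop("tetrads do not form a single stack; detected blocks: ",
         paste(vapply(blocks, paste, "", collapse = " | "), collapse = " // "))
  }
  pol <- vapply(tetrads[ord], function(t) {
    v <- sweep(t$n9, 2L, t$centroid)
    s <- 0
    for (i in 1:4) {
      j <- i %% 4L + 1L
      s <- s + sum(.cross3(v[i, ], v[j, ]) * axis)
    }
    sign(s)
  }, 0)
  rel <- ifelse(pol[-1L] == pol[-length(pol)], "same", "reverse")
  out <- list(order = ord, axis = axis, polarity_sign = pol,
              relative_polarity = rel)
  class(out) <- "g4_stack"
  out
}

# map guanine key -> layer and corner column.  Columns chain stacked
# guanines between adjacent layers by nearest projected base centroid.
.assign_layers_columns <- function(tetrads, stack) {
  ord <- stack$order
  axis <- stack$axis
  n_layers <- length(ord)
  layer_of <- col_of <- integer(0)
  proj <- function(p) p - drop(p %*% axis) %*% t(axis)  # rows projected
  # layer 1 defines columns 1..4 in cyclic order
  cols <- list()
  for (l in seq_len(n_layers)) {
    t <- tetrads[[ord[l]]]
    layer_of[t$members] <- l
    if (l == 1L) {
      col_of[t$members] <- 1:4
      cols[[1L]] <- proj(t$base_centroids)
    } else {
      prev <- tetrads[[ord[l - 1L]]]
      P <- proj(prev$base_centroids)
      Q <- proj(t$base_centroids)
      D <- matrix(0, 4L, 4L)
      for (i in 1:4) D[i, ] <- sqrt(rowSums(sweep(Q, 2L, P[i, ])^2))
      # greedy bipartite matching, smallest distance first
      assign <- integer(4L)
      used_p <- used_q <- logical(4L)
      for (k in 1:4) {
        w <- which(D == min(D[!used_p, !used_q, drop = FALSE]), arr.ind = TRUE)
        w <- w[!used_p[w[, 1L]] & !used_q[w[, 2L]], , drop = FALSE][1L, ]
        assign[w[2L]] <- col_of[prev$members[w[1L]]]
        used_p[w[1L]] <- TRUE; used_q[w[2L]] <- TRUE
      }
      col_of[t$members] <- assign
    }
  }
  list(layer = layer_of, column = col_of)
}

#' Classify the connecting loops of a G-quadruplex
#'
#' Walks the residue sequence and, for every maximal run of non-tetrad
#' residues (possibly empty) between two tetrad guanines of the same
#' strand, assigns a loop type:
#' \describe{
#'   \item{edgewise / diagonal}{flanks in the same layer, Hoogsteen-cycle
#'     adjacent / opposite;}
#'   \item{bulge}{flanks stacked in the same corner column in adjacent
#'     layers with at least one interrupting residue;}
#'   \item{V_S / V_R}{flanks in different layers where the covalent G-G
#'     support of a corner column is missing -- either the flanks share a
#'     column two or more layers apart, or one flank lacks a
#'     sequence-adjacent same-column guanine in a neighbouring layer;
#'     subtype `V_S` when the two connected layers have the same polarity,
#'     `V_R` when reversed;}
#'   \item{propeller}{flanks in different columns of same-polarity layers,
#'     both covalently supported in their columns;}
#'   \item{linker}{any other connector (diagnosed, not classified);}
#'   \item{tract}{a direct same-column step between adjacent layers (an
#'     ordinary G-tract step, not a loop).}
#' }
#'
#' @param st A `g4_structure`.
#' @param model Model index.
#' @param tetrads,stack Optional precomputed [assemble_tetrads()] /
#'   [order_stack_and_polarity()] results.
#' @param cutoff,planarity_max Passed on when `tetrads` is NULL.
#' @return Data frame with one row per connector: `flank5`, `flank3`
#'   (labels), `kind`, `loop_len`, `span_layers`, `layer5`, `layer3`,
#'   `column5`, `column3`, `residues` (comma-separated loop residue
#'   labels), `is_loop`.
#' @export
classify_loops <- function(st, model = 1L, tetrads = NULL, stack = NULL,
                           cutoff = 3.5, planarity_max = 0.75) {
  if (is.null(tetrads)) {
    tetrads <- assemble_tetrads(st, model, cutoff = cutoff,
                                planarity_max = planarity_max)
  }
  if (is.null(stack)) stack <- order_stack_and_polarity(tetrads)
  lc <- .assign_layers_columns(tetrads, stack)
  res <- .residue_table(st)
  in_tetrad <- res$key %in% names(lc$layer)
  # cyclic position within the layer's tetrad
  cyc_pos <- integer(0)
  for (t in tetrads) cyc_pos[t$members] <- 1:4
  pol <- stack$polarity_sign
  # covalent column support: a sequence-adjacent guanine in the same
  # column, one layer away
  supported <- function(i) {
    k <- res$key[i]
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > nrow(res)) next
      if (res$chain[j] != res$chain[i]) next
      if (abs(res$resno[j] - res$resno[i]) != 1L) next
      kj <- res$key[j]
      if (!kj %in% names(lc$layer)) next
      if (lc$column[kj] == lc$column[k] &&
          abs(lc$layer[kj] - lc$layer[k]) == 1L) {
        return(TRUE)
      }
    }
    FALSE
  }
  out <- list()
  for (ch in unique(res$chain)) {
    ridx <- which(res$chain == ch)
    tg <- ridx[in_tetrad[ridx]]
    if (length(tg) < 2L) next
    for (p in seq_len(length(tg) - 1L)) {
      i5 <- tg[p]; i3 <- tg[p + 1L]
      between <- ridx[ridx > i5 & ridx < i3]
      r <- length(between)
      k5 <- res$key[i5]; k3 <- res$key[i3]
      a <- lc$layer[k5]; b <- lc$layer[k3]
      ca <- lc$column[k5]; cb <- lc$column[k3]
      pol_same <- pol[a] == pol[b]
      if (a == b) {
        dpos <- abs(cyc_pos[k5] - cyc_pos[k3])
        kind <- if (dpos %in% c(1L, 3L)) "edgewise" else "diagonal"
      } else if (ca == cb) {
        if (abs(a - b) == 1L) {
          kind <- if (r == 0L) "tract" else "bulge"
        } else {
          kind <- if (pol_same) "V_S" else "V_R"
        }
      } else {
        if (!supported(i5) || !supported(i3)) {
          kind <- if (pol_same) "V_S" else "V_R"
        } else {
          kind <- if (pol_same) "propeller" else "linker"
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        flank5 = res$label[i5], flank3 = res$label[i3], kind = kind,
        loop_len = r, span_layers = abs(a - b) + 1L,
        layer5 = unname(a), layer3 = unname(b),
        column5 = unname(ca), column3 = unname(cb),
        residues = paste(res$label[between], collapse = ","),
        is_loop = kind != "tract", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(flank5 = character(0), flank3 = character(0),
                      kind = character(0), loop_len = integer(0),
                      span_layers = integer(0), layer5 = integer(0),
                      layer3 = integer(0), column5 = integer(0),
                      column3 = integer(0), residues = character(0),
                      is_loop = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect intra-locked two-block architecture
#'
#' Blocks are maximal groups of adjacent layers not separated by a polarity
#' reversal.  Bridging linkers are connectors (loops, bulges, V-loops or
#' direct G-G steps) whose flanking guanines lie in different blocks.  A
#' structure is intra-locked when it has at least two blocks fastened by at
#' least two bridging linkers.
#'
#' @param stack A `g4_stack` from [order_stack_and_polarity()].
#' @param connectors Connector table from [classify_loops()].
#' @return List with `blocks` (list of layer-index vectors),
#'   `block_of_layer`, `bridging` (subset of `connectors`), `n_blocks`,
#'   `n_bridging`, `intra_locked`.
#' @export
detect_intralock <- function(stack, connectors) {
  n_layers <- length(stack$polarity_sign)
  breaks <- stack$relative_polarity == "reverse"
  block_of <- cumsum(c(1L, as.integer(breaks)))
  blocks <- split(seq_len(n_layers), block_of)
  bridging <- connectors[block_of[connectors$layer5] !=
                           block_of[connectors$layer3], , drop = FALSE]
  list(blocks = unname(blocks), block_of_layer = block_of,
       bridging = bridging, n_blocks = length(blocks),
       n_bridging = nrow(bridging),
       intra_locked = length(blocks) >= 2L && nrow(bridging) >= 2L)
}

#' Pairwise superposed RMSD over an ensemble of models
#'
#' For every unordered pair of models, performs an optimal least-squares
#' rigid superposition on the selected atom subset and reports the mean and
#' standard deviation of the resulting coordinate RMSDs.
#'
#' @param st A `g4_structure` with at least two models.
#' @param subset `"tetrad_core_heavy"` (heavy atoms of the tetrad guanine
#'   nucleotides; tetrads detected on model 1 unless `tetrad_keys` is
#'   given) or `"all_heavy"`.
#' @param tetrad_keys Optional character vector of residue keys
#'   (`"chain:resno"`) defining the core.
#' @return Object of class `ensemble_rmsd`: list with `mean`, `sd`,
#'   `n_pairs`, `n_atoms`, `subset`.
#' @export
ensemble_rmsd <- function(st, subset = c("tetrad_core_heavy", "all_heavy"),
                          tetrad_keys = NULL) {
  subset <- match.arg(subset)
  if (st$n_models < 2L) stop("need at least 2 models for ensemble RMSD")
  heavy <- !grepl("^[0-9]*H", st$atom$elety)
  keep <- heavy
  if (subset == "tetrad_core_heavy") {
    if (is.null(tetrad_keys)) {
      tet <- assemble_tetrads(st, 1L)
      tetrad_keys <- unlist(lapply(tet, `[[`, "members"))
    }
    akey <- paste(st$atom$chain, st$atom$resno, sep = ":")
    keep <- keep & akey %in% tetrad_keys
  }
  if (!any(keep)) stop("empty atom subset for RMSD")
  cols <- as.vector(t(outer(which(keep), 0:2,
                            function(i, j) 3L * (i - 1L) + 1L + j)))
  pairs <- utils::combn(st$n_models, 2L)
  vals <- apply(pairs, 2L, function(p) {
    bio3d::rmsd(st$xyz[p[1L], cols], st$xyz[p[2L], cols], fit = TRUE)
  })
  out <- list(mean = mean(vals), sd = stats::sd(vals),
              n_pairs = ncol(pairs), n_atoms = sum(keep), subset = subset)
  class(out) <- "ensemble_rmsd"
  out
}

#' @export
print.ensemble_rmsd <- function(x, ...) {
  cat(sprintf("Pairwise superposed RMSD (%s, %d atoms, %d pairs): %.2f +/- %.2f A\n",
              x$subset, x$n_atoms, x$n_pairs, x$mean,
              if (is.na(x$sd)) 0 else x$sd))
  invisible(x)
}

# full single-model analysis
.model_topology <- function(st, model, cutoff, planarity_max, sep_range) {
  tetrads <- assemble_tetrads(st, model, cutoff = cutoff,
                              planarity_max = planarity_max)
  if (!length(tetrads)) {
    return(list(tetrads = tetrads, stack = NULL, connectors = NULL,
                lock = NULL))
  }
  if (length(tetrads) == 1L) {
    # degenerate single-layer stack: axis = plane normal
    stack <- list(order = 1L, axis = tetrads[[1L]]$normal,
                  polarity_sign = 1, relative_polarity = character(0))
    class(stack) <- "g4_stack"
  } else {
    stack <- order_stack_and_polarity(tetrads, sep_range)
  }
  connectors <- classify_loops(st, model, tetrads, stack)
  lock <- detect_intralock(stack, connectors)
  list(tetrads = tetrads, stack = stack, connectors = connectors,
       lock = lock)
}

# majority vote over a character vector
.majority <- function(x, n_total) {
  tab <- sort(table(x), decreasing = TRUE)
  if (!length(tab) || tab[1L] * 2L <= n_total) return(NA_character_)
  names(tab)[1L]
}

#' Full topology report of a G-quadruplex ensemble
#'
#' Runs the complete per-model analysis chain (Hoogsteen edges, tetrads,
#' stacking order and polarity, corner columns, loop taxonomy, intra-lock
#' detection) and reports the ensemble consensus: a feature is kept when it
#' is present in more than half of the models.  Glycosidic angles are
#' reported as circular mean and circular standard deviation over models.
#'
#' @param st A `g4_structure`.
#' @param cutoff Hoogsteen heavy-atom distance cutoff (angstrom).
#' @param planarity_max Maximum tetrad planarity RMSD (angstrom).
#' @param sep_range Allowed adjacent-layer centroid separation (angstrom).
#' @param rmsd Compute ensemble RMSDs when the structure has >= 2 models.
#' @return Object of class `g4_topology` with elements `chi` (data frame),
#'   `tetrads` (list of label vectors in cyclic order, bottom to top),
#'   `polarity_sign`, `relative_polarity`, `loops` (consensus connector
#'   table), `blocks`, `bridging`, `intra_locked`, `rmsd`, `n_models`, and
#'   `per_model` (raw per-model results).
#' @examples
#' fx <- build_ideal_g4(plan_parallel(3), n_models = 2, seed = 1)
#' topo <- g4_topology(fx$structure)
#' topo$intra_locked
#' @export
g4_topology <- function(st, cutoff = 3.5, planarity_max = 0.75,
                        sep_range = c(2.5, 5.0), rmsd = TRUE) {
  stopifnot(inherits(st, "g4_structure"))
  n <- st$n_models
  per <- lapply(seq_len(n), function(m) {
    .model_topology(st, m, cutoff, planarity_max, sep_range)
  })
  # consensus tetrad compositions (unordered member sets)
  comp <- lapply(per, function(p) {
    vapply(p$tetrads, function(t) paste(sort(t$members), collapse = "|"), "")
  })
  all_sets <- unique(unlist(comp))
  keep_sets <- all_sets[vapply(all_sets, function(s) {
    sum(vapply(comp, function(cc) s %in% cc, TRUE)) * 2L > n
  }, TRUE)]
  # representative model: first model containing all consensus sets
  rep_m <- which(vapply(comp, function(cc) all(keep_sets %in% cc), TRUE))[1L]
  if (is.na(rep_m)) rep_m <- 1L
  rep <- per[[rep_m]]
  rep_sets <- comp[[rep_m]]
  sel <- which(rep_sets %in% keep_sets)
  ord <- if (!is.null(rep$stack)) rep$stack$order else seq_along(sel)
  ord <- ord[ord %in% sel]
  tet_labels <- lapply(rep$tetrads[ord], `[[`, "labels")
  # consensus loop kinds per connector
  loops <- NULL
  if (!is.null(rep$connectors) && nrow(rep$connectors)) {
    loops <- rep$connectors
    key <- paste(loops$flank5, loops$flank3)
    kinds <- lapply(seq_len(n), function(m) {
      cm <- per[[m]]$connectors
      if (is.null(cm)) return(stats::setNames(character(0), character(0)))
      stats::setNames(cm$kind, paste(cm$flank5, cm$flank3))
    })
    loops$kind <- vapply(key, function(k) {
      v <- unlist(lapply(kinds, function(km) km[k]))
      mk <- .majority(v[!is.na(v)], n)
      if (is.na(mk)) "linker" else mk
    }, "")
    loops$is_loop <- loops$kind != "tract"
  }
  lock <- rep$lock
  rmsd_out <- NULL
  if (rmsd && n >= 2L) {
    keys <- unlist(lapply(rep$tetrads[ord], `[[`, "members"))
    rmsd_out <- list(
      tetrad_core_heavy = ensemble_rmsd(st, "tetrad_core_heavy",
                                        tetrad_keys = keys),
      all_heavy = ensemble_rmsd(st, "all_heavy"))
  }
  out <- list(
    chi = chi_table(st),
    tetrads = tet_labels,
    polarity_sign = if (!is.null(rep$stack)) rep$stack$polarity_sign else NULL,
    relative_polarity = if (!is.null(rep$stack)) {
      rep$stack$relative_polarity
    } else NULL,
    loops = loops,
    blocks = if (!is.null(lock)) lock$blocks else list(),
    bridging = if (!is.null(lock)) lock$bridging else NULL,
    intra_locked = if (!is.null(lock)) lock$intra_locked else FALSE,
    rmsd = rmsd_out, n_models = n, representative_model = rep_m,
    per_model = per)
  class(out) <- "g4_topology"
  out
}

#' @export
print.g4_topology <- function(x, ...) {
  cat(sprintf("G-quadruplex topology (%d model(s))\n", x$n_models))
  cat(sprintf("  %d tetrad layer(s), bottom to top:\n", length(x$tetrads)))
  for (i in seq_along(x$tetrads)) {
    cat(sprintf("    L%d: %s  [polarity %+d]\n", i,
                paste(x$tetrads[[i]], collapse = "."),
                x$polarity_sign[i]))
  }
  if (length(x$relative_polarity)) {
    cat("  relative polarity:", paste(x$relative_polarity, collapse = ", "),
        "\n")
  }
  if (!is.null(x$loops)) {
    lp <- x$loops[x$loops$is_loop, , drop = FALSE]
    if (nrow(lp)) {
      cat("  loops:\n")
      for (i in seq_len(nrow(lp))) {
        cat(sprintf("    %s -> %s: %s (%d nt, spans %d layer(s))\n",
                    lp$flank5[i], lp$flank3[i], lp$kind[i], lp$loop_len[i],
                    lp$span_layers[i]))
      }
    }
  }
  cat(sprintf("  blocks: %d; bridging linkers: %d; intra-locked: %s\n",
              length(x$blocks),
              if (is.null(x$bridging)) 0L else nrow(x$bridging),
              x$intra_locked))
  syn <- x$chi$label[x$chi$class == "syn"]
  cat(sprintf("  syn guanines: %s\n",
              if (length(syn)) paste(syn, collapse = ", ") else "none"))
  if (!is.null(x$rmsd)) {
    cat(sprintf("  pairwise RMSD: core %.2f +/- %.2f A; all heavy %.2f +/- %.2f A\n",
                x$rmsd$tetrad_core_heavy$mean, x$rmsd$tetrad_core_heavy$sd,
                x$rmsd$all_heavy$mean, x$rmsd$all_heavy$sd))
  }
  invisible(x)
}
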