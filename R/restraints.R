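# NMR-style restraint table generation from a declared topology.
#
# Targets and tolerances follow the standard G4 NMR structure-calculation
# recipe: Hoogsteen H-bond distances H21-N7 (2.0 +/- 0.2 A), N2-N7
# (2.9 +/- 0.3 A), H1-O6 (2.0 +/- 0.2 A), N1-O6 (2.9 +/- 0.3 A); chi
# dihedrals anti (240 +/- 70) deg and syn (60 +/- 70) deg; NOE classes as
# in `noe_bounds()`.

.hbond_defs <- data.frame(
  atom_a = c("H21", "N2", "H1", "N1"),
  atom_b = c("N7", "N7", "O6", "O6"),
  target = c(2.0, 2.9, 2.0, 2.9),
  tolerance = c(0.2, 0.3, 0.2, 0.3),
  stringsAsFactors = FALSE)

.noe_classes <- data.frame(
  name = c("strong", "medium", "medium_weak", "weak",
           "strong", "medium", "weak"),
  exchangeable = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  target = c(2.7, 3.8, 4.6, 5.5, 4.0, 4.8, 5.5),
  tolerance = c(0.8, 0.9, 1.2, 1.7, 1.2, 1.4, 1.7),
  stringsAsFactors = FALSE)

#' Hoogsteen hydrogen-bond restraints for declared tetrads
#'
#' Generates the four distance restraints (H21-N7, N2-N7, H1-O6, N1-O6) for
#' every donor-to-acceptor pair of each tetrad: 16 restraints per tetrad.
#'
#' @param tetrads List of character vectors, each a 4-tuple of residue
#'   labels in cyclic donor-to-acceptor order (e.g. [at26_tetrads()]).
#' @return A data frame of class `restraint_table` with columns
#'   `residue_a`, `atom_a`, `residue_b`, `atom_b`, `target`, `tolerance`,
#'   `category` (`"hbond"`).
#' @examples
#' nrow(hoogsteen_restraints(at26_tetrads()))  # 64
#' @export
hoogsteen_restraints <- function(tetrads) {
  stopifnot(is.list(tetrads))
  if (!length(tetrads)) return(.empty_restraints())
  lens <- vapply(tetrads, length, 0L)
  if (any(lens != 4L)) stop("every tetrad must have exactly 4 guanines")
  all_g <- unlist(tetrads)
  if (anyDuplicated(all_g)) {
    stop("guanine(s) appear in more than one tetrad: ",
         paste(unique(all_g[duplicated(all_g)]), collapse = ", "))
  }
  rows <- list()
  for (tet in tetrads) {
    for (i in 1:4) {
      donor <- tet[i]; acceptor <- tet[i %% 4L + 1L]
      for (k in seq_len(nrow(.hbond_defs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          residue_a = donor, atom_a = .hbond_defs$atom_a[k],
          residue_b = acceptor, atom_b = .hbond_defs$atom_b[k],
          target = .hbond_defs$target[k],
          tolerance = .hbond_defs$tolerance[k],
          category = "hbond", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("restraint_table", "data.frame")
  out
}

.empty_restraints <- function() {
  out <- data.frame(residue_a = character(0), atom_a = character(0),
                    residue_b = character(0), atom_b = character(0),
                    target = numeric(0), tolerance = numeric(0),
                    category = character(0), stringsAsFactors = FALSE)
  class(out) <- c("restraint_table", "data.frame")
  out
}

#' Glycosidic dihedral restraints from syn/anti classes
#'
#' One O4'-C1'-N9-C4 dihedral restraint per classified guanine:
#' (240 +/- 70) degrees for anti, (60 +/- 70) degrees for syn.  Residues in
#' `exclusions` (e.g. guanines with undefined glycosidic conformation, like
#' G3 of AT26) receive no restraint.
#'
#' @param chi_classes Named character vector mapping residue labels to
#'   `"syn"` or `"anti"`.
#' @param exclusions Character vector of residue labels to exclude.
#' @return A data frame of class `dihedral_table` with columns `residue`,
#'   `atoms`, `target`, `tolerance`, `class`.
#' @examples
#' nrow(dihedral_restraints(at26_chi_classes(), exclusions = "G3"))  # 15
#' @export
dihedral_restraints <- function(chi_classes, exclusions = character(0)) {
  stopifnot(is.character(chi_classes), !is.null(names(chi_classes)))
  bad <- setdiff(unique(chi_classes), c("syn", "anti"))
  if (length(bad)) stop("chi classes must be 'syn' or 'anti', got: ",
                        paste(bad, collapse = ", "))
  both <- intersect(names(chi_classes), exclusions)
  if (length(both)) {
    stop("residue(s) both classified and excluded: ",
         paste(both, collapse = ", "))
  }
  keep <- setdiff(names(chi_classes), exclusions)
  if (!length(keep)) {
    out <- data.frame(residue = character(0), atoms = character(0),
                      target = numeric(0), tolerance = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
    class(out) <- c("dihedral_table", "data.frame")
    return(out)
  }
  out <- data.frame(
    residue = keep,
    atoms = "O4'-C1'-N9-C4",
    target = ifelse(chi_classes[keep] == "anti", 240, 60),
    tolerance = 70,
    class = unname(chi_classes[keep]),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("dihedral_table", "data.frame")
  out
}

#' NOE distance-restraint bounds for a peak class
#'
#' Returns the target and tolerance (angstrom) for an NOE intensity class.
#' Non-exchangeable classes: strong (2.7 +/- 0.8), medium (3.8 +/- 0.9),
#' medium_weak (4.6 +/- 1.2), weak (5.5 +/- 1.7).  Exchangeable classes:
#' strong (4.0 +/- 1.2), medium (4.8 +/- 1.4), weak (5.5 +/- 1.7); there is
#' no exchangeable medium_weak class.  Distances involving thymine methyl
#' protons are loosened by 0.5 A.
#'
#' @param class_name One of `"strong"`, `"medium"`, `"medium_weak"`,
#'   `"weak"`.
#' @param exchangeable Logical; exchangeable-proton class table.
#' @param methyl_involved Logical; widen the tolerance by 0.5 A.
#' @return Named numeric vector `c(target = , tolerance = )`.
#' @examples
#' noe_bounds("strong")                      # 2.7 +/- 0.8
#' noe_bounds("weak", exchangeable = TRUE)   # 5.5 +/- 1.7
#' @export
noe_bounds <- function(class_name, exchangeable = FALSE,
                       methyl_involved = FALSE) {
  class_name <- match.arg(class_name,
                          c("strong", "medium", "medium_weak", "weak"))
  row <- .noe_classes[.noe_classes$name == class_name &
                        .noe_classes$exchangeable == exchangeable, ,
                      drop = FALSE]
  if (!nrow(row)) {
    stop("no '", class_name, "' class for exchangeable protons")
  }
  tol <- row$tolerance + if (isTRUE(methyl_involved)) 0.5 else 0
  c(target = row$target, tolerance = tol)
}

#' Planarity restraint groups for declared tetrads
#'
#' One planarity group per tetrad; the weight (default 1, the customary
#' force constant in kcal mol^-1 A^-2 for tetrad planarity) is recorded as
#' metadata only.
#'
#' @param tetrads List of 4-tuples of residue labels.
#' @param weight Force-constant placeholder.
#' @return Data frame with `group`, `guanines`, `weight`.
#' @export
planarity_groups <- function(tetrads, weight = 1) {
  stopifnot(is.list(tetrads))
  if (!length(tetrads)) {
    return(data.frame(group = integer(0), guanines = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(group = seq_along(tetrads),
             guanines = vapply(tetrads, paste, "", collapse = "."),
             weight = weight, stringsAsFactors = FALSE)
}

#' Write a restraint table as TSV (optionally XPLOR-flavoured text)
#'
#' The native format is a neutral tab-separated table.  With
#' `xplor = TRUE` an XPLOR-style `assign` statement is emitted per distance
#' restraint (convenience output; engine-exact syntax is not claimed).
#'
#' @param restraints A `restraint_table` (distance restraints).
#' @param path Output path.
#' @param xplor Emit XPLOR-flavoured text instead of TSV.
#' @return Invisibly, `path`.
#' @export
write_restraints <- function(restraints, path, xplor = FALSE) {
  stopifnot(is.data.frame(restraints))
  if (xplor) {
    lines <- sprintf(
      "assign (resid %s and name %s) (resid %s and name %s) %.1f %.1f %.1f",
      gsub("[^0-9]", "", restraints$residue_a), restraints$atom_a,
      gsub("[^0-9]", "", restraints$residue_b), restraints$atom_b,
      restraints$target, restraints$tolerance, restraints$tolerance)
    writeLines(lines, path)
  } else {
    utils::write.table(restraints, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV restraint table written by [write_restraints()]
#'
#' @param path Path to the TSV file.
#' @return A `restraint_table` data frame.
#' @export
read_restraints <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("restraint_table", "data.frame")
  out
}
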