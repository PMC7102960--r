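# Brute-force scanning oracle: tests every start position of a sequence
# against the query language definition directly (maximal G-runs as
# tracts, loops consuming the whole inter-run gap).  Independent of the
# regex path used by scan_sequence().
oracle_scan <- function(s, q, strict = FALSE) {
  ch <- strsplit(toupper(s), "")[[1L]]
  n <- length(ch)
  out <- list()
  for (start in seq_len(n)) {
    pos <- start
    ok <- TRUE
    for (ti in seq_along(q$tracts)) {
      m <- q$tracts[[ti]]$min_len
      run <- 0L
      while (pos + run <= n && ch[pos + run] == "G") run <- run + 1L
      if (strict) {
        if (run != m || (pos > 1L && ch[pos - 1L] == "G")) {
          ok <- FALSE; break
        }
      } else if (run < m) {
        ok <- FALSE; break
      }
      pos <- pos + run
      if (ti < length(q$tracts)) {
        gap <- 0L
        while (pos + gap <= n && ch[pos + gap] %in% c("A", "C", "T")) {
          gap <- gap + 1L
        }
        if (pos + gap > n || ch[pos + gap] != "G" ||
            gap < q$loop_min || gap > q$loop_max) {
          ok <- FALSE; break
        }
        pos <- pos + gap
      }
    }
    if (ok) out[[length(out) + 1L]] <- c(start = start - 1L, len = pos - start)
  }
  if (length(out)) do.call(rbind, out) else {
    matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "len")))
  }
}

# rotate a structure's coordinates by a fixed rotation + translation
transform_structure <- function(st, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- st$xyz
  for (m in seq_len(nrow(xyz))) {
    X <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    X <- X %*% t(R)
    X <- sweep(X, 2L, shift, "+")
    xyz[m, ] <- as.vector(t(X))
  }
  g4_structure(st$atom, xyz)
}

rotation_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

random_rotation_matrix <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# loop table reduced to comparable columns, row order normalised
loop_kinds <- function(df) {
  if ("is_loop" %in% names(df)) df <- df[df$is_loop, , drop = FALSE]
  out <- df[, c("flank5", "flank3", "kind", "loop_len", "span_layers")]
  out <- out[order(out$flank5, out$flank3), , drop = FALSE]
  rownames(out) <- NULL
  out
}
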