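# Small 3D geometry kernel: torsions, internal-coordinate atom placement,
# plane fits.  Kept internal; bio3d handles superposition and file parsing.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) v / .vnorm(v)

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.rotz <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# signed torsion p1-p2-p3-p4 in degrees, (-180, 180], standard convention
.torsion_deg <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- .unit(p3 - p2)
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  atan2(sum(.cross3(b1, v) * w), sum(v * w)) * 180 / pi
}

# place atom D bonded to c at `bond` A, with angle D-c-b and torsion
# D-c-b-a (degrees); standard internal-coordinate (NeRF) construction
.place_atom <- function(a, b, cc, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- .unit(cc - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  cc + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# rmsd of points from their least-squares plane
.plane_rmsd <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  s <- svd(Xc, nu = 0L, nv = 3L)
  normal <- s$v[, 3L]
  sqrt(mean((Xc %*% normal)^2))
}

# unit normal of the least-squares plane
.plane_normal <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  svd(Xc, nu = 0L, nv = 3L)$v[, 3L]
}

# Standard planar guanine heavy-atom geometry (base reference frame,
# base in the z = 0 plane), plus the sugar C1' attachment point.
.guanine_base <- function() {
  rbind("C1'" = c(-2.477, 5.399, 0),
        N9    = c(-1.289, 4.551, 0),
        C8    = c( 0.023, 4.962, 0),
        N7    = c( 0.870, 3.969, 0),
        C5    = c( 0.071, 2.833, 0),
        C6    = c( 0.424, 1.460, 0),
        O6    = c( 1.554, 0.955, 0),
        N1    = c(-0.700, 0.641, 0),
        C2    = c(-1.999, 1.087, 0),
        N2    = c(-2.949, 0.139, 0),
        N3    = c(-2.342, 2.364, 0),
        C4    = c(-1.265, 3.177, 0))
}

# Guanine placed so that four-fold rotation about the z axis produces a
# Hoogsteen-bonded G-tetrad: d(N2_k, N7_{k+1}) = d(N1_k, O6_{k+1}) = 2.90 A
# with the donor-to-acceptor cycle running counterclockwise viewed from +z.
# In-plane transform solved once by least squares against those targets.
.guanine_tetrad_unit <- function() {
  p <- c(phi = 4.03211, tx = 2.447178, ty = 1.183822)
  g <- .guanine_base()
  a <- p[["phi"]]
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  xy <- g[, 1:2] %*% t(R)
  cbind(sweep(xy, 2L, c(p[["tx"]], p[["ty"]]), "+"), 0)
}

.base_atom_names <- function() {
  c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4")
}
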