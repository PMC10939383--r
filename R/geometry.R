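# --- small vector helpers (rows of n x 3 matrices) ---------------------------

row_norm <- function(m) sqrt(rowSums(m * m))

row_unit <- function(m) m / row_norm(m)

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_row <- function(v) matrix(v, nrow = 1)

#' Rigid-body transforms
#'
#' A rigid transform is a list with a proper rotation matrix `R`
#' (det = +1) and a translation `t`; it maps a point `p` to `R p + t`.
#' `transform_apply` applies it to an n x 3 coordinate matrix,
#' `transform_inverse` inverts it, `transform_compose(f, g)` returns the
#' transform equivalent to applying `g` first and then `f`, and
#' `random_rigid_transform` draws a uniformly random rotation plus a
#' translation for invariance testing.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @param t Length-3 translation vector (Angstrom).
#' @return `rigid_transform` object (a list with `R` and `t`).
#' @export
rigid_transform <- function(R, t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3, 3)))
  if (abs(det(R) - 1) > 1e-6) stop("rotation must be proper (det = +1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf A `rigid_transform`.
#' @param coords n x 3 coordinate matrix (a length-3 vector is accepted).
#' @export
transform_apply <- function(tf, coords) {
  vec <- is.null(dim(coords))
  if (vec) coords <- as_row(coords)
  out <- coords %*% t(tf$R) +
    matrix(tf$t, nrow(coords), 3, byrow = TRUE)
  if (vec) out <- drop(out)
  out
}

#' @rdname rigid_transform
#' @export
transform_inverse <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' @rdname rigid_transform
#' @param f,g `rigid_transform` objects; `g` is applied first.
#' @export
transform_compose <- function(f, g) {
  rigid_transform(f$R %*% g$R, as.numeric(f$R %*% g$t) + f$t)
}

#' @rdname rigid_transform
#' @param seed Optional integer seed for reproducible draws.
#' @export
random_rigid_transform <- function(seed = NULL) {
  draw <- function() {
    # QR of a Gaussian matrix -> Haar-ish rotation; force det +1
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    rigid_transform(q, stats::rnorm(3, sd = 10))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# --- virtual C-beta ----------------------------------------------------------

CB_BOND_LENGTH <- 1.522
CB_TETRAHEDRAL_COS <- -1 / 3  # cos of the ideal tetrahedral angle 109.47 deg

# vectorised over rows; N, CA, C are n x 3 matrices
place_virtual_cbeta_mat <- function(N, CA, C) {
  u1 <- row_unit(N - CA)
  u2 <- row_unit(C - CA)
  cr <- row_cross(u1, u2)
  crn <- row_norm(cr)
  if (any(crn < 1e-6)) stop("degenerate geometry: N, CA, C are collinear")
  nrm <- cr / crn
  cos_tau <- rowSums(u1 * u2)
  cos_half <- sqrt((1 + cos_tau) / 2)
  m <- row_unit(-(u1 + u2))
  a <- -CB_TETRAHEDRAL_COS / cos_half
  b <- sqrt(pmax(0, 1 - a * a))
  CA + CB_BOND_LENGTH * (a * m + b * nrm)
}

#' Place the virtual C-beta of a residue
#'
#' Constructs the ideal tetrahedral C-beta position from the backbone N,
#' C-alpha and C atoms (bond length 1.522 Angstrom, L-amino-acid
#' chirality). The construction uses only backbone atoms, so the placed
#' C-beta carries no information about the residue's identity; glycine
#' receives a virtual C-beta like every other residue.
#'
#' @param n,ca,c Length-3 coordinate vectors (Angstrom).
#' @return Length-3 C-beta coordinate vector.
#' @export
place_virtual_cbeta <- function(n, ca, c) {
  drop(place_virtual_cbeta_mat(as_row(n), as_row(ca), as_row(c)))
}

#' Fill virtual C-beta coordinates for every residue
#'
#' @param structure A `backbone` object.
#' @return The structure with `cb_x/cb_y/cb_z` populated.
#' @export
ensure_virtual_cbeta <- function(structure) {
  r <- structure$residues
  cb <- place_virtual_cbeta_mat(
    as.matrix(r[, c("n_x", "n_y", "n_z")]),
    as.matrix(r[, c("ca_x", "ca_y", "ca_z")]),
    as.matrix(r[, c("c_x", "c_y", "c_z")]))
  structure$residues$cb_x <- cb[, 1]
  structure$residues$cb_y <- cb[, 2]
  structure$residues$cb_z <- cb[, 3]
  structure
}

#' Apply a rigid transform to a whole backbone
#'
#' @param structure A `backbone` object.
#' @param tf A `rigid_transform`.
#' @return The transformed structure (virtual C-beta included if set).
#' @export
transform_backbone <- function(structure, tf) {
  for (a in c("n", "ca", "c", "o", "cb")) {
    cols <- paste0(a, c("_x", "_y", "_z"))
    m <- as.matrix(structure$residues[, cols])
    ok <- !is.na(m[, 1])
    if (any(ok)) {
      structure$residues[ok, cols] <- transform_apply(tf, m[ok, , drop = FALSE])
    }
  }
  structure
}

#' Canonical residue frame
#'
#' Returns the rigid transform that puts a residue into its canonical
#' pose: C-alpha at the origin, the C-alpha to N direction along +X, and
#' C in the XY plane with positive Y, so that the N-CA-C plane is the XY
#' plane and +Z is its right-handed normal. Voxelising in this frame
#' makes the resulting tensors invariant to rigid motions of the input
#' structure.
#'
#' @param n,ca,c Backbone atom coordinates (length-3 vectors).
#' @return A `rigid_transform` mapping world coordinates to the canonical
#'   frame.
#' @export
residue_canonical_transform <- function(n, ca, c) {
  x <- n - ca
  v <- c - ca
  z <- c(x[2] * v[3] - x[3] * v[2],
         x[3] * v[1] - x[1] * v[3],
         x[1] * v[2] - x[2] * v[1])
  nz <- sqrt(sum(z * z))
  if (nz < 1e-6) stop("degenerate geometry: N, CA, C are collinear")
  x <- x / sqrt(sum(x * x))
  z <- z / nz
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  rigid_transform(R, -as.numeric(R %*% ca))
}

# --- Kabsch superposition ----------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation + translation that superposes `coords_b`
#' onto `coords_a` in the least-squares sense and returns it together
#' with the post-superposition RMSD
#' \eqn{\sqrt{\sum_i \|a_i - \hat b_i\|^2 / n}}.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices with 1:1 row
#'   correspondence, n >= 3.
#' @return List with `transform` (a `rigid_transform` mapping b onto a)
#'   and `rmsd` (Angstrom).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("coordinate sets must have identical dimensions")
  }
  if (nrow(coords_a) < 3) stop("need at least 3 points for superposition")
  ca_mean <- colMeans(coords_a); cb_mean <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca_mean)
  B <- sweep(coords_b, 2, cb_mean)
  H <- crossprod(B, A)  # 3 x 3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- ca_mean - as.numeric(R %*% cb_mean)
  Bs <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((A - Bs)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

# --- torsions ----------------------------------------------------------------

# dihedral angle (degrees) for points p1-p2-p3-p4, rows of 3-vectors
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
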