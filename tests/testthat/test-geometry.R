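test_that("virtual C-beta has the ideal bond length and constant chirality", {
  h <- ensure_virtual_cbeta(make_helix(10))
  r <- h$residues
  d <- sqrt((r$cb_x - r$ca_x)^2 + (r$cb_y - r$ca_y)^2 +
              (r$cb_z - r$ca_z)^2)
  expect_equal(d, rep(1.522, 10), tolerance = 1e-6)
  # L chirality: det[N-CA, C-CA, CB-CA] has constant sign
  dets <- vapply(seq_len(10), function(i) {
    det(cbind(c(r$n_x[i] - r$ca_x[i], r$n_y[i] - r$ca_y[i],
                r$n_z[i] - r$ca_z[i]),
              c(r$c_x[i] - r$ca_x[i], r$c_y[i] - r$ca_y[i],
                r$c_z[i] - r$ca_z[i]),
              c(r$cb_x[i] - r$ca_x[i], r$cb_y[i] - r$ca_y[i],
                r$cb_z[i] - r$ca_z[i])))
  }, numeric(1))
  expect_true(all(dets > 0) || all(dets < 0))
})

test_that("C-beta placement is equivariant under rigid motions", {
  h <- make_helix(6)
  r <- h$residues
  n <- c(r$n_x[3], r$n_y[3], r$n_z[3])
  ca <- c(r$ca_x[3], r$ca_y[3], r$ca_z[3])
  cc <- c(r$c_x[3], r$c_y[3], r$c_z[3])
  cb <- place_virtual_cbeta(n, ca, cc)
  for (seed in 1:5) {
    tf <- random_rigid_transform(seed)
    cb_t <- place_virtual_cbeta(transform_apply(tf, n),
                                transform_apply(tf, ca),
                                transform_apply(tf, cc))
    expect_equal(cb_t, transform_apply(tf, cb), tolerance = 1e-6)
  }
  expect_error(place_virtual_cbeta(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("canonical transform puts N on +X and C in the XY plane", {
  s <- make_strand(8)
  r <- s$residues
  for (i in c(2, 5)) {
    n <- c(r$n_x[i], r$n_y[i], r$n_z[i])
    ca <- c(r$ca_x[i], r$ca_y[i], r$ca_z[i])
    cc <- c(r$c_x[i], r$c_y[i], r$c_z[i])
    tf <- residue_canonical_transform(n, ca, cc)
    expect_equal(abs(det(tf$R)), 1, tolerance = 1e-9)
    nc <- transform_apply(tf, n)
    cac <- transform_apply(tf, ca)
    ccc <- transform_apply(tf, cc)
    expect_equal(cac, c(0, 0, 0), tolerance = 1e-9)
    expect_gt(nc[1], 0)
    expect_equal(nc[2:3], c(0, 0), tolerance = 1e-9)
    expect_equal(ccc[3], 0, tolerance = 1e-9)
    expect_gt(ccc[2], 0)
  }
})

test_that("a residue already in canonical pose yields the identity", {
  h <- make_helix(5)
  r <- h$residues
  tf <- residue_canonical_transform(
    c(r$n_x[3], r$n_y[3], r$n_z[3]),
    c(r$ca_x[3], r$ca_y[3], r$ca_z[3]),
    c(r$c_x[3], r$c_y[3], r$c_z[3]))
  h_c <- transform_backbone(h, tf)
  rc <- h_c$residues
  tf2 <- residue_canonical_transform(
    c(rc$n_x[3], rc$n_y[3], rc$n_z[3]),
    c(rc$ca_x[3], rc$ca_y[3], rc$ca_z[3]),
    c(rc$c_x[3], rc$c_y[3], rc$c_z[3]))
  expect_equal(tf2$R, diag(3), tolerance = 1e-6)
  expect_equal(tf2$t, c(0, 0, 0), tolerance = 1e-6)
})

test_that("canonical-frame coordinates are invariant to rigid motions", {
  h <- make_helix(10)
  rt <- random_rigid_transform(99)
  h2 <- transform_backbone(h, rt)
  canon <- function(s) {
    r <- s$residues
    tf <- residue_canonical_transform(
      c(r$n_x[5], r$n_y[5], r$n_z[5]),
      c(r$ca_x[5], r$ca_y[5], r$ca_z[5]),
      c(r$c_x[5], r$c_y[5], r$c_z[5]))
    transform_apply(tf, atom_coords(s, "ca"))
  }
  expect_equal(canon(h2), canon(h), tolerance = 1e-6)
})

test_that("transforms compose and invert to the identity", {
  f <- random_rigid_transform(1)
  g <- random_rigid_transform(2)
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(transform_apply(transform_compose(f, g), p),
               transform_apply(f, transform_apply(g, p)),
               tolerance = 1e-9)
  ident <- transform_compose(f, transform_inverse(f))
  expect_equal(ident$R, diag(3), tolerance = 1e-6)
  expect_equal(ident$t, c(0, 0, 0), tolerance = 1e-6)
})

test_that("kabsch recovers rigid copies exactly and is symmetric", {
  a <- atom_coords(make_helix(12), "ca")
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-9)
  b <- transform_apply(random_rigid_transform(5), a)
  fit <- kabsch_superpose(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_equal(transform_apply(fit$transform, b), a, tolerance = 1e-6,
               ignore_attr = TRUE)
  # symmetry and non-negativity on a perturbed pair
  set.seed(8)
  b2 <- a + matrix(rnorm(length(a), sd = 0.5), ncol = 3)
  expect_equal(kabsch_superpose(a, b2)$rmsd,
               kabsch_superpose(b2, a)$rmsd, tolerance = 1e-9)
  expect_gte(kabsch_superpose(a, b2)$rmsd, 0)
  expect_error(kabsch_superpose(a, a[1:5, ]), "identical dimensions")
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("kabsch rmsd matches the independent bio3d superposition", {
  set.seed(21)
  a <- matrix(rnorm(36, sd = 4), 12, 3)
  b <- transform_apply(random_rigid_transform(3), a) +
    matrix(rnorm(36, sd = 0.8), 12, 3)
  ours <- kabsch_superpose(a, b)$rmsd
  xyz_a <- as.vector(t(a)); xyz_b <- as.vector(t(b))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_a,
                                            mobile = xyz_b))
  ref <- bio3d::rmsd(xyz_a, fitted)
  # bio3d rounds fitted coordinates to PDB precision
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("a single displaced point gives the brute-force optimum", {
  # 4 points, one displaced by 2 A; compare against a quaternion-free
  # numeric search over rotations (Euler angles) + centroid alignment
  a <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  b <- a
  b[4, 3] <- b[4, 3] + 2
  ours <- kabsch_superpose(a, b)$rmsd
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    R <- matrix(c(cy * cz, cy * sz, -sy,
                  sx * sy * cz - cx * sz, sx * sy * sz + cx * cz, sx * cy,
                  cx * sy * cz + sx * sz, cx * sy * sz - sx * cz, cx * cy),
                3, 3, byrow = TRUE)
    bc <- sweep(b, 2, colMeans(b)) %*% t(R)
    sqrt(mean(rowSums((sweep(a, 2, colMeans(a)) - bc)^2)))
  }
  best <- Inf
  for (sx in seq(-pi, pi, length.out = 5)) {
    for (sy in seq(-pi / 2, pi / 2, length.out = 5)) {
      for (sz in seq(-pi, pi, length.out = 5)) {
        r <- stats::optim(c(sx, sy, sz), obj)$value
        best <- min(best, r)
      }
    }
  }
  expect_equal(ours, best, tolerance = 1e-4)
  expect_lte(ours, best + 1e-8)
})
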