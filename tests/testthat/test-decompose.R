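test_that("center-of-mass displacement is the mass-weighted mean", {
  g <- bent_molecule()
  u <- c(0.3, -0.2, 0.5)
  unif <- matrix(rep(u, each = 3), 3)
  expect_equal(com_displacement(g, unif), u)
  g2 <- fake_group(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 3))
  d2 <- rbind(c(1, 0, 0), c(0, 0, 0))
  expect_equal(com_displacement(g2, d2), c(0.25, 0, 0))
  # random field vs direct summation
  set.seed(4)
  g3 <- fake_group(matrix(rnorm(36), 12), masses = runif(12, 1, 16))
  d3 <- matrix(rnorm(36), 12)
  oracle <- colSums(d3 * g3$masses) / sum(g3$masses)
  expect_equal(com_displacement(g3, d3), oracle, tolerance = 1e-12)
})

test_that("the rigid-body frame reproduces brute-force inertia sums", {
  # collinear triatomic along x: smallest moment ~ 0, axis parallel to x
  g <- fake_group(rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                  masses = c(1, 12, 1))
  fr <- rigid_body_frame(g)
  expect_lt(fr$moments[3] / fr$moments[1], 1e-12)
  expect_equal(abs(fr$axes[, 3]), c(1, 0, 0), tolerance = 1e-8)

  g2 <- bent_molecule()
  fr2 <- rigid_body_frame(g2)
  # element-wise oracle
  com <- colSums(g2$coords * g2$masses) / sum(g2$masses)
  s <- sweep(g2$coords, 2, com)
  I <- matrix(0, 3, 3)
  for (i in 1:3) {
    I <- I + g2$masses[i] * (sum(s[i, ]^2) * diag(3) - outer(s[i, ], s[i, ]))
  }
  expect_equal(sort(eigen(I, symmetric = TRUE)$values, decreasing = TRUE),
               fr2$moments, tolerance = 1e-10)
  expect_equal(fr2$inertia, I, tolerance = 1e-10)
  # orthonormal right-handed axes
  expect_equal(crossprod(fr2$axes), diag(3), tolerance = 1e-10)
  expect_equal(det(fr2$axes), 1, tolerance = 1e-10)
})

test_that("principal moments are invariant under rigid rotation", {
  set.seed(5)
  g <- fake_group(matrix(rnorm(24, sd = 1.5), 8), masses = runif(8, 1, 16))
  fr <- rigid_body_frame(g)
  for (i in 1:5) {
    R <- rand_rotation()
    g2 <- g; g2$coords <- g$coords %*% t(R)
    expect_equal(rigid_body_frame(g2)$moments, fr$moments, tolerance = 1e-9)
  }
})

test_that("libration angles recover constructed rigid rotations", {
  g <- bent_molecule()
  fr <- rigid_body_frame(g)
  # rotation by 0.01 rad about principal axis 3
  axis3 <- fr$axes[, 3]
  d <- rotate_about(g$coords, g$masses, axis3, 0.01) - g$coords
  th <- libration_angles(g, d, fr)
  # recovered angle is sin(theta) for a finite rotation: O(theta^3) error
  expect_lt(abs(th[3] - 0.01), 1e-6)
  expect_lt(max(abs(th[1:2])), 1e-6)

  # pure translation leaves no libration
  d_tr <- matrix(rep(c(0.1, 0.2, -0.3), each = 3), 3)
  expect_equal(libration_angles(g, d_tr, fr), c(0, 0, 0), tolerance = 1e-12)

  # arbitrary axis: angle projects onto the principal axes, O(theta^2)
  set.seed(6)
  g8 <- fake_group(matrix(rnorm(24, sd = 1.4), 8), masses = runif(8, 1, 16))
  fr8 <- rigid_body_frame(g8)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  theta <- 0.015
  d8 <- rotate_about(g8$coords, g8$masses, u, theta) - g8$coords
  th8 <- libration_angles(g8, d8, fr8)
  # O(theta^2) coupling between non-principal rotation components
  expect_frac_equal(th8, theta * drop(u %*% fr8$axes), 5 * theta^2)
})

test_that("single atoms and near-linear molecules give zero angles", {
  g1 <- fake_group(matrix(c(1, 2, 3), 1), masses = 16)
  expect_equal(libration_angles(g1, matrix(c(1, 1, 1), 1)), c(0, 0, 0))
  glin <- fake_group(rbind(c(-1.1, 0, 0), c(0, 0, 0), c(1.1, 0, 0)),
                     masses = c(16, 12, 16))
  fr <- rigid_body_frame(glin)
  d <- matrix(rnorm(9, sd = 0.01), 3)
  expect_equal(libration_angles(glin, d, fr)[3], 0)
})

test_that("libration displacement fields follow finite-rotation geometry", {
  g <- bent_molecule()
  fr <- rigid_body_frame(g)
  # zero angles give zero fields
  z <- libration_displacements(g, fr, c(0, 0, 0))
  expect_true(all(vapply(z, function(f) max(abs(f)), numeric(1)) == 0))
  # exact Rodrigues value for a point at principal position (1, 0, 0):
  # a cross-shaped body whose largest-moment axis carries an atom at 1 A
  gp <- fake_group(rbind(c(1, 0, 0), c(-1, 0, 0),
                         c(0, 1.2, 0), c(0, -1.2, 0),
                         c(0, 0, 1.1), c(0, 0, -1.1)),
                   masses = rep(1, 6))
  frp <- rigid_body_frame(gp)
  theta <- 0.01
  sp <- sweep(gp$coords, 2, frp$com) %*% frp$axes
  expect_equal(abs(sp[1, ]), c(1, 0, 0), tolerance = 1e-9)
  f3 <- libration_displacements(gp, frp, c(0, 0, theta))[[3]]
  got <- (f3 %*% frp$axes)[1, ]
  # Rodrigues: (s1 (cos t - 1), s1 sin t, 0) ~ (-5e-5, 1e-2, 0) for s1 = 1
  want <- c(sp[1, 1] * (cos(theta) - 1), sp[1, 1] * sin(theta), 0)
  expect_equal(drop(got), want, tolerance = 1e-9)
  # the summed per-axis fields approximate one rigid rotation to O(theta^2)
  set.seed(7)
  g8 <- fake_group(matrix(rnorm(24, sd = 1.4), 8), masses = runif(8, 1, 16))
  fr8 <- rigid_body_frame(g8)
  th <- c(0.012, -0.008, 0.015)
  fields <- libration_displacements(g8, fr8, th)
  total <- Reduce(`+`, fields)
  u <- drop(fr8$axes %*% th)
  rigid <- rotate_about(g8$coords, g8$masses, u / sqrt(sum(u^2)),
                        sqrt(sum(th^2))) - g8$coords
  expect_lt(abs(sqrt(sum(total^2)) - sqrt(sum(rigid^2))) / sqrt(sum(rigid^2)),
            0.05)
})

test_that("decomposition reconstructs the input exactly", {
  set.seed(8)
  p <- toy_partition()
  d <- matrix(rnorm(3 * n_atoms(p$structure)), ncol = 3)
  for (g in p$molecules[c(1, 5)]) {
    dec <- decompose_displacements(g, d)
    recon <- Reduce(`+`, dec$trans) + Reduce(`+`, dec$lib) + dec$intra
    expect_equal(recon, dec$total, tolerance = 1e-12)
  }
})

test_that("pure rigid motions leave no intramolecular residual", {
  g <- toy_partition()$molecules[[1]]
  # pure translation
  d_tr <- matrix(rep(c(0.02, -0.01, 0.03), each = nrow(g$coords)),
                 nrow(g$coords))
  dec <- decompose_displacements(g, d_tr)
  expect_equal(dec$theta, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(max(abs(dec$intra)), 1e-12 * max(abs(d_tr)))
  # pure small libration: no COM displacement, tiny second-order residual
  fr <- rigid_body_frame(g)
  d_rot <- rotate_about(g$coords, g$masses, fr$axes[, 2], 0.01) - g$coords
  dec2 <- decompose_displacements(g, d_rot)
  expect_equal(dec2$com_disp, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(mw_rms_test(dec2$intra, g$masses),
            1e-3 * mw_rms_test(d_rot, g$masses))
})

test_that("percentage contributions follow the mass-weighted RMS equation", {
  g <- toy_partition()$molecules[[1]]
  O <- nrow(g$coords)
  # pure X translation
  d <- matrix(0, O, 3); d[, 1] <- 0.05
  pc <- percentage_contributions(decompose_displacements(g, d))
  expect_equal(pc$p_trans_x, 100, tolerance = 1e-9)
  expect_equal(pc$p_intra + pc$p_trans_y + pc$p_trans_z +
                 pc$p_lib_x + pc$p_lib_y + pc$p_lib_z, 0, tolerance = 1e-9)
  # constructed 50/50 translation/intramolecular split
  part <- toy_partition()
  mode5050 <- make_mode_field(part, mixture_spec(
    fractions = c(0.5, 0, 0, 0, 0, 0, 0.5), seed = 3))
  ch <- mode_character(part$structure, mode5050, part)
  expect_frac_equal(ch$p_trans_x, rep(50, 8), 1e-6)
  expect_frac_equal(ch$p_intra, rep(50, 8), 1e-6)
  # independent RMS oracle on one molecule
  dec <- decompose_displacements(g, mode5050$displacements[[1]])
  s <- c(sapply(dec$trans, mw_rms_test, m = g$masses),
         sapply(dec$lib, mw_rms_test, m = g$masses),
         mw_rms_test(dec$intra, g$masses))
  expect_equal(as.numeric(percentage_contributions(dec)[1, ]),
               unname(100 * s / sum(s)), tolerance = 1e-12)
  # normalization holds for any field
  set.seed(10)
  dr <- matrix(rnorm(3 * O), O)
  expect_equal(sum(percentage_contributions(
    decompose_displacements(g, dr))), 100, tolerance = 1e-6)
})

test_that("percentages are invariant to mass rescaling and co-rotation", {
  set.seed(11)
  g <- toy_partition()$molecules[[2]]
  d <- matrix(rnorm(3 * nrow(g$coords), sd = 0.02), ncol = 3)
  p0 <- as.numeric(percentage_contributions(decompose_displacements(g, d)))
  # doubling all masses changes nothing
  g2 <- g; g2$masses <- 2 * g$masses
  p2 <- as.numeric(percentage_contributions(decompose_displacements(g2, d)))
  expect_equal(p2, p0, tolerance = 1e-9)
  # a global rotation applied to structure and displacements together:
  # expressing the rotated system in co-rotated crystallographic axes gives
  # numerically identical inputs, so the per-axis percentages carry over;
  # in the fixed frame the rotation-invariant aggregates must survive —
  # the intramolecular RMS, the Euclidean norm of the translation RMS
  # vector and the multiset of librational field RMS values
  dec0 <- decompose_displacements(g, d)
  s_tr0 <- vapply(dec0$trans, mw_rms_test, numeric(1), m = g$masses)
  s_li0 <- sort(vapply(dec0$lib, mw_rms_test, numeric(1), m = g$masses))
  s_in0 <- mw_rms_test(dec0$intra, g$masses)
  for (i in 1:5) {
    R <- rand_rotation()
    g3 <- g; g3$coords <- g$coords %*% t(R)
    dec3 <- decompose_displacements(g3, d %*% t(R))
    s_tr3 <- vapply(dec3$trans, mw_rms_test, numeric(1), m = g$masses)
    s_li3 <- sort(vapply(dec3$lib, mw_rms_test, numeric(1), m = g$masses))
    expect_equal(sqrt(sum(s_tr3^2)), sqrt(sum(s_tr0^2)), tolerance = 1e-9)
    expect_equal(s_li3, s_li0, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(mw_rms_test(dec3$intra, g$masses), s_in0, tolerance = 1e-9)
  }
})

test_that("an all-zero field is rejected with a clear error", {
  g <- toy_partition()$molecules[[1]]
  d <- matrix(0, nrow(g$coords), 3)
  expect_error(percentage_contributions(decompose_displacements(g, d)),
               "undefined")
})
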