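rigid <- function(points, ang = c(0.4, -1.1, 2.0), shift = c(3, -5, 8)) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  sweep(points %*% t(R), 2, -shift)
}

test_that("Kabsch recovers exact superpositions", {
  set.seed(71)
  pa <- matrix(rnorm(30 * 3, sd = 6), ncol = 3)
  # identical points: zero RMSD, identity rotation
  fit0 <- kabsch(paired_coords <- list(points_a = pa, points_b = pa))
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  # rigidly moved copy: zero RMSD, proper orthonormal rotation
  fit1 <- kabsch(list(points_a = pa, points_b = rigid(pa)))
  expect_lt(fit1$rmsd, 1e-8)
  expect_equal(t(fit1$rotation) %*% fit1$rotation, diag(3),
               tolerance = 1e-8)
  expect_equal(det(fit1$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch RMSD matches the numerical-minimization oracle", {
  set.seed(73)
  # 4-point toy with one displaced coordinate
  pa <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2),
               ncol = 3, byrow = TRUE)
  pb <- pa
  pb[4, 3] <- pb[4, 3] + 1
  fit <- kabsch(list(points_a = pa, points_b = rigid(pb)))
  expect_equal(fit$rmsd, optim_rmsd(pa, pb), tolerance = 1e-5)
  # small random clouds
  for (k in 1:3) {
    qa <- matrix(rnorm(6 * 3, sd = 3), ncol = 3)
    qb <- qa + matrix(rnorm(6 * 3, sd = 0.4), ncol = 3)
    fit <- kabsch(list(points_a = qa, points_b = qb))
    expect_equal(fit$rmsd, optim_rmsd(qa, qb), tolerance = 1e-4)
  }
})

test_that("RMSD is symmetric and invariant under common rigid transforms", {
  set.seed(79)
  pa <- matrix(rnorm(40 * 3, sd = 5), ncol = 3)
  pb <- pa + matrix(rnorm(40 * 3, sd = 0.5), ncol = 3)
  r_ab <- kabsch(list(points_a = pa, points_b = pb))$rmsd
  r_ba <- kabsch(list(points_a = pb, points_b = pa))$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  moved <- kabsch(list(points_a = rigid(pa), points_b = rigid(pb)))$rmsd
  expect_equal(moved, r_ab, tolerance = 1e-9)
})

test_that("Kabsch agrees with an independent fitting routine", {
  set.seed(83)
  pa <- matrix(rnorm(25 * 3, sd = 4), ncol = 3)
  pb <- rigid(pa + matrix(rnorm(25 * 3, sd = 0.3), ncol = 3))
  fit <- kabsch(list(points_a = pa, points_b = pb))
  ref <- bio3d::rmsd(as.vector(t(pa)), as.vector(t(pb)), fit = TRUE)
  # the reference routine reports at 3 decimals
  expect_equal(fit$rmsd, ref, tolerance = 2e-3)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(list(points_a = line, points_b = line)), "degenerate")
})

test_that("iterative refinement rejects planted outliers", {
  set.seed(89)
  pa <- matrix(rnorm(50 * 3, sd = 6), ncol = 3)
  pb <- pa + matrix(rnorm(50 * 3, sd = 0.1), ncol = 3)
  clean_rmsd <- kabsch(list(points_a = pa, points_b = pb))$rmsd
  pb_out <- pb
  pb_out[17, ] <- pb_out[17, ] + c(10, 0, 0)
  pairs <- list(points_a = pa, points_b = rigid(pb_out))
  plain <- kabsch(pairs)
  refined <- refine_superposition(pairs)
  expect_equal(refined$n_rejected, 1)
  expect_equal(refined$n_used + refined$n_rejected, 50)
  expect_equal(refined$rmsd, clean_rmsd, tolerance = 0.02)
  # refinement never increases the RMSD
  expect_lte(refined$rmsd, plain$rmsd)
  # nothing beyond the cutoff: refinement is a plain fit
  no_out <- refine_superposition(list(points_a = pa, points_b = pb))
  expect_equal(no_out$n_rejected, 0)
  expect_equal(no_out$rmsd, clean_rmsd, tolerance = 1e-10)
})

test_that("CA pairing follows the alignment columns", {
  spec <- backbone_spec("GAVILMNQKR")
  st <- build_backbone(spec, id = "s1")
  aln <- needleman_wunsch(chain_sequence(st), chain_sequence(st))
  pairs <- pair_ca_atoms(aln, st, st)
  expect_equal(nrow(pairs$points_a), 10)
  expect_equal(pairs$points_a, pairs$points_b)

  # gap columns contribute no pairs
  st_del <- build_backbone(backbone_spec("GAVIMNQKR"), id = "s2")  # L removed
  aln2 <- needleman_wunsch(chain_sequence(st), chain_sequence(st_del))
  pairs2 <- pair_ca_atoms(aln2, st, st_del)
  expect_equal(nrow(pairs2$points_a), 9)

  # residues without a CA are skipped
  st_noca <- st
  st_noca$atoms <- st_noca$atoms[!(st_noca$atoms$resno == 4 &
                                   st_noca$atoms$elety == "CA"), ]
  pairs3 <- pair_ca_atoms(aln, st, st_noca)
  expect_equal(nrow(pairs3$points_a), 9)
})
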