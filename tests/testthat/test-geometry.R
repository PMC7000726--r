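test_that("dihedral angle follows the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0)
  # mirroring through the z = 0 plane flips the sign
  p <- list(c(0.2, 0.1, 0.3), c(1.1, 0.2, -0.2), c(1.4, 1.3, 0.4),
            c(2.5, 1.2, 1.0))
  mirror <- lapply(p, function(v) c(v[1], v[2], -v[3]))
  expect_equal(do.call(dihedral_angle, mirror),
               -do.call(dihedral_angle, p), tolerance = 1e-9)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("omega classification reproduces the planarity thresholds", {
  expect_equal(classify_omega(180), "trans_planar")
  expect_equal(classify_omega(165), "trans_nonplanar")
  expect_equal(classify_omega(25), "cis_nonplanar")
  expect_equal(classify_omega(0), "cis_planar")
  # boundary probes around the trans (170) and cis (20) thresholds
  expect_equal(classify_omega(c(169.99, 170.01, -169.99, -170.01)),
               c("trans_nonplanar", "trans_planar",
                 "trans_nonplanar", "trans_planar"))
  expect_equal(classify_omega(c(19.99, 20.01, -19.99, -20.01)),
               c("cis_planar", "cis_nonplanar",
                 "cis_planar", "cis_nonplanar"))
  expect_equal(classify_omega(NA), "undefined")
})

test_that("omega classification partitions (-180, 180]", {
  grid <- seq(-179.95, 180, by = 0.05)
  cls <- classify_omega(grid)
  expect_true(all(cls %in% c("trans_planar", "trans_nonplanar",
                             "cis_planar", "cis_nonplanar")))
  # brute-force re-derivation from the threshold inequalities
  want <- ifelse(abs(grid) > 90,
                 ifelse(abs(grid) < 170, "trans_nonplanar", "trans_planar"),
                 ifelse(abs(grid) > 20, "cis_nonplanar", "cis_planar"))
  expect_equal(cls, want)
})

test_that("backbone torsions round trip through the builder", {
  set.seed(97)
  for (k in 1:5) {
    n <- sample(8:25, 1)
    spec <- backbone_spec(random_sequence(n),
                          phi = runif(n, -180, 180),
                          psi = runif(n, -180, 180),
                          omega = runif(n, -180, 180))
    tor <- backbone_torsions(build_backbone(spec))
    expect_true(is.na(tor$phi[1]))
    expect_true(is.na(tor$omega[1]))
    expect_true(is.na(tor$psi[n]))
    expect_equal(tor$phi[-1], spec$phi[-1], tolerance = 1e-6)
    expect_equal(tor$psi[-n], spec$psi[-n], tolerance = 1e-6)
    expect_equal(tor$omega[-1], spec$omega[-1], tolerance = 1e-6)
  }
})

test_that("helix torsions are recovered and classified alpha_R", {
  st <- build_backbone(backbone_spec(strrep("A", 12),
                                     phi = -57, psi = -47, omega = 180))
  tor <- backbone_torsions(st)
  expect_equal(tor$omega[5], 180, tolerance = 1e-6)
  lab <- ramachandran_classify(tor$phi, tor$psi)
  expect_true(all(lab[!is.na(tor$phi) & !is.na(tor$psi)] == "alpha_R"))
})

test_that("planted non-planar bonds are counted under the thresholds", {
  n <- 12
  omega <- rep(180, n)
  omega[c(4, 8, 11)] <- 160
  st <- build_backbone(backbone_spec(strrep("A", n), omega = omega))
  expect_equal(count_nonplanar(st), 3)
  tor <- backbone_torsions(st)
  expect_equal(tor$omega[4], 160, tolerance = 1e-6)
  # all-planar chain
  expect_equal(count_nonplanar(build_backbone(backbone_spec(strrep("G", 10)))), 0)
  # counts agree with a brute-force scan at threshold boundaries
  for (probe in c(170 - 1e-3, 170 + 1e-3, 20 - 1e-3, 20 + 1e-3)) {
    om <- rep(180, 10)
    om[5] <- probe
    stp <- build_backbone(backbone_spec(strrep("A", 10), omega = om))
    torp <- backbone_torsions(stp)
    brute <- sum(!is.na(torp$omega) &
                 ((abs(torp$omega) > 90 & abs(torp$omega) < 170) |
                  (abs(torp$omega) <= 90 & abs(torp$omega) > 20)))
    expect_equal(count_nonplanar(stp), brute)
  }
})

test_that("torsions are undefined across chain breaks", {
  st <- build_backbone(backbone_spec(strrep("A", 10)))
  at <- st$atoms
  # translate residues 6..10 far away: C(5)-N(6) stretches beyond 2.5 A
  sel <- at$resno >= 6
  at$x[sel] <- at$x[sel] + 50
  broken <- protein_structure("broken", at)
  tor <- backbone_torsions(broken)
  expect_true(is.na(tor$phi[6]))
  expect_true(is.na(tor$omega[6]))
  expect_true(is.na(tor$psi[5]))
  expect_false(is.na(tor$omega[5]))
  expect_false(is.na(tor$omega[8]))
})

test_that("flanking-residue counts track non-planar bonds", {
  # one non-planar bond between Gly(3) and Ala(4)
  omega <- rep(180, 8)
  omega[4] <- 150
  st <- build_backbone(backbone_spec("LKGAVIMN", omega = omega))
  fc <- flank_composition(st)
  expect_equal(fc$omega_a[fc$resid == "GLY"], 1)
  expect_equal(fc$omega_b[fc$resid == "ALA"], 1)
  expect_equal(sum(fc$omega_a), 1)
  expect_equal(sum(fc$omega_b), 1)
  # no non-planar bonds: empty table
  expect_equal(nrow(flank_composition(build_backbone(backbone_spec("LKGAVIMN")))), 0)
  # conservation: totals per flank equal the non-planar bond count
  omega2 <- rep(180, 10)
  omega2[c(3, 6, 9)] <- 160
  st2 <- build_backbone(backbone_spec(strrep("A", 5), omega = rep(180, 5)))
  st3 <- build_backbone(backbone_spec("GAVILMNQKR", omega = omega2))
  fc3 <- flank_composition(st3)
  expect_equal(sum(fc3$omega_a), count_nonplanar(st3))
  expect_equal(sum(fc3$omega_b), count_nonplanar(st3))
})

test_that("Ramachandran regions classify the canonical conformations", {
  expect_equal(ramachandran_classify(-60, -45), "alpha_R")
  expect_equal(ramachandran_classify(-120, 130), "beta")
  expect_equal(ramachandran_classify(60, 45), "alpha_L")
  expect_equal(ramachandran_classify(0, 0), "other")
  expect_equal(ramachandran_classify(NA, 10), NA_character_)
  # default rectangles do not overlap
  reg <- default_rama_regions()
  for (i in 1:(nrow(reg) - 1)) for (j in (i + 1):nrow(reg)) {
    overlap <- reg$phi_min[i] <= reg$phi_max[j] &
      reg$phi_max[i] >= reg$phi_min[j] &
      reg$psi_min[i] <= reg$psi_max[j] &
      reg$psi_max[i] >= reg$psi_min[j]
    expect_false(overlap)
  }
})

test_that("salt bridges are detected by O-N distance with residue dedup", {
  base <- build_backbone(backbone_spec(strrep("A", 30)))
  hit <- plant_salt_bridge(base, 3, 25, 3.0)
  found <- find_salt_bridges(hit)
  expect_equal(nrow(found), 1)
  expect_equal(found$resid_acid, "ASP")
  expect_equal(found$resid_base, "LYS")
  expect_equal(found$distance, 3.0, tolerance = 1e-9)
  expect_equal(nrow(find_salt_bridges(plant_salt_bridge(base, 3, 25, 3.5))), 0)
  expect_equal(nrow(find_salt_bridges(plant_salt_bridge(base, 3, 25, 3.5),
                                      cutoff = 3.6)), 1)

  # NZ within the cutoff of both carboxylate oxygens: still one bridge
  at <- hit$atoms
  od1 <- at[at$elety == "OD1", ]
  nz <- at[at$elety == "NZ", ]
  u <- c(nz$x - od1$x, nz$y - od1$y, nz$z - od1$z)
  u <- 0.4 * u / sqrt(sum(u^2))
  extra <- od1
  extra$elety <- "OD2"
  extra$x <- extra$x + u[1]
  extra$y <- extra$y + u[2]
  extra$z <- extra$z + u[3]
  dedup <- protein_structure("dedup", rbind(at, extra))
  both <- find_salt_bridges(dedup)
  expect_equal(nrow(both), 1)
  # the closest contact is the one reported
  expect_equal(both$atom_acid, "OD2")

  # two planted bridges count separately
  two <- plant_salt_bridge(hit, 10, 18, 2.8)
  expect_equal(nrow(find_salt_bridges(two)), 2)
})

test_that("salt-bridge detection is invariant under rigid transforms", {
  st <- plant_salt_bridge(build_backbone(backbone_spec(strrep("A", 30))),
                          3, 25, 3.1)
  set.seed(101)
  moved <- extremoprot:::transform_structure(
    st, extremoprot:::random_rotation(), c(12, -7, 30))
  expect_equal(nrow(find_salt_bridges(moved)), nrow(find_salt_bridges(st)))
  d0 <- find_salt_bridges(st)$distance
  expect_equal(find_salt_bridges(moved)$distance, d0, tolerance = 1e-9)
})

test_that("histidine counts as basic only when enabled", {
  base <- build_backbone(backbone_spec(strrep("A", 20)))
  st <- plant_salt_bridge(base, 3, 15, 3.0)
  at <- st$atoms
  at$resid[at$resno == 15] <- "HIS"
  at$elety[at$elety == "NZ"] <- "ND1"
  his <- protein_structure("his", at)
  expect_equal(nrow(find_salt_bridges(his)), 0)
  expect_equal(nrow(find_salt_bridges(his, include_his = TRUE)), 1)
})
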