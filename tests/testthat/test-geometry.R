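test_that("dihedral follows the IUPAC convention on planar chains", {
  # cis: p1 and p4 on the same side of the central bond
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, 1, 0)), 0)
  # trans: opposite sides, +180 (never -180)
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(2, -1, 0)), 180)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("dihedral matches independent oracles on random quadruples", {
  set.seed(11)
  for (i in 1:500) {
    p <- random_quad()
    ref <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]), ref,
                 tolerance = 1e-9)
    expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 as.numeric(bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)),
                 tolerance = 1e-6)
  }
})

test_that("dihedral is antisymmetric under mirror reflection", {
  set.seed(12)
  for (i in 1:200) {
    p <- random_quad()
    m <- p
    m[, 1] <- -m[, 1]
    expect_equal(dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ]),
                 -dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("handedness is the sign of chi3", {
  expect_identical(classify_handedness(108.23), "right")
  expect_identical(classify_handedness(-79.10), "left")
  expect_identical(classify_handedness(1e-6), "right")
  expect_error(classify_handedness(0), "ambiguous")
})

test_that("internal-coordinate build and measure are mutually inverse", {
  set.seed(13)
  for (i in 1:300) {
    ic <- random_internal_chain()
    pos <- build_from_internal(ic)
    back <- measure_internal(pos, ic$labels)
    expect_equal(back$lengths, ic$lengths, tolerance = 1e-6)
    expect_equal(back$angles, ic$angles, tolerance = 1e-6)
    expect_equal(back$dihedrals, ic$dihedrals, tolerance = 1e-6)
  }
})

test_that("internal_chain validates its inputs", {
  expect_error(internal_chain(c("A", "B"), numeric(0)), "n-1 lengths")
  expect_error(internal_chain(c("A", "B"), -1), "positive")
  expect_error(internal_chain(c("A", "B", "C"), c(1, 1), 190), "0, 180")
  expect_error(build_from_internal(
    internal_chain(c("A", "B", "C", "D"), c(1, 1, 1), c(90, 179.99999999999),
                   60)), "degenerate")
})

test_that("measure_internal handles minimal chains", {
  two <- rbind(c(0, 0, 0), c(2.051, 0, 0))
  expect_equal(measure_internal(two)$lengths, 2.051)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(measure_internal(tri)$angles, 60)
  expect_error(measure_internal(rbind(c(0, 0, 0))), "at least two")
})

test_that("measured internal coordinates are invariant under rigid motion", {
  set.seed(14)
  ic <- random_internal_chain(6)
  pos <- build_from_internal(ic)
  R <- random_rotation()
  moved <- pos %*% t(R) + matrix(rnorm(3), nrow(pos), 3, byrow = TRUE)
  a <- measure_internal(pos)
  b <- measure_internal(moved)
  expect_equal(a$lengths, b$lengths, tolerance = 1e-9)
  expect_equal(a$angles, b$angles, tolerance = 1e-9)
  expect_equal(a$dihedrals, b$dihedrals, tolerance = 1e-9)
  # reflection flips every torsion and hence the handedness call
  mir <- pos
  mir[, 3] <- -mir[, 3]
  expect_equal(measure_internal(mir)$dihedrals, -a$dihedrals,
               tolerance = 1e-9)
})

test_that("kabsch superposition recovers exact and noisy alignments", {
  set.seed(15)
  P <- matrix(rnorm(24), 8, 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation()
  Q <- P %*% t(R) + matrix(c(1, -2, 3), 8, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(Q, P)$rmsd, 0, tolerance = 1e-9)

  for (i in 1:100) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  degenerate <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(degenerate, degenerate), "degenerate")
})
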