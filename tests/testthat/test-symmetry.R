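test_that("unit-cell volume and transforms are self-consistent", {
  # hexagonal volume a^2 c sin(120) against the generic triclinic formula
  uc <- unit_cell(81.827, 81.827, 33.849, 90, 90, 120)
  expect_equal(uc$volume, 81.827^2 * 33.849 * sin(120 * pi / 180),
               tolerance = 1e-6 * uc$volume)
  expect_equal(uc$frac %*% uc$orth, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(21)
  p <- rnorm(3) * 20
  expect_equal(as.vector(uc$orth %*% (uc$frac %*% p)), p, tolerance = 1e-9)
  expect_error(unit_cell(-1, 1, 1), "positive")
  expect_error(unit_cell(1, 1, 1, alpha = 190), "0, 180")
})

test_that("space-group operators have the right group structure", {
  expect_length(spacegroup_ops("P1"), 1)
  for (nm in list("H3", "R3:H", "R 3", 146, "146")) {
    ops <- spacegroup_ops(nm)
    expect_length(ops, 9)
  }
  expect_error(spacegroup_ops("P212121"), "unsupported")

  ops <- spacegroup_ops("H3")
  pt <- c(0.123, 0.456, 0.789)
  images <- lapply(ops, function(op) as.vector(op$R %*% pt + op$t))
  # all nine images of a general point are distinct (mod 1)
  mods <- vapply(images, function(v) paste(round(v %% 1, 9), collapse = ","),
                 character(1))
  expect_length(unique(mods), 9)
  # literal-formula oracle gives the same image set
  ref <- vapply(oracle_h3_images(pt), function(v)
    paste(round(v %% 1, 9), collapse = ","), character(1))
  expect_setequal(mods, ref)
  # each three-fold rotation applied three times returns the start
  for (op in ops[vapply(ops, function(o) !all(o$R == diag(3)), logical(1))]) {
    v <- pt
    for (k in 1:3) v <- as.vector(op$R %*% v + op$t)
    expect_equal(v %% 1, pt %% 1, tolerance = 1e-9)
  }
})

test_that("symmetry neighbours reproduce the three-fold coordination", {
  z <- make_zn_site(list(list(resid = "HIS", elety = "NE2", dist = 2.05)))
  zn <- z$atom[z$atom$elety == "ZN", ]
  center <- c(zn$x, zn$y, zn$z)
  nb <- symmetry_neighbors(z, center, 2.5)
  ne2 <- nb[nb$elety == "NE2", ]
  expect_equal(nrow(ne2), 3)
  expect_equal(ne2$dist, rep(2.05, 3), tolerance = 1e-9)
  expect_length(unique(ne2$op), 3)
  # radius zero returns nothing
  expect_equal(nrow(symmetry_neighbors(z, center + 1, 0)), 0)
  expect_error(symmetry_neighbors(make_helix("alpha", 5), c(0, 0, 0), 3),
               "crystal")
})

test_that("neighbour search equals brute-force enumeration", {
  z <- make_zn_site(list(list(resid = "HIS", elety = "NE2", dist = 2.05),
                         list(resid = "HOH", elety = "O", dist = 2.21)))
  zn <- z$atom[z$atom$elety == "ZN", ]
  center <- c(zn$x, zn$y, zn$z) + c(1.5, -0.5, 0.5)
  for (radius in c(2, 4.5, 8)) {
    got <- symmetry_neighbors(z, center, radius)
    ref <- oracle_neighbors(z, center, radius)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(sort(got$dist), sort(ref$d), tolerance = 1e-9)
  }
})

test_that("matthews volume follows its defining ratio", {
  cube <- unit_cell(100, 100, 100)
  expect_equal(matthews(cube, 1, 1e6)$v_m, 1.0)
  uc <- unit_cell(81.827, 81.827, 33.849, 90, 90, 120)
  m <- matthews(uc, 9, 11466)
  expect_equal(m$v_m, 81.827^2 * 33.849 * sin(2 * pi / 3) / (9 * 11466),
               tolerance = 1e-9)
  expect_equal(matthews(uc, 9, 2 * 11466)$v_m, m$v_m / 2, tolerance = 1e-12)
  expect_equal(m$solvent_fraction, 1 - 1.23 / m$v_m)
  expect_error(matthews(uc, 9, -5), "positive")
})
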