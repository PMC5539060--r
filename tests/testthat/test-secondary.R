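test_that("backbone torsions reproduce the generator values", {
  s <- make_helix("alpha", 10)
  tor <- backbone_torsions(s, "A")
  expect_equal(tor$phi[2:10], rep(-57, 9), tolerance = 1e-6)
  expect_equal(tor$psi[1:9], rep(-47, 9), tolerance = 1e-6)
  expect_true(is.na(tor$phi[1]))
  expect_true(is.na(tor$psi[10]))
  expect_equal(tor$omega[2:10], rep(180, 9), tolerance = 1e-6)

  h4 <- make_helix("alpha", 4)$atom
  one <- new_structure(h4[h4$resno == 1, ])
  t1 <- backbone_torsions(one, "A")
  expect_true(all(is.na(c(t1$phi, t1$psi))))
})

test_that("main-chain bond offsets identify the helix kind", {
  for (case in list(list(kind = "alpha", k = 4, n = 12),
                    list(kind = "three_ten", k = 3, n = 8),
                    list(kind = "pi", k = 5, n = 9))) {
    s <- make_helix(case$kind, case$n)
    pat <- mainchain_hbond_pattern(s, find_hbonds(s))
    expect_gt(nrow(pat$helical), 0)
    expect_true(all(pat$helical$k == case$k),
                label = sprintf("%s offsets", case$kind))
  }
})

test_that("ideal fixtures are assigned their planted kind and span", {
  for (fx in list(make_helix("alpha", 18),
                  make_helix("alpha", 10, flank = c(3, 3)),
                  make_helix("three_ten", 7, flank = c(2, 0)),
                  make_helix("pi", 8))) {
    plan <- attr(fx, "expected")
    ss <- assign_secondary_structure(fx)
    hel <- Filter(function(e) grepl("helix|pi", e$kind), ss)
    expect_length(hel, 1)
    expect_identical(hel[[1]]$kind, plan$kind)
    expect_equal(c(hel[[1]]$from, hel[[1]]$to), c(plan$from, plan$to))
  }
})

test_that("an embedded pi turn is annotated inside its alpha helix", {
  fx <- make_mixed_helix()
  ss <- assign_secondary_structure(fx)
  hel <- Filter(function(e) e$kind == "alpha_helix", ss)
  expect_length(hel, 1)
  expect_true(5 %in% hel[[1]]$offsets)
  expect_match(hel[[1]]$sub_annotation, "mixed")
})

test_that("a hairpin yields two strands, one sheet and one turn", {
  fx <- make_hairpin(5)
  plan <- attr(fx, "expected")
  ss <- assign_secondary_structure(fx)
  strands <- Filter(function(e) e$kind == "strand", ss)
  sheets <- Filter(function(e) e$kind == "sheet", ss)
  turns <- Filter(function(e) e$kind == "turn_I", ss)
  expect_length(strands, 2)
  expect_length(sheets, 1)
  expect_length(turns, 1)
  expect_equal(c(strands[[1]]$from, strands[[1]]$to), plan$strand1)
  expect_equal(c(strands[[2]]$from, strands[[2]]$to), plan$strand2)
  expect_equal(c(turns[[1]]$from, turns[[1]]$to), plan$turn)
  expect_identical(sheets[[1]]$topology, "antiparallel")
  # dual extents: the hydrogen-bond extent never exceeds the phi/psi extent
  for (st in strands) {
    he <- st$hbond_extent
    if (!anyNA(he)) {
      expect_gte(he[1], st$phipsi_extent[1])
      expect_lte(he[2], st$phipsi_extent[2])
    }
  }
})

test_that("an isolated i->i+4 bond outside a helix is an open alpha-turn", {
  fx <- make_helix("alpha", 10, flank = c(3, 3))
  ss <- assign_secondary_structure(fx)
  open_turns <- Filter(function(e) e$kind == "open_alpha_turn", ss)
  # the flanked fixture must not sprout spurious turns at its boundaries
  expect_length(open_turns, 0)
})

test_that("serine-style capping bonds at helix ends are recorded", {
  # append a serine-like OG that bonds the amide of the residue after the
  # helix C-terminus
  fx <- make_helix("alpha", 8, flank = c(0, 2))
  a <- fx$atom
  n_last <- a[a$resno == 9 & a$elety == "N", ]
  h_last <- a[a$resno == 9 & a$elety == "H", ]
  og <- h_last
  og$elety <- "OG"
  og$elesy <- "O"
  og$resno <- 8
  dirv <- unlist(h_last[, c("x", "y", "z")]) - unlist(n_last[, c("x", "y", "z")])
  dirv <- dirv / sqrt(sum(dirv^2))
  og[, c("x", "y", "z")] <- h_last[, c("x", "y", "z")] + 1.9 * dirv
  s <- new_structure(rbind(a, og))
  ss <- assign_secondary_structure(s)
  hel <- Filter(function(e) grepl("helix", e$kind), ss)
  expect_length(hel, 1)
  expect_true(any(grepl("OG", hel[[1]]$caps)))
})

test_that("assignment is invariant under rigid-body motion", {
  set.seed(51)
  fx <- make_hairpin(5)
  ss1 <- assign_secondary_structure(fx)
  R <- random_rotation()
  a <- fx$atom
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + 7.3
  a$y <- xyz[, 2] - 4.1
  a$z <- xyz[, 3] + 2.2
  moved <- new_structure(a)
  ss2 <- assign_secondary_structure(moved)
  expect_equal(vapply(ss2, `[[`, character(1), "kind"),
               vapply(ss1, `[[`, character(1), "kind"))
  expect_equal(vapply(ss2, function(e) c(e$from, e$to), numeric(2)),
               vapply(ss1, function(e) c(e$from, e$to), numeric(2)))
})

test_that("per-residue torsion and region tables are attached", {
  ss <- assign_secondary_structure(make_helix("alpha", 8))
  res <- attr(ss, "residues")
  expect_true(all(c("phi", "psi", "region") %in% names(res)))
  expect_true(all(res$region[2:7] == "helical"))
})
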