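simple_pdb <- paste(
  "CRYST1   81.827   81.827   33.849  90.00  90.00 120.00 H 3",
  "ATOM      1  N   GLY A   1      11.000   2.000   3.000  1.00 10.00           N",
  "ATOM      2  CA  GLY A   1      12.200   2.500   3.400  1.00 11.00           C",
  "ATOM      3  C   GLY A   1      13.100   1.500   4.100  1.00 12.00           C",
  "END", sep = "\n")

test_that("a minimal PDB text parses into the structure model", {
  s <- read_structure(simple_pdb)
  expect_s3_class(s, "ultra_structure")
  expect_equal(nrow(s$atom), 3)
  expect_equal(unique(s$atom$chain), "A")
  expect_equal(s$atom$elety, c("N", "CA", "C"))
  expect_equal(s$atom$category, rep("polymer", 3))
  expect_equal(s$crystal$a, 81.827)
  expect_equal(s$crystal$gamma, 120)
  expect_equal(s$crystal$space_group, "H 3")
})

test_that("malformed coordinate records fail with the offending line", {
  bad <- sub("12.200", "xx.xxx", simple_pdb)
  expect_error(read_structure(bad), "line 3")
})

test_that("read-write-read is idempotent on synthetic structures", {
  for (s in list(make_helix("alpha", 8),
                 synthetic_insulin_benchmark())) {
    txt <- write_structure(s)
    s2 <- read_structure(txt)
    txt2 <- write_structure(s2)
    expect_identical(txt, txt2)
    expect_equal(s2$atom$x, s$atom$x, tolerance = 1e-3)
    expect_equal(s2$atom$o, s$atom$o, tolerance = 1e-2)
    expect_identical(s2$atom$elety, s$atom$elety)
    expect_identical(s2$atom$alt, s$atom$alt)
    expect_identical(s2$atom$chain, s$atom$chain)
  }
})

test_that("split conformers write one record per altloc with the label set", {
  s <- make_disulphide(100, altloc_split = list(occ = c(0.8, 0.2),
                                                chi3_b = -80))
  lines <- strsplit(write_structure(s), "\n")[[1]]
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  sg11 <- atom_lines[grepl(" SG ", atom_lines) &
                       as.integer(substr(atom_lines, 23, 26)) == 11]
  expect_length(sg11, 2)
  expect_setequal(substr(sg11, 17, 17), c("A", "B"))
  occ <- as.numeric(substr(sg11, 55, 60))
  expect_setequal(occ, c(0.8, 0.2))
})

test_that("an empty structure writes a header-only file", {
  s <- read_structure("END\n")
  expect_equal(nrow(s$atom), 0)
  expect_match(write_structure(s), "^END$")
  expect_error(
    write_structure(new_structure(data.frame(
      elety = "O", resid = "HOH", chain = "WA", resno = 1,
      x = 0, y = 0, z = 0, elesy = "O"))), "single-character")
})

test_that("conformer expansion distributes atoms and weights", {
  gly <- data.frame(elety = c("N", "CA", "C", "O"), resid = "GLY",
                    chain = "A", resno = 1, insert = "", alt = "",
                    o = 1, x = 1:4, y = 0, z = 0, elesy = c("N", "C", "C", "O"))
  out <- conformer_expand(gly)
  expect_length(out, 1)
  expect_equal(out[[1]]$weight, 1)

  split3 <- rbind(gly,
                  data.frame(elety = "CB", resid = "GLY", chain = "A",
                             resno = 1, insert = "", alt = c("A", "B", "C"),
                             o = c(0.5, 0.3, 0.2), x = 5:7, y = 1, z = 0,
                             elesy = "C"))
  out3 <- conformer_expand(split3)
  expect_length(out3, 3)
  expect_equal(sum(vapply(out3, `[[`, numeric(1), "weight")), 1,
               tolerance = 1e-6)
  # blank-altloc atoms are shared by every conformer
  expect_true(all(vapply(out3, function(cf)
    all(c("N", "CA", "C", "O", "CB") %in% cf$residue$elety), logical(1))))

  dup <- rbind(gly, gly[1, ])
  expect_error(conformer_expand(dup), "duplicate")
})

test_that("split-sulphur occupancies are preserved through a round trip", {
  s <- make_disulphide(108.23, altloc_split = list(occ = c(0.8, 0.2),
                                                   chi3_b = -79.10))
  s2 <- read_structure(write_structure(s))
  sg <- s2$atom[s2$atom$resno == 11 & s2$atom$elety == "SG", ]
  expect_setequal(sg$alt, c("A", "B"))
  expect_equal(sort(sg$o), c(0.2, 0.8))
  r11 <- s2$atom[s2$atom$resno == 11, ]
  conf <- conformer_expand(r11)
  expect_equal(sum(vapply(conf, `[[`, numeric(1), "weight")), 1,
               tolerance = 1e-6)
})

test_that("waters are counted from parsed residues", {
  s <- make_water_network(5, ww_edges = rbind(c(1, 2)))
  expect_equal(water_count(s), 5)
  s2 <- read_structure(write_structure(s))
  expect_equal(water_count(s2), 5)
  expect_equal(unique(s2$atom$category[s2$atom$resid == "HOH"]), "water")
})

test_that("impossible occupancies are rejected or flagged", {
  bad <- data.frame(elety = "O", resid = "HOH", chain = "W", resno = 1,
                    x = 0, y = 0, z = 0, o = 1.5, elesy = "O")
  expect_error(new_structure(bad), "occupanc")
  over <- data.frame(elety = c("CB", "CB"), resid = "ALA", chain = "A",
                     resno = 1, alt = c("A", "B"), o = c(0.8, 0.8),
                     x = c(0, 1), y = 0, z = 0, elesy = "C")
  expect_warning(new_structure(over), "exceed 1")
})
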