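water_pair <- function(d) {
  new_structure(data.frame(elety = "O", resid = "HOH", chain = "W",
                           resno = 1:2, x = c(0, d), y = 0, z = 0,
                           elesy = "O"))
}

test_that("water-water bonds respect the distance cutoff", {
  b <- suppressWarnings(find_hbonds(water_pair(2.8)))
  expect_equal(nrow(b), 1)
  expect_equal(b$class, "W-W")
  expect_equal(b$d_da, 2.8, tolerance = 1e-9)
  expect_equal(nrow(suppressWarnings(find_hbonds(water_pair(5)))), 0)
})

test_that("a six-water ring gives six unique W-W bonds of type (0,2)", {
  s <- make_water_network(6, ring = TRUE)
  bonds <- suppressWarnings(find_hbonds(s))
  expect_equal(nrow(bonds), 6)
  cen <- water_census(bonds, s)
  expect_equal(cen$total_w_w, 6)
  expect_equal(cen$matrix, data.frame(n_sc = 0L, n_ww = 2L, n = 6L))
})

test_that("the census reproduces planted topologies exactly", {
  s <- make_water_network(7, ww_edges = rbind(c(1, 2), c(1, 3)),
                          sc_counts = c(4, 0, 1, 2, 0, 0, 0))
  cen <- water_census(suppressWarnings(find_hbonds(s)), s)
  plan <- attr(s, "expected")
  expect_equal(cen$per_water$n_sc, plan$n_sc)
  expect_equal(cen$per_water$n_ww, plan$n_ww)
  # the (4,2) water of the plan appears in the matrix
  expect_true(any(cen$matrix$n_sc == 4 & cen$matrix$n_ww == 2))
})

test_that("census conservation identities hold on random plans", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    # random forest over the waters
    edges <- NULL
    for (v in 2:n) if (stats::runif(1) < 0.7)
      edges <- rbind(edges, c(sample(v - 1, 1), v))
    sc <- sample(0:2, n, replace = TRUE)
    s <- try(make_water_network(n, ww_edges = edges, sc_counts = sc),
             silent = TRUE)
    if (inherits(s, "try-error")) next  # geometrically unrealisable draw
    bonds <- suppressWarnings(find_hbonds(s))
    cen <- water_census(bonds, s)
    expect_equal(sum(cen$matrix$n_sc * cen$matrix$n), cen$total_sc_w)
    expect_equal(sum(cen$matrix$n_ww * cen$matrix$n), 2 * cen$total_w_w)
    expect_equal(sum(cen$matrix$n) + cen$isolated, cen$n_waters)
    # detection equals the plan: zero false positives or negatives
    plan <- attr(s, "expected")
    expect_equal(cen$per_water$n_sc, plan$n_sc)
    expect_equal(cen$per_water$n_ww, plan$n_ww)
  }
})

test_that("shrinking a cutoff never increases the bond count", {
  s <- make_water_network(6, ww_edges = rbind(c(1, 2), c(2, 3), c(3, 4)),
                          sc_counts = c(1, 0, 2, 0, 1, 0))
  cuts <- seq(3.4, 2.0, by = -0.2)
  counts <- vapply(cuts, function(dd)
    nrow(suppressWarnings(find_hbonds(s, hbond_criteria(max_da = dd)))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("salt bridges reproduce the benchmark table and nothing else", {
  b <- synthetic_insulin_benchmark()
  sb <- find_salt_bridges(b)
  want <- attr(b, "expected")$salt_bridges
  expect_equal(nrow(sb), 6)
  expect_equal(sb$d_contact, want$distance, tolerance = 1e-3)
  expect_equal(
    sub(":.*", "", sb$acceptor_label),
    paste0(want$acceptor_res, want$acceptor_chain, want$acceptor_resno))
  # the guanidinium reaches the same oxygen twice, one record per hydrogen
  arg <- sb[grepl("^ARGB22", sb$donor_label), ]
  expect_equal(nrow(arg), 2)
  expect_equal(unique(arg$acceptor_label), "GLUA17:OE2")
})

test_that("distant basic groups form no salt bridge", {
  atoms <- rbind(
    data.frame(elety = "NZ", resid = "LYS", chain = "A", resno = 1,
               x = 0, y = 0, z = 0, elesy = "N"),
    data.frame(elety = "OE1", resid = "GLU", chain = "A", resno = 5,
               x = 6, y = 0, z = 0, elesy = "O"))
  expect_equal(nrow(find_salt_bridges(new_structure(atoms))), 0)
  atoms$x[2] <- 2.49
  sb <- find_salt_bridges(new_structure(atoms))
  expect_equal(nrow(sb), 1)
  expect_equal(sb$d_contact, 2.49)
  expect_equal(sb$via, "N")
})

test_that("residues without water contacts are listed per chain", {
  s <- make_water_network(3, sc_counts = c(1, 1, 0))
  bonds <- suppressWarnings(find_hbonds(s))
  dry <- residues_without_water(s, bonds)
  # both serine stubs touch a water, so no polymer residue is dry
  expect_equal(sum(dry$counts), 0)
  # push one hydroxyl out of range and it becomes dry
  a <- s$atom
  og1 <- which(a$resid == "SER" & a$resno == 1 & a$elety == "OG")
  shift <- which(a$resid == "SER" & a$resno == 1)
  a[shift, c("x", "y", "z")] <- a[shift, c("x", "y", "z")] + 50
  s2 <- new_structure(a)
  dry2 <- residues_without_water(s2, suppressWarnings(find_hbonds(s2)))
  expect_equal(unname(dry2$counts["X"]), 1)
  expect_match(dry2$by_chain$X, "SERX1")
})

test_that("criteria calibration recovers totals it can see", {
  s <- make_water_network(6, ww_edges = rbind(c(1, 2), c(2, 3), c(4, 5)),
                          sc_counts = c(2, 0, 1, 1, 0, 0))
  bonds <- suppressWarnings(find_hbonds(s))
  cen <- water_census(bonds, s)
  cal <- suppressWarnings(calibrate_hbond_criteria(
    s, target_sc = cen$total_sc_w, target_ww = cen$total_w_w))
  expect_s3_class(cal$best, "hbond_criteria")
  expect_true(all(c("max_da", "sc_w", "w_w", "score") %in% names(cal$report)))
  best_row <- cal$report[which.min(cal$report$score), ]
  expect_equal(best_row$sc_w, cen$total_sc_w)
  expect_equal(best_row$w_w, cen$total_w_w)
  expect_equal(best_row$score, 0)
})
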