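two_atom_chains <- function(d) {
  make_structure(rbind(atom_row("CA", "ALA", "A", 1, 0, 0, 0, "C"),
                       atom_row("CA", "ALA", "B", 1, d, 0, 0, "C")))
}

test_that("the neighbor criterion is strictly below 5 Angstrom", {
  expect_equal(interchain_neighbors(two_atom_chains(4.9), "A", "B"), "A:1")
  expect_equal(length(interchain_neighbors(two_atom_chains(5.0), "A", "B")), 0)
  expect_error(interchain_neighbors(two_atom_chains(4), "A", "Z"), "unknown chain")
  expect_error(interchain_neighbors(two_atom_chains(4), "A", "A"), "disjoint")
})

test_that("hydrogen bonds require typed donor/acceptor pairs within 3.5 A", {
  ser_glu <- function(d) make_structure(rbind(
    atom_row("OG", "SER", "A", 1, 0, 0, 0, "O"),
    atom_row("OE1", "GLU", "B", 1, d, 0, 0, "O")))
  hb <- interchain_hbonds(ser_glu(3.0), "A", "B")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$atom_a, "OG")
  expect_equal(hb$donor_side, "a")
  expect_equal(nrow(interchain_hbonds(ser_glu(3.5), "A", "B")), 1)  # inclusive
  expect_equal(nrow(interchain_hbonds(ser_glu(3.51), "A", "B")), 0)
  # carbon is neither donor nor acceptor
  expect_equal(nrow(interchain_hbonds(two_atom_chains(3.0), "A", "B")), 0)
})

test_that("hydrogen-bonded residues are always a subset of neighbor residues", {
  dimer <- fixture_dimer()
  nb <- interchain_neighbors(dimer$structure, "A", "B")
  hb <- interchain_hbonds(dimer$structure, "A", "B")
  expect_true(all(unique(hb$res_a) %in% nb))
})

test_that("neighbor detection matches a naive all-pairs scan and is symmetric", {
  set.seed(21)
  n <- 100
  df <- rbind(
    do.call(rbind, lapply(1:n, function(i)
      atom_row("CA", "ALA", "A", i, runif(1, 0, 15), runif(1, 0, 15),
               runif(1, 0, 15), "C"))),
    do.call(rbind, lapply(1:n, function(i)
      atom_row("CA", "ALA", "B", i, runif(1, 0, 15), runif(1, 0, 15),
               runif(1, 0, 15), "C"))))
  st <- make_structure(df)
  expect_setequal(interchain_neighbors(st, "A", "B"),
                  naive_neighbors(st, "A", "B"))
  # symmetry through the same atom pairs
  ab <- interchain_neighbors(st, "A", "B")
  ba <- interchain_neighbors(st, "B", "A")
  expect_equal(length(ab) > 0, length(ba) > 0)
})

test_that("interface detections are invariant under rigid motion", {
  dimer <- fixture_dimer()
  st <- dimer$structure
  R <- euler_rotation(0.5, 1.1, -0.8)
  st2 <- st
  xyz <- rigid_transform(as.matrix(st$atom[, c("x", "y", "z")]), R, c(5, -3, 11))
  st2$atom$x <- xyz[, 1]; st2$atom$y <- xyz[, 2]; st2$atom$z <- xyz[, 3]
  expect_setequal(interchain_neighbors(st, "A", "B"),
                  interchain_neighbors(st2, "A", "B"))
  hb1 <- interchain_hbonds(st, "A", "B")
  hb2 <- interchain_hbonds(st2, "A", "B")
  expect_setequal(paste(hb1$res_a, hb1$atom_a, hb1$res_b, hb1$atom_b),
                  paste(hb2$res_a, hb2$atom_a, hb2$res_b, hb2$atom_b))
})

test_that("epitope groups follow the exposure/contact truth table and partition", {
  acc <- data.frame(
    key = paste0("A:", 1:6),
    resid = "ALA", sasa_rel = c(30, 30, 5, 5, 15, 15),
    burial = c("exposed", "exposed", "buried", "buried",
               "intermediate", "intermediate"),
    stringsAsFactors = FALSE)
  rec <- classify_epitope_residues(acc, neighbors = c("A:1", "A:3", "A:5"),
                                   hbonds = c("A:1"))
  expect_equal(rec$epitope_group, c(1L, 2L, 3L, 0L, 3L, 0L))
  expect_equal(sum(table(rec$epitope_group)), nrow(acc))
  expect_true(all(rec$is_hbonded <= rec$is_neighbor))
  expect_error(classify_epitope_residues(acc, neighbors = "A:9", hbonds = character(0)),
               "A:9")
})

test_that("candidate ranking puts designed exposed contact residues first", {
  dimer <- fixture_dimer()
  rs <- residue_sasa(dimer$structure)
  acc <- rs[rs$chain == "A", ]
  nb <- interchain_neighbors(dimer$structure, "A", "B")
  hb <- interchain_hbonds(dimer$structure, "A", "B")
  rec <- classify_epitope_residues(acc, nb, intersect(unique(hb$res_a), acc$key))
  ranked <- nominate_candidates(rec)
  expect_equal(ranked$epitope_group[1], 1L)
  # top residue is the most exposed among group 1
  g1 <- rec[rec$epitope_group == 1L, ]
  expect_equal(ranked$key[1], g1$key[which.max(g1$sasa_rel)])
  expect_equal(nrow(nominate_candidates(rec[0, ])), 0)
})
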