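test_that("dimer generation is deterministic: same spec, same bytes", {
  spec <- synthetic_dimer_spec(n_residues_per_chain = 12,
                               interchain_distance = 9, seed = 5)
  d1 <- make_synthetic_dimer(spec)
  d2 <- make_synthetic_dimer(spec)
  expect_identical(write_pdb(d1$structure), write_pdb(d2$structure))
  expect_identical(d1$truth, d2$truth)
})

test_that("widely separated chains have no inter-chain neighbor labels", {
  spec <- synthetic_dimer_spec(n_residues_per_chain = 12,
                               interchain_distance = 20, seed = 2)
  d <- make_synthetic_dimer(spec)
  expect_false(any(d$truth$is_neighbor))
  expect_equal(length(interchain_neighbors(d$structure, "A", "B")), 0)
})

test_that("constructed ground truth is recovered by the analysis modules", {
  # seeded sweep over specs: neighbor flags must agree exactly; burial
  # classes may disagree only within +/-2% of the class thresholds
  for (s in 1:8) {
    spec <- synthetic_dimer_spec(n_residues_per_chain = 14,
                                 interchain_distance = 8.5 + 0.5 * s,
                                 seed = s)
    d <- make_synthetic_dimer(spec)
    nb <- interchain_neighbors(d$structure, "A", "B")
    expect_setequal(nb, d$truth$key[d$truth$is_neighbor])
    rs <- residue_sasa(d$structure)
    m <- merge(d$truth, rs[, c("key", "burial", "sasa_rel")], by = "key")
    disagree <- m$burial.x != m$burial.y
    near_threshold <- pmin(abs(m$sasa_rel - 10), abs(m$sasa_rel - 25)) < 2
    expect_true(all(!disagree | near_threshold))
    expect_gte(mean(!disagree), 0.9)
  }
})

test_that("designed donor/acceptor pairs are detected as hydrogen bonds", {
  spec <- synthetic_dimer_spec(
    n_residues_per_chain = 20, interchain_distance = 10,
    place_donor_acceptor_pairs = data.frame(res_a = 17, res_b = 17,
                                            distance = 3.0),
    seed = 3)
  d <- make_synthetic_dimer(spec)
  expect_true("A:17" %in% d$truth$key[d$truth$is_hbonded])
  hb <- interchain_hbonds(d$structure, "A", "B")
  expect_true(any(hb$res_a == "A:17" & hb$res_b == "B:17" &
                    abs(hb$distance - 3.0) < 1e-6))
  # infeasible placement is rejected
  bad <- synthetic_dimer_spec(
    n_residues_per_chain = 20, interchain_distance = 10,
    place_donor_acceptor_pairs = data.frame(res_a = 13, res_b = 13,
                                            distance = 3.0),
    seed = 3)
  expect_error(make_synthetic_dimer(bad), "inconsistent")
})

test_that("mimotope derivation is seeded, bounded, and exact when unmutated", {
  region <- "TLFLGILKNWKEES"
  mp0 <- make_mimotope_pair(region, 0, 0, seed = 1)
  expect_equal(mp0$query, region)
  expect_equal(mp0$identity_pct, 100)
  m <- alignment_metrics(align_overlap(mp0$query, region))
  expect_equal(m$identity_pct, 100)
  mp1 <- make_mimotope_pair(region, 3, 1, seed = 4)
  mp2 <- make_mimotope_pair(region, 3, 1, seed = 4)
  expect_identical(mp1, mp2)
  expect_error(make_mimotope_pair(region, 10, 4, seed = 1), "smaller")
})

test_that("the optimal alignment score dominates the designed-alignment score", {
  region <- "TLFLGILKNWKEES"
  S <- substitution_matrix()
  for (s in 1:25) {
    mp <- make_mimotope_pair(region, n_mut = 7, n_gap = 2, seed = s)
    aln <- align_overlap(mp$query, region)
    expect_gte(aln$score, score_alignment_path(mp$truth, S) - 1e-9)
  }
})

test_that("gapless moderate mutation loads are recovered exactly", {
  region <- "TLFLGILKNWKEES"
  for (s in 1:25) {
    mp <- make_mimotope_pair(region, n_mut = 3, n_gap = 0, seed = s)
    m <- alignment_metrics(align_overlap(mp$query, region))
    expect_equal(m$identity_pct, mp$identity_pct)
  }
})
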