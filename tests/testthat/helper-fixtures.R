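# Shared fixtures and independent oracles, all built in code at test time.

# build an epistructure straight from an atom data.frame
make_structure <- function(df) epitomap:::.as_structure(df)

atom_row <- function(elety, resid, chain, resno, x, y, z, element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", elety), 1, 1)
  data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
             insert = "", x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}

# the standard synthetic dimer fixture used across modules (memoized)
.fixture_cache <- new.env()
fixture_dimer <- function() {
  if (is.null(.fixture_cache$dimer)) {
    spec <- synthetic_dimer_spec(
      n_residues_per_chain = 20, interchain_distance = 10,
      place_donor_acceptor_pairs = data.frame(res_a = 17, res_b = 17,
                                              distance = 3.0),
      seed = 7)
    .fixture_cache$dimer <- make_synthetic_dimer(spec)
  }
  .fixture_cache$dimer
}

# per-residue absolute SASA of fixture_dimer() chain A computed with an
# independent reference Shrake-Rupley implementation (960 points, 1.4 A
# probe, element van der Waals radii); frozen oracle values
FIXTURE_SASA_ORACLE <- c(
  `A:1` = 140.944, `A:2` = 84.178, `A:3` = 101.258, `A:4` = 66.102,
  `A:5` = 83.642, `A:6` = 60.942, `A:7` = 82.802, `A:8` = 61.189,
  `A:9` = 58.191, `A:10` = 49.355, `A:11` = 83.947, `A:12` = 27.198,
  `A:13` = 3.857, `A:14` = 60.788, `A:15` = 83.500, `A:16` = 21.538,
  `A:17` = 61.803, `A:18` = 76.404, `A:19` = 103.562, `A:20` = 120.193)

# exhaustive enumeration of every overlap-mode alignment of tiny sequences;
# affine gap cost go + k*ge, target end gaps free, query fully consumed
enumerate_overlap_score <- function(q, t, S, go = 8, ge = 2) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  best <- -Inf
  rec <- function(i, j, sc, state) {
    if (i == m) { best <<- max(best, sc); return(invisible()) }
    if (j < n)  # pair
      rec(i + 1, j + 1, sc + S[qc[i + 1], tc[j + 1]], "M")
    if (j < n)  # gap in query, consumes target
      rec(i, j + 1, sc - ge - if (state == "GX") 0 else go, "GX")
    # gap in target, consumes query
    rec(i + 1, j, sc - ge - if (state == "GY") 0 else go, "GY")
  }
  for (j0 in 0:n) rec(0, j0, 0, "S")
  best
}

# brute-force rigid superposition: coarse Euler-angle grid then Nelder-Mead
# refinement of the residual; never uses the SVD route
brute_force_rmsd <- function(P, Q, step_deg = 12) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(ang) {
    R <- euler_rotation(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  }
  step <- step_deg * pi / 180
  grid_a <- seq(0, 2 * pi, by = step)
  grid_b <- seq(-pi / 2, pi / 2, by = step)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid_a) for (b in grid_b) for (g in grid_a) {
    v <- obj(c(a, b, g))
    if (v < best) { best <- v; best_ang <- c(a, b, g) }
  }
  opt <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  min(best, opt$value)
}

# naive all-pairs neighbor scan (independent of the module implementation)
naive_neighbors <- function(structure, chains_a, chains_b, cutoff = 5) {
  at <- structure$atom[structure$atom$is_heavy, ]
  a <- at[at$chain %in% chains_a, ]; b <- at[at$chain %in% chains_b, ]
  keys <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < cutoff) keys <- c(keys, residue_key(a[i, ]))
    }
  }
  unique(keys)
}

# scoring a given alignment path with the affine gap cost (for dominance
# checks against the DP optimum)
score_alignment_path <- function(truth, S, go = 8, ge = 2) {
  sc <- 0; run <- 0
  for (i in seq_len(nrow(truth))) {
    qch <- truth$query_char[i]; tch <- truth$target_char[i]
    if (qch == "-" || tch == "-") run <- run + 1
    else {
      if (run > 0) { sc <- sc - (go + ge * run); run <- 0 }
      sc <- sc + S[qch, tch]
    }
  }
  if (run > 0) sc <- sc - (go + ge * run)
  sc
}

# path to a locally supplied IFN-gamma dimer/receptor structure (PDB 1FG9);
# the coordinates are not redistributed with the package
find_1fg9 <- function() {
  candidates <- c(
    testthat::test_path("data", "1fg9.pdb"),
    system.file("extdata", "1fg9.pdb", package = "epitomap"))
  hit <- candidates[nzchar(candidates) & file.exists(candidates)]
  if (length(hit)) hit[1] else NA_character_
}
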