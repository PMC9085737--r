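# Deterministic synthetic fixtures with known ground truth: idealized
# two-helix "dimers" whose inter-chain separation, donor/acceptor placement
# and burial gradients are controlled by construction, and mutated mimotope
# peptides with a known true alignment. Every pipeline stage can thus be
# validated without any external structure.

# --- internal-coordinate chain building (NeRF placement) ------------------

.place_atom <- function(a, b, c, bond, angle, dihedral) {
  angle <- angle * pi / 180; dihedral <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# single functional side-chain atom per residue type (stub beyond CB)
.FUNCTIONAL_ATOM <- c(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
                      LYS = "NZ", ARG = "NH1", ASN = "OD1", GLN = "OE1",
                      ASP = "OD1", GLU = "OE1", HIS = "ND1", TRP = "NE1",
                      MET = "SD")
.FUNCTIONAL_ELEMENT <- c(OG = "O", OG1 = "O", OH = "O", SG = "S", NZ = "N",
                         NH1 = "N", OD1 = "O", OE1 = "O", ND1 = "N",
                         NE1 = "N", SD = "S")

# ideal backbone chain with CB stubs; default torsions give an alpha helix
# (phi -57, psi -47); beta-strand values (-139, 135) give an extended chain
.build_helix <- function(sequence3, chain_id, phi = -57, psi = -47) {
  n_res <- length(sequence3)
  rows <- list()
  # seed atoms for the first residue
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- .place_atom(c(0, 1, 0), N, CA, 1.525, 111.2, -100)  # arbitrary seed
  for (i in seq_len(n_res)) {
    resid <- sequence3[i]
    O <- .place_atom(N, CA, C, 1.231, 120.8, psi + 180)
    rows[[length(rows) + 1]] <- data.frame(
      elety = c("N", "CA", "C", "O"),
      resid = resid, chain = chain_id, resno = i, insert = "",
      x = c(N[1], CA[1], C[1], O[1]), y = c(N[2], CA[2], C[2], O[2]),
      z = c(N[3], CA[3], C[3], O[3]),
      element = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
    if (resid != "GLY") {
      CB <- .place_atom(C, N, CA, 1.53, 110.5, 122.7)
      rows[[length(rows) + 1]] <- data.frame(
        elety = "CB", resid = resid, chain = chain_id, resno = i,
        insert = "", x = CB[1], y = CB[2], z = CB[3], element = "C",
        stringsAsFactors = FALSE)
      fa <- .FUNCTIONAL_ATOM[resid]
      if (!is.na(fa)) {
        u <- CB - CA; u <- u / sqrt(sum(u^2))
        FP <- CB + 1.45 * u
        rows[[length(rows) + 1]] <- data.frame(
          elety = unname(fa), resid = resid, chain = chain_id, resno = i,
          insert = "", x = FP[1], y = FP[2], z = FP[3],
          element = unname(.FUNCTIONAL_ELEMENT[fa]), stringsAsFactors = FALSE)
      }
    }
    if (i < n_res) {
      N2 <- .place_atom(N, CA, C, 1.329, 116.2, psi)
      CA2 <- .place_atom(CA, C, N2, 1.458, 121.7, 180) # omega
      C2 <- .place_atom(C, N2, CA2, 1.525, 111.2, phi)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  do.call(rbind, rows)
}

.as_structure <- function(atom, title = "synthetic") {
  atom$eleno <- seq_len(nrow(atom))
  atom$o <- 1; atom$b <- 0
  atom$is_heavy <- atom$element != "H"
  atom <- atom[, c("eleno", "elety", "resid", "chain", "resno", "insert",
                   "x", "y", "z", "o", "b", "element", "is_heavy")]
  rownames(atom) <- NULL
  structure(list(atom = atom, title = title, source = "<synthetic>"),
            class = "epistructure")
}

#' Specification for a synthetic two-helix dimer
#'
#' @param n_residues_per_chain Residues per chain (default 30).
#' @param interchain_distance Axis-to-axis separation of the two parallel
#'   helices in Angstrom (default 10).
#' @param sequence_a,sequence_b One-letter sequences; default alternating
#'   Ser/Leu/Glu/Ala pattern giving a mix of donors, acceptors and apolar
#'   stubs. Recycled or truncated to the chain length.
#' @param place_donor_acceptor_pairs data.frame (or NULL) with columns
#'   `res_a`, `res_b` (residue numbers) and `distance` (Angstrom): the
#'   functional atoms of those residues are re-placed on the line between
#'   the two residues so that their mutual distance is exactly `distance`.
#' @param seed Integer seed for the stochastic ground-truth burial check.
#' @return List of class `synthetic_dimer_spec`.
#' @export
synthetic_dimer_spec <- function(n_residues_per_chain = 30,
                                 interchain_distance = 10,
                                 sequence_a = NULL, sequence_b = NULL,
                                 place_donor_acceptor_pairs = NULL,
                                 seed = 1L) {
  if (interchain_distance <= 0) stop("interchain_distance must be positive")
  mk_seq <- function(s) {
    if (is.null(s))
      s <- paste(rep(c("S", "L", "E", "A"), length.out = n_residues_per_chain),
                 collapse = "")
    ch <- .check_aa(s, "sequence")
    if (length(ch) < n_residues_per_chain)
      ch <- rep(ch, length.out = n_residues_per_chain)
    paste(ch[seq_len(n_residues_per_chain)], collapse = "")
  }
  structure(list(n_residues_per_chain = n_residues_per_chain,
                 interchain_distance = interchain_distance,
                 sequence_a = mk_seq(sequence_a), sequence_b = mk_seq(sequence_b),
                 place_donor_acceptor_pairs = place_donor_acceptor_pairs,
                 seed = as.integer(seed)),
            class = "synthetic_dimer_spec")
}

# independent stochastic burial estimate used only for ground-truth labels:
# random (seeded) points on each expanded atom sphere, naive occlusion scan
.ground_truth_burial <- function(atom, seed, n_pts = 350) {
  set.seed(seed)
  radii <- vdw_radii()
  R <- radii[atom$element] + 1.4
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  n <- nrow(xyz)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_pts), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    P <- sweep(u * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_pts)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- sum((xyz[i, ] - xyz[j, ])^2)
      if (d2 >= (R[i] + R[j])^2) next
      dj <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      free <- free & dj >= R[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * R[i]^2
  }
  key <- residue_key(atom)
  first <- !duplicated(key)
  abs_area <- tapply(areas, key, sum)
  ref <- max_sasa_reference()
  rel <- 100 * as.numeric(abs_area[key[first]]) / ref[atom$resid[first]]
  data.frame(key = key[first], sasa_rel_mc = rel,
             burial = classify_burial(rel), stringsAsFactors = FALSE)
}

#' Build a synthetic two-helix dimer with ground-truth labels
#'
#' Two idealized parallel alpha-helices (chains A and B) separated along x
#' by the requested axis distance, chain B rotated so its side-chain stubs
#' face chain A. Ground-truth labels are derived from the constructed
#' geometry by independent code paths (naive distance scans; a seeded
#' random-point burial estimate), not from the analysis modules.
#'
#' @param spec A [synthetic_dimer_spec()].
#' @return List: `structure` (an `epistructure`) and `truth`, a data.frame
#'   per residue of chain A with `key`, `is_neighbor`, `is_hbonded`,
#'   `burial` and the Monte-Carlo relative SASA `sasa_rel_mc`.
#' @export
make_synthetic_dimer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_dimer_spec"))
  seq_a <- bio3d::aa123(strsplit(spec$sequence_a, "")[[1]])
  seq_b <- bio3d::aa123(strsplit(spec$sequence_b, "")[[1]])
  ha <- .build_helix(seq_a, "A")
  hb <- .build_helix(seq_b, "B")
  # center each helix axis on the z axis, then separate along x
  center_axis <- function(h) {
    ca <- h[h$elety == "CA", c("x", "y", "z")]
    h$x <- h$x - mean(ca$x); h$y <- h$y - mean(ca$y); h$z <- h$z - mean(ca$z)
    h
  }
  ha <- center_axis(ha); hb <- center_axis(hb)
  # rotate chain B by 180 degrees about z so the two helices face each other
  xb <- -hb$x; yb <- -hb$y
  hb$x <- xb + spec$interchain_distance
  hb$y <- yb
  ha$x <- ha$x  # chain A stays at the origin
  atom <- rbind(ha, hb)
  # re-place functional atoms of requested donor/acceptor pairs
  pairs <- spec$place_donor_acceptor_pairs
  placed <- list()
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- pairs$res_a[k]; rb <- pairs$res_b[k]; d <- pairs$distance[k]
      ia <- which(atom$chain == "A" & atom$resno == ra &
                    atom$elety %in% names(.FUNCTIONAL_ELEMENT))
      ib <- which(atom$chain == "B" & atom$resno == rb &
                    atom$elety %in% names(.FUNCTIONAL_ELEMENT))
      if (!length(ia) || !length(ib))
        stop("donor/acceptor pair refers to residues without functional atoms")
      cba <- which(atom$chain == "A" & atom$resno == ra & atom$elety == "CB")
      cbb <- which(atom$chain == "B" & atom$resno == rb & atom$elety == "CB")
      pa <- as.numeric(atom[cba, c("x", "y", "z")])
      pb <- as.numeric(atom[cbb, c("x", "y", "z")])
      u <- pb - pa; L <- sqrt(sum(u^2)); u <- u / L
      stretch <- (L - d) / 2  # CB-to-functional-atom bond each side
      if (stretch < 0.5 || stretch > 3.2)
        stop("requested donor/acceptor distance is inconsistent with the chain separation")
      mid <- (pa + pb) / 2
      fa <- mid - (d / 2) * u
      fb <- mid + (d / 2) * u
      atom[ia[1], c("x", "y", "z")] <- as.list(fa)
      atom[ib[1], c("x", "y", "z")] <- as.list(fb)
      placed[[length(placed) + 1]] <- data.frame(
        res_a = ra, res_b = rb, distance = d,
        role_a = .hbond_role(atom$resid[ia[1]], atom$elety[ia[1]]),
        role_b = .hbond_role(atom$resid[ib[1]], atom$elety[ib[1]]),
        stringsAsFactors = FALSE)
    }
  }
  st <- .as_structure(atom, title = "synthetic two-helix dimer")
  # ground truth by direct geometry scans
  a_at <- atom[atom$chain == "A", , drop = FALSE]
  b_at <- atom[atom$chain == "B", , drop = FALSE]
  keys <- unique(residue_key(a_at))
  min_d <- vapply(keys, function(k) {
    sel <- residue_key(a_at) == k
    m <- Inf
    for (r in which(sel)) {
      d <- sqrt((b_at$x - a_at$x[r])^2 + (b_at$y - a_at$y[r])^2 +
                  (b_at$z - a_at$z[r])^2)
      m <- min(m, min(d))
    }
    m
  }, numeric(1))
  truth <- data.frame(key = keys, min_interchain_dist = as.numeric(min_d),
                      is_neighbor = as.numeric(min_d) < 5.0,
                      stringsAsFactors = FALSE)
  hkeys <- character(0)
  if (length(placed)) {
    pl <- do.call(rbind, placed)
    ok <- pl$distance <= 3.5 &
      ((pl$role_a %in% c("donor", "both") & pl$role_b %in% c("acceptor", "both")) |
         (pl$role_b %in% c("donor", "both") & pl$role_a %in% c("acceptor", "both")))
    hkeys <- paste0("A:", pl$res_a[ok])
  }
  truth$is_hbonded <- truth$key %in% hkeys
  bt <- .ground_truth_burial(atom, spec$seed)
  truth <- merge(truth, bt, by = "key", sort = FALSE)
  truth <- truth[match(keys, truth$key), , drop = FALSE]
  rownames(truth) <- NULL
  list(structure = st, truth = truth, spec = spec)
}

#' Derive a mutated mimotope peptide with known alignment truth
#'
#' Applies seeded point substitutions and internal deletions to a copy of
#' an antigen region, returning the peptide together with the true
#' alignment and its designed identity.
#'
#' @param region_seq Antigen region sequence (one-letter codes).
#' @param n_mut Number of substitutions.
#' @param n_gap Number of single-residue deletions (internal positions).
#' @param seed Integer seed.
#' @return List: `query` (peptide string), `truth` (data.frame of
#'   `query_char`, `target_char` columns of the true alignment),
#'   `identity_pct` (designed identity over the region length).
#' @export
make_mimotope_pair <- function(region_seq, n_mut, n_gap, seed = 1L) {
  ch <- .check_aa(region_seq, "region_seq")
  L <- length(ch)
  if (n_mut + n_gap >= L) stop("n_mut + n_gap must be smaller than the region length")
  set.seed(seed)
  internal <- 2:(L - 1)
  gap_pos <- if (n_gap > 0) sort(sample(internal, n_gap)) else integer(0)
  mut_pos <- if (n_mut > 0) sort(sample(setdiff(seq_len(L), gap_pos), n_mut)) else integer(0)
  q <- ch
  for (p in mut_pos) q[p] <- sample(setdiff(AA20, ch[p]), 1)
  qcol <- q
  qcol[gap_pos] <- "-"
  truth <- data.frame(query_char = qcol, target_char = ch,
                      stringsAsFactors = FALSE)
  list(query = paste(qcol[qcol != "-"], collapse = ""),
       truth = truth,
       identity_pct = round(100 * sum(qcol == ch) / L, 2))
}
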