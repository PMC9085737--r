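# Inter-chain interface analysis: neighbor residues (< 5 A heavy-atom
# contact), geometric hydrogen bonds (typed donor/acceptor heavy atoms
# within 3.5 A), and the combination with burial classes into candidate
# epitope groups.

#' Neighbor criteria
#'
#' @param cutoff Heavy-atom distance cutoff in Angstrom; comparison is
#'   strict (`<`). Default 5.0.
#' @return List of class `neighbor_criteria`.
#' @export
neighbor_criteria <- function(cutoff = 5.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(cutoff = cutoff), class = "neighbor_criteria")
}

#' Hydrogen-bond criteria
#'
#' Heavy-atom donor-acceptor distance criterion (inclusive, `<=`). An
#' angular window is deliberately not applied by default: without modeled
#' hydrogens the operative geometric criterion is the donor-acceptor
#' distance.
#'
#' @param dmax Maximum donor-acceptor distance in Angstrom (default 3.5).
#' @return List of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dmax = 3.5) {
  if (dmax <= 0) stop("dmax must be positive")
  structure(list(dmax = dmax), class = "hbond_criteria")
}

# cross-group heavy-atom pairs within cutoff; returns data.frame of atom
# row pairs and distances
.cross_pairs <- function(a, b, cutoff, inclusive = FALSE) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  hit <- if (inclusive) d2 <= cutoff^2 else d2 < cutoff^2
  idx <- which(hit, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             distance = sqrt(d2[idx]), stringsAsFactors = FALSE)
}

#' Inter-chain neighbor residues
#'
#' A residue of `chains_a` is a neighbor if at least one of its heavy atoms
#' lies strictly within the cutoff of any heavy atom of `chains_b`.
#'
#' @param structure An `epistructure`.
#' @param chains_a,chains_b Disjoint chain groups.
#' @param criteria A [neighbor_criteria()] object.
#' @return Character vector of residue keys (see [residue_key()]) of
#'   `chains_a`, in file order.
#' @export
interchain_neighbors <- function(structure, chains_a, chains_b,
                                 criteria = neighbor_criteria()) {
  if (length(intersect(chains_a, chains_b)))
    stop("chain groups must be disjoint")
  a <- .atoms_in_chains(structure, chains_a)
  b <- .atoms_in_chains(structure, chains_b)
  pr <- .cross_pairs(a, b, criteria$cutoff, inclusive = FALSE)
  keys <- residue_key(a)
  unique(keys[pr$i[order(pr$i)]])
}

# donor/acceptor role of one heavy atom given its residue context
.hbond_role <- function(resid, elety) {
  roles <- rep("none", length(elety))
  roles[elety == "N" & resid != "PRO"] <- "donor"
  roles[elety %in% c("O", "OXT")] <- "acceptor"
  tab <- .hbond_table()
  m <- match(paste(resid, elety), paste(tab$resid, tab$atom))
  roles[!is.na(m)] <- tab$role[m[!is.na(m)]]
  roles
}

#' Inter-chain hydrogen bonds
#'
#' Reports cross-chain heavy-atom pairs where one atom is a typed donor and
#' the other a typed acceptor, within the distance criterion. Typing uses a
#' fixed residue-template table (backbone N donor except proline, backbone
#' O/OXT acceptor, side-chain roles per residue; histidine ring nitrogens
#' act as both).
#'
#' @param structure An `epistructure`.
#' @param chains_a,chains_b Disjoint chain groups.
#' @param criteria An [hbond_criteria()] object.
#' @return data.frame with one row per bond: `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `donor_side` ("a" or "b"), `distance`.
#' @export
interchain_hbonds <- function(structure, chains_a, chains_b,
                              criteria = hbond_criteria()) {
  if (length(intersect(chains_a, chains_b)))
    stop("chain groups must be disjoint")
  a <- .atoms_in_chains(structure, chains_a)
  b <- .atoms_in_chains(structure, chains_b)
  role_a <- .hbond_role(a$resid, a$elety)
  role_b <- .hbond_role(b$resid, b$elety)
  keep_a <- role_a != "none"
  keep_b <- role_b != "none"
  a <- a[keep_a, , drop = FALSE]; role_a <- role_a[keep_a]
  b <- b[keep_b, , drop = FALSE]; role_b <- role_b[keep_b]
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(res_a = character(0), atom_a = character(0),
                      res_b = character(0), atom_b = character(0),
                      donor_side = character(0), distance = numeric(0)))
  pr <- .cross_pairs(a, b, criteria$dmax, inclusive = TRUE)
  if (nrow(pr) == 0)
    return(data.frame(res_a = character(0), atom_a = character(0),
                      res_b = character(0), atom_b = character(0),
                      donor_side = character(0), distance = numeric(0)))
  ra <- role_a[pr$i]; rb <- role_b[pr$j]
  a_donates <- ra %in% c("donor", "both") & rb %in% c("acceptor", "both")
  b_donates <- rb %in% c("donor", "both") & ra %in% c("acceptor", "both")
  keep <- a_donates | b_donates
  pr <- pr[keep, , drop = FALSE]
  data.frame(res_a = residue_key(a)[pr$i], atom_a = a$elety[pr$i],
             res_b = residue_key(b)[pr$j], atom_b = b$elety[pr$j],
             donor_side = ifelse(a_donates[keep], "a", "b"),
             distance = pr$distance, stringsAsFactors = FALSE)
}

#' Combine burial, neighbor and hydrogen-bond evidence into epitope groups
#'
#' Group 1: exposed residues in inter-chain contact; group 2: exposed,
#' no contact; group 3: buried or intermediate residues in contact;
#' group 0: buried or intermediate without contact (added so the mapping is
#' total).
#'
#' @param accessibility data.frame from [residue_sasa()] (possibly
#'   region-restricted), needing columns `key` and `burial`.
#' @param neighbors Character vector of neighbor residue keys.
#' @param hbonds Either the data.frame from [interchain_hbonds()] or a
#'   character vector of hydrogen-bonded residue keys.
#' @return The accessibility data.frame with added logical columns
#'   `is_neighbor`, `is_hbonded` and integer `epitope_group`.
#' @export
classify_epitope_residues <- function(accessibility, neighbors, hbonds) {
  hkeys <- if (is.data.frame(hbonds)) unique(hbonds$res_a) else hbonds
  extra <- setdiff(c(neighbors, hkeys), accessibility$key)
  if (length(extra))
    stop("residue set mismatch; keys absent from accessibility records: ",
         paste(extra, collapse = ", "))
  out <- accessibility
  out$is_neighbor <- out$key %in% neighbors
  out$is_hbonded <- out$key %in% hkeys
  exposed <- out$burial == "exposed"
  out$epitope_group <- ifelse(exposed & out$is_neighbor, 1L,
                       ifelse(exposed & !out$is_neighbor, 2L,
                       ifelse(out$is_neighbor, 3L, 0L)))
  out
}

#' Rank candidate epitope-critical residues
#'
#' Orders residues by epitope group (group 1 first, then 3, 2, 0), then by
#' decreasing relative SASA, then by membership in a receptor-contact set,
#' then by key for determinism.
#'
#' @param records Output of [classify_epitope_residues()].
#' @param receptor_contacts Character vector of residue keys in contact
#'   with a receptor (may be empty).
#' @return `records` reordered, with an added integer `rank` column.
#' @export
nominate_candidates <- function(records, receptor_contacts = character(0)) {
  if (nrow(records) == 0) return(records)
  grp_order <- match(records$epitope_group, c(1L, 3L, 2L, 0L))
  in_contact <- records$key %in% receptor_contacts
  ord <- order(grp_order, -records$sasa_rel, !in_contact, records$key)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
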