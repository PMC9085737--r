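# Pairwise nonbonded energetics (Lennard-Jones + Coulomb) for
# residue-fragment interaction energies IE = E_AB - E_A - E_B, interface
# selection, and a contact-based binding-affinity predictor.
#
# The forcefield is a deliberately minimal, fully pinned parameter set:
# per-element Lennard-Jones terms with Lorentz-Berthelot combination and
# heavy-atom template charges whose per-residue sums equal the residue
# formal charge. Interaction energies are meaningful as relative,
# self-consistent quantities, not as literal molecular-mechanics energies.

COULOMB_K <- 332.0636  # kcal * Angstrom / (mol * e^2)
GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal / (mol * K)

#' Forcefield parameters
#'
#' @param dielectric Relative permittivity (default 1: gas phase).
#' @param lj Include the Lennard-Jones term (default TRUE).
#' @param coulomb Include the Coulomb term (default TRUE).
#' @return List of class `forcefield_params` with the pinned per-element
#'   Lennard-Jones table and charge templates attached.
#' @export
forcefield_params <- function(dielectric = 1, lj = TRUE, coulomb = TRUE) {
  if (dielectric <= 0) stop("dielectric must be positive")
  ljt <- .lj_table()
  structure(list(dielectric = dielectric, use_lj = lj, use_coulomb = coulomb,
                 rstar = ljt$rstar, eps = ljt$eps),
            class = "forcefield_params")
}

#' Template partial charges for the atoms of a structure
#'
#' Backbone N/CA/C/O carry a fixed neutral set; side-chain charges come from
#' the shipped template table; atoms without a template entry are neutral.
#' Per-residue sums equal the residue's formal charge.
#'
#' @param atom Atom data.frame of an `epistructure`.
#' @return Numeric charge vector (elementary charges), one per atom row.
#' @export
template_charges <- function(atom) {
  q <- rep(0, nrow(atom))
  m <- match(atom$elety, names(.backbone_charges))
  q[!is.na(m)] <- .backbone_charges[m[!is.na(m)]]
  sc <- .sidechain_charge_table()
  m2 <- match(paste(atom$resid, atom$elety), paste(sc$resid, sc$atom))
  q[!is.na(m2)] <- sc$charge[m2[!is.na(m2)]]
  q
}

#' Nonbonded energy of one atom pair
#'
#' `LJ(r) + k q_i q_j / (dielectric * r)` with
#' `LJ(r) = eps_ij ((r*_ij/r)^12 - 2 (r*_ij/r)^6)`, `r*_ij = r*_i + r*_j`
#' (each stored as Rmin/2) and `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @param atom_i,atom_j Lists or one-row data.frames with `element`, `x`,
#'   `y`, `z` and `charge`.
#' @param params A [forcefield_params()] object.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(atom_i, atom_j, params = forcefield_params()) {
  r <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
              (atom_i$z - atom_j$z)^2)
  if (r == 0) stop("coincident atoms: r = 0")
  e <- 0
  if (params$use_lj) {
    rs <- params$rstar[atom_i$element] + params$rstar[atom_j$element]
    ep <- sqrt(params$eps[atom_i$element] * params$eps[atom_j$element])
    if (anyNA(c(rs, ep)))
      stop("no Lennard-Jones parameters for element pair ",
           atom_i$element, "/", atom_j$element)
    s6 <- (rs / r)^6
    e <- e + ep * (s6^2 - 2 * s6)
  }
  if (params$use_coulomb)
    e <- e + COULOMB_K * atom_i$charge * atom_j$charge / (params$dielectric * r)
  unname(e)
}

# vectorized total cross energy between two atom tables (with charges);
# self = TRUE computes the internal pair energy of one table (diagonal and
# double counting removed)
.cross_energy <- function(a, b, params, self = FALSE) {
  ax <- as.matrix(a[, c("x", "y", "z")])
  bx <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rep(1, nrow(bx))) +
    outer(rep(1, nrow(ax)), rowSums(bx^2)) - 2 * ax %*% t(bx)
  r <- sqrt(pmax(d2, 0))
  if (self) diag(r) <- Inf
  if (any(r < 1e-9)) stop("coincident atoms across fragments: r = 0")
  e <- 0
  if (params$use_lj) {
    rs <- outer(params$rstar[a$element], params$rstar[b$element], "+")
    ep <- sqrt(outer(params$eps[a$element], params$eps[b$element]))
    if (anyNA(rs) || anyNA(ep))
      stop("missing Lennard-Jones parameters for some element")
    s6 <- (rs / r)^6
    e <- e + sum(ep * (s6^2 - 2 * s6))
  }
  if (params$use_coulomb)
    e <- e + sum(COULOMB_K * outer(a$charge, b$charge) / (params$dielectric * r))
  e
}

# total pairwise energy within one atom table
.self_energy <- function(a, params) {
  if (nrow(a) < 2) return(0)
  .cross_energy(a, a, params, self = TRUE) / 2
}

.atoms_for_keys <- function(structure, keys, heavy_only = TRUE) {
  a <- structure$atom
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  k <- residue_key(a)
  missing <- setdiff(keys, unique(k))
  if (length(missing))
    stop("residue key(s) not present in structure: ",
         paste(missing, collapse = ", "))
  a <- a[k %in% keys, , drop = FALSE]
  a$charge <- template_charges(a)
  a
}

#' Interaction energy between two residue fragments
#'
#' Computes IE = E_AB - E_A - E_B. With a pairwise potential this equals the
#' sum of cross-fragment atom-pair energies; both routes are evaluated and
#' asserted to agree, which serves as a structural self-check.
#'
#' @param structure An `epistructure`.
#' @param frag_a,frag_b Disjoint character vectors of residue keys
#'   ("chain:number").
#' @param params A [forcefield_params()] object.
#' @return List of class `energy_record`: `fragment_a`, `fragment_b`, `ie`
#'   (kcal/mol), plus the two routes `ie_cross` and `ie_totals`.
#' @export
fragment_interaction_energy <- function(structure, frag_a, frag_b,
                                        params = forcefield_params()) {
  if (length(intersect(frag_a, frag_b)))
    stop("fragments must be disjoint")
  if (!length(frag_a) || !length(frag_b)) stop("fragments must be non-empty")
  a <- .atoms_for_keys(structure, frag_a)
  b <- .atoms_for_keys(structure, frag_b)
  ie_cross <- .cross_energy(a, b, params)
  e_a <- .self_energy(a, params)
  e_b <- .self_energy(b, params)
  e_ab <- .self_energy(rbind(a, b), params)
  ie_tot <- e_ab - e_a - e_b
  if (abs(ie_tot - ie_cross) > 1e-6 * max(1, abs(ie_cross)))
    stop("internal inconsistency: the two interaction-energy routes disagree")
  structure(list(fragment_a = frag_a, fragment_b = frag_b,
                 ie = ie_cross, ie_cross = ie_cross, ie_totals = ie_tot),
            class = "energy_record")
}

#' @export
print.energy_record <- function(x, ...) {
  cat(sprintf("IE(%s | %s) = %.4f kcal/mol\n",
              paste(x$fragment_a, collapse = ","),
              paste(x$fragment_b, collapse = ","), x$ie))
  invisible(x)
}

#' Residues of two parts within an interface cutoff
#'
#' @param structure An `epistructure`.
#' @param part_a,part_b Disjoint chain-id vectors.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (inclusive,
#'   default 5.0).
#' @return List with character vectors `a` and `b` of residue keys having
#'   at least one heavy atom within the cutoff of the other part.
#' @export
interface_selection <- function(structure, part_a, part_b, cutoff = 5.0) {
  if (length(intersect(part_a, part_b))) stop("parts must be disjoint")
  a <- .atoms_in_chains(structure, part_a)
  b <- .atoms_in_chains(structure, part_b)
  pr <- .cross_pairs(a, b, cutoff, inclusive = TRUE)
  list(a = unique(residue_key(a)[sort(pr$i)]),
       b = unique(residue_key(b)[sort(pr$j)]))
}

.aa_class <- function(resid) {
  cls <- .residue_class_table()
  aa1 <- bio3d::aa321(resid)
  out <- cls[aa1]
  if (anyNA(out))
    stop("no chemical class for residue(s): ",
         paste(unique(resid[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Interface contact counts by residue-class pair
#'
#' One contact per cross-part residue pair with any heavy-atom distance at
#' or below the cutoff, classified by the chemical classes of the two
#' residues (charged: D,E,K,R,H; polar: N,Q,S,T,Y,W,C; apolar: the rest).
#'
#' @param structure An `epistructure`.
#' @param part_a,part_b Disjoint chain-id vectors.
#' @param cutoff Heavy-atom distance cutoff (default 5.5 A, inclusive).
#' @return Named integer vector with elements `charged_charged`,
#'   `charged_polar`, `charged_apolar`, `polar_polar`, `polar_apolar`,
#'   `apolar_apolar`.
#' @export
interface_contacts <- function(structure, part_a, part_b, cutoff = 5.5) {
  if (length(intersect(part_a, part_b))) stop("parts must be disjoint")
  a <- .atoms_in_chains(structure, part_a)
  b <- .atoms_in_chains(structure, part_b)
  pr <- .cross_pairs(a, b, cutoff, inclusive = TRUE)
  counts <- c(charged_charged = 0L, charged_polar = 0L, charged_apolar = 0L,
              polar_polar = 0L, polar_apolar = 0L, apolar_apolar = 0L)
  if (nrow(pr) == 0) return(counts)
  ka <- residue_key(a); kb <- residue_key(b)
  pairs <- data.frame(ra = pr$i, rb = pr$j)[
    !duplicated(paste(ka[pr$i], kb[pr$j])), , drop = FALSE]
  ca <- .aa_class(a$resid[pairs$ra])
  cb <- .aa_class(b$resid[pairs$rb])
  lab <- ifelse(ca <= cb, paste(ca, cb, sep = "_"), paste(cb, ca, sep = "_"))
  # alphabetical pairing gives apolar_charged / apolar_polar; normalize
  lab[lab == "apolar_charged"] <- "charged_apolar"
  lab[lab == "apolar_polar"] <- "polar_apolar"
  lab[lab == "charged_polar"] <- "charged_polar"
  tab <- table(lab)
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  counts
}

#' Non-interacting surface composition of a complex
#'
#' Solvent-exposed residues of the whole complex (relative SASA at or above
#' `rel_cutoff`) that are not part of the interface, tallied by chemical
#' class and expressed as percentages of all such residues.
#'
#' @param structure An `epistructure` (restricted to the complex chains).
#' @param interface_keys Character vector of interface residue keys.
#' @param sasa A precomputed [residue_sasa()] table for the same structure,
#'   or NULL to compute one.
#' @param rel_cutoff Relative-SASA threshold in percent (default 5).
#' @param params [sasa_params()] used when `sasa` is NULL.
#' @return Named numeric vector `charged`, `polar`, `apolar` (percentages
#'   summing to 100).
#' @export
nis_percentages <- function(structure, interface_keys, sasa = NULL,
                            rel_cutoff = 5, params = sasa_params()) {
  if (is.null(sasa)) sasa <- residue_sasa(structure, params)
  nis <- sasa[sasa$sasa_rel >= rel_cutoff & !(sasa$key %in% interface_keys), ,
              drop = FALSE]
  out <- c(charged = 0, polar = 0, apolar = 0)
  if (nrow(nis) == 0) return(out)
  cls <- .aa_class(nis$resid)
  tab <- table(factor(cls, levels = c("charged", "polar", "apolar")))
  pct <- 100 * as.numeric(tab) / nrow(nis)
  names(pct) <- c("charged", "polar", "apolar")
  pct
}

#' Linear contact-based affinity model
#'
#' @param ic_counts Named vector as returned by [interface_contacts()].
#' @param nis Named vector as returned by [nis_percentages()] (percent).
#' @return Predicted binding free energy dG in kcal/mol.
#' @export
affinity_model_dg <- function(ic_counts, nis = c(charged = 0, polar = 0, apolar = 0)) {
  cf <- .affinity_coefficients()
  unname(cf["intercept"] +
           cf["ic_charged_charged"] * ic_counts["charged_charged"] +
           cf["ic_charged_apolar"] * ic_counts["charged_apolar"] +
           cf["ic_polar_polar"] * ic_counts["polar_polar"] +
           cf["ic_polar_apolar"] * ic_counts["polar_apolar"] +
           cf["nis_apolar"] * nis["apolar"] +
           cf["nis_charged"] * nis["charged"])
}

#' Predict interface binding affinity from contacts
#'
#' Counts interface contacts at 5.5 A, computes the non-interacting-surface
#' composition of the complex, applies the frozen linear model, and converts
#' dG to a dissociation constant at the given temperature.
#'
#' @param structure An `epistructure` containing both parts (other chains,
#'   if any, are ignored).
#' @param part_a,part_b Disjoint chain-id vectors.
#' @param temperature Kelvin (default 298.15).
#' @param sasa_params [sasa_params()] for the NIS computation.
#' @return List of class `affinity_estimate`: `ic_counts`, `nis`, `dg`
#'   (kcal/mol), `temperature`, `kd` (mol/L).
#' @export
predict_affinity <- function(structure, part_a, part_b, temperature = 298.15,
                             sasa_params = epitomap::sasa_params()) {
  complex <- subset_chains(structure, c(part_a, part_b))
  ic <- interface_contacts(complex, part_a, part_b)
  sel <- interface_selection(complex, part_a, part_b, cutoff = 5.5)
  if (sum(ic) == 0) {
    warning("empty interface: returning an intercept-only estimate")
    nis <- c(charged = 0, polar = 0, apolar = 0)
  } else {
    sasa <- residue_sasa(complex, sasa_params)
    nis <- nis_percentages(complex, c(sel$a, sel$b), sasa = sasa)
  }
  dg <- affinity_model_dg(ic, nis)
  structure(list(ic_counts = ic, nis = nis, dg = dg,
                 temperature = temperature,
                 kd = dg_to_kd(dg, temperature)),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("predicted dG = %.2f kcal/mol, Kd = %.2e M at %.2f K\n",
              x$dg, x$kd, x$temperature))
  cat("contacts:", paste(names(x$ic_counts), x$ic_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Convert binding free energy to a dissociation constant
#'
#' `Kd = exp(dG / (R T))` with R = 1.9872e-3 kcal/(mol K).
#'
#' @param dg Binding free energy in kcal/mol.
#' @param temperature Kelvin.
#' @return Dissociation constant in mol/L.
#' @export
dg_to_kd <- function(dg, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  exp(dg / (GAS_CONSTANT_KCAL * temperature))
}

#' Convert a dissociation constant to binding free energy
#'
#' @param kd Dissociation constant in mol/L (> 0).
#' @param temperature Kelvin.
#' @return dG in kcal/mol.
#' @export
kd_to_dg <- function(kd, temperature = 298.15) {
  if (any(kd <= 0)) stop("kd must be positive")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Alanine substitution by side-chain truncation
#'
#' Replaces a residue by alanine by deleting side-chain atoms beyond the
#' beta carbon, without repacking the environment. Glycine (no CB) simply
#' gets renamed.
#'
#' @param structure An `epistructure`.
#' @param chain Chain id.
#' @param resno Residue number.
#' @param insert Insertion code (default "").
#' @return A new `epistructure` with the mutation applied.
#' @export
mutate_to_alanine <- function(structure, chain, resno, insert = "") {
  a <- structure$atom
  hit <- a$chain == chain & a$resno == resno & a$insert == insert
  if (!any(hit)) stop("residue not found: ", chain, ":", resno)
  keep_names <- c("N", "CA", "C", "O", "OXT", "CB")
  drop <- hit & !(a$elety %in% keep_names)
  a <- a[!drop, , drop = FALSE]
  a$resid[a$chain == chain & a$resno == resno & a$insert == insert] <- "ALA"
  structure(list(atom = a, title = structure$title, source = structure$source),
            class = "epistructure")
}
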