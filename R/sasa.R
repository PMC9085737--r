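# Solvent-accessible surface area by sphere-point quadrature and the
# buried/intermediate/exposed classification.
#
# Each heavy atom carries a deterministic quasi-uniform (Fibonacci spiral)
# point set on its solvent-expanded sphere (vdW radius + probe). An atom's
# area is the fraction of its points not inside any neighbor's expanded
# sphere times the sphere area. Hydrogens are excluded by default (typical
# X-ray structures carry none).

#' SASA parameters
#'
#' @param n_points Quadrature points per atom (default 240, minimum 60).
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, water).
#' @param radius_set Name of the van der Waals radius table (only the
#'   shipped Bondi-type set is available).
#' @return List of class `sasa_params`.
#' @export
sasa_params <- function(n_points = 240, probe_radius = 1.4,
                        radius_set = "bondi") {
  if (n_points < 60) stop("n_points must be at least 60")
  if (probe_radius <= 0) stop("probe_radius must be positive")
  structure(list(n_points = as.integer(n_points), probe_radius = probe_radius,
                 radius_set = radius_set),
            class = "sasa_params")
}

#' Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-atom solvent-accessible surface area
#'
#' @param structure An `epistructure`.
#' @param params A [sasa_params()] object.
#' @param chains Optional chain subset on which to run the calculation
#'   (atoms outside it are ignored entirely, i.e. do not occlude).
#' @param include_hydrogens Include hydrogens in the calculation (default
#'   FALSE: hydrogens get `NA` area and do not occlude).
#' @return Numeric vector of areas (Angstrom^2), one per atom row of the
#'   (possibly chain-restricted) structure; `NA` for excluded hydrogens.
#'   The atom table used is attached as attribute `"atom"`.
#' @export
atom_sasa <- function(structure, params = sasa_params(), chains = NULL,
                      include_hydrogens = FALSE) {
  stopifnot(inherits(structure, "epistructure"))
  a <- structure$atom
  if (!is.null(chains)) a <- .atoms_in_chains(structure, chains, heavy_only = FALSE)
  use <- if (include_hydrogens) rep(TRUE, nrow(a)) else a$is_heavy
  au <- a[use, , drop = FALSE]
  if (nrow(au) == 0) stop("no atoms selected for SASA")
  radii <- vdw_radii()
  unknown <- setdiff(unique(au$element), names(radii))
  if (length(unknown))
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  R <- radii[au$element] + params$probe_radius
  xyz <- as.matrix(au[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- fibonacci_sphere(params$n_points)
  areas <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + maxR)^2 & d2 > 1e-12)
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    P <- pts * R[i]
    P[, 1] <- P[, 1] + xyz[i, 1]
    P[, 2] <- P[, 2] + xyz[i, 2]
    P[, 3] <- P[, 3] + xyz[i, 3]
    free <- rep(TRUE, params$n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
        (P[, 3] - xyz[j, 3])^2
      free <- free & dj >= R[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * R[i]^2
  }
  out <- rep(NA_real_, nrow(a))
  out[use] <- areas
  attr(out, "atom") <- a
  out
}

#' Per-residue absolute and relative SASA with burial classes
#'
#' Sums atom areas per residue, normalizes by the residue-type reference
#' maximum, and classifies burial.
#'
#' @param structure An `epistructure`.
#' @param params A [sasa_params()] object.
#' @param chains Optional chain subset (see [atom_sasa()]).
#' @param atom_areas Optional precomputed result of [atom_sasa()] for this
#'   structure/chain selection.
#' @param reference Named numeric vector of per-residue reference maxima;
#'   defaults to the shipped theoretical table.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `resid`, `key`, `sasa_abs` (Angstrom^2), `sasa_rel` (%), `burial`.
#' @export
residue_sasa <- function(structure, params = sasa_params(), chains = NULL,
                         atom_areas = NULL,
                         reference = max_sasa_reference()) {
  if (is.null(atom_areas)) atom_areas <- atom_sasa(structure, params, chains)
  a <- attr(atom_areas, "atom")
  key <- residue_key(a)
  first <- !duplicated(key)
  abs_area <- tapply(ifelse(is.na(atom_areas), 0, atom_areas), key, sum)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   insert = a$insert[first], resid = a$resid[first],
                   key = key[first], stringsAsFactors = FALSE)
  rt$sasa_abs <- as.numeric(abs_area[rt$key])
  missing <- setdiff(unique(rt$resid), names(reference))
  if (length(missing))
    stop("residue type(s) absent from the reference table: ",
         paste(missing, collapse = ", "))
  rt$sasa_rel <- 100 * rt$sasa_abs / reference[rt$resid]
  rt$burial <- classify_burial(rt$sasa_rel)
  rownames(rt) <- NULL
  rt
}

#' Classify relative SASA into burial classes
#'
#' Residues with relative SASA below 10% are `buried`, above 25% `exposed`;
#' the boundary values themselves fall in the `intermediate` class.
#'
#' @param sasa_rel Numeric vector of relative SASA percentages.
#' @return Character vector: "buried", "intermediate" or "exposed".
#' @export
classify_burial <- function(sasa_rel) {
  if (any(sasa_rel < 0)) stop("relative SASA cannot be negative")
  ifelse(sasa_rel < 10, "buried",
         ifelse(sasa_rel > 25, "exposed", "intermediate"))
}
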