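# Frozen parameter tables shipped with the package (inst/extdata/params).
# All are small plain-text CSVs so that every numeric constant used by the
# analyses is inspectable and versioned with the code.

.param_env <- new.env(parent = emptyenv())

.read_param_csv <- function(name) {
  key <- paste0("csv_", name)
  if (!is.null(.param_env[[key]])) return(.param_env[[key]])
  path <- system.file("extdata", "params", paste0(name, ".csv"),
                      package = "epitomap", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .param_env[[key]] <- x
  x
}

#' Van der Waals radii by element
#'
#' Bondi-type radii (Angstrom) for the elements found in protein heavy atoms,
#' used by the solvent-accessibility quadrature.
#'
#' @return Named numeric vector of radii, names are element symbols.
#' @export
vdw_radii <- function() {
  x <- .read_param_csv("vdw_radii")
  stats::setNames(x$radius, x$element)
}

#' Reference maximal per-residue solvent accessibility
#'
#' Theoretical maximum solvent-accessible surface areas (Angstrom^2) per
#' residue type, used to normalize absolute residue SASA into a relative
#' percentage.
#'
#' @return Named numeric vector, names are 3-letter residue codes.
#' @export
max_sasa_reference <- function() {
  x <- .read_param_csv("max_sasa")
  stats::setNames(x$max_sasa, x$resid)
}

# Side-chain hydrogen-bond donor/acceptor typing; backbone rules (N donor
# except proline, O/OXT acceptor) are added in code.
.hbond_table <- function() .read_param_csv("hbond_types")

# Minimal per-element Lennard-Jones parameters (rstar = Rmin/2 in Angstrom,
# eps in kcal/mol) with Lorentz-Berthelot combination downstream.
.lj_table <- function() {
  x <- .read_param_csv("ff_lj")
  list(rstar = stats::setNames(x$rstar, x$element),
       eps = stats::setNames(x$eps, x$element))
}

# Heavy-atom partial charges: fixed backbone set plus side-chain entries from
# the CSV. Per-residue sums equal the residue formal charge by construction.
.backbone_charges <- c(N = -0.40, CA = 0.35, C = 0.55, O = -0.50)

.residue_formal_charge <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1)

.sidechain_charge_table <- function() .read_param_csv("ff_charges_sidechain")

# Contact-based affinity model: frozen linear coefficients over interface
# contact counts (5.5 A) and non-interacting-surface percentages.
.affinity_coefficients <- function() {
  x <- .read_param_csv("affinity_model")
  stats::setNames(x$coefficient, x$term)
}

# Chemical class (charged/polar/apolar) per one-letter amino-acid code, used
# both for contact classification and for the non-interacting surface.
.residue_class_table <- function() {
  x <- .read_param_csv("residue_classes")
  stats::setNames(x$class, x$aa)
}
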