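# PDB-format structure input/output and the flat atom-table model used by
# all downstream analyses. Reading is backed by bio3d::read.pdb; the module
# then applies the package's own conventions: protein atoms only, one
# conformer per atom, selenomethionine-type residues mapped to their parent,
# hydrogens kept but flagged.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Common non-standard residues mapped to their parent so that sequence
# extraction and template lookups stay usable.
NONSTANDARD_AA_MAP <- c(MSE = "MET", SEC = "CYS", HYP = "PRO", SEP = "SER",
                        TPO = "THR", PTR = "TYR", CSO = "CYS", MLY = "LYS",
                        KCX = "LYS", PCA = "GLU")

#' Residue keys ("chain:number[insert]") for an atom or residue table
#'
#' @param x data.frame with columns `chain`, `resno` and optionally `insert`.
#' @return Character vector of keys, one per row.
#' @export
residue_key <- function(x) {
  ins <- if ("insert" %in% names(x)) x$insert else ""
  ins[is.na(ins)] <- ""
  paste0(x$chain, ":", x$resno, ins)
}

.element_from_name <- function(elety) {
  # fallback when the element column is absent: strip digits, take the
  # leading alphabetic part; two-letter protein elements are rare (SE)
  nm <- gsub("[^A-Za-z]", "", elety)
  ifelse(toupper(nm) %in% c("SE"), "SE", toupper(substr(nm, 1, 1)))
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records found in PDB input")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: shorter than coordinate fields", i))
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

.resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  # keep, per (chain, resno, insert, atom name), the conformer with the
  # highest occupancy; ties broken by altloc label order
  ins <- atom$insert
  ins[is.na(ins)] <- ""
  grp <- paste(atom$chain, atom$resno, ins, atom$elety, sep = "\r")
  occ <- atom$o
  occ[is.na(occ)] <- 1
  ord <- order(grp, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(grp[ord]), , drop = FALSE]
}

.structure_from_bio3d <- function(pdb, title = "", source = "") {
  atom <- pdb$atom
  resid <- atom$resid
  mapped <- NONSTANDARD_AA_MAP[resid]
  resid[!is.na(mapped)] <- mapped[!is.na(mapped)]
  keep <- resid %in% STANDARD_AA
  atom <- atom[keep, , drop = FALSE]
  if (nrow(atom) == 0) stop("structure contains no protein atoms")
  atom$resid <- resid[keep]
  atom <- .resolve_altloc(atom)
  elem <- toupper(atom$elesy)
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_name(atom$elety[bad])
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  ins <- atom$insert
  ins[is.na(ins)] <- ""
  out <- data.frame(
    eleno = atom$eleno, elety = atom$elety, resid = atom$resid,
    chain = chain, resno = atom$resno, insert = ins,
    x = atom$x, y = atom$y, z = atom$z,
    o = ifelse(is.na(atom$o), 1, atom$o), b = ifelse(is.na(atom$b), 0, atom$b),
    element = elem, stringsAsFactors = FALSE)
  out$is_heavy <- out$element != "H"
  rownames(out) <- NULL
  structure(list(atom = out, title = title, source = source),
            class = "epistructure")
}

#' Parse a PDB-format character stream into a structure
#'
#' Retains ATOM records of standard amino acids (common modified residues
#' such as MSE are mapped to their parent type); waters and other non-protein
#' HETATM records are dropped. Alternate locations are resolved to a single
#' conformer (highest occupancy, ties by altloc label). Hydrogens, if
#' present, are kept but flagged (`is_heavy = FALSE`). Only the first MODEL
#' of a multi-model file is read.
#'
#' @param text Character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @param title Optional free-text title stored on the structure.
#' @return An object of class `epistructure`: a list with an `atom`
#'   data.frame (`elety`, `resid`, `chain`, `resno`, `insert`, `x`, `y`,
#'   `z`, `o`, `b`, `element`, `is_heavy`), a `title` and a `source` string.
#' @export
parse_pdb <- function(text, title = "") {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  .validate_pdb_lines(text)
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(text, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, rm.alt = FALSE, multi = FALSE,
                                          verbose = FALSE))
  .structure_from_bio3d(pdb, title = title, source = "<text>")
}

#' Read a structure from a PDB file
#'
#' @param file Path to a PDB-format file.
#' @inherit parse_pdb return
#' @export
read_structure <- function(file) {
  if (!file.exists(file)) stop("structure file not found: ", file)
  .validate_pdb_lines(readLines(file, warn = FALSE))
  pdb <- suppressWarnings(bio3d::read.pdb(file, rm.alt = FALSE, multi = FALSE,
                                          verbose = FALSE))
  .structure_from_bio3d(pdb, title = basename(file), source = file)
}

#' Write a structure as fixed-column PDB ATOM records
#'
#' @param structure An `epistructure`.
#' @param file Optional path; when `NULL` the lines are returned only.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "epistructure"))
  a <- structure$atom
  if (nrow(a) == 0) stop("cannot write an empty structure")
  if (any(a$resno > 9999 | a$resno < -999))
    stop("residue number outside the 4-digit PDB field")
  name <- ifelse(nchar(a$elety) < 4 & nchar(a$element) == 1,
                 sprintf(" %-3s", a$elety), sprintf("%-4s", a$elety))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, a$resid, a$chain, a$resno,
    ifelse(a$insert == "", " ", a$insert),
    a$x, a$y, a$z, a$o, a$b, a$element)
  # TER between chains, END at the end
  out <- character(0)
  for (ch in unique(a$chain)) {
    out <- c(out, lines[a$chain == ch], "TER")
  }
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' @export
print.epistructure <- function(x, ...) {
  a <- x$atom
  res <- unique(residue_key(a))
  cat("epistructure:", if (nzchar(x$title)) x$title else "<untitled>", "\n")
  cat(sprintf("  %d atoms (%d heavy), %d residues, chains: %s\n",
              nrow(a), sum(a$is_heavy), length(res),
              paste(unique(a$chain), collapse = ", ")))
  invisible(x)
}

#' Table of residues in a structure
#'
#' @param structure An `epistructure`.
#' @param chains Optional chain subset.
#' @return data.frame with one row per residue (`chain`, `resno`, `insert`,
#'   `resid`, `key`) in file order.
#' @export
residue_table <- function(structure, chains = NULL) {
  a <- structure$atom
  if (!is.null(chains)) {
    missing <- setdiff(chains, unique(a$chain))
    if (length(missing)) stop("unknown chain id(s): ", paste(missing, collapse = ", "))
    a <- a[a$chain %in% chains, , drop = FALSE]
  }
  key <- residue_key(a)
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

#' One-letter amino-acid sequence of a chain
#'
#' @param structure An `epistructure`.
#' @param chain Chain identifier.
#' @return Single string; residues absent from the model are simply absent
#'   (no gap characters are inserted for numbering discontinuities).
#' @export
structure_sequence <- function(structure, chain) {
  rt <- residue_table(structure, chains = chain)
  paste(bio3d::aa321(rt$resid), collapse = "")
}

#' Coordinates of (a subset of) a structure as an n x 3 matrix
#'
#' @param structure An `epistructure`.
#' @param chains Optional chain subset.
#' @param heavy_only Drop hydrogens (default TRUE).
#' @param elety Optional atom-name subset (e.g. "CA").
#' @return Numeric matrix with columns x, y, z.
#' @export
structure_coords <- function(structure, chains = NULL, heavy_only = TRUE,
                             elety = NULL) {
  a <- structure$atom
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  if (!is.null(elety)) a <- a[a$elety %in% elety, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# internal: subset the atom table by chains (with validation) and heaviness
.atoms_in_chains <- function(structure, chains, heavy_only = TRUE) {
  a <- structure$atom
  missing <- setdiff(chains, unique(a$chain))
  if (length(missing)) stop("unknown chain id(s): ", paste(missing, collapse = ", "))
  a <- a[a$chain %in% chains, , drop = FALSE]
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  a
}

#' Restrict a structure to a chain subset
#'
#' @param structure An `epistructure`.
#' @param chains Chains to keep.
#' @return A new `epistructure`.
#' @export
subset_chains <- function(structure, chains) {
  a <- .atoms_in_chains(structure, chains, heavy_only = FALSE)
  structure(list(atom = a, title = structure$title, source = structure$source),
            class = "epistructure")
}
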