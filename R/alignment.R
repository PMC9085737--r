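# Overlap (end-gap-free) pairwise alignment of a short mimotope peptide
# against an antigen sequence, with affine gaps and BLOSUM-style scoring,
# plus the identity/similarity metrics and region mapping used to place the
# peptide on the antigen.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a substitution matrix by name
#'
#' @param name Matrix name available in Biostrings (e.g. "BLOSUM62").
#' @return Integer scoring matrix with amino-acid row/column names.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  e[[name]]
}

#' Alignment parameters
#'
#' Defaults correspond to a BLOSUM62 matrix with affine gap cost
#' `gap_open + k * gap_extend` for a k-residue gap, in end-gap-free
#' ("allow ends to slide") overlap mode.
#'
#' @param matrix Substitution matrix name.
#' @param gap_open Gap initiation penalty (positive number, default 8).
#' @param gap_extend Per-residue gap extension penalty (default 2).
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 8, gap_extend = 2) {
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("require gap_open >= gap_extend >= 0")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 mode = "overlap"),
            class = "alignment_params")
}

.check_aa <- function(s, what) {
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), AA20)
  if (length(bad))
    stop(sprintf("%s contains non-amino-acid character(s): %s",
                 what, paste(bad, collapse = ", ")))
  ch
}

#' Overlap-align a query peptide to a target sequence
#'
#' Dynamic-programming optimum in overlap mode: the query is fully consumed
#' (its residues are aligned or sit in internal gaps), while unaligned
#' leading/trailing stretches of the target are free. Internal gaps cost
#' `gap_open + k * gap_extend`. Among co-optimal alignments the longest
#' aligned span is reported (maximal antigen coverage), with gaps placed
#' leftmost; the traceback is deterministic.
#'
#' @param query Peptide sequence (uppercase one-letter codes, length >= 3).
#' @param target Protein sequence to align against.
#' @param params An [alignment_params()] object.
#' @return Object of class `epialignment`: list with `columns` (data.frame
#'   of `query_char`, `target_char`, `target_index`; gaps are "-"),
#'   `score`, `target_start`, `target_end` (1-based indices into `target`),
#'   `query`, `target`, `params`.
#' @export
align_overlap <- function(query, target, params = alignment_params()) {
  q <- .check_aa(query, "query")
  t <- .check_aa(target, "target")
  if (length(q) < 3) stop("query must be at least 3 residues long")
  S <- substitution_matrix(params$matrix)
  go <- params$gap_open; ge <- params$gap_extend
  m <- length(q); n <- length(t)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)   # column ends in a residue pair
  GX <- matrix(NEG, m + 1, n + 1)  # gap in query (consumes target)
  GY <- matrix(NEG, m + 1, n + 1)  # gap in target (consumes query)
  M[1, ] <- 0                      # leading target residues are free
  for (i in 2:(m + 1)) GY[i, 1] <- -(go + (i - 1) * ge)
  for (i in 2:(m + 1)) {
    si <- S[q[i - 1], t]
    for (j in 2:(n + 1)) {
      M[i, j] <- si[j - 1] + max(M[i - 1, j - 1], GX[i - 1, j - 1], GY[i - 1, j - 1])
      GX[i, j] <- max(M[i, j - 1] - go - ge, GX[i, j - 1] - ge)
      GY[i, j] <- max(M[i - 1, j] - go - ge, GY[i - 1, j] - ge)
    }
  }
  fin <- pmax(M[m + 1, ], GY[m + 1, ])
  best <- max(fin)
  jend <- max(which(fin == best)) - 1  # rightmost end => longest span
  st <- if (jend == 0 || M[m + 1, jend + 1] >= GY[m + 1, jend + 1]) "M" else "GY"
  if (jend == 0) st <- "GY"
  i <- m; j <- jend
  qa <- character(0); ta <- character(0); ti <- integer(0)
  while (i > 0) {
    if (st == "M") {
      qa <- c(q[i], qa); ta <- c(t[j], ta); ti <- c(j, ti)
      tgt <- M[i + 1, j + 1] - S[q[i], t[j]]
      prev <- c(M = M[i, j], GX = GX[i, j], GY = GY[i, j])
      # preferring the diagonal on ties places gaps leftmost
      st <- names(prev)[which(abs(prev - tgt) < 1e-9)][1]
      i <- i - 1; j <- j - 1
    } else if (st == "GX") {
      qa <- c("-", qa); ta <- c(t[j], ta); ti <- c(j, ti)
      st <- if (abs(GX[i + 1, j + 1] - (M[i + 1, j] - go - ge)) < 1e-9) "M" else "GX"
      j <- j - 1
    } else {
      qa <- c(q[i], qa); ta <- c("-", ta); ti <- c(NA_integer_, ti)
      st <- if (j > 0 && abs(GY[i + 1, j + 1] - (M[i, j + 1] - go - ge)) < 1e-9)
        "M" else "GY"
      i <- i - 1
    }
  }
  cols <- data.frame(query_char = qa, target_char = ta, target_index = ti,
                     stringsAsFactors = FALSE)
  tidx <- cols$target_index[!is.na(cols$target_index)]
  structure(list(columns = cols, score = best,
                 target_start = if (length(tidx)) min(tidx) else NA_integer_,
                 target_end = if (length(tidx)) max(tidx) else NA_integer_,
                 query = query, target = target, params = params),
            class = "epialignment")
}

#' @export
print.epialignment <- function(x, ...) {
  cat("overlap alignment, score", x$score, "\n")
  cat("  query : ", paste(x$columns$query_char, collapse = ""), "\n")
  cat("  target: ", paste(x$columns$target_char, collapse = ""),
      sprintf("  (target %d-%d)", x$target_start, x$target_end), "\n")
  m <- alignment_metrics(x)
  cat(sprintf("  identity %.2f%%, similarity %.2f%% over %d columns\n",
              m$identity_pct, m$similarity_pct, m$n_columns))
  invisible(x)
}

#' Identity and similarity over the aligned span
#'
#' Both percentages use all columns of the aligned span (gap columns
#' included) as denominator. Identity counts exact matches; similarity adds
#' residue pairs with a strictly positive substitution-matrix score.
#'
#' @param result An `epialignment`.
#' @param matrix Substitution matrix (defaults to the one the alignment used).
#' @return List: `identity_pct`, `similarity_pct` (rounded to 2 decimals),
#'   `n_columns`, `n_identical`, `n_similar`.
#' @export
alignment_metrics <- function(result, matrix = NULL) {
  stopifnot(inherits(result, "epialignment"))
  cols <- result$columns
  if (nrow(cols) == 0) stop("empty alignment")
  if (is.null(matrix)) matrix <- substitution_matrix(result$params$matrix)
  qc <- cols$query_char; tc <- cols$target_char
  aligned <- qc != "-" & tc != "-"
  ident <- aligned & qc == tc
  pos <- aligned & !ident &
    matrix[cbind(ifelse(aligned, qc, "A"), ifelse(aligned, tc, "A"))] > 0
  n <- nrow(cols)
  list(identity_pct = round(100 * sum(ident) / n, 2),
       similarity_pct = round(100 * (sum(ident) + sum(pos)) / n, 2),
       n_columns = n, n_identical = sum(ident),
       n_similar = sum(ident) + sum(pos))
}

#' Map the aligned span onto antigen author numbering
#'
#' @param result An `epialignment`.
#' @param target_numbering_offset Author residue number of the first residue
#'   of the target string (e.g. 25 when the target is numbered 25..42).
#' @return List: `start`, `end` (inclusive residue-number range) and
#'   `gap_positions` (antigen numbering of columns where the query has a
#'   gap).
#' @export
map_region <- function(result, target_numbering_offset = 1) {
  stopifnot(inherits(result, "epialignment"))
  cols <- result$columns
  if (nrow(cols) == 0) stop("empty alignment")
  off <- target_numbering_offset - 1
  gaps <- cols$target_index[cols$query_char == "-"]
  list(start = result$target_start + off,
       end = result$target_end + off,
       gap_positions = gaps[!is.na(gaps)] + off)
}

#' Read sequences from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  stats::setNames(toupper(as.character(x)), names(x))
}
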