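## Needle-style affine-gap global protein alignment.

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 integer substitution matrix shipped with
#' Biostrings (the default matrix of classic global protein aligners),
#' covering the 20 standard residues plus B, J, Z, X and `*`.
#'
#' @return Symmetric integer matrix with residue dimnames.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Affine-gap global pairwise alignment
#'
#' Aligns two protein sequences globally under an affine gap model in
#' which a gap of length L costs `gap_open + (L - 1) * gap_extend`.  By
#' default end gaps are not penalised, matching the global mode of the
#' classic needle aligner whose conventions define the similarity
#' statistic: `pct_identity` is the percentage of alignment columns with
#' identical residues and `pct_similarity` the percentage of columns
#' whose substitution score is positive, both over the full alignment
#' length (gap columns count in the denominator only).  Traceback is
#' deterministic (diagonal preferred over a gap in `b`, over a gap in
#' `a`).
#'
#' @param a,b Non-empty protein strings over the matrix alphabet.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties (defaults 10 and 0.5).
#' @param end_gaps_penalized Penalise leading/trailing gaps
#'   (default `FALSE`).
#' @return Object of class `pairwise_alignment`: a list with
#'   `aligned_a`, `aligned_b`, `score`, `pct_identity`,
#'   `pct_similarity`, `n_gap_cols`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5, end_gaps_penalized = FALSE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1,
            length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop_fmt("sequences must be non-empty")
  alpha <- rownames(matrix)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ia <- match(ca, alpha); ib <- match(cb, alpha)
  if (anyNA(ia))
    stop_fmt("residue '%s' not in the substitution alphabet",
             ca[which(is.na(ia))[1]])
  if (anyNA(ib))
    stop_fmt("residue '%s' not in the substitution alphabet",
             cb[which(is.na(ib))[1]])
  res <- gotoh_align(ia, ib, matrix, gap_open, gap_extend,
                     end_gaps_penalized)
  ga <- ifelse(res$a_idx == 0, "-", ca[pmax(res$a_idx, 1)])
  gb <- ifelse(res$b_idx == 0, "-", cb[pmax(res$b_idx, 1)])
  len <- length(ga)
  both <- res$a_idx > 0 & res$b_idx > 0
  ident <- sum(ga[both] == gb[both])
  simil <- sum(matrix[cbind(ga[both], gb[both])] > 0)
  structure(list(aligned_a = paste(ga, collapse = ""),
                 aligned_b = paste(gb, collapse = ""),
                 score = res$score,
                 pct_identity = 100 * ident / len,
                 pct_similarity = 100 * simil / len,
                 n_gap_cols = sum(!both)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.1f%%, similarity %.1f%%, %d gap column(s)\n",
              x$score, x$pct_identity, x$pct_similarity, x$n_gap_cols))
  n <- nchar(x$aligned_a)
  for (at in seq(1, n, by = width)) {
    cat(substr(x$aligned_a, at, min(at + width - 1, n)), "\n")
    cat(substr(x$aligned_b, at, min(at + width - 1, n)), "\n\n")
  }
  invisible(x)
}
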