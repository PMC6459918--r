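## Similarity-rate tables against fixed references and the coevolution
## regression/correlation fit.
##
## Rationale: if a modification component (DndCD) and its partner
## (PbeAC or DndFGH) evolve at the same speed from a common ancestor,
## their divergence degrees (1 minus the similarity rate) across strains
## should be linearly related; the rank correlation of paired similarity
## rates is invariant under that similarity/divergence flip.

#' Per-strain similarity rates against fixed references
#'
#' For each strain, globally aligns the concatenated modification-family
#' sequences and the concatenated partner-family sequences against the
#' corresponding concatenated references and records the similarity
#' percentage of each alignment.  Components are concatenated in the
#' fixed gene order they are supplied in (e.g. C then D, A then C).
#' Strains with a missing or empty component are skipped with a warning,
#' never silently.
#'
#' @param strains `data.frame` with columns `strain_id`, `mod_seq`,
#'   `res_seq` (each possibly a single pre-concatenated string), or a
#'   list of `list(strain_id, mod_seqs, res_seqs)` whose sequence fields
#'   are character vectors of components.
#' @param ref_mod,ref_res Character vectors of reference components,
#'   concatenated in the same order.
#' @param concat Concatenate components before aligning (default
#'   `TRUE`); when `FALSE`, per-component similarities are averaged
#'   instead.
#' @param ... Passed to [global_align()].
#' @return `data.frame` of class `similarity_pair_table` with columns
#'   `strain_id`, `mod_similarity`, `res_similarity`, sorted by
#'   `strain_id`.
#' @export
similarity_rates <- function(strains, ref_mod, ref_res, concat = TRUE, ...) {
  if (is.data.frame(strains)) {
    strains <- lapply(seq_len(nrow(strains)), function(i)
      list(strain_id = strains$strain_id[i], mod_seqs = strains$mod_seq[i],
           res_seqs = strains$res_seq[i]))
  }
  rm_cat <- paste(ref_mod, collapse = ""); rr_cat <- paste(ref_res, collapse = "")
  if (!nzchar(rm_cat) || !nzchar(rr_cat))
    stop_fmt("reference sequences must be non-empty")
  sim_vs_ref <- function(seqs, refs, ref_cat) {
    if (concat)
      return(global_align(paste(seqs, collapse = ""), ref_cat, ...)$pct_similarity)
    if (length(seqs) != length(refs))
      stop_fmt("component count differs from reference in per-component mode")
    mean(vapply(seq_along(seqs), function(k)
      global_align(seqs[k], refs[k], ...)$pct_similarity, numeric(1)))
  }
  rows <- list()
  for (s in strains) {
    ms <- s$mod_seqs %||% s$mod_seq; rs <- s$res_seqs %||% s$res_seq
    if (is.null(ms) || is.null(rs) || any(!nzchar(ms)) || any(!nzchar(rs)) ||
        anyNA(ms) || anyNA(rs)) {
      warning(sprintf("strain '%s' skipped: missing or empty component",
                      s$strain_id %||% "?"), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = s$strain_id,
      mod_similarity = sim_vs_ref(ms, ref_mod, rm_cat),
      res_similarity = sim_vs_ref(rs, ref_res, rr_cat),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop_fmt("no complete strains to align")
  out <- do.call(rbind, rows)
  out <- out[order(out$strain_id), ]
  rownames(out) <- NULL
  class(out) <- c("similarity_pair_table", "data.frame")
  out
}

#' Fit the coevolution relation between paired similarity rates
#'
#' Computes the Spearman rank correlation `rho` (the headline statistic;
#' invariant under the similarity-to-divergence flip `s -> 100 - s`
#' applied to both columns), the Pearson correlation `r`, and the least
#' squares regression of partner similarity on modification similarity.
#'
#' @param table A [similarity_rates()] table, or any `data.frame` with
#'   columns `mod_similarity` and `res_similarity`.
#' @return Object of class `coevolution_fit` with components `n`, `rho`,
#'   `r`, `slope`, `intercept`, the underlying `lm` fit (`model`) and
#'   the input `table`.  A constant column flags the correlations as
#'   undefined (`NA`) with a warning.
#' @export
coevolution_fit <- function(table) {
  stopifnot(all(c("mod_similarity", "res_similarity") %in% names(table)))
  n <- nrow(table)
  if (n < 3) stop_fmt("need at least 3 strains, got %d", n)
  x <- table$mod_similarity; y <- table$res_similarity
  constant <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (constant)
    warning("constant similarity column: correlations undefined",
            call. = FALSE)
  rho <- if (constant) NA_real_ else cor(x, y, method = "spearman")
  r <- if (constant) NA_real_ else cor(x, y, method = "pearson")
  fit <- lm(res_similarity ~ mod_similarity, data = table)
  structure(list(n = n, rho = rho, r = r,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 model = fit, table = table),
            class = "coevolution_fit")
}

#' @export
print.coevolution_fit <- function(x, ...) {
  cat("Coevolution fit of paired similarity rates\n")
  cat(sprintf("  strains: %d\n", x$n))
  cat(sprintf("  Spearman rho: %s\n",
              if (is.na(x$rho)) "undefined" else sprintf("%.3f", x$rho)))
  cat(sprintf("  Pearson r:    %s\n",
              if (is.na(x$r)) "undefined" else sprintf("%.3f", x$r)))
  cat(sprintf("  regression:   res = %.3f + %.3f * mod\n",
              x$intercept, x$slope))
  invisible(x)
}

#' @export
#' @method summary coevolution_fit
summary.coevolution_fit <- function(object, ...) {
  print(object)
  cat("\nLeast-squares detail:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
#' @method coef coevolution_fit
coef.coevolution_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.coevolution_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$table
  if (is.numeric(newdata)) newdata <- data.frame(mod_similarity = newdata)
  unname(predict(object$model, newdata = newdata))
}

#' @export
#' @method residuals coevolution_fit
residuals.coevolution_fit <- function(object, ...) {
  unname(stats::residuals(object$model))
}

#' @export
#' @method plot coevolution_fit
plot.coevolution_fit <- function(x, ...) {
  graphics::plot(x$table$mod_similarity, x$table$res_similarity,
                 xlab = "modification-family similarity (%)",
                 ylab = "partner-family similarity (%)", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
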