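## Scalar virology assay formulas.  All three are pure and vectorised;
## eop() and unadsorbed_pct() are invariant under a common rescaling of
## both titres.

#' Efficiency of plating
#'
#' Ratio of the viral titre obtained on a test host to the titre on a
#' reference host (both in PFU/mL).
#'
#' @param titre_test,titre_ref Positive titres; `titre_ref` must be > 0.
#' @return `titre_test / titre_ref`.
#' @export
eop <- function(titre_test, titre_ref) {
  if (any(titre_ref <= 0)) stop_fmt("reference titre must be positive")
  titre_test / titre_ref
}

#' Relative viral genome load from qPCR cycle thresholds
#'
#' The delta-CT estimate `2^(CT(radA) - CT(repA))` of viral genome
#' copies per host chromosome, where `radA` is the single-copy host
#' chromosomal gene and `repA` lies in the viral replication region.
#' The CT difference direction is host minus virus, so a more abundant
#' viral template (smaller `CT(repA)`) gives a larger fold value.
#'
#' @param ct_radA,ct_repA Finite cycle-threshold values.
#' @return Fold level of viral DNA relative to the host chromosome.
#' @export
relative_viral_load <- function(ct_radA, ct_repA) {
  if (any(!is.finite(ct_radA)) || any(!is.finite(ct_repA)))
    stop_fmt("cycle thresholds must be finite")
  2^(ct_radA - ct_repA)
}

#' Percentage of unadsorbed virus
#'
#' Extracellular titre at time t as a percentage of the initial titre
#' (the virus-only control, taken as 100%).
#'
#' @param titre_t Titre at the sampled time point.
#' @param titre_0 Initial titre; must be > 0.
#' @return `100 * titre_t / titre_0`.
#' @export
unadsorbed_pct <- function(titre_t, titre_0) {
  if (any(titre_0 <= 0)) stop_fmt("initial titre must be positive")
  100 * titre_t / titre_0
}
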