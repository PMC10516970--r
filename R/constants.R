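#' Physical constants of the qSIP density-shift model
#'
#' The qSIP estimator converts a taxon's buoyant-density shift between
#' natural-abundance and \eqn{^{18}}O-labeled gradients into an excess atom
#' fraction of \eqn{^{18}}O in its DNA. That conversion rests on three
#' empirical linear relationships: buoyant density vs GC content, DNA
#' molecular weight vs GC content, and the maximum molecular-weight gain
#' attainable when every oxygen atom in the DNA backbone is \eqn{^{18}}O.
#'
#' Defaults are the values established for bacterial genomic DNA in CsCl
#' gradients and used throughout the qSIP literature:
#' \describe{
#'   \item{density_gc_slope, density_gc_intercept}{unlabeled buoyant density
#'     (g/mL) = intercept + slope * GC, so GC can be inferred from the
#'     unlabeled weighted average density.}
#'   \item{mw_gc_slope, mw_gc_intercept}{mean nucleotide molecular weight
#'     (g/mol) = intercept + slope * GC, for unlabeled DNA.}
#'   \item{mw_18O_max_shift}{molecular-weight increase (g/mol) at full
#'     \eqn{^{18}}O substitution.}
#'   \item{nat_abund_18O}{natural abundance of \eqn{^{18}}O as an atom
#'     fraction (0.002000429); enrichment is expressed in excess of this.}
#' }
#'
#' @param density_gc_slope g/mL per unit GC fraction.
#' @param density_gc_intercept g/mL at GC = 0.
#' @param mw_gc_slope g/mol per unit GC fraction.
#' @param mw_gc_intercept g/mol at GC = 0.
#' @param mw_18O_max_shift g/mol gained at full \eqn{^{18}}O substitution.
#' @param nat_abund_18O natural \eqn{^{18}}O atom fraction.
#'
#' @return A named list of class `qsip_constants`.
#' @examples
#' qsip_constants()
#' qsip_constants(nat_abund_18O = 0.002)  # explicit override
#' @export
qsip_constants <- function(density_gc_slope = 0.083506,
                           density_gc_intercept = 1.646057,
                           mw_gc_slope = 0.496,
                           mw_gc_intercept = 307.691,
                           mw_18O_max_shift = 12.07747,
                           nat_abund_18O = 0.002000429) {
  vals <- list(
    density_gc_slope = density_gc_slope,
    density_gc_intercept = density_gc_intercept,
    mw_gc_slope = mw_gc_slope,
    mw_gc_intercept = mw_gc_intercept,
    mw_18O_max_shift = mw_18O_max_shift,
    nat_abund_18O = nat_abund_18O
  )
  if (!all(vapply(vals, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1)))) {
    abort("all qSIP constants must be single finite numbers")
  }
  if (nat_abund_18O <= 0 || nat_abund_18O >= 1) {
    abort("`nat_abund_18O` must be an atom fraction in (0, 1)")
  }
  structure(vals, class = "qsip_constants")
}

as_qsip_constants <- function(x) {
  if (inherits(x, "qsip_constants")) return(x)
  do.call(qsip_constants, as.list(x))
}

# Upper bound of excess atom fraction: DNA fully substituted with 18O still
# started from natural abundance, so EAF <= 1 - nat_abund_18O.
eaf_max <- function(constants = qsip_constants()) 1 - constants$nat_abund_18O
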