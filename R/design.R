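#' Experimental design constants
#'
#' The study design comprises three experiments, each a set of
#' intraperitoneal drug treatments hybridized against a common pooled
#' control: receptor agonists (SKF 38393, a D1 agonist, and LY 171555, a
#' D2 agonist), receptor antagonists (SCH 23390, D1-specific, and
#' sulpiride, D2-specific), and catecholamine depletion (MPTP combined
#' with alpha-methyl-p-tyrosine).  `da_experiments()` returns the
#' experiment-to-treatment map; `da_treatments()` the closed treatment
#' set; `treatment_experiment()` the inverse lookup.
#'
#' @return `da_experiments()`: named list of treatment-id vectors.
#'   `da_treatments()`: character vector.  `treatment_experiment()`:
#'   named character vector mapping treatment id to experiment id.
#' @export
da_experiments <- function() {
  list(agonist    = c("SKF", "LY"),
       antagonist = c("SCH", "sulpiride"),
       depletion  = "MPTP_aMPT")
}

#' @rdname da_experiments
#' @export
da_treatments <- function() unlist(da_experiments(), use.names = FALSE)

#' @rdname da_experiments
#' @export
treatment_experiment <- function() {
  ex <- da_experiments()
  stats::setNames(rep(names(ex), lengths(ex)), unlist(ex, use.names = FALSE))
}

# drug -> receptor selectivity; MPTP+aMPT depletion is receptor-nonspecific
.d1_drugs <- c("SKF", "SCH")
.d2_drugs <- c("LY", "sulpiride")
.agonists <- c("SKF", "LY")
.blockers <- c("SCH", "sulpiride", "MPTP_aMPT")
.antagonists <- c("SCH", "sulpiride")
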