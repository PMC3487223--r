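#' Configuration for the synthetic two-color array generator
#'
#' Describes a simulated version of the study design: five drug
#' treatments in three experiments, two brain tissues, four
#' hybridizations per treatment-tissue pool against a common control
#' pool, one of which is a dye-reversal replicate, and duplicate spots
#' per gene.  A configurable fraction of genes is planted as regulated
#' by dopamine: such a gene responds to the agonist of its assigned
#' receptor with some log2 effect and to the matching antagonist and to
#' catecholamine depletion with the opposite sign (optionally
#' attenuated), which is the generative converse of the reciprocal
#' selection rule applied downstream.
#'
#' @param n_genes Number of genes on the platform.
#' @param spot_replicates Spots per gene (the platform prints duplicates).
#' @param tissues Tissue labels; hypothalamus and telencephalon by default.
#' @param arrays_per_pool Hybridizations per treatment-tissue; the last is
#'   a dye-reversal replicate of the first RNA pool.
#' @param frac_regulated Fraction of genes planted as dopamine-regulated.
#' @param effect_log2_mean,effect_log2_sd Mean and spread of the absolute
#'   planted log2 effect size (a zero sd plants a fixed magnitude).
#' @param attenuation_blocker Multiplier in (0, 1] applied to antagonist
#'   and depletion effects relative to the agonist effect.
#' @param receptor_mix Named proportions (`D1`, `D2`, `both`) of receptor
#'   assignment among regulated genes; must sum to 1.
#' @param noise_sd Per-spot log2 noise standard deviation on the
#'   treatment channel (duplicate spots get independent noise).
#' @param pool_sd Between-pool biological standard deviation of the
#'   per-gene log2 effect (the study pooled 2-3 brains per RNA pool; the
#'   pool, not the animal, is the generative unit).
#' @param control_log2_mean,control_log2_sd Log2-normal parameters of the
#'   shared control-pool expression vector per tissue.
#' @param distortion List describing per-array affine distortion in the
#'   two-dimensional (log2 channel-1, log2 channel-2) space:
#'   `rotation_deg` (maximal absolute rotation angle), `scale` (range of
#'   the isotropic scale factor), `translation` (maximal absolute
#'   per-coordinate shift).  These are the systematic dye/scanner biases
#'   that Procrustes normalization is meant to remove.
#' @param rng_seed Integer seed; identical configurations give
#'   byte-identical outputs.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_truth()], [generate_experiment()], [generate_study()]
#' @examples
#' cfg <- sim_config(n_genes = 50, rng_seed = 1)
#' cfg$frac_regulated
#' @export
sim_config <- function(n_genes = 1000,
                       spot_replicates = 2,
                       tissues = c("Hyp", "Tel"),
                       arrays_per_pool = 4,
                       frac_regulated = 0.10,
                       effect_log2_mean = 1.0,
                       effect_log2_sd = 0,
                       attenuation_blocker = 1.0,
                       receptor_mix = c(D1 = 0.4, D2 = 0.4, both = 0.2),
                       noise_sd = 0.25,
                       pool_sd = 0.10,
                       control_log2_mean = 10,
                       control_log2_sd = 1.5,
                       distortion = list(rotation_deg = 5,
                                         scale = c(0.9, 1.1),
                                         translation = 0.3),
                       rng_seed = 20121102) {
  if (n_genes < 1) stopf("n_genes must be >= 1")
  if (spot_replicates < 1) stopf("spot_replicates must be >= 1")
  if (arrays_per_pool < 2) stopf("arrays_per_pool must be >= 2")
  if (frac_regulated < 0 || frac_regulated > 1)
    stopf("frac_regulated must lie in [0, 1]")
  if (attenuation_blocker <= 0 || attenuation_blocker > 1)
    stopf("attenuation_blocker must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (pool_sd < 0) stopf("pool_sd must be >= 0")
  if (!all(c("D1", "D2", "both") %in% names(receptor_mix)))
    stopf("receptor_mix needs named proportions D1, D2, both")
  if (abs(sum(receptor_mix) - 1) > 1e-9)
    stopf("receptor_mix proportions must sum to 1 (got %.12g)",
          sum(receptor_mix))
  if (any(receptor_mix < 0)) stopf("receptor_mix proportions must be >= 0")
  d <- distortion
  if (!all(c("rotation_deg", "scale", "translation") %in% names(d)))
    stopf("distortion needs rotation_deg, scale and translation")
  if (length(d$scale) != 2 || any(d$scale <= 0) || d$scale[1] > d$scale[2])
    stopf("distortion$scale must be a positive increasing range")
  cfg <- list(n_genes = as.integer(n_genes),
              spot_replicates = as.integer(spot_replicates),
              experiments = da_experiments(),
              tissues = tissues,
              arrays_per_pool = as.integer(arrays_per_pool),
              frac_regulated = frac_regulated,
              effect_log2_mean = effect_log2_mean,
              effect_log2_sd = effect_log2_sd,
              attenuation_blocker = attenuation_blocker,
              receptor_mix = receptor_mix[c("D1", "D2", "both")],
              noise_sd = noise_sd,
              pool_sd = pool_sd,
              control_log2_mean = control_log2_mean,
              control_log2_sd = control_log2_sd,
              distortion = d,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic two-color array design\n")
  cat(sprintf("  %d genes x %d spots, %s tissues, %d arrays/pool (1 dye-swap)\n",
              x$n_genes, x$spot_replicates,
              paste(x$tissues, collapse = "/"), x$arrays_per_pool))
  cat(sprintf("  regulated: %.0f%% at |log2 effect| ~ %.2f (sd %.2f), blocker attenuation %.2f\n",
              100 * x$frac_regulated, x$effect_log2_mean, x$effect_log2_sd,
              x$attenuation_blocker))
  cat(sprintf("  noise sd %.2f, pool sd %.2f, seed %d\n",
              x$noise_sd, x$pool_sd, x$rng_seed))
  invisible(x)
}
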