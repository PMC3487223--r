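#' Plant the ground truth of a simulated study
#'
#' Chooses which genes are dopamine-regulated, assigns each a receptor
#' (`D1`, `D2` or `both`) and a per-treatment true log2 effect.  The
#' agonist of the assigned receptor carries a random sign; the matching
#' antagonist and the depletion treatment carry the opposite sign scaled
#' by `attenuation_blocker`; all other treatments are exactly zero.
#' Every regulated gene therefore has at least one agonist/blocker pair
#' with strictly opposite true effects, and unregulated genes are null
#' throughout.
#'
#' @param config A [sim_config()].
#' @return A `truth_table` data frame with one row per gene: `gene_id`,
#'   `regulated`, `receptor` and one true-effect column per treatment.
#' @examples
#' truth <- generate_truth(sim_config(n_genes = 20, rng_seed = 7))
#' table(truth$receptor)
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  n_reg <- round(config$frac_regulated * n)
  trt <- da_treatments()
  eff <- matrix(0, n, length(trt), dimnames = list(gene_id, trt))
  regulated <- rep(FALSE, n)
  receptor <- rep(NA_character_, n)

  if (n_reg > 0) {
    with_seed(subseed(config$rng_seed, "truth"), {
      idx <- sample.int(n, n_reg)
      regulated[idx] <- TRUE
      # receptor counts follow the configured mix within rounding
      counts <- round(config$receptor_mix * n_reg)
      while (sum(counts) > n_reg) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
      while (sum(counts) < n_reg) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
      rec <- sample(rep(c("D1", "D2", "both"), counts))
      receptor[idx] <- rec
      mag <- abs(stats::rnorm(n_reg, config$effect_log2_mean,
                              config$effect_log2_sd))
      sgn <- sample(c(-1, 1), n_reg, replace = TRUE)
      att <- config$attenuation_blocker
      for (k in seq_len(n_reg)) {
        g <- idx[k]; e <- sgn[k] * mag[k]
        if (rec[k] %in% c("D1", "both")) {
          eff[g, "SKF"] <- e
          eff[g, "SCH"] <- -e * att
        }
        if (rec[k] %in% c("D2", "both")) {
          eff[g, "LY"] <- e
          eff[g, "sulpiride"] <- -e * att
        }
        eff[g, "MPTP_aMPT"] <- -e * att
      }
    })
  }
  out <- data.frame(gene_id = gene_id, regulated = regulated,
                    receptor = receptor, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(eff))
  rownames(out) <- NULL
  class(out) <- c("truth_table", "data.frame")
  out
}
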