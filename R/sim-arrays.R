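#' Generate raw two-color arrays for one experiment and tissue
#'
#' Emulates the hybridization design: for every treatment of the
#' experiment, `arrays_per_pool` hybridizations against the tissue's
#' common control pool.  Arrays 1..(n-1) use distinct treated RNA pools;
#' the last array is a dye-reversal replicate of pool 1 (same biology,
#' fresh hybridization noise, channels exchanged).  The treatment
#' channel of a spot is the control expression times `2^(true effect +
#' pool deviation)` times multiplicative log-normal spot noise; each
#' array is then distorted by its own random rotation/scale/translation
#' in (log2 ch1, log2 ch2) space, the affine dye/scanner bias that the
#' Procrustes normalization stage estimates and removes.
#'
#' @param config A [sim_config()].
#' @param truth A `truth_table` from [generate_truth()] for the same config.
#' @param experiment_id One of `"agonist"`, `"antagonist"`, `"depletion"`.
#' @param tissue One of `config$tissues`.
#' @return List of `two_color_array` objects, one per treatment and
#'   hybridization.  Each holds `array_id`, `pool_id`, `treatment`,
#'   `tissue`, `dye_reversed` and a `spots` data frame with
#'   `spot_id`, `gene_id`, `intensity_ch1`, `intensity_ch2`.
#' @seealso [generate_study()] for the full design, [write_arrays()].
#' @examples
#' cfg <- sim_config(n_genes = 10, rng_seed = 1)
#' arr <- generate_experiment(cfg, generate_truth(cfg), "depletion", "Hyp")
#' length(arr)   # arrays_per_pool hybridizations for the single treatment
#' @export
generate_experiment <- function(config, truth, experiment_id, tissue) {
  stopifnot(inherits(config, "sim_config"))
  if (!experiment_id %in% names(config$experiments))
    stopf("unknown experiment id '%s'", experiment_id)
  if (!tissue %in% config$tissues)
    stopf("unknown tissue '%s'", tissue)
  treatments <- config$experiments[[experiment_id]]
  n <- config$n_genes
  rep_spots <- config$spot_replicates
  gidx <- rep(seq_len(n), each = rep_spots)
  spot_id <- sprintf("%s_s%d", truth$gene_id[gidx],
                     rep(seq_len(rep_spots), times = n))
  ctrl <- control_pool(config, tissue)

  arrays <- list()
  with_seed(subseed(config$rng_seed,
                    paste("exp", experiment_id, tissue)), {
    for (trt in treatments) {
      npool <- config$arrays_per_pool - 1L
      pooldev <- matrix(stats::rnorm(n * npool, 0, config$pool_sd), n, npool)
      eff <- truth[[trt]]
      for (k in seq_len(config$arrays_per_pool)) {
        reversed <- k == config$arrays_per_pool
        pool <- if (reversed) 1L else k
        treat_log2 <- ctrl[gidx] + eff[gidx] + pooldev[gidx, pool] +
          stats::rnorm(length(gidx), 0, config$noise_sd)
        ctrl_log2 <- ctrl[gidx]
        P <- if (reversed) cbind(ctrl_log2, treat_log2)
             else cbind(treat_log2, ctrl_log2)
        d <- config$distortion
        ang <- stats::runif(1, -d$rotation_deg, d$rotation_deg) * pi / 180
        sc <- stats::runif(1, d$scale[1], d$scale[2])
        tr <- stats::runif(2, -d$translation, d$translation)
        R <- rotation2(ang)
        P <- sc * P %*% R
        P <- sweep(P, 2, tr, `+`)
        a <- list(array_id = sprintf("%s_%s_%s_a%d", experiment_id, tissue,
                                     trt, k),
                  pool_id = sprintf("%s_%s_%s_p%d", experiment_id, tissue,
                                    trt, pool),
                  treatment = trt, tissue = tissue, dye_reversed = reversed,
                  seed = config$rng_seed,
                  spots = data.frame(spot_id = spot_id,
                                     gene_id = truth$gene_id[gidx],
                                     intensity_ch1 = 2^P[, 1],
                                     intensity_ch2 = 2^P[, 2],
                                     stringsAsFactors = FALSE))
        class(a) <- "two_color_array"
        arrays[[a$array_id]] <- a
      }
    }
  })
  arrays
}

# shared control-pool expression vector for one tissue (log2 scale)
control_pool <- function(config, tissue) {
  with_seed(subseed(config$rng_seed, paste("control", tissue)),
            stats::rnorm(config$n_genes, config$control_log2_mean,
                         config$control_log2_sd))
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Distortion settings that leave arrays undistorted
#'
#' Convenience for simulations that should expose the generative model
#' exactly (identity rotation, unit scale, zero translation).
#' @return A distortion list accepted by [sim_config()].
#' @export
no_distortion <- function() {
  list(rotation_deg = 0, scale = c(1, 1), translation = 0)
}

#' Generate the complete simulated study
#'
#' Runs [generate_experiment()] for every experiment and tissue of the
#' design and assembles a manifest.  With the default configuration this
#' yields 16 agonist arrays, 16 antagonist arrays and 8 depletion arrays
#' (two tissues each).
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-computed [generate_truth()] table.
#' @param tissues Subset of tissues to generate (default: all configured).
#' @return A list with `arrays` (named list of `two_color_array`),
#'   `manifest` (data frame), `truth` and `config`.
#' @examples
#' study <- generate_study(sim_config(n_genes = 10, rng_seed = 1),
#'                         tissues = "Hyp")
#' table(study$manifest$treatment)
#' @export
generate_study <- function(config, truth = generate_truth(config),
                           tissues = config$tissues) {
  arrays <- list()
  for (ex in names(config$experiments))
    for (ti in tissues)
      arrays <- c(arrays, generate_experiment(config, truth, ex, ti))
  manifest <- do.call(rbind, lapply(arrays, function(a)
    data.frame(array_id = a$array_id, treatment = a$treatment,
               tissue = a$tissue, pool_id = a$pool_id,
               dye_reversed = a$dye_reversed,
               experiment = treatment_experiment()[[a$treatment]],
               stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL
  list(arrays = arrays, manifest = manifest, truth = truth, config = config)
}

#' Write and read two-color array tables
#'
#' One TSV per array, holding the array metadata in `# key: value`
#' header comments and the spot table below; intensities are printed at
#' full double precision so the files round-trip losslessly through
#' [read_arrays()].  A `manifest.tsv` lists array ids with their
#' treatment, tissue, pool and dye-orientation flag.
#'
#' @param arrays List of `two_color_array` objects.
#' @param dir Output directory (created if missing).
#' @return `write_arrays()`: the directory, invisibly.  `read_arrays()`:
#'   a named list of `two_color_array` objects.
#' @export
write_arrays <- function(arrays, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (a in arrays) {
    stopifnot(inherits(a, "two_color_array"))
    df <- a$spots
    df$intensity_ch1 <- sprintf("%.17g", df$intensity_ch1)
    df$intensity_ch2 <- sprintf("%.17g", df$intensity_ch2)
    write_tsv(df, file.path(dir, paste0(a$array_id, ".tsv")),
              comments = c(paste0("array_id: ", a$array_id),
                           paste0("pool_id: ", a$pool_id),
                           paste0("treatment: ", a$treatment),
                           paste0("tissue: ", a$tissue),
                           paste0("dye_reversed: ", a$dye_reversed),
                           paste0("seed: ", a$seed %||% NA)))
  }
  man <- do.call(rbind, lapply(arrays, function(a)
    data.frame(array_id = a$array_id, file = paste0(a$array_id, ".tsv"),
               treatment = a$treatment, tissue = a$tissue,
               pool_id = a$pool_id, dye_reversed = a$dye_reversed,
               stringsAsFactors = FALSE)))
  if (!is.null(man)) {
    rownames(man) <- NULL
    write_tsv(man, file.path(dir, "manifest.tsv"))
  }
  invisible(dir)
}

#' @rdname write_arrays
#' @export
read_arrays <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) return(list())
  man <- read_tsv(manifest_path)
  arrays <- list()
  for (i in seq_len(nrow(man))) {
    path <- file.path(dir, man$file[i])
    hdr <- readLines(path, n = 10)
    hdr <- hdr[startsWith(hdr, "# ")]
    kv <- strsplit(sub("^# ", "", hdr), ": ")
    meta <- stats::setNames(vapply(kv, function(x) x[2] %||% "", ""),
                            vapply(kv, `[`, "", 1))
    spots <- read_tsv(path)
    spots$intensity_ch1 <- as.numeric(spots$intensity_ch1)
    spots$intensity_ch2 <- as.numeric(spots$intensity_ch2)
    a <- list(array_id = meta[["array_id"]], pool_id = meta[["pool_id"]],
              treatment = meta[["treatment"]], tissue = meta[["tissue"]],
              dye_reversed = as.logical(meta[["dye_reversed"]]),
              seed = suppressWarnings(as.integer(meta[["seed"]])),
              spots = spots)
    class(a) <- "two_color_array"
    arrays[[a$array_id]] <- a
  }
  arrays
}
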