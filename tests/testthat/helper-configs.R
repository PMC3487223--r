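# shared builders for small test objects

small_config <- function(n_genes = 50, seed = 1, ...) {
  sim_config(n_genes = n_genes, rng_seed = seed, ...)
}

clean_config <- function(n_genes = 50, seed = 1, ...) {
  sim_config(n_genes = n_genes, rng_seed = seed, noise_sd = 0, pool_sd = 0,
             distortion = no_distortion(), ...)
}

# raw array_configuration from an explicit n x 2 matrix
make_conf <- function(xy, id = "a", treatment = "SKF", tissue = "Hyp",
                      genes = NULL, reversed = FALSE) {
  n <- nrow(xy)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(n))
  structure(list(array_id = id, treatment = treatment, tissue = tissue,
                 dye_reversed = reversed,
                 spot_id = sprintf("s%03d", seq_len(n)),
                 gene_id = genes, xy = unname(xy)),
            class = "array_configuration")
}

# base two-channel cloud whose null spots lie exactly on the diagonal;
# `effect` is a per-spot log2 displacement of the treatment channel
base_cloud <- function(n = 200, effect = rep(0, n), seed = 1) {
  set.seed(seed)
  ctrl <- rnorm(n, 10, 1.5)
  cbind(ctrl + effect, ctrl)
}

rot_ccw <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

distort <- function(xy, deg = 0, scale = 1, shift = c(0, 0)) {
  sweep(scale * xy %*% rot_ccw(deg), 2, shift, `+`)
}
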