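test_that("configuration loading clips, logs and resolves dye orientation", {
  spots <- data.frame(spot_id = c("s1", "s2"), gene_id = c("g1", "g2"),
                      intensity_ch1 = c(1024, 0), intensity_ch2 = c(2, 8))
  a <- structure(list(array_id = "a", pool_id = "p", treatment = "SKF",
                      tissue = "Hyp", dye_reversed = FALSE, spots = spots),
                 class = "two_color_array")
  cf <- load_configuration(a, floor = 1)
  expect_equal(unname(cf$xy[1, 1]), 10)      # log2(1024)
  expect_equal(unname(cf$xy[2, 1]), 0)       # clipped at the floor
  expect_error(load_configuration(a, floor = 0), "floor")

  a$dye_reversed <- TRUE
  cr <- load_configuration(a)
  expect_equal(unname(cr$xy[, 1]), log2(pmax(spots$intensity_ch2, 1)))
  expect_equal(unname(cr$xy[, 2]), log2(pmax(spots$intensity_ch1, 1)))
})

test_that("aligning identical configurations is the identity", {
  A <- base_cloud(100, seed = 5)
  g <- gpa_align(list(make_conf(A, "a"), make_conf(A, "b")))
  for (R in g$rotations) expect_equal(R, diag(2), tolerance = 1e-9)
  expect_equal(g$scales, c(1, 1), tolerance = 1e-9)
  expect_equal(g$translations[[1]], g$translations[[2]])
  expect_lt(tail(g$residual_history, 1), 1e-18)
})

test_that("a known rotation/scale distortion is recovered and inverted", {
  A <- base_cloud(150, seed = 6)
  B <- distort(A, deg = 30, scale = 1.5)
  g <- gpa_align(list(make_conf(A, "a"), make_conf(B, "b")))
  expect_lt(tail(g$residual_history, 1), 1e-12)
  # the relative scale and rotation between the fitted transforms invert
  # the constructed distortion
  expect_equal(g$scales[1] / g$scales[2], 1.5, tolerance = 1e-9)
  comp <- g$rotations[[1]] %*% t(g$rotations[[2]])
  ang <- atan2(comp[2, 1], comp[1, 1]) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)
  # both aligned configurations coincide
  rm <- extract_ratios(g, list(make_conf(A, "a"), make_conf(B, "b")))
  expect_equal(rm$ratios[, 1], rm$ratios[, 2], tolerance = 1e-9)
})

test_that("rotation matrices are proper and the residual never increases", {
  set.seed(42)
  for (rep in 1:5) {
    A <- base_cloud(80, effect = c(rep(0.8, 8), rep(0, 72)), seed = rep)
    cfs <- lapply(1:5, function(i)
      make_conf(distort(A, deg = runif(1, -45, 45),
                        scale = runif(1, 0.5, 2),
                        shift = runif(2, -2, 2)), paste0("a", i)))
    g <- gpa_align(cfs, tol = 1e-10)
    expect_true(all(diff(g$residual_history) <= 1e-9))
    for (i in seq_along(cfs)) {
      R <- g$rotations[[i]]
      expect_equal(crossprod(R), diag(2), tolerance = 1e-9)
      expect_equal(det(R), 1, tolerance = 1e-9)
      expect_gt(g$scales[i], 0)
    }
    # total-size constraint
    ss <- vapply(cfs, function(cf)
      sum(scale(cf$xy, scale = FALSE)^2), 0)
    expect_equal(sum(g$scales^2 * ss), sum(ss), tolerance = 1e-8)
    # residual history tail agrees with direct recomputation from the fit
    Y <- Map(function(cf, R, b, tr) b * (sweep(cf$xy, 2, tr) %*% R),
             cfs, g$rotations, g$scales, g$translations)
    C <- Reduce(`+`, Y) / length(Y)
    direct <- sum(vapply(Y, function(y) sum((y - C)^2), 0))
    expect_equal(direct, tail(g$residual_history, 1), tolerance = 1e-8)
  }
})

test_that("alignment is idempotent", {
  A <- base_cloud(100, seed = 8)
  cfs <- lapply(1:3, function(i)
    make_conf(distort(A, deg = runif(1, -20, 20), scale = runif(1, 0.8, 1.2)),
              paste0("a", i)))
  g1 <- gpa_align(cfs)
  aligned <- Map(function(cf, R, b, tr) {
    make_conf(b * (sweep(cf$xy, 2, tr) %*% R), cf$array_id)
  }, cfs, g1$rotations, g1$scales, g1$translations)
  g2 <- gpa_align(aligned)
  for (R in g2$rotations) expect_equal(R, diag(2), tolerance = 1e-6)
  expect_equal(g2$scales, rep(1, 3), tolerance = 1e-6)
  expect_lt(tail(g2$residual_history, 1),
            tail(g1$residual_history, 1) + 1e-8)
})

test_that("a common pre-rotation changes neither residual nor ratios", {
  eff <- c(rep(1, 12), rep(0, 108))
  A <- base_cloud(120, effect = eff, seed = 9)
  set.seed(21)
  cfs <- lapply(1:4, function(i)
    make_conf(distort(A, deg = runif(1, -10, 10), scale = runif(1, 0.9, 1.1),
                      shift = runif(2, -0.5, 0.5)), paste0("a", i)))
  Q <- rot_ccw(17)
  cfsQ <- lapply(cfs, function(cf) make_conf(cf$xy %*% Q, cf$array_id))
  g1 <- gpa_align(cfs); g2 <- gpa_align(cfsQ)
  expect_equal(tail(g1$residual_history, 1), tail(g2$residual_history, 1),
               tolerance = 1e-6)
  r1 <- extract_ratios(g1, cfs)
  r2 <- extract_ratios(g2, cfsQ)
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-6)
})

test_that("degenerate configurations are rejected with a message", {
  flat <- matrix(5, 50, 2)
  expect_error(gpa_align(list(make_conf(flat, "a"),
                              make_conf(base_cloud(50), "b"))),
               "degenerate")
  expect_error(gpa_align(list(make_conf(base_cloud(50), "a"))), "at least 2")
  cf1 <- make_conf(base_cloud(50), "a")
  cf2 <- make_conf(base_cloud(40), "b")
  expect_error(gpa_align(list(cf1, cf2)), "spot set")
})

test_that("null arrays yield zero ratios and duplicate spots average", {
  A <- base_cloud(100, seed = 10)
  g <- gpa_align(list(make_conf(A, "a"), make_conf(A, "b")))
  rm <- extract_ratios(g, list(make_conf(A, "a"), make_conf(A, "b")))
  expect_true(all(abs(rm$ratios) < 1e-9))

  # one gene with duplicate-spot log ratios {1, 2} among null spots -> 1.5
  eff <- c(1, 2, rep(0, 98))
  genes <- c("gX", "gX", sprintf("g%03d", 3:100))
  B <- base_cloud(100, effect = eff, seed = 12)
  cB <- list(make_conf(B, "a", genes = genes),
             make_conf(B, "b", genes = genes))
  gB <- gpa_align(cB)
  rB <- extract_ratios(gB, cB)
  expect_equal(unname(rB$ratios["gX", ]), c(1.5, 1.5), tolerance = 1e-9)
})

test_that("planted effects pass through normalization exactly at zero noise", {
  cfg <- clean_config(n_genes = 60, frac_regulated = 0.2, seed = 13)
  study <- generate_study(cfg, tissues = "Hyp")
  dep <- Filter(function(a) a$treatment == "MPTP_aMPT", study$arrays)
  cfs <- lapply(dep, load_configuration)
  g <- gpa_align(cfs)
  rm <- extract_ratios(g, cfs)
  truth_eff <- study$truth$MPTP_aMPT[match(rownames(rm$ratios),
                                           study$truth$gene_id)]
  for (j in seq_len(ncol(rm$ratios)))
    expect_equal(unname(rm$ratios[, j]), truth_eff, tolerance = 1e-9)
})

test_that("distorted arrays are inverted to the common ratio vector", {
  cfg <- sim_config(n_genes = 80, frac_regulated = 0.15, rng_seed = 14,
                    noise_sd = 0, pool_sd = 0,
                    distortion = list(rotation_deg = 45,
                                      scale = c(0.5, 2), translation = 2))
  study <- generate_study(cfg, tissues = "Hyp")
  dep <- Filter(function(a) a$treatment == "MPTP_aMPT", study$arrays)
  cfs <- lapply(dep, load_configuration)
  g <- gpa_align(cfs)
  rm <- extract_ratios(g, cfs)
  # between-array distortion differences removed
  for (j in 2:ncol(rm$ratios))
    expect_equal(rm$ratios[, 1], rm$ratios[, j], tolerance = 1e-6)
  truth_eff <- study$truth$MPTP_aMPT[match(rownames(rm$ratios),
                                           study$truth$gene_id)]
  # null genes recover exactly zero; regulated genes recover the planted
  # effects up to the one common (unidentifiable) scale gauge
  expect_true(all(abs(rm$ratios[truth_eff == 0, ]) < 1e-6))
  reg <- truth_eff != 0
  gauge <- rm$ratios[reg, 1] / truth_eff[reg]
  expect_lt(diff(range(gauge)), 1e-6)
  expect_gt(min(gauge), 0)
})

test_that("normalize_arrays groups per experiment-tissue and labels columns", {
  cfg <- small_config(n_genes = 25, seed = 15)
  study <- generate_study(cfg, tissues = "Hyp")
  rm <- normalize_arrays(study$arrays)
  expect_identical(ncol(rm$ratios), 20L)
  expect_identical(nrow(rm$ratios), 25L)
  expect_setequal(unique(rm$arrays$treatment), da_treatments())
  expect_identical(colnames(rm$ratios), rm$arrays$array_id)
})
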