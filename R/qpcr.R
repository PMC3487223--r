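#' Fit a relative standard curve
#'
#' Least-squares fit of threshold cycle (Ct) against log10 relative
#' template quantity over a cDNA dilution series (the default series
#' runs 1:10 with five-fold steps down to 1:31,250).  The amplification
#' efficiency is `(10^(-1/slope) - 1) * 100`; the curve passes quality
#' control iff R^2 > 0.99 and the efficiency lies within 90-110%.
#'
#' @param dilution Dilution factors of the standard wells (e.g. 10, 50,
#'   ...); relative quantity is `1 / dilution`.
#' @param ct Observed threshold cycles, parallel to `dilution`.
#' @return A `standard_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency` (percent), `pass`, `n_points`.
#' @examples
#' dil <- 10 * 5^(0:5)
#' ct <- 30 - log2(1 / dil)     # perfect doubling per cycle
#' fit_standard_curve(dil, ct)$efficiency   # 100
#' @export
fit_standard_curve <- function(dilution, ct) {
  stopifnot(length(dilution) == length(ct))
  ok <- !is.na(ct)
  dilution <- dilution[ok]; ct <- ct[ok]
  if (any(dilution <= 0)) stopf("dilution factors must be > 0")
  if (length(unique(dilution)) < 3)
    stopf("standard curve needs >= 3 distinct dilution points")
  lq <- log10(1 / dilution)
  if (stats::var(lq) == 0) stopf("zero variance in dilution series")
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  eff <- (10^(-1 / slope) - 1) * 100
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = eff,
                 pass = r2 > 0.99 && eff >= 90 && eff <= 110,
                 n_points = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: slope %.4f, R^2 %.4f, efficiency %.1f%% [%s]\n",
    x$slope, x$r_squared, x$efficiency, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Relative quantity from a Ct value
#'
#' `quantity = 10^((Ct - intercept) / slope)`; strictly decreasing in Ct
#' for the usual negative slope.  Refuses curves that failed quality
#' control.
#'
#' @param ct Threshold cycle(s).
#' @param curve A passing [fit_standard_curve()].
#' @return Relative quantity (same units as the standards).
#' @export
qpcr_quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$pass)
    stopf(paste0("standard curve failed QC (R^2 = %.4f, efficiency = ",
                 "%.1f%%); refusing to quantify"),
          curve$r_squared, curve$efficiency)
  10^((ct - curve$intercept) / curve$slope)
}

#' Reference-gene normalization and group comparison
#'
#' Normalizes each sample's target quantity by its reference-gene
#' quantity (samples whose reference quantity is zero are excluded with
#' a warning), summarizes groups by the arithmetic mean, reports the
#' treated-versus-control ratio as a signed fold change (decreases
#' negative), and tests the group difference with a two-tailed
#' Mann-Whitney U test (exact for small untied samples).
#'
#' @param target,reference Named-free numeric vectors of relative
#'   quantities, parallel across samples.
#' @param group Factor/character vector with levels `treated` and
#'   `control`, parallel to the quantities.
#' @return List with `fold_change` (signed), `ratio`, `p.value`, `U`,
#'   `n_treated`, `n_control` and the per-sample `normalized` values.
#' @examples
#' tq <- c(2, 2.1, 1.9, 4, 4.2, 3.8)
#' rq <- rep(2, 6)
#' grp <- rep(c("treated", "control"), each = 3)
#' normalize_and_test(tq, rq, grp)$fold_change
#' @export
normalize_and_test <- function(target, reference, group) {
  stopifnot(length(target) == length(reference),
            length(target) == length(group))
  group <- as.character(group)
  if (!all(group %in% c("treated", "control")))
    stopf("group must be 'treated' or 'control'")
  drop <- reference == 0
  if (any(drop)) {
    warnf("excluding %d sample(s) with zero reference quantity", sum(drop))
    target <- target[!drop]; reference <- reference[!drop]
    group <- group[!drop]
  }
  norm <- target / reference
  treated <- norm[group == "treated"]
  control <- norm[group == "control"]
  if (length(treated) < 3 || length(control) < 3)
    stopf("need >= 3 samples per group (got %d treated, %d control)",
          length(treated), length(control))
  ratio <- mean(treated) / mean(control)
  fc <- signed_fold_change(log2(ratio))
  mw <- mann_whitney_u(treated, control)
  list(fold_change = fc, ratio = ratio, p.value = mw$p.value, U = mw$U,
       n_treated = length(treated), n_control = length(control),
       normalized = norm)
}

#' Quality control of plate negative controls and standards
#'
#' Checks that no-template (NTC) and no-reverse-transcriptase (NoRT)
#' wells show no amplification (Ct recorded as NA) and that standard
#' wells carry strictly positive dilution factors.
#'
#' @param plate Data frame of wells: `sample_id`, `gene`, `ct` (NA means
#'   no amplification), `well_type` (`unknown`, `standard`, `NTC`,
#'   `NoRT`) and `dilution` (standards only).
#' @return List with `pass` and a character vector of `failures`.
#' @export
qpcr_plate_qc <- function(plate) {
  need <- c("sample_id", "gene", "ct", "well_type")
  if (!all(need %in% names(plate)))
    stopf("plate needs columns %s", paste(need, collapse = ", "))
  failures <- character()
  neg <- plate$well_type %in% c("NTC", "NoRT")
  amp <- neg & !is.na(plate$ct)
  if (any(amp))
    failures <- c(failures,
                  sprintf("amplification in %s well '%s' (Ct %.1f)",
                          plate$well_type[amp], plate$sample_id[amp],
                          plate$ct[amp]))
  std <- plate$well_type == "standard"
  if (any(std)) {
    if (is.null(plate$dilution) || any(is.na(plate$dilution[std])) ||
        any(plate$dilution[std] <= 0))
      failures <- c(failures,
                    "standard wells must carry strictly positive dilutions")
  }
  list(pass = length(failures) == 0, failures = failures)
}

#' Default cDNA dilution series
#'
#' 1:10 followed by five-fold steps to 1:31,250 (10, 50, 250, 1250,
#' 6250, 31250), the series used for the relative standard curves.
#' @return Numeric vector of dilution factors.
#' @export
default_dilution_series <- function() 10 * 5^(0:5)
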