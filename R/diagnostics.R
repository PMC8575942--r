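# Instrument-strength, directionality and power diagnostics.

#' Per-SNP F-statistics for instrument strength
#'
#' F_j = (beta_Xj / se_Xj)^2, the squared SNP-exposure association divided by
#' its variance. A mean F below 10 flags a potentially weak instrument set.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column (index or name)
#' @return list with `per_snp_f`, `f_mean`, `f_min`, `f_max`, `weak`
#' @export
f_statistics <- function(hset, exposure = 1) {
  bx <- hset$exposure_betas[, exposure]
  sx <- hset$exposure_ses[, exposure]
  f <- (bx / sx)^2
  list(per_snp_f = f, f_mean = mean(f), f_min = min(f), f_max = max(f),
       weak = mean(f) < 10)
}

#' Variance of the exposure explained by an instrument set
#'
#' Default (`method = "2pq"`): r2 = sum over SNPs of
#' `2 * eaf * (1 - eaf) * beta^2` with betas on the SD scale (assumes
#' Hardy-Weinberg). When betas are in native units, supply `trait_sd` to
#' rescale first. The alternative (`method = "f_approx"`) sums
#' `F / (F + n - 2)` per SNP and needs no frequencies.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @param method `"2pq"` (default) or `"f_approx"`
#' @param trait_sd phenotypic SD if betas are in native units (NULL = already
#'   per SD)
#' @return list with `r2`, `n_snps_used`, `partial` (TRUE when SNPs with
#'   missing frequency were skipped)
#' @export
variance_explained <- function(hset, exposure = 1, method = c("2pq", "f_approx"),
                               trait_sd = NULL) {
  method <- match.arg(method)
  bx <- hset$exposure_betas[, exposure]
  sx <- hset$exposure_ses[, exposure]
  if (!length(bx)) return(list(r2 = 0, n_snps_used = 0L, partial = FALSE))
  if (!is.null(trait_sd)) {
    bx <- bx / trait_sd
    sx <- sx / trait_sd
  }
  if (method == "f_approx") {
    n <- hset$n_exposure[[if (is.character(exposure))
      match(exposure, hset$exposure_names) else exposure]]
    if (is.na(n)) stop_usage("f_approx requires the exposure sample size")
    f <- (bx / sx)^2
    return(list(r2 = sum(f / (f + n - 2)), n_snps_used = length(bx), partial = FALSE))
  }
  ok <- !is.na(hset$eaf)
  if (any(!ok)) warning(sum(!ok), " SNP(s) with missing eaf skipped; r2 is partial")
  r2 <- sum(2 * hset$eaf[ok] * (1 - hset$eaf[ok]) * bx[ok]^2)
  list(r2 = r2, n_snps_used = sum(ok), partial = any(!ok))
}

#' I-squared statistic for variability of instrument strength (NOME)
#'
#' Q_GX is the inverse-variance-weighted heterogeneity of the SNP-exposure
#' effects; I2_GX = max(0, (Q_GX - (k - 1)) / Q_GX). Values below 0.9 suggest
#' the no-measurement-error assumption behind MR-Egger is violated.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @return scalar in \[0, 1\]; NA with a warning when k < 2
#' @export
i_squared_gx <- function(hset, exposure = 1) {
  bx <- hset$exposure_betas[, exposure]
  sx <- hset$exposure_ses[, exposure]
  k <- length(bx)
  if (k < 2) {
    warning("I2_GX undefined for fewer than 2 SNPs")
    return(NA_real_)
  }
  w <- 1 / sx^2
  bw <- sum(w * bx) / sum(w)
  q <- sum(w * (bx - bw)^2)
  max(0, (q - (k - 1)) / q)
}

# scale-free per-SNP pseudo-r2 from a z statistic and sample size
pseudo_r2 <- function(beta, se, n) {
  z2 <- (beta / se)^2
  z2 / (z2 + n)
}

#' Steiger test of causal directionality
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. Per-SNP r2 on either side uses the
#' scale-free pseudo-r2 z^2/(z^2+n) (for binary outcomes this is on the
#' observed log-odds scale). The set-level comparison applies Fisher's
#' z-transform to the square roots of the summed r2; direction is
#' exposure -> outcome when the exposure side explains more.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @return list: `direction` ("exposure_to_outcome"/"outcome_to_exposure"),
#'   `z`, `pvalue`, `r2_exposure`, `r2_outcome`, `per_snp_direction`
#' @export
steiger_test <- function(hset, exposure = 1) {
  e <- if (is.character(exposure)) match(exposure, hset$exposure_names) else exposure
  nx <- hset$n_exposure[e]
  ny <- hset$n_outcome
  if (is.na(nx) || is.na(ny)) stop_usage("steiger_test needs sample sizes for both traits")
  r2x <- pseudo_r2(hset$exposure_betas[, e], hset$exposure_ses[, e], nx)
  r2y <- pseudo_r2(hset$outcome_beta, hset$outcome_se, ny)
  rx <- sqrt(min(sum(r2x), 1 - 1e-12))
  ry <- sqrt(min(sum(r2y), 1 - 1e-12))
  z <- (atanh(rx) - atanh(ry)) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
  list(direction = if (rx >= ry) "exposure_to_outcome" else "outcome_to_exposure",
       z = z, pvalue = 2 * stats::pnorm(-abs(z)),
       r2_exposure = sum(r2x), r2_outcome = sum(r2y),
       per_snp_direction = r2x > r2y)
}

#' MR power approximation
#'
#' Noncentrality approximation: an MR study needs roughly the observational
#' sample size divided by the variance in the exposure explained by the
#' instrument. With `effect = NULL`, returns the smallest detectable effect
#' (per SD of exposure) at the stated alpha and power: for a continuous
#' outcome `(z_{1-alpha/2} + z_{power}) / sqrt(n * r2)`; for a binary outcome
#' the detectable log odds ratio divides additionally by
#' `sqrt(cf * (1 - cf))`. With `effect` supplied, returns the achieved power
#' for that effect instead.
#'
#' @param n outcome sample size
#' @param r2 variance of the exposure explained by the instruments
#' @param case_fraction case fraction for binary outcomes (NULL = continuous)
#' @param alpha two-sided significance level (default 0.05)
#' @param power target power for the detectable-effect mode (default 0.8)
#' @param effect effect size (beta or log OR per SD) for the achieved-power
#'   mode
#' @return list with `detectable_effect` (and `detectable_or` when binary) or
#'   `achieved_power`
#' @export
mr_power <- function(n, r2, case_fraction = NULL, alpha = 0.05, power = 0.8,
                     effect = NULL) {
  if (r2 <= 0 || r2 > 1) stop_usage("r2 must be in (0, 1]")
  scale <- n * r2 * if (!is.null(case_fraction)) {
    if (case_fraction <= 0 || case_fraction >= 1) stop_usage("case_fraction must be in (0,1)")
    case_fraction * (1 - case_fraction)
  } else 1
  if (is.null(effect)) {
    det <- (z_alpha(alpha) + stats::qnorm(power)) / sqrt(scale)
    out <- list(detectable_effect = det)
    if (!is.null(case_fraction)) out$detectable_or <- exp(det)
    out
  } else {
    list(achieved_power = stats::pnorm(abs(effect) * sqrt(scale) - z_alpha(alpha)))
  }
}

#' Full instrument diagnostics block
#'
#' Bundles the univariable diagnostics (and, for multivariable sets, the
#' conditional F-statistics) for one harmonised set.
#'
#' @param hset an `mr_hset`
#' @param rho phenotypic correlation (scalar or matrix) for the conditional F
#'   when the set has > 1 exposure
#' @param alpha,power passed to [mr_power()]
#' @return nested list, one element per exposure, plus `conditional_f`
#' @export
instrument_diagnostics <- function(hset, rho = 0.69, alpha = 0.05, power = 0.8) {
  out <- lapply(seq_along(hset$exposure_names), function(e) {
    fs <- f_statistics(hset, e)
    ve <- variance_explained(hset, e)
    pw <- if (!is.na(hset$n_outcome) && ve$r2 > 0) {
      cf <- if (!is.na(hset$case_fraction)) hset$case_fraction else NULL
      mr_power(hset$n_outcome, ve$r2, case_fraction = cf,
               alpha = alpha, power = power)
    } else NULL
    st <- if (!any(is.na(c(hset$n_exposure[e], hset$n_outcome)))) {
      steiger_test(hset, e)
    } else NULL
    list(f_mean = fs$f_mean, f_min = fs$f_min, f_max = fs$f_max, weak = fs$weak,
         r2_explained = ve$r2, i2_gx = i_squared_gx(hset, e),
         power = pw, steiger = st)
  })
  names(out) <- hset$exposure_names
  if (length(hset$exposure_names) > 1) {
    out$conditional_f <- conditional_f(hset, rho = rho)
  }
  out
}
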