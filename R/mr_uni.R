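# Univariable two-sample MR estimators and pleiotropy-robust sensitivity
# analyses. All estimators consume an `mr_hset` and return an `mr_result`.

new_mr_result <- function(method, estimate, se, pvalue = NULL, n_snps = NA_integer_,
                          ci_level = 0.95, q = NA_real_, q_df = NA_real_,
                          q_pvalue = NA_real_, intercept = NULL, extras = list()) {
  estimate <- unname(estimate)
  se <- unname(se)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  res <- c(list(method = method, estimate = estimate, se = se,
                ci_low = estimate - zq * se, ci_high = estimate + zq * se,
                pvalue = pvalue %||% pvalue_from_z(estimate, se),
                n_snps = n_snps, q = q, q_df = q_df, q_pvalue = q_pvalue,
                intercept = intercept),
           extras)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: estimate %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  if (!is.na(x$q)) cat(sprintf("  Cochran Q = %.3g on %g df (p = %.3g)\n",
                               x$q, x$q_df, x$q_pvalue))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4g (SE %.4g), p = %.3g\n",
                x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  }
  invisible(x)
}

#' Odds-ratio view of an MR result
#' @param x an `mr_result` on the log-odds scale
#' @return named numeric (or, or_ci_low, or_ci_high)
#' @export
exponentiate <- function(x) {
  c(or = exp(x$estimate), or_ci_low = exp(x$ci_low), or_ci_high = exp(x$ci_high))
}

#' Wald ratio estimate for a single SNP
#'
#' `ratio = by / bx`; the default first-order delta-method SE is
#' `|se_y / bx|` (exposure uncertainty ignored, matching the IVW weighting
#' convention); `second_order = TRUE` adds the exposure term
#' `sqrt(se_y^2/bx^2 + by^2 * se_x^2 / bx^4)`.
#'
#' @param bx,se_x SNP-exposure effect and SE
#' @param by,se_y SNP-outcome effect and SE
#' @param second_order include exposure-side uncertainty
#' @return list(estimate, se)
#' @export
wald_ratio <- function(bx, se_x, by, se_y, second_order = FALSE) {
  if (any(bx == 0)) stop_usage("undefined Wald ratio: bx = 0")
  est <- by / bx
  se <- if (second_order) {
    sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
  } else {
    abs(se_y / bx)
  }
  list(estimate = est, se = se)
}

# core weighted-through-origin fit shared by mr_ivw and mv_ivw (d = 1)
ivw_fit <- function(bx, by, se_y) {
  w <- 1 / se_y^2
  sxx <- sum(w * bx^2)
  est <- sum(w * bx * by) / sxx
  k <- length(bx)
  q <- sum(w * (by - est * bx)^2)
  se_fixed <- sqrt(1 / sxx)
  scale <- if (k > 1) max(1, sqrt(q / (k - 1))) else 1
  list(estimate = est, se_fixed = se_fixed, se = se_fixed * scale,
       q = q, q_df = k - 1, scale = scale)
}

#' Inverse-variance-weighted estimator with multiplicative random effects
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin with weights `1/se_y^2` (equivalently the
#' inverse-variance-weighted combination of per-SNP Wald ratios). The
#' multiplicative random-effects SE multiplies the fixed-effects SE by
#' `max(1, sqrt(Q/(k-1)))`; Cochran's Q and its p-value are reported. A
#' single SNP degrades to the Wald ratio.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column for multivariable sets (default first)
#' @return an `mr_result`
#' @export
mr_ivw <- function(hset, exposure = 1) {
  bx <- hset$exposure_betas[, exposure]
  by <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- length(bx)
  if (k < 1) stop_usage("no SNPs in harmonised set")
  if (k == 1) {
    wr <- wald_ratio(bx, hset$exposure_ses[, exposure], by, sy)
    return(new_mr_result("IVW (single-SNP Wald ratio)", wr$estimate, wr$se, n_snps = 1L))
  }
  fit <- ivw_fit(bx, by, sy)
  new_mr_result("IVW (multiplicative random effects)", fit$estimate, fit$se,
                n_snps = k, q = fit$q, q_df = fit$q_df,
                q_pvalue = stats::pchisq(fit$q, fit$q_df, lower.tail = FALSE),
                extras = list(se_fixed = fit$se_fixed, re_scale = fit$scale))
}

# percentile-convention weighted median with w_j/2 offset
weighted_median_interp <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(v[1])
  if (s[length(s)] <= 0.5) return(v[length(v)])
  below <- max(which(s < 0.5))
  v[below] + (v[below + 1] - v[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted median estimator
#'
#' Orders the per-SNP Wald ratios, weights them by the inverse variance of
#' the ratio (`bx^2/se_y^2`, normalised), and interpolates the estimate at
#' cumulative weight 0.5 (percentile convention with a w_j/2 offset).
#' Consistent when more than half of the weight comes from valid
#' instruments. The SE comes from a parametric bootstrap resampling
#' (bx_j, by_j) from their sampling normals.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @param n_bootstrap bootstrap replicates for the SE (default 1000)
#' @param seed RNG seed for the bootstrap (recorded in the result)
#' @return an `mr_result`
#' @export
mr_weighted_median <- function(hset, exposure = 1, n_bootstrap = 1000, seed = 1) {
  bx <- hset$exposure_betas[, exposure]
  sx <- hset$exposure_ses[, exposure]
  by <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- length(bx)
  if (k < 1) stop_usage("no SNPs in harmonised set")
  if (any(bx == 0)) stop_usage("weighted median undefined with bx = 0")
  est <- weighted_median_interp(by / bx, bx^2 / sy^2)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, by, sy)
      bxs[bxs == 0] <- .Machine$double.eps
      weighted_median_interp(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_result("Weighted median", est, se, n_snps = k,
                extras = list(n_bootstrap = n_bootstrap, seed = seed))
}

# evaluate expr with a locally-seeded RNG, restoring global state
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects with an intercept, weights `1/se_y^2`, after orienting all SNPs
#' so the SNP-exposure effect is positive. The slope is the causal estimate
#' (consistent under InSIDE even when all instruments are pleiotropic); a
#' non-zero intercept indicates directional pleiotropy. Multiplicative
#' random-effects SE scaling by `max(1, sqrt(Q/(k-2)))` as in [mr_ivw()].
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @return an `mr_result` with an `intercept` block
#' @export
mr_egger <- function(hset, exposure = 1) {
  bx <- hset$exposure_betas[, exposure]
  by <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- length(bx)
  if (k < 3) stop_usage("MR-Egger needs at least 3 SNPs")
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip
  by <- by * flip
  w <- 1 / sy^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coef
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (k - 2)))
  ses <- sqrt(diag(solve(xtwx))) * scale
  new_mr_result("MR-Egger", coef[2], ses[2], n_snps = k,
                q = q, q_df = k - 2,
                q_pvalue = stats::pchisq(q, k - 2, lower.tail = FALSE),
                intercept = list(estimate = unname(coef[1]), se = unname(ses[1]),
                                 pvalue = unname(pvalue_from_z(coef[1], ses[1]))),
                extras = list(re_scale = scale))
}

# leave-one-out IVW slopes, vectorised; bx, by length-k, w = 1/se_y^2
loo_ivw <- function(bx, by, w) {
  swxy <- sum(w * bx * by)
  swxx <- sum(w * bx^2)
  (swxy - w * bx * by) / (swxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed inverse-variance-weighted residual sum of
#' squares (each SNP's outcome effect vs the leave-one-out IVW prediction)
#' is compared with `n_sim` parametric simulations under the fitted model.
#' Outlier test: per-SNP simulated residual distribution, Bonferroni across
#' SNPs. Corrected estimate: IVW on non-outliers. Distortion test: the
#' relative change between raw and corrected estimates compared against a
#' null built by dropping random non-outlier subsets of the same size.
#'
#' @param hset an `mr_hset`
#' @param exposure exposure column
#' @param n_sim parametric simulations (default 1000)
#' @param seed RNG seed (recorded)
#' @param outlier_p familywise threshold for flagging outliers (default 0.05)
#' @param distortion run the distortion test (default TRUE)
#' @return an `mr_result` (the outlier-corrected IVW when outliers are found,
#'   else the raw IVW) with extras `global_pvalue`, `outliers`,
#'   `outlier_pvalues`, `distortion_p`, `raw` (the uncorrected `mr_result`)
#' @export
mr_presso <- function(hset, exposure = 1, n_sim = 1000, seed = 1,
                      outlier_p = 0.05, distortion = TRUE) {
  bx <- hset$exposure_betas[, exposure]
  sx <- hset$exposure_ses[, exposure]
  by <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- length(bx)
  if (k < 4) stop_usage("MR-PRESSO needs at least 4 SNPs for outlier logic")
  w <- 1 / sy^2
  beta_loo <- loo_ivw(bx, by, w)
  resid_obs <- by - beta_loo * bx
  rss_obs <- sum(w * resid_obs^2)
  obs_sq <- w * resid_obs^2

  sim <- withr_seed(seed, {
    rss_sim <- numeric(n_sim)
    exceed <- numeric(k)
    for (s in seq_len(n_sim)) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, beta_loo * bxs, sy)
      bl <- loo_ivw(bxs, bys, w)
      rs <- w * (bys - bl * bxs)^2
      rss_sim[s] <- sum(rs)
      exceed <- exceed + (rs >= obs_sq)
    }
    list(rss_sim = rss_sim, exceed = exceed)
  })
  global_p <- (1 + sum(sim$rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_pvalues <- (1 + sim$exceed) / (n_sim + 1)
  outlier_idx <- which(outlier_pvalues * k < outlier_p)
  outliers <- hset$variant_ids[outlier_idx]

  raw_fit <- ivw_fit(bx, by, sy)
  raw <- new_mr_result("MR-PRESSO (raw IVW)", raw_fit$estimate, raw_fit$se,
                       n_snps = k, q = raw_fit$q, q_df = raw_fit$q_df,
                       q_pvalue = stats::pchisq(raw_fit$q, raw_fit$q_df, lower.tail = FALSE))

  distortion_p <- NA_real_
  if (length(outlier_idx) && k - length(outlier_idx) >= 2) {
    keep <- setdiff(seq_len(k), outlier_idx)
    corr_fit <- ivw_fit(bx[keep], by[keep], sy[keep])
    if (distortion) {
      d_obs <- (corr_fit$estimate - raw_fit$estimate) / abs(raw_fit$estimate)
      d_null <- withr_seed(seed + 1, {
        vapply(seq_len(n_sim), function(s) {
          drop <- sample(keep, length(outlier_idx), replace = FALSE)
          kk <- setdiff(seq_len(k), drop)
          f <- ivw_fit(bx[kk], by[kk], sy[kk])
          (f$estimate - raw_fit$estimate) / abs(raw_fit$estimate)
        }, numeric(1))
      })
      distortion_p <- mean(abs(d_null) >= abs(d_obs))
    }
    res <- new_mr_result("MR-PRESSO (outlier-corrected)", corr_fit$estimate, corr_fit$se,
                         n_snps = length(keep), q = corr_fit$q, q_df = corr_fit$q_df,
                         q_pvalue = stats::pchisq(corr_fit$q, corr_fit$q_df, lower.tail = FALSE))
  } else {
    res <- raw
    res$method <- "MR-PRESSO (no outliers; raw IVW)"
  }
  res$global_pvalue <- global_p
  res$outliers <- outliers
  res$outlier_pvalues <- outlier_pvalues
  res$distortion_p <- distortion_p
  res$raw <- raw
  res$seed <- seed
  res$n_sim <- n_sim
  res
}

#' Run the univariable estimator suite over exposure-outcome pairs
#'
#' For each exposure and outcome: select instruments (p < `p_threshold`),
#' clump when an LD reference is given, harmonise, then run IVW, weighted
#' median, MR-Egger and MR-PRESSO. Binary outcomes are additionally reported
#' as odds ratios.
#'
#' @param exposures named list of [sumstats] objects (exposure GWASs; may
#'   include pulse pressure as a supplementary exposure)
#' @param outcomes named list of [sumstats] objects
#' @param ld an [ld_reference] or NULL (no clumping/proxies)
#' @param p_threshold instrument threshold (default 5e-8)
#' @param clump_r2 clumping threshold (default 0.001); NULL skips clumping
#' @param n_bootstrap,n_presso_sim,seed estimator settings
#' @param methods subset of c("ivw","median","egger","presso")
#' @return data.frame: one row per (exposure, outcome, method) with estimate,
#'   se, CI, p, heterogeneity, intercept and OR columns
#' @export
run_total_effects <- function(exposures, outcomes, ld = NULL, p_threshold = 5e-8,
                              clump_r2 = 0.001, n_bootstrap = 1000,
                              n_presso_sim = 1000, seed = 1,
                              methods = c("ivw", "median", "egger", "presso")) {
  rows <- list()
  hsets <- list()
  for (xn in names(exposures)) {
    cand <- select_instruments(exposures[[xn]], p_threshold)
    if (!is.null(ld) && !is.null(clump_r2)) {
      cand <- cand[cand$variant_id %in% clump(cand, ld, clump_r2), , drop = FALSE]
    }
    for (yn in names(outcomes)) {
      hs <- harmonise(exposures[[xn]], outcomes[[yn]], cand$variant_id, ld = ld)
      hsets[[paste(xn, yn, sep = ".")]] <- hs
      res <- list()
      if ("ivw" %in% methods) res$ivw <- mr_ivw(hs)
      if ("median" %in% methods)
        res$median <- mr_weighted_median(hs, n_bootstrap = n_bootstrap, seed = seed)
      if ("egger" %in% methods && n_snps(hs) >= 3) res$egger <- mr_egger(hs)
      if ("presso" %in% methods && n_snps(hs) >= 4)
        res$presso <- mr_presso(hs, n_sim = n_presso_sim, seed = seed)
      for (r in res) {
        rows[[length(rows) + 1L]] <- mr_result_row(r, xn, yn,
                                                   binary = outcomes[[yn]]$trait_type == "binary")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "hsets") <- hsets
  out
}

mr_result_row <- function(r, exposure, outcome, binary = FALSE) {
  data.frame(exposure = exposure, outcome = outcome, method = r$method,
             n_snps = r$n_snps, estimate = r$estimate, se = r$se,
             ci_low = r$ci_low, ci_high = r$ci_high, pvalue = r$pvalue,
             q = r$q %||% NA_real_, q_df = r$q_df %||% NA_real_,
             q_pvalue = r$q_pvalue %||% NA_real_,
             egger_intercept = if (!is.null(r$intercept)) r$intercept$estimate else NA_real_,
             egger_intercept_p = if (!is.null(r$intercept)) r$intercept$pvalue else NA_real_,
             presso_global_p = r$global_pvalue %||% NA_real_,
             presso_n_outliers = if (!is.null(r$outliers)) length(r$outliers) else NA_integer_,
             presso_distortion_p = r$distortion_p %||% NA_real_,
             or = if (binary) exp(r$estimate) else NA_real_,
             or_ci_low = if (binary) exp(r$ci_low) else NA_real_,
             or_ci_high = if (binary) exp(r$ci_high) else NA_real_,
             stringsAsFactors = FALSE)
}
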