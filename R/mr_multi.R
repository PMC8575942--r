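# Multivariable MR: joint direct effects, conditional instrument strength
# (Sanderson-Windmeijer) and the covariance-aware modified Cochran's Q.

# Expand a scalar/partial correlation spec into a d x d matrix
rho_matrix <- function(rho, d) {
  if (is.matrix(rho)) {
    stopifnot(nrow(rho) == d, ncol(rho) == d)
    if (max(abs(rho - t(rho))) > 1e-12 || any(abs(diag(rho) - 1) > 1e-12)) {
      stop_usage("correlation matrix must be symmetric with unit diagonal")
    }
    return(rho)
  }
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}

check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop_usage("collinearity error: exposure column(s) not of full rank: ",
               paste(bad, collapse = ", "))
  }
}

mv_wls <- function(X, y, w) {
  xtwx <- crossprod(X, w * X)
  coef <- solve(xtwx, crossprod(X, w * y))
  resid <- y - X %*% coef
  list(coef = drop(coef), resid = drop(resid), q = sum(w * resid^2),
       cov_fixed = solve(xtwx))
}

#' Multivariable inverse-variance-weighted MR
#'
#' Weighted multiple regression (no intercept) of the SNP-outcome effects on
#' all exposures' SNP effects with weights `1/se_y^2`; the coefficient on
#' each exposure is its direct effect conditional on the others.
#' Multiplicative random-effects SE scaling by `max(1, sqrt(Q/(k-d)))`.
#' With a single exposure this is numerically identical to [mr_ivw()].
#'
#' @param hset an `mr_hset` with >= 1 exposure columns; needs more SNPs than
#'   exposures and a full-rank exposure matrix
#' @return list of `mr_result`, one per exposure, plus attributes `q`,
#'   `q_df`, `q_pvalue`
#' @export
mv_ivw <- function(hset) {
  X <- hset$exposure_betas
  y <- hset$outcome_beta
  w <- 1 / hset$outcome_se^2
  k <- nrow(X)
  d <- ncol(X)
  if (k <= d) stop_usage("need more SNPs than exposures")
  check_rank(X)
  fit <- mv_wls(X, y, w)
  scale <- max(1, sqrt(fit$q / (k - d)))
  ses <- sqrt(diag(fit$cov_fixed)) * scale
  out <- lapply(seq_len(d), function(e) {
    r <- new_mr_result("Multivariable IVW", fit$coef[e], ses[e], n_snps = k,
                       q = fit$q, q_df = k - d,
                       q_pvalue = stats::pchisq(fit$q, k - d, lower.tail = FALSE),
                       extras = list(re_scale = scale))
    r
  })
  names(out) <- hset$exposure_names
  attr(out, "q") <- fit$q
  attr(out, "q_df") <- k - d
  attr(out, "q_pvalue") <- stats::pchisq(fit$q, k - d, lower.tail = FALSE)
  out
}

# Q-statistic for exposure e regressed on the others, minimised over delta;
# weights propagate the cross-exposure covariance of estimated SNP effects,
# cov(bX_e, bX_o) = rho_eo * se_e * se_o.
sw_q_exposure <- function(hset, e, rho_m) {
  bx <- hset$exposure_betas
  sx <- hset$exposure_ses
  others <- setdiff(seq_len(ncol(bx)), e)
  target <- bx[, e]
  if (!length(others)) {
    return(list(q = sum((target / sx[, e])^2), delta = numeric(0)))
  }
  Z <- bx[, others, drop = FALSE]
  qfun <- function(delta) {
    pred <- drop(Z %*% delta)
    v <- sx[, e]^2
    for (i in seq_along(others)) {
      o <- others[i]
      v <- v + delta[i]^2 * sx[, o]^2 - 2 * delta[i] * rho_m[e, o] * sx[, e] * sx[, o]
      if (i < length(others)) for (j in seq(i + 1, length(others))) {
        o2 <- others[j]
        v <- v + 2 * delta[i] * delta[j] * rho_m[o, o2] * sx[, o] * sx[, o2]
      }
    }
    v <- pmax(v, 1e-30)
    sum((target - pred)^2 / v)
  }
  start <- stats::coef(stats::lm.fit(Z, target))
  if (length(start) == 1) {
    opt <- stats::optimize(function(dd) qfun(dd), interval = start + c(-10, 10) * max(1, abs(start)))
    list(q = opt$objective, delta = opt$minimum)
  } else {
    opt <- stats::optim(start, qfun, method = "BFGS")
    list(q = opt$value, delta = opt$par)
  }
}

#' Sanderson-Windmeijer conditional F-statistics
#'
#' Conditional instrument strength for each exposure given the others:
#' the exposure's SNP effects are regressed on the other exposures' SNP
#' effects by minimising a Q-statistic whose per-SNP variance propagates the
#' cross-exposure covariance of the estimated effects
#' (`rho * se_e * se_o`, with `rho` the phenotypic correlation between the
#' exposure GWAS traits); the conditional F is the minimised Q divided by
#' `k - d + 1`, which reduces to the mean univariable F for a single
#' exposure. Values below 10 flag conditionally weak instruments.
#'
#' @param hset an `mr_hset`
#' @param rho phenotypic correlation between exposures: scalar (all pairs) or
#'   full matrix; default 0.69 (systolic/diastolic blood pressure)
#' @return named numeric vector, one conditional F per exposure
#' @export
conditional_f <- function(hset, rho = 0.69) {
  d <- ncol(hset$exposure_betas)
  k <- nrow(hset$exposure_betas)
  rho_m <- rho_matrix(rho, d)
  out <- vapply(seq_len(d), function(e) {
    sw_q_exposure(hset, e, rho_m)$q / (k - d + 1)
  }, numeric(1))
  names(out) <- hset$exposure_names
  out
}

#' Modified Cochran's Q for multivariable MR
#'
#' Instrument-pleiotropy heterogeneity statistic whose per-SNP variance
#' propagates both the outcome variance and the covariance of the estimated
#' exposure effects:
#' `s_j^2 = se_yj^2 + sum_ee' theta_e theta_e' cov(bX_je, bX_je')` with
#' `cov(bX_je, bX_je') = rho_ee' * se_je * se_je'`. The coefficients are
#' re-estimated by iteratively reweighted least squares under these
#' weights. df = k - d; p-value from the chi-square distribution.
#'
#' @param hset an `mr_hset`
#' @param rho phenotypic correlation (scalar or matrix), default 0.69
#' @param max_iter,tol IRLS controls
#' @return list(q, df, pvalue, theta)
#' @export
modified_q <- function(hset, rho = 0.69, max_iter = 100, tol = 1e-10) {
  X <- hset$exposure_betas
  SX <- hset$exposure_ses
  y <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- nrow(X)
  d <- ncol(X)
  rho_m <- rho_matrix(rho, d)
  theta <- mv_wls(X, y, 1 / sy^2)$coef
  s2 <- function(theta) {
    v <- sy^2
    for (e in seq_len(d)) for (f in seq_len(d)) {
      v <- v + theta[e] * theta[f] * rho_m[e, f] * SX[, e] * SX[, f]
    }
    pmax(v, 1e-30)
  }
  for (it in seq_len(max_iter)) {
    w <- 1 / s2(theta)
    new_theta <- mv_wls(X, y, w)$coef
    if (max(abs(new_theta - theta)) < tol) {
      theta <- new_theta
      break
    }
    theta <- new_theta
  }
  q <- sum((y - drop(X %*% theta))^2 / s2(theta))
  list(q = q, df = k - d, pvalue = stats::pchisq(q, k - d, lower.tail = FALSE),
       theta = stats::setNames(theta, hset$exposure_names))
}

#' Multivariable MR-Egger
#'
#' [mv_ivw()] plus an intercept column, after orienting every SNP so the
#' reference exposure's SNP effect is positive; a non-zero intercept flags
#' directional pleiotropy in the multivariable model.
#'
#' @param hset an `mr_hset`
#' @param reference_exposure exposure whose effects set the orientation
#'   (default the first)
#' @return list of per-exposure `mr_result` (each carrying the shared
#'   `intercept` block)
#' @export
mv_egger <- function(hset, reference_exposure = 1) {
  X0 <- hset$exposure_betas
  k <- nrow(X0)
  d <- ncol(X0)
  if (k <= d + 1) stop_usage("need more SNPs than exposures + 1")
  flip <- ifelse(X0[, reference_exposure] < 0, -1, 1)
  X <- X0 * flip
  y <- hset$outcome_beta * flip
  w <- 1 / hset$outcome_se^2
  Xi <- cbind(`(intercept)` = 1, X)
  check_rank(Xi)
  fit <- mv_wls(Xi, y, w)
  df <- k - d - 1
  scale <- max(1, sqrt(fit$q / df))
  ses <- sqrt(diag(fit$cov_fixed)) * scale
  icpt <- list(estimate = unname(fit$coef[1]), se = unname(ses[1]),
               pvalue = unname(pvalue_from_z(fit$coef[1], ses[1])))
  out <- lapply(seq_len(d), function(e) {
    new_mr_result("Multivariable MR-Egger", fit$coef[e + 1], ses[e + 1], n_snps = k,
                  q = fit$q, q_df = df,
                  q_pvalue = stats::pchisq(fit$q, df, lower.tail = FALSE),
                  intercept = icpt, extras = list(re_scale = scale))
  })
  names(out) <- hset$exposure_names
  out
}

# weighted L1 (median) regression through the origin via IRLS
l1_wls <- function(X, y, w, max_iter = 200, tol = 1e-10) {
  beta <- mv_wls(X, y, w)$coef
  for (it in seq_len(max_iter)) {
    r <- abs(y - drop(X %*% beta))
    wi <- w / pmax(r, 1e-8)
    new_beta <- mv_wls(X, y, wi)$coef
    if (max(abs(new_beta - beta)) < tol) return(new_beta)
    beta <- new_beta
  }
  beta
}

#' Multivariable weighted median
#'
#' Inverse-variance-weighted median (L1) regression of the SNP-outcome
#' effects on the exposures' SNP effects through the origin, robust to up to
#' half the weight coming from pleiotropic SNPs; SEs from a parametric
#' bootstrap resampling the summary statistics from their sampling normals.
#'
#' @param hset an `mr_hset` with at least `d + 2` SNPs
#' @param n_bootstrap bootstrap replicates (default 1000)
#' @param seed RNG seed (recorded)
#' @return list of per-exposure `mr_result`
#' @export
mv_median <- function(hset, n_bootstrap = 1000, seed = 1) {
  X <- hset$exposure_betas
  SX <- hset$exposure_ses
  y <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- nrow(X)
  d <- ncol(X)
  if (k < d + 2) stop_usage("need at least ", d + 2, " SNPs for the multivariable median")
  check_rank(X)
  w <- 1 / sy^2
  est <- l1_wls(X, y, w)
  boot <- withr_seed(seed, {
    t(vapply(seq_len(n_bootstrap), function(b) {
      Xs <- X + matrix(stats::rnorm(k * d), k, d) * SX
      ys <- stats::rnorm(k, y, sy)
      l1_wls(Xs, ys, w)
    }, numeric(d)))
  })
  ses <- apply(boot, 2, stats::sd)
  out <- lapply(seq_len(d), function(e) {
    new_mr_result("Multivariable weighted median", est[e], ses[e], n_snps = k,
                  extras = list(n_bootstrap = n_bootstrap, seed = seed))
  })
  names(out) <- hset$exposure_names
  out
}

# leave-one-out mv fits for each SNP, returning k x d coefficients
loo_mv_coef <- function(X, y, w) {
  xtwx <- crossprod(X, w * X)
  xtwy <- crossprod(X, w * y)
  t(vapply(seq_len(nrow(X)), function(j) {
    xj <- X[j, ]
    drop(solve(xtwx - w[j] * tcrossprod(xj), xtwy - w[j] * xj * y[j]))
  }, numeric(ncol(X))))
}

#' Multivariable MR-PRESSO
#'
#' The global/outlier/distortion logic of [mr_presso()] with residuals taken
#' from leave-one-out multivariable IVW fits.
#'
#' @param hset an `mr_hset`
#' @param n_sim parametric simulations (default 1000)
#' @param seed RNG seed (recorded)
#' @param outlier_p familywise outlier threshold (default 0.05)
#' @return list of per-exposure `mr_result` (outlier-corrected when outliers
#'   are found) with attributes `global_pvalue`, `outliers`, `distortion_p`
#' @export
mv_presso <- function(hset, n_sim = 1000, seed = 1, outlier_p = 0.05) {
  X <- hset$exposure_betas
  SX <- hset$exposure_ses
  y <- hset$outcome_beta
  sy <- hset$outcome_se
  k <- nrow(X)
  d <- ncol(X)
  if (k < d + 3) stop_usage("MR-PRESSO needs at least ", d + 3, " SNPs")
  w <- 1 / sy^2
  coef_loo <- loo_mv_coef(X, y, w)
  pred <- rowSums(X * coef_loo)
  resid_obs <- y - pred
  obs_sq <- w * resid_obs^2
  rss_obs <- sum(obs_sq)

  sim <- withr_seed(seed, {
    rss_sim <- numeric(n_sim)
    exceed <- numeric(k)
    for (s in seq_len(n_sim)) {
      Xs <- X + matrix(stats::rnorm(k * d), k, d) * SX
      ys <- stats::rnorm(k, rowSums(Xs * coef_loo), sy)
      cl <- loo_mv_coef(Xs, ys, w)
      rs <- w * (ys - rowSums(Xs * cl))^2
      rss_sim[s] <- sum(rs)
      exceed <- exceed + (rs >= obs_sq)
    }
    list(rss_sim = rss_sim, exceed = exceed)
  })
  global_p <- (1 + sum(sim$rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_pvalues <- (1 + sim$exceed) / (n_sim + 1)
  outlier_idx <- which(outlier_pvalues * k < outlier_p)
  outliers <- hset$variant_ids[outlier_idx]

  target <- hset
  method <- "Multivariable MR-PRESSO (no outliers; raw IVW)"
  if (length(outlier_idx) && k - length(outlier_idx) > d) {
    target <- subset_hset(hset, setdiff(seq_len(k), outlier_idx))
    method <- "Multivariable MR-PRESSO (outlier-corrected)"
  }
  raw <- mv_ivw(hset)
  res <- mv_ivw(target)
  distortion_p <- NA_real_
  if (length(outlier_idx) && k - length(outlier_idx) > d) {
    keep <- setdiff(seq_len(k), outlier_idx)
    d_obs <- vapply(seq_len(d), function(e)
      (res[[e]]$estimate - raw[[e]]$estimate) / abs(raw[[e]]$estimate), numeric(1))
    d_null <- withr_seed(seed + 1, {
      t(vapply(seq_len(min(n_sim, 500)), function(s) {
        drop_idx <- sample(keep, length(outlier_idx), replace = FALSE)
        kk <- setdiff(seq_len(k), drop_idx)
        fit <- mv_wls(X[kk, , drop = FALSE], y[kk], w[kk])
        (fit$coef - vapply(raw, `[[`, numeric(1), "estimate")) /
          abs(vapply(raw, `[[`, numeric(1), "estimate"))
      }, numeric(d)))
    })
    distortion_p <- mean(apply(abs(d_null) >= matrix(abs(d_obs), nrow(d_null), d, byrow = TRUE),
                               1, any))
  }
  for (e in seq_len(d)) {
    res[[e]]$method <- method
    res[[e]]$global_pvalue <- global_p
    res[[e]]$outliers <- outliers
    res[[e]]$distortion_p <- distortion_p
    res[[e]]$raw <- raw[[e]]
    res[[e]]$seed <- seed
  }
  attr(res, "global_pvalue") <- global_p
  attr(res, "outliers") <- outliers
  attr(res, "distortion_p") <- distortion_p
  res
}

#' Run the multivariable (direct-effects) suite over outcomes
#'
#' Per-exposure instruments are selected at `p_threshold`, merged with the
#' lower p retained when a SNP instruments several exposures, clumped, then
#' harmonised jointly with all exposures (plus optional covariate-exposure
#' tables, e.g. education, smoking, BMI). For each outcome the suite runs
#' multivariable IVW, MR-Egger, weighted median and MR-PRESSO plus the
#' conditional F-statistics and modified Q.
#'
#' @inheritParams run_total_effects
#' @param covariates optional named list of [sumstats] tables appended as
#'   additional exposure columns (their instruments are not added)
#' @param rho phenotypic correlation between exposures (scalar or matrix)
#' @return data.frame of per-(exposure, outcome, method) rows; attribute
#'   `diagnostics` holds per-outcome conditional F and modified Q
#' @export
run_direct_effects <- function(exposures, outcomes, ld = NULL, covariates = NULL,
                               p_threshold = 5e-8, clump_r2 = 0.001, rho = 0.69,
                               n_bootstrap = 1000, n_presso_sim = 1000, seed = 1,
                               methods = c("ivw", "egger", "median", "presso")) {
  cand <- merge_exposure_instruments(
    lapply(exposures, function(e) select_instruments(e, p_threshold)))
  if (!is.null(ld) && !is.null(clump_r2)) {
    cand <- cand[cand$variant_id %in% clump(cand, ld, clump_r2), , drop = FALSE]
  }
  all_exp <- c(exposures, covariates)
  d_main <- length(exposures)
  rows <- list()
  diag_blocks <- list()
  for (yn in names(outcomes)) {
    hs <- harmonise(all_exp, outcomes[[yn]], cand$variant_id, ld = ld)
    binary <- outcomes[[yn]]$trait_type == "binary"
    rho_full <- if (is.null(covariates)) rho else {
      # covariate columns assumed uncorrelated with the exposures' errors
      m <- diag(length(all_exp))
      m[seq_len(d_main), seq_len(d_main)] <- rho_matrix(rho, d_main)
      m
    }
    res <- list()
    if ("ivw" %in% methods) res$ivw <- mv_ivw(hs)
    if ("egger" %in% methods) res$egger <- mv_egger(hs)
    if ("median" %in% methods)
      res$median <- mv_median(hs, n_bootstrap = n_bootstrap, seed = seed)
    if ("presso" %in% methods && n_snps(hs) >= ncol(hs$exposure_betas) + 3)
      res$presso <- mv_presso(hs, n_sim = n_presso_sim, seed = seed)
    for (r in res) for (e in seq_along(r)) {
      rows[[length(rows) + 1L]] <- mr_result_row(r[[e]], names(r)[e], yn, binary = binary)
    }
    diag_blocks[[yn]] <- list(
      conditional_f = conditional_f(hs, rho = rho_full),
      modified_q = modified_q(hs, rho = rho_full),
      n_snps = n_snps(hs),
      exclusions = hs$exclusion_log)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diag_blocks
  out
}
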