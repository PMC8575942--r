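# Synthetic two-sample GWAS summary statistics with recorded ground truth.
# Emulates the statistical structure of large blood-pressure and
# cardiovascular GWAS: a few hundred genome-wide-significant instruments,
# two highly correlated exposures, binary outcomes with realistic case
# fractions, a standardised lifespan outcome, optional pleiotropy, LD
# blocks, palindromes, and outcome-missing variants with proxies.

.default_outcomes <- function() {
  list(
    cvd = list(type = "binary", n = 420531, case_fraction = 58863 / 420531,
               theta = c(log(1.83), log(1.18))),
    cad = list(type = "binary", n = 419724, case_fraction = 37672 / 419724,
               theta = c(log(1.80), log(1.24))),
    istroke = list(type = "binary", n = 418936, case_fraction = 11303 / 418936,
                   theta = c(log(1.80), log(1.12))),
    hf = list(type = "binary", n = 419557, case_fraction = 7451 / 419557,
              theta = c(log(1.80), log(1.05))),
    af = list(type = "binary", n = 1030836, case_fraction = 60620 / 1030836,
              theta = c(log(1.50), log(1.08))),
    lifespan = list(type = "continuous", n = 389166, theta = c(-0.13, -0.07)))
}

#' Generating parameters for a synthetic two-sample MR study
#'
#' The defaults emulate the blood-pressure study design: two exposures
#' (systolic/diastolic, phenotypic SDs 20.1 and 11.2 mmHg, SNP effects on
#' the SD scale) instrumented by a few hundred genome-wide-significant
#' variants explaining ~2.6/3.0% of variance in a GWAS of n = 757,601;
#' cross-exposure correlation 0.7 of true SNP effects and 0.69 of their
#' estimation errors (shared-sample phenotypic correlation); binary
#' outcomes with UK-Biobank-scale case fractions and a z-scored parental
#' lifespan outcome; direct effects on the log-odds / z-score scale.
#'
#' @param n_snps candidate instruments (LD-block leads), default 400
#' @param exposures exposure names
#' @param exposure_sds phenotypic SDs in native units
#' @param r2_target per-exposure total variance explained by the candidate
#'   set (fractions)
#' @param n_exposure exposure GWAS sample size
#' @param genetic_correlation correlation of true SNP effects across
#'   exposures
#' @param phenotypic_correlation correlation of estimation errors across
#'   exposures (shared-sample GWAS)
#' @param outcomes named list: each element list(type, n, case_fraction?,
#'   theta = per-exposure direct effects); default six
#'   cardiovascular/lifespan outcomes
#' @param pleiotropy list(mode = "none"|"balanced"|"directional"|
#'   "inside-violating", mean, sd): a direct SNP-outcome effect added to
#'   every outcome
#' @param overlap_fraction fraction of outcome samples shared with the
#'   exposure GWAS (induces correlated estimation noise)
#' @param ld_blocks list(block_size, within_r2): extra tag SNPs per lead for
#'   clumping to remove
#' @param palindrome_rate fraction of A/T-or-C/G variants
#' @param missing_outcome_rate fraction of leads absent from outcome tables
#' @param proxy_rate fraction of missing leads that get an r2 = 0.9 proxy
#' @param annotation_rate fraction of variants flagged as strongly
#'   BMI-associated in the annotation table
#' @param seed RNG seed (the generator is deterministic given the truth)
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(n_snps = 400,
                            exposures = c("sbp", "dbp"),
                            exposure_sds = c(20.1, 11.2),
                            r2_target = c(0.0259, 0.0296),
                            n_exposure = 757601,
                            genetic_correlation = 0.7,
                            phenotypic_correlation = 0.69,
                            outcomes = .default_outcomes(),
                            pleiotropy = list(mode = "none", mean = 0, sd = 0),
                            overlap_fraction = 0,
                            ld_blocks = list(block_size = 1, within_r2 = 0.5),
                            palindrome_rate = 0.05,
                            missing_outcome_rate = 0.037,
                            proxy_rate = 0.5,
                            annotation_rate = 0.05,
                            seed = 1) {
  stopifnot(n_snps > 0, length(exposures) == length(r2_target),
            abs(genetic_correlation) <= 1, abs(phenotypic_correlation) <= 1)
  if (any(r2_target <= 0) || any(r2_target >= 1)) {
    stop_usage("infeasible r2 target: each must be in (0, 1)")
  }
  for (o in outcomes) {
    if (o$type == "binary" && (o$case_fraction <= 0 || o$case_fraction >= 1)) {
      stop_usage("case_fraction must be in (0, 1)")
    }
    if (length(o$theta) != length(exposures)) {
      stop_usage("each outcome needs one theta per exposure")
    }
  }
  structure(list(n_snps = n_snps, exposures = exposures,
                 exposure_sds = exposure_sds, r2_target = r2_target,
                 n_exposure = n_exposure,
                 genetic_correlation = genetic_correlation,
                 phenotypic_correlation = phenotypic_correlation,
                 outcomes = outcomes, pleiotropy = pleiotropy,
                 overlap_fraction = overlap_fraction, ld_blocks = ld_blocks,
                 palindrome_rate = palindrome_rate,
                 missing_outcome_rate = missing_outcome_rate,
                 proxy_rate = proxy_rate, annotation_rate = annotation_rate,
                 seed = seed),
            class = "synthetic_truth")
}

corr2 <- function(rho, d = 2) {
  m <- matrix(rho, d, d)
  diag(m) <- 1
  m
}

rmvn_chol <- function(n, R) {
  matrix(stats::rnorm(n * nrow(R)), n) %*% chol(R)
}

.NONPAL_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Generate a full synthetic study
#'
#' Draws allele frequencies Uniform(0.05, 0.95), true per-SNP exposure
#' effects (bivariate normal across exposures at the genetic correlation,
#' rescaled so the candidate set explains exactly the target variance),
#' outcome effects as the causal combination plus any pleiotropy term, and
#' estimated effects as truth plus sampling noise with standard errors
#' derived from the sample sizes and allele frequencies
#' (`se = 1/sqrt(2p(1-p) n)` for standardised continuous traits,
#' `se = 1/sqrt(2p(1-p) n cf (1-cf))` on the log-odds scale for binary
#' ones). Estimation errors are correlated across exposures at the
#' phenotypic correlation and, when `overlap_fraction > 0`, between
#' exposures and outcome at
#' `overlap_fraction * sqrt(phenotypic_correlation)`. LD blocks, palindromic
#' variants, outcome-missing variants and proxies are planted at the
#' configured rates.
#'
#' @param truth a [synthetic_truth]
#' @return list: `exposures` (named list of [sumstats]), `outcomes` (named
#'   list of [sumstats]), `ld` ([ld_reference]), `annotations` (data.frame),
#'   `truth` (the input plus a per-variant `variants` truth table)
#' @export
generate_study <- function(truth) {
  withr_seed(truth$seed, {
    d <- length(truth$exposures)
    n_lead <- truth$n_snps
    bs <- max(1, truth$ld_blocks$block_size)

    eaf <- stats::runif(n_lead, 0.05, 0.95)
    pal <- stats::runif(n_lead) < truth$palindrome_rate
    alleles <- t(vapply(seq_len(n_lead), function(i) {
      if (pal[i]) {
        if (stats::runif(1) < 0.5) c("A", "T") else c("C", "G")
      } else {
        .NONPAL_PAIRS[[sample.int(length(.NONPAL_PAIRS), 1)]]
      }
    }, character(2)))

    # true effects on the exposure SD scale, rescaled to hit r2 targets
    b_true <- rmvn_chol(n_lead, corr2(truth$genetic_correlation, d))
    hw <- 2 * eaf * (1 - eaf)
    for (e in seq_len(d)) {
      b_true[, e] <- b_true[, e] * sqrt(truth$r2_target[e] / sum(hw * b_true[, e]^2))
    }

    ids <- sprintf("rs%06d", seq_len(n_lead))
    variants <- data.frame(variant_id = ids, eaf = eaf,
                           effect_allele = alleles[, 1], other_allele = alleles[, 2],
                           block = seq_len(n_lead), is_lead = TRUE,
                           stringsAsFactors = FALSE)
    b_all <- b_true

    # tag SNPs within LD blocks (for clumping to remove)
    if (bs > 1) {
      for (t in seq_len(bs - 1)) {
        tag_ids <- sprintf("rs%06d_t%d", seq_len(n_lead), t)
        tag_b <- b_true * sqrt(truth$ld_blocks$within_r2)
        variants <- rbind(variants,
                          data.frame(variant_id = tag_ids, eaf = eaf,
                                     effect_allele = "A", other_allele = "G",
                                     block = seq_len(n_lead), is_lead = FALSE,
                                     stringsAsFactors = FALSE))
        b_all <- rbind(b_all, tag_b)
      }
    }

    # outcome-missing leads and their proxies
    n_missing <- round(truth$missing_outcome_rate * n_lead)
    missing_idx <- if (n_missing > 0) sort(sample.int(n_lead, n_missing)) else integer(0)
    proxy_rows <- NULL
    if (length(missing_idx)) {
      has_proxy <- missing_idx[seq_len(round(truth$proxy_rate * length(missing_idx)))]
      if (length(has_proxy)) {
        proxy_ids <- sprintf("rs%06d_p", has_proxy)
        proxy_b <- b_true[has_proxy, , drop = FALSE] * sqrt(0.9)
        variants <- rbind(variants,
                          data.frame(variant_id = proxy_ids, eaf = eaf[has_proxy],
                                     effect_allele = alleles[has_proxy, 1],
                                     other_allele = alleles[has_proxy, 2],
                                     block = has_proxy, is_lead = FALSE,
                                     stringsAsFactors = FALSE))
        b_all <- rbind(b_all, proxy_b)
        proxy_rows <- data.frame(missing_id = ids[has_proxy], proxy_id = proxy_ids,
                                 r2 = 0.9, stringsAsFactors = FALSE)
      }
    }
    missing_ids <- ids[missing_idx]

    m <- nrow(variants)
    hw_all <- 2 * variants$eaf * (1 - variants$eaf)
    se_x <- sqrt(1 / (hw_all * truth$n_exposure))
    se_x <- matrix(se_x, m, d)

    # estimation noise, correlated across exposures (shared sample)
    eps_x <- rmvn_chol(m, corr2(truth$phenotypic_correlation, d)) * se_x
    bhat_x <- b_all + eps_x

    # directional pleiotropy is defined relative to the exposure-raising
    # allele of the first exposure (allele labels are arbitrary, so a mean
    # shift in the unoriented frame would wash out on re-orientation)
    pl <- truth$pleiotropy
    orient <- ifelse(b_all[, 1] < 0, -1, 1)
    pleio <- switch(pl$mode,
      none = rep(0, m),
      balanced = stats::rnorm(m, 0, pl$sd),
      directional = orient * stats::rnorm(m, pl$mean, pl$sd),
      `inside-violating` = orient * pl$mean + pl$sd * b_all[, 1] / stats::sd(b_all[, 1]),
      stop_usage("unknown pleiotropy mode: ", pl$mode))

    exposure_tables <- lapply(seq_len(d), function(e) {
      sumstats(data.frame(variant_id = variants$variant_id,
                          effect_allele = variants$effect_allele,
                          other_allele = variants$other_allele,
                          eaf = variants$eaf,
                          beta = bhat_x[, e], se = se_x[, e],
                          n = truth$n_exposure, stringsAsFactors = FALSE),
               trait_name = truth$exposures[e], trait_type = "continuous",
               trait_sd = truth$exposure_sds[e])
    })
    names(exposure_tables) <- truth$exposures

    c_ov <- truth$overlap_fraction * sqrt(abs(truth$phenotypic_correlation))
    outcome_tables <- lapply(truth$outcomes, function(o) {
      alpha <- drop(b_all %*% o$theta) + pleio
      se_y <- if (o$type == "binary") {
        sqrt(1 / (hw_all * o$n * o$case_fraction * (1 - o$case_fraction)))
      } else {
        sqrt(1 / (hw_all * o$n))
      }
      eps_y <- if (c_ov > 0) {
        # share of outcome noise correlated with the first exposure's noise
        z <- stats::rnorm(m)
        (c_ov * eps_x[, 1] / se_x[, 1] + sqrt(1 - c_ov^2) * z) * se_y
      } else {
        stats::rnorm(m, 0, se_y)
      }
      keep <- !(variants$variant_id %in% missing_ids)
      df <- data.frame(variant_id = variants$variant_id,
                       effect_allele = variants$effect_allele,
                       other_allele = variants$other_allele,
                       eaf = variants$eaf,
                       beta = alpha + eps_y, se = se_y, n = o$n,
                       stringsAsFactors = FALSE)[keep, ]
      if (o$type == "binary") df$n_cases <- round(o$n * o$case_fraction)
      sumstats(df, trait_name = "outcome", trait_type = o$type)
    })
    for (yn in names(outcome_tables)) outcome_tables[[yn]]$trait_name <- yn

    # LD reference: within-block pairs
    ld_pairs <- NULL
    blocks <- split(variants$variant_id, variants$block)
    multi <- blocks[lengths(blocks) > 1]
    if (length(multi)) {
      ld_pairs <- do.call(rbind, lapply(multi, function(bl) {
        cmb <- utils::combn(sort(bl), 2)
        data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                   r2 = truth$ld_blocks$within_r2, stringsAsFactors = FALSE)
      }))
      if (!is.null(proxy_rows)) {
        key <- paste(pmin(proxy_rows$missing_id, proxy_rows$proxy_id),
                     pmax(proxy_rows$missing_id, proxy_rows$proxy_id))
        ldk <- paste(ld_pairs$id_a, ld_pairs$id_b)
        ld_pairs$r2[ldk %in% key] <- 0.9
      }
    }

    n_ann <- round(truth$annotation_rate * m)
    annotations <- if (n_ann > 0) {
      flagged <- sample(variants$variant_id, n_ann)
      rbind(data.frame(variant_id = flagged, trait = "bmi",
                       pvalue = 10^stats::runif(n_ann, -20, -8.5),
                       stringsAsFactors = FALSE),
            data.frame(variant_id = sample(variants$variant_id, n_ann),
                       trait = "bmi", pvalue = 10^stats::runif(n_ann, -6, -2),
                       stringsAsFactors = FALSE))
    } else {
      data.frame(variant_id = character(0), trait = character(0), pvalue = numeric(0))
    }

    truth_tab <- variants
    colnames(b_all) <- paste0("b_", truth$exposures)
    truth_tab <- cbind(truth_tab, b_all, pleiotropy = pleio)
    truth_tab$missing_in_outcome <- truth_tab$variant_id %in% missing_ids

    rec <- truth
    rec$variants <- truth_tab
    list(exposures = exposure_tables, outcomes = outcome_tables,
         ld = ld_reference(ld_pairs, proxy_rows), annotations = annotations,
         truth = rec)
  })
}

#' Generate correlated CVD-subtype outcome tables for composite construction
#'
#' Each subtype shares the latent per-SNP outcome effect implied by the
#' truth's first outcome (so the subtypes are aetiologically correlated), has
#' its own sample size and case count, and the estimation noise is
#' correlated across subtypes at `noise_corr` (overlapping controls). The
#' tables are intended to feed [meta_analyse_fixed_effects()] followed by
#' [inflate_standard_errors()]: with `noise_corr > 0` the naive pooled SE is
#' anti-conservative.
#'
#' @param truth a [synthetic_truth]
#' @param subtype_specs named list: each list(n, case_fraction); defaults are
#'   UK-Biobank-scale coronary artery disease, ischaemic stroke, heart
#'   failure and intracranial haemorrhage
#' @param noise_corr pairwise correlation of subtype estimation noise
#' @param noise_seed seed for the subtype noise (default derived from the
#'   truth seed; vary it with the truth fixed to obtain replicate draws of
#'   the same study)
#' @return named list of [sumstats] tables (one per subtype)
#' @export
generate_composite_subtypes <- function(truth,
                                        subtype_specs = list(
                                          cad = list(n = 419724, case_fraction = 37672 / 419724),
                                          istroke = list(n = 418936, case_fraction = 11303 / 418936),
                                          hf = list(n = 419557, case_fraction = 7451 / 419557),
                                          ihaem = list(n = 410070, case_fraction = 2437 / 410070)),
                                        noise_corr = 0, noise_seed = truth$seed + 1000L) {
  study <- generate_study(truth)
  tv <- study$truth$variants
  b_all <- as.matrix(tv[, paste0("b_", truth$exposures)])
  theta <- truth$outcomes[[1]]$theta
  alpha <- drop(b_all %*% theta) + tv$pleiotropy
  m <- nrow(tv)
  s <- length(subtype_specs)
  R <- matrix(noise_corr, s, s)
  diag(R) <- 1
  withr_seed(noise_seed, {
    z <- rmvn_chol(m, R)
    out <- lapply(seq_len(s), function(i) {
      sp <- subtype_specs[[i]]
      hw <- 2 * tv$eaf * (1 - tv$eaf)
      se_y <- sqrt(1 / (hw * sp$n * sp$case_fraction * (1 - sp$case_fraction)))
      sumstats(data.frame(variant_id = tv$variant_id,
                          effect_allele = tv$effect_allele,
                          other_allele = tv$other_allele,
                          eaf = tv$eaf,
                          beta = alpha + z[, i] * se_y, se = se_y,
                          n = sp$n, n_cases = round(sp$n * sp$case_fraction),
                          stringsAsFactors = FALSE),
               trait_name = names(subtype_specs)[i], trait_type = "binary")
    })
    names(out) <- names(subtype_specs)
    out
  })
}
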