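# Fixtures built in code: small summary-stats tables, a frozen 5-SNP
# harmonised set, and compact synthetic-truth configurations.

make_ss <- function(df, trait_name = "trait", trait_type = "continuous",
                    trait_sd = NA_real_) {
  sumstats(df, trait_name = trait_name, trait_type = trait_type, trait_sd = trait_sd)
}

# deterministic 3-variant exposure-style table
tiny_table <- function(trait_name = "bp", trait_sd = 20.1) {
  make_ss(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "T"),
    other_allele = c("G", "T", "C"),
    eaf = c(0.30, 0.60, 0.10),
    beta = c(0.020, -0.015, 0.030),
    se = c(0.003, 0.003, 0.004),
    n = 757601), trait_name = trait_name, trait_sd = trait_sd)
}

# frozen 5-SNP fixture used for the closed-form estimator oracles
fixture_hset5 <- function() {
  harmonised_set(
    exposure_betas = c(0.021, 0.034, 0.048, 0.062, 0.079),
    exposure_ses = c(0.004, 0.005, 0.006, 0.005, 0.007),
    outcome_beta = c(0.012, 0.020, 0.019, 0.040, 0.037),
    outcome_se = c(0.006, 0.007, 0.005, 0.009, 0.008),
    eaf = c(0.2, 0.35, 0.5, 0.65, 0.8),
    exposure_names = "bp", outcome_name = "cvd", outcome_type = "binary",
    n_exposure = 757601, n_outcome = 420531, case_fraction = 0.14)
}

# two-exposure hset with known structure, built from raw normals
sim_hset2 <- function(k = 100, theta = c(0.6, 0.0), rho_g = 0.7, rho_err = 0.69,
                      se_x = 0.003, se_y = 0.01, pleio = 0, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(2 * k), k)
  b2r <- rho_g * z[, 1] + sqrt(1 - rho_g^2) * z[, 2]
  bx_true <- cbind(0.02 * z[, 1], 0.02 * b2r)
  e <- matrix(rnorm(2 * k), k)
  err <- cbind(e[, 1], rho_err * e[, 1] + sqrt(1 - rho_err^2) * e[, 2]) * se_x
  bx <- bx_true + err
  by <- drop(bx_true %*% theta) + pleio + rnorm(k, 0, se_y)
  harmonised_set(bx, matrix(se_x, k, 2), by, rep(se_y, k),
                 eaf = runif(k, 0.1, 0.9),
                 exposure_names = c("e1", "e2"),
                 n_exposure = 757601, n_outcome = 420531)
}

# compact study conditions for pipeline-level tests
quick_truth <- function(n_snps = 80, seed = 1,
                        outcomes = list(
                          cvd = list(type = "binary", n = 420531, case_fraction = 0.14,
                                     theta = c(log(1.83), log(1.18))),
                          lifespan = list(type = "continuous", n = 389166,
                                          theta = c(-0.13, -0.07))),
                        ...) {
  synthetic_truth(n_snps = n_snps, seed = seed, outcomes = outcomes, ...)
}

# single-outcome null/alt truth for replicate simulations
replicate_truth <- function(seed, theta = c(0, 0), n_snps = 250, type = "continuous",
                            rho_g = 0.7, pleiotropy = list(mode = "none", mean = 0, sd = 0),
                            phenotypic_correlation = 0.69) {
  out <- if (type == "binary") {
    list(y = list(type = "binary", n = 420531, case_fraction = 0.14, theta = theta))
  } else {
    list(y = list(type = "continuous", n = 420531, theta = theta))
  }
  synthetic_truth(n_snps = n_snps, seed = seed, outcomes = out,
                  genetic_correlation = rho_g, pleiotropy = pleiotropy,
                  phenotypic_correlation = phenotypic_correlation,
                  palindrome_rate = 0, missing_outcome_rate = 0,
                  annotation_rate = 0)
}

# one-exposure harmonised set straight from a replicate study
replicate_hset <- function(seed, exposure = 1, ...) {
  st <- generate_study(replicate_truth(seed, ...))
  cand <- select_instruments(st$exposures[[exposure]])
  harmonise(st$exposures[[exposure]], st$outcomes$y, cand$variant_id)
}
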