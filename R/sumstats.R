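# GWAS summary-statistics tables: construction, IO, meta-analysis, scaling.

#' Default column dialect for summary-statistics files
#'
#' Canonical (GWAS-SSF-like) header names mapped from the internal field
#' names. Override entries to read files with different headers, e.g.
#' `c(variant_id = "SNP", beta = "b")`.
#'
#' @return named character vector, internal field -> file column name
#' @export
default_dialect <- function() {
  c(variant_id = "variant_id",
    effect_allele = "effect_allele",
    other_allele = "other_allele",
    eaf = "effect_allele_frequency",
    beta = "beta",
    se = "standard_error",
    pvalue = "p_value",
    n = "n",
    n_cases = "n_cases")
}

.MANDATORY_FIELDS <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
.SS_FIELDS <- c("variant_id", "effect_allele", "other_allele", "eaf",
                "beta", "se", "pvalue", "pvalue_reported", "n", "n_cases")

#' Construct a summary-statistics table
#'
#' One row per variant: rsID, effect/other allele, effect-allele frequency,
#' effect size, standard error, p-value, sample size and (for binary traits)
#' case count. The p-value column is always recomputed from beta/se under the
#' two-sided normal approximation; the value supplied on input is retained as
#' `pvalue_reported`.
#'
#' @param data data.frame with at least columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`; optionally `eaf`,
#'   `pvalue`, `n`, `n_cases`.
#' @param trait_name trait label
#' @param trait_type `"continuous"` or `"binary"`
#' @param trait_sd phenotypic standard deviation in native units (e.g. 20.1
#'   mmHg for systolic blood pressure), or `NA` if unknown/already on the SD
#'   scale
#' @param validate reject rows violating invariants (with a message) rather
#'   than erroring
#' @return object of class `sumstats`
#' @export
sumstats <- function(data, trait_name, trait_type = c("continuous", "binary"),
                     trait_sd = NA_real_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  if (!is.na(trait_sd) && trait_sd <= 0) stop_usage("trait_sd must be > 0")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.MANDATORY_FIELDS, names(data))
  if (length(missing_cols)) {
    stop_usage("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("eaf", "pvalue", "n", "n_cases")) {
    if (!opt %in% names(data)) data[[opt]] <- NA_real_
  }
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  data$variant_id <- as.character(data$variant_id)

  dup <- unique(data$variant_id[duplicated(data$variant_id)])
  if (length(dup)) {
    stop_usage("duplicate variant_id: ", paste(utils::head(dup, 10), collapse = ", "))
  }

  bad <- !(data$effect_allele %in% names(.COMPLEMENT)) |
    !(data$other_allele %in% names(.COMPLEMENT)) |
    data$effect_allele == data$other_allele |
    !is.finite(data$beta) | !is.finite(data$se) | data$se <= 0 |
    (!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1))
  if (any(bad)) {
    if (!validate) {
      stop_usage(sum(bad), " row(s) violate summary-statistics invariants")
    }
    message(sum(bad), " row(s) rejected (invalid alleles, se <= 0, or eaf outside [0,1])")
    data <- data[!bad, , drop = FALSE]
  }

  data$pvalue_reported <- if ("pvalue" %in% names(data)) as.numeric(data$pvalue) else NA_real_
  data$pvalue <- pvalue_from_z(data$beta, data$se)
  data <- data[, .SS_FIELDS]
  rownames(data) <- NULL

  structure(list(trait_name = trait_name, trait_type = trait_type,
                 trait_sd = trait_sd, data = data, n_rejected = sum(bad)),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s (%s%s): %d variants\n", x$trait_name, x$trait_type,
              if (!is.na(x$trait_sd)) sprintf(", SD = %g", x$trait_sd) else "",
              nrow(x$data)))
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Tab- or comma-separated with a header row; gzip handled transparently.
#' Rows violating the record invariants (non-SNP or identical alleles,
#' non-positive SE, frequency outside \[0,1\]) are rejected with a reported
#' count; alleles are upper-cased; p-values are recomputed from beta/se and
#' the file's p-value kept as `pvalue_reported`.
#'
#' @inheritParams sumstats
#' @param path file path
#' @param dialect named character vector mapping internal field names to file
#'   column names; see [default_dialect()]
#' @return a [sumstats] object
#' @export
read_summary_stats <- function(path, trait_name = basename(path),
                               trait_type = c("continuous", "binary"),
                               trait_sd = NA_real_, dialect = default_dialect()) {
  trait_type <- match.arg(trait_type)
  raw <- data.table::fread(path, sep = "auto", header = TRUE, data.table = FALSE)
  full <- default_dialect()
  full[names(dialect)] <- dialect
  present <- full[full %in% names(raw)]
  missing_mand <- setdiff(.MANDATORY_FIELDS, names(present))
  if (length(missing_mand)) {
    stop_usage("configuration error: file lacks mandatory column(s): ",
               paste(full[missing_mand], collapse = ", "))
  }
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)
  sumstats(df, trait_name = trait_name, trait_type = trait_type, trait_sd = trait_sd)
}

#' Write a summary-statistics table
#'
#' TSV with the (possibly overridden) dialect header. Numeric columns are
#' written at full precision so that read -> write -> read round-trips.
#'
#' @param x a [sumstats] object
#' @param path output path (`.gz` suffix compresses)
#' @param dialect see [default_dialect()]
#' @return `path`, invisibly
#' @export
write_summary_stats <- function(x, path, dialect = default_dialect()) {
  full <- default_dialect()
  full[names(dialect)] <- dialect
  out <- x$data[, names(full)]
  names(out) <- unname(full)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- vapply(out[[j]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = NA, trim = TRUE)
    }, character(1))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Fixed-effects inverse-variance-weighted meta-analysis of GWAS tables
#'
#' Pools per-variant effect estimates across studies with weights `1/se^2`:
#' pooled beta `= sum(beta_i/se_i^2) / sum(1/se_i^2)`, pooled SE
#' `= 1/sqrt(sum(1/se_i^2))`. Used here to build a composite endpoint (e.g.
#' major cardiovascular events from coronary artery disease, ischaemic
#' stroke, intracranial haemorrhage and heart failure), so sample sizes and
#' case counts are summed. Each table is first aligned to the first table's
#' effect allele per variant; variants whose alleles cannot be reconciled by
#' swap/strand-flip are dropped with a warning. Variants absent from some
#' tables are pooled over the tables that carry them and the per-variant
#' contributing-study count is recorded in column `n_studies`.
#'
#' @param tables list of [sumstats] objects of the same trait type
#' @param trait_name name for the pooled trait
#' @return a [sumstats] object; its `data` has an extra `n_studies` column
#' @export
meta_analyse_fixed_effects <- function(tables, trait_name = "composite") {
  if (!length(tables)) stop_usage("empty input list")
  types <- unique(vapply(tables, function(t) t$trait_type, character(1)))
  if (length(types) != 1) stop_usage("all tables must share trait_type")
  if (length(tables) == 1) {
    out <- tables[[1]]
    out$data$n_studies <- 1L
    out$trait_name <- trait_name
    return(out)
  }

  # reference alleles: first table to carry each variant
  ref <- list()
  for (t in tables) {
    d <- t$data
    new <- !(d$variant_id %in% names(ref))
    for (i in which(new)) {
      ref[[d$variant_id[i]]] <- c(d$effect_allele[i], d$other_allele[i])
    }
  }

  acc <- new.env(parent = emptyenv())
  dropped <- character(0)
  for (t in tables) {
    d <- t$data
    for (i in seq_len(nrow(d))) {
      v <- d$variant_id[i]
      r <- ref[[v]]
      act <- allele_action(r[1], r[2], d$effect_allele[i], d$other_allele[i])
      if (act == "mismatch") {
        dropped <- c(dropped, v)
        next
      }
      b <- if (act == "flip") -d$beta[i] else d$beta[i]
      f <- if (act == "flip") 1 - d$eaf[i] else d$eaf[i]
      w <- 1 / d$se[i]^2
      cur <- if (exists(v, acc)) get(v, acc) else
        list(swb = 0, sw = 0, n = 0, n_cases = 0, k = 0L, eaf = NA_real_)
      cur$swb <- cur$swb + w * b
      cur$sw <- cur$sw + w
      cur$n <- cur$n + (if (is.na(d$n[i])) 0 else d$n[i])
      cur$n_cases <- cur$n_cases + (if (is.na(d$n_cases[i])) 0 else d$n_cases[i])
      cur$k <- cur$k + 1L
      if (is.na(cur$eaf)) cur$eaf <- f
      assign(v, cur, acc)
    }
  }
  if (length(dropped)) {
    warning("dropped variant(s) with irreconcilable alleles: ",
            paste(unique(dropped), collapse = ", "))
  }
  ids <- ls(acc)
  pooled <- do.call(rbind, lapply(ids, function(v) {
    cur <- get(v, acc)
    data.frame(variant_id = v,
               effect_allele = ref[[v]][1], other_allele = ref[[v]][2],
               eaf = cur$eaf,
               beta = cur$swb / cur$sw, se = 1 / sqrt(cur$sw),
               n = if (cur$n > 0) cur$n else NA_real_,
               n_cases = if (cur$n_cases > 0) cur$n_cases else NA_real_,
               n_studies = cur$k, stringsAsFactors = FALSE)
  }))
  out <- sumstats(pooled, trait_name = trait_name, trait_type = types,
                  trait_sd = tables[[1]]$trait_sd)
  out$data$n_studies <- pooled$n_studies[match(out$data$variant_id, pooled$variant_id)]
  out
}

#' Inflate standard errors by the square root of an LD-score-regression intercept
#'
#' Genomic control for a composite endpoint built from correlated
#' sub-endpoints: every SE is multiplied by `sqrt(ldsc_intercept)`, betas are
#' unchanged, and p-values are recomputed from the normal approximation.
#' The intercept is a configuration input (estimated externally, e.g. 1.337
#' for a four-subtype cardiovascular composite).
#'
#' @param x a [sumstats] object
#' @param ldsc_intercept positive scalar; values < 1 are accepted with a
#'   warning but no deflation is applied
#' @return a [sumstats] object
#' @export
inflate_standard_errors <- function(x, ldsc_intercept) {
  if (!is.numeric(ldsc_intercept) || length(ldsc_intercept) != 1 || ldsc_intercept <= 0) {
    stop_usage("ldsc_intercept must be a positive scalar")
  }
  fac <- sqrt(ldsc_intercept)
  if (ldsc_intercept < 1) {
    warning("ldsc_intercept < 1: no deflation applied")
    fac <- 1
  }
  x$data$se <- x$data$se * fac
  x$data$pvalue <- pvalue_from_z(x$data$beta, x$data$se)
  x
}

#' Rescale effect sizes to per-SD or per-unit increments
#'
#' Multiplies beta and SE by the phenotypic SD (`mode = "per-sd"`, e.g. a
#' causal effect per mmHg becomes per 20.1 mmHg = 1 SD of systolic pressure)
#' or by an arbitrary increment in native units (`mode = "per-unit"`, e.g.
#' per 10 mmHg). p-values are invariant under rescaling.
#'
#' @param x a [sumstats] object
#' @param mode `"per-sd"` or `"per-unit"`
#' @param unit_increment increment in native units, required for `"per-unit"`
#' @return a [sumstats] object
#' @export
scale_effects <- function(x, mode = c("per-sd", "per-unit"), unit_increment = NULL) {
  mode <- match.arg(mode)
  fac <- if (mode == "per-sd") {
    if (is.na(x$trait_sd)) stop_usage("per-sd scaling requires trait_sd")
    x$trait_sd
  } else {
    if (is.null(unit_increment)) stop_usage("per-unit scaling requires unit_increment")
    unit_increment
  }
  x$data$beta <- x$data$beta * fac
  x$data$se <- x$data$se * fac
  x$data$pvalue <- pvalue_from_z(x$data$beta, x$data$se)
  x
}
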