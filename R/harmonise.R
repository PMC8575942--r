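# Instrument selection, LD clumping and exposure/outcome allele harmonisation.

#' LD reference: pairwise r-squared plus proxy lookup
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2` (symmetric;
#'   self-pairs implied at r2 = 1), or NULL for an empty reference
#' @param proxies data.frame with columns `missing_id`, `proxy_id`, `r2`, or
#'   NULL
#' @return object of class `ld_reference`
#' @export
ld_reference <- function(pairs = NULL, proxies = NULL) {
  lookup <- new.env(parent = emptyenv())
  if (!is.null(pairs) && nrow(pairs)) {
    keys <- ifelse(pairs$id_a < pairs$id_b,
                   paste(pairs$id_a, pairs$id_b, sep = "|"),
                   paste(pairs$id_b, pairs$id_a, sep = "|"))
    for (i in seq_along(keys)) assign(keys[i], pairs$r2[i], lookup)
  }
  structure(list(lookup = lookup,
                 pairs = pairs %||% data.frame(id_a = character(0), id_b = character(0),
                                               r2 = numeric(0)),
                 proxies = proxies %||% data.frame(missing_id = character(0),
                                                   proxy_id = character(0),
                                                   r2 = numeric(0))),
            class = "ld_reference")
}

#' Read an LD reference from 3-column TSVs
#' @param pairs_path TSV with columns id_a, id_b, r2 (or NULL)
#' @param proxies_path TSV with columns missing_id, proxy_id, r2 (or NULL)
#' @return an [ld_reference] object
#' @export
read_ld_reference <- function(pairs_path = NULL, proxies_path = NULL) {
  pairs <- if (!is.null(pairs_path))
    data.table::fread(pairs_path, data.table = FALSE) else NULL
  proxies <- if (!is.null(proxies_path))
    data.table::fread(proxies_path, data.table = FALSE) else NULL
  ld_reference(pairs, proxies)
}

ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  key <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
  if (exists(key, ld$lookup)) get(key, ld$lookup) else 0
}

#' Select genome-wide-significant (and optionally replicated) instruments
#'
#' @param table a [sumstats] object for the exposure
#' @param p_threshold significance threshold (default 5e-8)
#' @param replicated_flags optional named logical vector (variant_id ->
#'   externally replicated); when supplied, unreplicated variants are dropped
#' @return data.frame (variant_id, pvalue) sorted by ascending p
#' @export
select_instruments <- function(table, p_threshold = 5e-8, replicated_flags = NULL) {
  d <- table$data
  keep <- d$pvalue < p_threshold
  if (!is.null(replicated_flags)) {
    rep_ok <- replicated_flags[d$variant_id]
    rep_ok[is.na(rep_ok)] <- FALSE
    keep <- keep & rep_ok
  }
  out <- d[keep, c("variant_id", "pvalue")]
  out <- out[order(out$pvalue, out$variant_id), ]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no variants pass the instrument selection threshold")
  out
}

#' Greedy p-value-ranked LD clumping
#'
#' Repeatedly takes the lowest-p unclaimed variant as the index and discards
#' all unclaimed variants with r2 >= `r2_threshold` to it (plink-style).
#' Ties in p are broken lexicographically by variant_id, making the result
#' independent of input order. Variant pairs absent from the LD reference are
#' treated as unlinked (r2 = 0).
#'
#' @param candidates data.frame (variant_id, pvalue), e.g. from
#'   [select_instruments()]
#' @param ld an [ld_reference] object
#' @param r2_threshold independence threshold (default 0.001)
#' @return character vector of retained variant_ids in selection order
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001) {
  cand <- candidates[order(candidates$pvalue, candidates$variant_id), ]
  kept <- character(0)
  remaining <- cand$variant_id
  while (length(remaining)) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2 <- vapply(remaining, function(v) ld_r2(ld, idx, v), numeric(1))
      remaining <- remaining[r2 < r2_threshold]
    }
  }
  kept
}

#' Merge per-exposure instrument candidates, retaining the lower p-value
#'
#' A variant instrumenting several exposures enters clumping once, with its
#' minimum p-value across exposures.
#'
#' @param per_exposure list of data.frames (variant_id, pvalue), one per
#'   exposure
#' @return data.frame (variant_id, pvalue) sorted by ascending p
#' @export
merge_exposure_instruments <- function(per_exposure) {
  all <- do.call(rbind, per_exposure)
  if (is.null(all) || !nrow(all)) return(data.frame(variant_id = character(0),
                                                    pvalue = numeric(0)))
  agg <- stats::aggregate(pvalue ~ variant_id, data = all, FUN = min)
  agg <- agg[order(agg$pvalue, agg$variant_id), c("variant_id", "pvalue")]
  rownames(agg) <- NULL
  agg
}

#' Construct a harmonised instrument set directly from vectors
#'
#' Convenience constructor used by the estimators and in tests; the
#' pipeline path builds the same object via [harmonise()].
#'
#' @param exposure_betas numeric vector or matrix (one column per exposure)
#'   of SNP-exposure effects
#' @param exposure_ses matching standard errors
#' @param outcome_beta,outcome_se SNP-outcome effects and SEs
#' @param variant_ids optional ids (default snp1..snpk)
#' @param eaf optional effect-allele frequencies
#' @param exposure_names,outcome_name labels
#' @param outcome_type `"continuous"` or `"binary"`
#' @param n_exposure,n_outcome per-trait sample sizes (scalars; exposures may
#'   be a vector, one per exposure)
#' @param case_fraction outcome case fraction for binary outcomes
#' @param exclusion_log data.frame (variant_id, reason)
#' @return object of class `mr_hset`
#' @export
harmonised_set <- function(exposure_betas, exposure_ses, outcome_beta, outcome_se,
                           variant_ids = NULL, eaf = NULL,
                           exposure_names = NULL, outcome_name = "outcome",
                           outcome_type = "continuous",
                           n_exposure = NA_real_, n_outcome = NA_real_,
                           case_fraction = NA_real_,
                           exclusion_log = NULL) {
  bx <- as.matrix(exposure_betas)
  sx <- as.matrix(exposure_ses)
  k <- nrow(bx)
  d <- ncol(bx)
  stopifnot(all(dim(bx) == dim(sx)), length(outcome_beta) == k,
            length(outcome_se) == k)
  if (any(sx <= 0) || any(outcome_se <= 0)) stop_usage("standard errors must be > 0")
  exposure_names <- exposure_names %||% colnames(bx) %||% paste0("exposure", seq_len(d))
  colnames(bx) <- colnames(sx) <- exposure_names
  structure(list(
    variant_ids = variant_ids %||% paste0("snp", seq_len(k)),
    exposure_betas = bx, exposure_ses = sx,
    outcome_beta = as.numeric(outcome_beta), outcome_se = as.numeric(outcome_se),
    eaf = eaf %||% rep(NA_real_, k),
    exposure_names = exposure_names, outcome_name = outcome_name,
    outcome_type = outcome_type,
    n_exposure = rep_len(n_exposure, d), n_outcome = n_outcome,
    case_fraction = case_fraction,
    exclusion_log = exclusion_log %||% data.frame(variant_id = character(0),
                                                  reason = character(0))),
    class = "mr_hset")
}

#' @export
print.mr_hset <- function(x, ...) {
  cat(sprintf("<mr_hset> %d SNPs; exposures: %s; outcome: %s (%s); %d exclusion(s)\n",
              length(x$variant_ids), paste(x$exposure_names, collapse = ", "),
              x$outcome_name, x$outcome_type, nrow(x$exclusion_log)))
  invisible(x)
}

#' Number of SNPs in a harmonised set
#' @param hset an `mr_hset`
#' @return integer
#' @export
n_snps <- function(hset) length(hset$variant_ids)

#' Subset a harmonised set by position or variant id
#' @param hset an `mr_hset`
#' @param keep logical/integer index or character vector of variant ids
#' @param reason optional exclusion reason logged for dropped variants
#' @return an `mr_hset`
#' @export
subset_hset <- function(hset, keep, reason = NULL) {
  if (is.character(keep)) keep <- hset$variant_ids %in% keep
  if (is.logical(keep)) keep <- which(keep)
  dropped <- setdiff(seq_along(hset$variant_ids), keep)
  if (length(dropped) && !is.null(reason)) {
    hset$exclusion_log <- rbind(hset$exclusion_log,
                                data.frame(variant_id = hset$variant_ids[dropped],
                                           reason = reason))
  }
  hset$variant_ids <- hset$variant_ids[keep]
  hset$exposure_betas <- hset$exposure_betas[keep, , drop = FALSE]
  hset$exposure_ses <- hset$exposure_ses[keep, , drop = FALSE]
  hset$outcome_beta <- hset$outcome_beta[keep]
  hset$outcome_se <- hset$outcome_se[keep]
  hset$eaf <- hset$eaf[keep]
  hset
}

#' Align exposure and outcome effect estimates to a shared effect allele
#'
#' For each instrument: (i) variants missing from the outcome table are
#' replaced by a proxy with r2 >= `proxy_r2_min` where the proxy table offers
#' one (highest r2 wins, ties by variant_id), else excluded; (ii)
#' non-palindromic variants are aligned by allele matching, flipping the
#' outcome beta sign and frequency when effect/other alleles are swapped
#' (strand flips resolved by complementing); (iii) palindromic variants (A/T,
#' C/G) with effect-allele frequency strictly inside `palindrome_window` on
#' either side are ambiguous and are proxy-substituted when possible, else
#' excluded; palindromic variants outside the window are aligned by matching
#' the minor allele across datasets; palindromes with a missing frequency on
#' either side are excluded. Every exclusion is logged with a reason.
#'
#' @param exposures a [sumstats] object or list of them (multivariable);
#'   instruments must be present in every exposure table
#' @param outcome a [sumstats] object
#' @param instruments character vector of variant ids (or data.frame with a
#'   `variant_id` column)
#' @param ld an [ld_reference] carrying the proxy table (optional)
#' @param palindrome_window exclusive ambiguity window on the effect-allele
#'   frequency, default `c(0.42, 0.58)`
#' @param proxy_r2_min minimum proxy r2, default 0.8
#' @return an `mr_hset`; `exclusion_log` records terminal exclusions
#'   (palindrome-ambiguous, allele-mismatch, missing-in-outcome,
#'   missing-in-exposure, annotation-screened) and non-terminal
#'   proxy substitutions
#' @export
harmonise <- function(exposures, outcome, instruments, ld = NULL,
                      palindrome_window = c(0.42, 0.58), proxy_r2_min = 0.8) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposures)
  if (is.data.frame(instruments)) instruments <- instruments$variant_id
  ld <- ld %||% ld_reference()
  d <- length(exposures)
  exp_names <- vapply(seq_len(d), function(i) exposures[[i]]$trait_name, character(1))
  exp_idx <- lapply(exposures, function(e) {
    structure(seq_len(nrow(e$data)), names = e$data$variant_id)
  })
  out_idx <- structure(seq_len(nrow(outcome$data)), names = outcome$data$variant_id)

  log <- list()
  add_log <- function(v, reason) log[[length(log) + 1L]] <<- c(v, reason)

  rows <- list()
  for (v0 in instruments) {
    v <- v0
    # presence in every exposure table
    in_exp <- vapply(exp_idx, function(ix) v %in% names(ix), logical(1))
    if (!all(in_exp)) {
      add_log(v0, "missing-in-exposure")
      next
    }

    substitute_proxy <- function() {
      px <- ld$proxies
      cand <- px[px$missing_id == v & px$r2 >= proxy_r2_min, , drop = FALSE]
      cand <- cand[cand$proxy_id %in% names(out_idx), , drop = FALSE]
      ok <- vapply(cand$proxy_id, function(p)
        all(vapply(exp_idx, function(ix) p %in% names(ix), logical(1))), logical(1))
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) return(NULL)
      cand <- cand[order(-cand$r2, cand$proxy_id), , drop = FALSE]
      cand$proxy_id[1]
    }

    if (!(v %in% names(out_idx))) {
      p <- substitute_proxy()
      if (is.null(p)) {
        add_log(v0, "missing-in-outcome")
        next
      }
      add_log(v0, "proxy-substituted")
      v <- p
    }

    align_one <- function(v) {
      ref <- exposures[[1]]$data[exp_idx[[1]][[v]], ]
      bx <- numeric(d); sx <- numeric(d)
      bx[1] <- ref$beta; sx[1] <- ref$se
      if (d > 1) for (e in 2:d) {
        r <- exposures[[e]]$data[exp_idx[[e]][[v]], ]
        act <- allele_action(ref$effect_allele, ref$other_allele,
                             r$effect_allele, r$other_allele)
        if (act == "mismatch") return("allele-mismatch")
        # palindromic exposure pairs: exposure GWASs assumed strand-consistent,
        # resolved letter-wise by allele_action
        bx[e] <- if (act == "flip") -r$beta else r$beta
        sx[e] <- r$se
      }
      o <- outcome$data[out_idx[[v]], ]
      act <- allele_action(ref$effect_allele, ref$other_allele,
                           o$effect_allele, o$other_allele)
      if (act == "mismatch") return("allele-mismatch")
      by <- if (act == "flip") -o$beta else o$beta
      f_out <- if (act == "flip") 1 - o$eaf else o$eaf
      if (is_palindromic(ref$effect_allele, ref$other_allele)) {
        if (is.na(ref$eaf) || is.na(f_out)) return("palindrome-ambiguous")
        inside <- function(f) f > palindrome_window[1] & f < palindrome_window[2]
        if (inside(ref$eaf) || inside(f_out)) return("palindrome-ambiguous")
        # minor-allele (frequency) matching decides orientation
        if ((ref$eaf - 0.5) * (f_out - 0.5) < 0) by <- -by
      }
      list(variant_id = v, bx = bx, sx = sx, by = by, se_y = o$se, eaf = ref$eaf)
    }

    res <- align_one(v)
    if (is.character(res) && res == "palindrome-ambiguous" && v == v0) {
      p <- substitute_proxy()
      if (!is.null(p)) {
        res2 <- align_one(p)
        if (is.list(res2)) {
          add_log(v0, "proxy-substituted")
          res <- res2
        }
      }
    }
    if (is.character(res)) {
      add_log(v0, res)
      next
    }
    rows[[length(rows) + 1L]] <- res
  }

  log_df <- if (length(log)) {
    data.frame(variant_id = vapply(log, `[`, character(1), 1),
               reason = vapply(log, `[`, character(1), 2))
  } else data.frame(variant_id = character(0), reason = character(0))

  if (!length(rows)) {
    return(harmonised_set(matrix(numeric(0), 0, d), matrix(numeric(0), 0, d),
                          numeric(0), numeric(0), variant_ids = character(0),
                          exposure_names = exp_names,
                          outcome_name = outcome$trait_name,
                          outcome_type = outcome$trait_type,
                          exclusion_log = log_df))
  }

  bx <- do.call(rbind, lapply(rows, `[[`, "bx"))
  sx <- do.call(rbind, lapply(rows, `[[`, "sx"))
  n_out <- stats::median(outcome$data$n, na.rm = TRUE)
  cf <- if (outcome$trait_type == "binary") {
    stats::median(outcome$data$n_cases / outcome$data$n, na.rm = TRUE)
  } else NA_real_
  harmonised_set(
    bx, sx,
    outcome_beta = vapply(rows, `[[`, numeric(1), "by"),
    outcome_se = vapply(rows, `[[`, numeric(1), "se_y"),
    variant_ids = vapply(rows, `[[`, character(1), "variant_id"),
    eaf = vapply(rows, `[[`, numeric(1), "eaf"),
    exposure_names = exp_names,
    outcome_name = outcome$trait_name, outcome_type = outcome$trait_type,
    n_exposure = vapply(exposures, function(e) stats::median(e$data$n, na.rm = TRUE),
                        numeric(1)),
    n_outcome = if (is.finite(n_out)) n_out else NA_real_,
    case_fraction = if (is.finite(cf)) cf else NA_real_,
    exclusion_log = log_df)
}

#' Remove instruments associated with listed secondary traits
#'
#' Table-driven pleiotropy screen: variants associated with any listed trait
#' (e.g. education, smoking, BMI) at `p < p_threshold` in the annotation
#' table are removed with reason `annotation-screened`. Variants absent from
#' the annotation table pass.
#'
#' @param hset an `mr_hset`
#' @param annotations data.frame (variant_id, trait, pvalue), long format
#' @param traits traits to screen on (default all in the table)
#' @param p_threshold default 5e-8
#' @return an `mr_hset`
#' @export
screen_annotations <- function(hset, annotations, traits = NULL, p_threshold = 5e-8) {
  ann <- annotations
  if (!is.null(traits)) ann <- ann[ann$trait %in% traits, , drop = FALSE]
  flagged <- unique(ann$variant_id[ann$pvalue < p_threshold])
  subset_hset(hset, !(hset$variant_ids %in% flagged), reason = "annotation-screened")
}

#' Read a long-format annotation table (variant_id, trait, pvalue)
#' @param path TSV path
#' @return data.frame
#' @export
read_annotations <- function(path) {
  data.table::fread(path, data.table = FALSE)
}
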