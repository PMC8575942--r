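#' @import stats
#' @import utils
#' @importFrom data.table fread fwrite
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sided p-value from an estimate and its standard error
#'
#' Normal approximation used throughout the package whenever a p-value is
#' (re)computed from a beta/SE pair.
#'
#' @param beta effect estimate(s)
#' @param se standard error(s), > 0
#' @return two-sided p-value(s) in (0, 1]
#' @export
pvalue_from_z <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic (A/T or C/G)?
#' @param a1,a2 single-base alleles
#' @return logical
#' @export
is_palindromic <- function(a1, a2) {
  unname(.COMPLEMENT[a1] == a2)
}

# Relate an allele pair to a reference pair for the same variant.
# Returns one of "keep", "flip", "mismatch".  Strand flips are resolved by
# complementing; palindromic pairs resolve letter-wise to "keep"/"flip" and
# need a frequency check downstream.
allele_action <- function(ea_ref, oa_ref, ea, oa) {
  if (ea == ea_ref && oa == oa_ref) return("keep")
  if (ea == oa_ref && oa == ea_ref) return("flip")
  cea <- .COMPLEMENT[[ea]]
  coa <- .COMPLEMENT[[oa]]
  if (cea == ea_ref && coa == oa_ref) return("keep")
  if (cea == oa_ref && coa == ea_ref) return("flip")
  "mismatch"
}

# z quantile helper for power formulas
z_alpha <- function(alpha) stats::qnorm(1 - alpha / 2)

stop_usage <- function(...) stop(..., call. = FALSE)
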