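#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of genotype counts against the
#' Hardy-Weinberg proportions (p^2, 2pq, q^2) implied by the observed allele
#' frequency, on 1 degree of freedom. No continuity correction and no exact
#' test: this is the plain asymptotic test customarily reported in the HWE
#' columns of genetic association tables. Applied to control groups, a
#' small P-value flags genotyping error or population structure.
#'
#' @param counts length-3 vector of genotype counts ordered (risk
#'   homozygote, heterozygote, reference homozygote).
#' @return list with `chi2`, `df` (always 1), `p_value` and `allele_freq`
#'   (the risk-allele frequency (2*hom + het) / 2n). A monomorphic sample
#'   fits its HWE expectation exactly and returns `chi2 = 0`, `p_value = 1`.
#' @examples
#' hwe_test(c(123, 128, 40))   # controls of a published study, P = 0.470
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("undefined for zero subjects", call. = FALSE)
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  ok <- expected > 0  # zero expectation forces a zero observation here
  chi2 <- sum((counts[ok] - expected[ok])^2 / expected[ok])
  list(chi2 = chi2, df = 1L,
       p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       allele_freq = p)
}

#' HWE test over every control arm of a panel
#'
#' @param ds a [snp_dataset].
#' @param alpha flagging threshold for departure from HWE (default 0.05).
#'   Flagged studies are retained; filtering is left to the caller, since
#'   sensitivity analysis is the usual remedy rather than exclusion.
#' @return data frame with one row per study: `study_id`, `allele_freq`,
#'   `chi2`, `p_value`, `hwe_flag` (TRUE when `p_value < alpha`).
#' @examples
#' hw <- hwe_controls(tox3_dataset("rs3803662"))
#' hw[hw$hwe_flag, ]
#' @export
hwe_controls <- function(ds, alpha = 0.05) {
  stopifnot(inherits(ds, "snp_dataset"))
  s <- ds$studies
  res <- lapply(seq_len(nrow(s)), function(i) {
    hwe_test(c(s$ctrl_hom_risk[i], s$ctrl_het[i], s$ctrl_hom_ref[i]))
  })
  data.frame(study_id = s$study_id,
             allele_freq = vapply(res, `[[`, numeric(1), "allele_freq"),
             chi2 = vapply(res, `[[`, numeric(1), "chi2"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             hwe_flag = vapply(res, `[[`, numeric(1), "p_value") < alpha,
             stringsAsFactors = FALSE)
}
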