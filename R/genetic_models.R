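#' The five classical genetic model contrasts
#'
#' For a biallelic SNP with risk allele R and reference allele r, each model
#' reduces the 2x3 genotype table to a 2x2 case-control exposure table:
#' \describe{
#'   \item{homozygote}{RR versus rr (heterozygotes dropped)}
#'   \item{heterozygote}{Rr versus rr (risk homozygotes dropped)}
#'   \item{dominant}{RR + Rr versus rr}
#'   \item{recessive}{RR versus Rr + rr}
#'   \item{allele}{R alleles versus r alleles (2 per subject: 2xRR + Rr)}
#' }
#'
#' @return character vector of the five model names.
#' @export
genetic_models <- function() {
  c("homozygote", "heterozygote", "dominant", "recessive", "allele")
}

#' Build a 2x2 exposure table for one study
#'
#' @param cases,controls length-3 integer vectors of genotype counts ordered
#'   (risk homozygote, heterozygote, reference homozygote).
#' @param model one of [genetic_models()].
#' @param study_id label propagated into the result.
#' @return one-row data frame with cells `a` (exposed cases), `b` (unexposed
#'   cases), `c` (exposed controls), `d` (unexposed controls) plus `study_id`
#'   and `model`.
#' @examples
#' build_contrast(c(271, 280, 72), c(270, 278, 72), "allele", "He 2014")
#' @export
build_contrast <- function(cases, controls, model = genetic_models(),
                           study_id = "study") {
  stopifnot(length(cases) == 3L, length(controls) == 3L,
            all(cases >= 0), all(controls >= 0))
  model <- match.arg(model)
  cells <- switch(model,
    homozygote   = c(cases[1L], cases[3L], controls[1L], controls[3L]),
    heterozygote = c(cases[2L], cases[3L], controls[2L], controls[3L]),
    dominant     = c(cases[1L] + cases[2L], cases[3L],
                     controls[1L] + controls[2L], controls[3L]),
    recessive    = c(cases[1L], cases[2L] + cases[3L],
                     controls[1L], controls[2L] + controls[3L]),
    allele       = c(2L * cases[1L] + cases[2L], 2L * cases[3L] + cases[2L],
                     2L * controls[1L] + controls[2L],
                     2L * controls[3L] + controls[2L]))
  data.frame(study_id = study_id, model = model,
             a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L],
             stringsAsFactors = FALSE)
}

#' Build the 2x2 exposure tables for every study in a panel
#'
#' Vectorised version of [build_contrast()] over a [snp_dataset].
#'
#' @param ds a [snp_dataset].
#' @param model one of [genetic_models()].
#' @return data frame with one row per study (`study_id`, `model`, `a`, `b`,
#'   `c`, `d`), in the panel's study order.
#' @examples
#' head(build_contrasts(tox3_dataset("rs8051542"), "allele"))
#' @export
build_contrasts <- function(ds, model = genetic_models()) {
  stopifnot(inherits(ds, "snp_dataset"))
  model <- match.arg(model)
  s <- ds$studies
  ch <- s$case_hom_risk; ce <- s$case_het; cr <- s$case_hom_ref
  th <- s$ctrl_hom_risk; te <- s$ctrl_het; tr <- s$ctrl_hom_ref
  cells <- switch(model,
    homozygote   = list(a = ch, b = cr, c = th, d = tr),
    heterozygote = list(a = ce, b = cr, c = te, d = tr),
    dominant     = list(a = ch + ce, b = cr, c = th + te, d = tr),
    recessive    = list(a = ch, b = ce + cr, c = th, d = te + tr),
    allele       = list(a = 2L * ch + ce, b = 2L * cr + ce,
                        c = 2L * th + te, d = 2L * tr + te))
  data.frame(study_id = s$study_id, model = model,
             a = cells$a, b = cells$b, c = cells$c, d = cells$d,
             stringsAsFactors = FALSE)
}
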