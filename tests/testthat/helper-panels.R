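# shared fixtures and independent oracles, built in code

# tiny hand-built panel with two ethnic strata
toy_panel <- function() {
  snp_dataset(
    data.frame(
      study_id = c("A 2010", "B 2011", "C 2012", "D 2013"),
      ethnicity = c("Asian", "Asian", "Caucasian", "Caucasian"),
      case_hom_risk = c(30L, 25L, 40L, 28L),
      case_het = c(80L, 70L, 90L, 75L),
      case_hom_ref = c(90L, 105L, 70L, 97L),
      ctrl_hom_risk = c(20L, 22L, 30L, 24L),
      ctrl_het = c(85L, 78L, 88L, 80L),
      ctrl_hom_ref = c(95L, 100L, 82L, 96L),
      stringsAsFactors = FALSE),
    snp_id = "rs_toy", risk_allele = "T", ref_allele = "C")
}

# panel of k copies of one study (useful for pooling identities)
replicated_panel <- function(k, cases = c(30L, 80L, 90L),
                             controls = c(20L, 85L, 95L)) {
  snp_dataset(
    data.frame(
      study_id = sprintf("S%02d", seq_len(k)),
      ethnicity = "X",
      case_hom_risk = cases[1L], case_het = cases[2L],
      case_hom_ref = cases[3L],
      ctrl_hom_risk = controls[1L], ctrl_het = controls[2L],
      ctrl_hom_ref = controls[3L],
      stringsAsFactors = FALSE),
    snp_id = "rs_rep")
}

# independent oracle: log OR and Woolf SE straight from the formulas
oracle_log_or <- function(a, b, c, d) log(a * d / (b * c))
oracle_se <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

# independent oracle: inverse-variance fixed-effect pooled log OR
oracle_iv_fixed <- function(yi, sei) {
  w <- 1 / sei^2
  c(log_or = sum(w * yi) / sum(w), se = 1 / sqrt(sum(w)))
}
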