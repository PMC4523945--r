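#' Configuration for a synthetic study panel
#'
#' Describes the generative world for [simulate_panel()]: k case-control
#' studies of a biallelic SNP whose controls are drawn under Hardy-Weinberg
#' equilibrium at risk-allele frequency `p_risk`, and whose cases are tilted
#' by a per-allele (multiplicative) odds ratio. Study-level log odds ratios
#' vary around log(`or_allele`) with between-study SD `tau`.
#'
#' Defaults mirror the bundled panels and the effect sizes typical of
#' low-penetrance susceptibility loci: 15 studies, control risk-allele
#' frequency 0.35, per-allele OR 1.15, no between-study heterogeneity, and
#' 1000 subjects per arm.
#'
#' @param k number of studies.
#' @param p_risk control risk-allele frequency, strictly inside (0, 1).
#' @param or_allele true per-allele odds ratio (> 0).
#' @param tau between-study SD of the log per-allele odds ratio (>= 0).
#' @param n_cases,n_controls per-study arm sizes: either a single fixed size
#'   or a length-2 range from which sizes are drawn log-uniformly, mimicking
#'   the wide size spread of real panels.
#' @param snp_id identifier stamped on the simulated panel.
#' @param seed optional RNG seed; with a seed the panel is reproducible.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(k = 20, or_allele = 1.15, n_cases = 1000,
#'                   n_controls = 1000, seed = 7)
#' @export
sim_config <- function(k = 15, p_risk = 0.35, or_allele = 1.15, tau = 0,
                       n_cases = 1000, n_controls = 1000,
                       snp_id = "sim_snp", seed = NULL) {
  if (!(is.numeric(k) && k >= 1 && k == trunc(k)))
    stop("k must be a positive integer", call. = FALSE)
  if (!(p_risk > 0 && p_risk < 1))
    stop("p_risk must lie strictly in (0, 1)", call. = FALSE)
  if (!(or_allele > 0)) stop("or_allele must be positive", call. = FALSE)
  if (!(tau >= 0)) stop("tau must be non-negative", call. = FALSE)
  for (nm in c("n_cases", "n_controls")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) %in% 1:2 && all(v >= 1)))
      stop(nm, " must be a positive size or a length-2 range", call. = FALSE)
  }
  structure(list(k = as.integer(k), p_risk = p_risk, or_allele = or_allele,
                 tau = tau, n_cases = n_cases, n_controls = n_controls,
                 snp_id = snp_id, seed = seed),
            class = "sim_config")
}

# genotype probabilities: HWE in controls; cases tilted by exp(theta * dose)
# for allele dose 2/1/0 and renormalised — the genotype distribution implied
# by a logistic per-allele model
.genotype_probs <- function(p_risk, theta) {
  hwe <- c(p_risk^2, 2 * p_risk * (1 - p_risk), (1 - p_risk)^2)
  tilt <- hwe * exp(theta * c(2, 1, 0))
  list(control = hwe, case = tilt / sum(tilt))
}

.draw_size <- function(spec, k) {
  if (length(spec) == 1L) rep(as.integer(spec), k)
  else as.integer(round(exp(stats::runif(k, log(spec[1L]), log(spec[2L])))))
}

#' Simulate a panel of case-control genotype-count studies
#'
#' Per study i: theta_i ~ Normal(log or_allele, tau^2); control genotypes
#' multinomial under HWE at `p_risk`; case genotype probabilities
#' proportional to the HWE frequencies times exp(theta_i x allele dose),
#' renormalised. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a [snp_dataset] whose `studies` carry the generating `theta` as an
#'   extra column; it round-trips through [write_dataset()] /
#'   [read_dataset()] like any other panel.
#' @examples
#' ds <- simulate_panel(sim_config(k = 5, seed = 42))
#' dataset_summary(ds)
#' @export
simulate_panel <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config",
                                         call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  theta <- stats::rnorm(cfg$k, mean = log(cfg$or_allele), sd = cfg$tau)
  n_cases <- .draw_size(cfg$n_cases, cfg$k)
  n_controls <- .draw_size(cfg$n_controls, cfg$k)
  rows <- lapply(seq_len(cfg$k), function(i) {
    pr <- .genotype_probs(cfg$p_risk, theta[i])
    ca <- stats::rmultinom(1L, n_cases[i], pr$case)[, 1L]
    co <- stats::rmultinom(1L, n_controls[i], pr$control)[, 1L]
    data.frame(study_id = sprintf("sim%03d", i), ethnicity = "Simulated",
               case_hom_risk = ca[1L], case_het = ca[2L], case_hom_ref = ca[3L],
               ctrl_hom_risk = co[1L], ctrl_het = co[2L], ctrl_hom_ref = co[3L],
               theta = theta[i], stringsAsFactors = FALSE)
  })
  snp_dataset(do.call(rbind, rows), snp_id = cfg$snp_id,
              risk_allele = "R", ref_allele = "r")
}

#' Null calibration of the HWE chi-square test
#'
#' Draws `reps` control samples of size `n` under exact Hardy-Weinberg
#' proportions at allele frequency `p_risk` and reports how often
#' [hwe_test()] rejects at `alpha`. Under a well-calibrated test the
#' rejection rate matches `alpha` up to Monte-Carlo and asymptotic error.
#'
#' @param n subjects per sample (>= 50, where the asymptotics are trusted).
#' @param p_risk allele frequency in (0, 1).
#' @param reps number of replicates (> 0).
#' @param alpha rejection threshold.
#' @param seed optional RNG seed.
#' @return list: `reps`, `n`, `p_risk`, `alpha`, `rejection_rate`.
#' @examples
#' simulate_null_hwe(n = 500, p_risk = 0.3, reps = 2000, seed = 1)
#' @export
simulate_null_hwe <- function(n, p_risk, reps, alpha = 0.05, seed = NULL) {
  if (!(n >= 50)) stop("n must be at least 50", call. = FALSE)
  if (!(p_risk > 0 && p_risk < 1)) stop("p_risk must lie in (0, 1)",
                                        call. = FALSE)
  if (!(reps >= 1)) stop("reps must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  probs <- c(p_risk^2, 2 * p_risk * (1 - p_risk), (1 - p_risk)^2)
  draws <- stats::rmultinom(reps, n, probs)
  # vectorised Pearson chi-square against the HWE expectation re-estimated
  # from each sample's own allele frequency
  p_hat <- (2 * draws[1L, ] + draws[2L, ]) / (2 * n)
  expected <- rbind(n * p_hat^2, 2 * n * p_hat * (1 - p_hat),
                    n * (1 - p_hat)^2)
  dev2 <- (draws - expected)^2
  chi2 <- colSums(ifelse(expected > 0, dev2 / expected, 0))
  p_values <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  list(reps = reps, n = n, p_risk = p_risk, alpha = alpha,
       rejection_rate = mean(p_values < alpha))
}
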