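#' @title Pooling engines
#' @description Mantel-Haenszel fixed-effect pooling of 2x2 tables with the
#'   Robins-Breslow-Greenland variance, DerSimonian-Laird random-effects
#'   pooling of log odds ratios, Cochran's Q / I-squared heterogeneity, and
#'   the conventional Q-driven choice between the two.
#' @name pooling
NULL

new_pooled_result <- function(model_used, k, log_or, se, weights, het,
                              single_study = FALSE) {
  w <- weights / sum(weights)
  structure(
    list(model_used = model_used, k = k,
         or = exp(log_or), ci_low = exp(log_or - Z95 * se),
         ci_high = exp(log_or + Z95 * se),
         log_or = log_or, se = se, weights = w, het = het,
         single_study = single_study),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled OR %.3f (95%% CI %.3f-%.3f), k = %d, %s-effect%s\n",
              x$or, x$ci_low, x$ci_high, x$k, x$model_used,
              if (isTRUE(x$single_study)) " [single study]" else ""))
  if (!is.null(x$het)) {
    cat(sprintf("Heterogeneity: Q = %.3f (df = %d, P = %.3g), I2 = %.1f%% (%s), tau2 = %.4f\n",
                x$het$q, x$het$df, x$het$p_q, x$het$i2, x$het$label,
                x$het$tau2))
  }
  invisible(x)
}

# apply the per-study 0.5 zero-cell correction used by both poolers
.corrected_cells <- function(contrasts) {
  a <- contrasts$a; b <- contrasts$b; c <- contrasts$c; d <- contrasts$d
  cc <- 0.5 * (a == 0 | b == 0 | c == 0 | d == 0)
  list(a = a + cc, b = b + cc, c = c + cc, d = d + cc)
}

#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Q is the inverse-variance weighted sum of squared deviations of the
#' per-study log odds ratios from their weighted mean, referred to a
#' chi-square with k - 1 df. I2 = 100 (Q - df) / Q, truncated at 0,
#' summarises the share of total variation attributable to between-study
#' heterogeneity, labelled mild (< 25%), moderate (25-50%) or large
#' (> 50%). tau2 is the DerSimonian-Laird moment estimator, truncated at 0.
#'
#' @param effects data frame from [estimate_effects()] (columns `yi`, `sei`).
#' @return list of class `heterogeneity_result`: `q`, `df`, `p_q`, `i2`
#'   (percent), `tau2`, `label`.
#' @examples
#' heterogeneity(estimate_effects(
#'   build_contrasts(tox3_dataset("rs8051542"), "allele")))
#' @export
heterogeneity <- function(effects) {
  k <- nrow(effects)
  if (k < 2L) stop("heterogeneity requires at least 2 studies", call. = FALSE)
  w <- 1 / effects$sei^2
  ybar <- sum(w * effects$yi) / sum(w)
  q <- sum(w * (effects$yi - ybar)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, 100 * (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(
    list(q = q, df = df,
         p_q = stats::pchisq(q, df = df, lower.tail = FALSE),
         i2 = i2, tau2 = tau2,
         label = if (i2 < 25) "mild" else if (i2 <= 50) "moderate" else "large"),
    class = "heterogeneity_result")
}

#' Mantel-Haenszel fixed-effect pooled odds ratio
#'
#' OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i), with the
#' Robins-Breslow-Greenland estimator for the variance of log OR_MH. A study
#' with a zero cell enters the sums with 0.5 added to all four of its cells
#' (consistently with [estimate_effects()]); other studies are unmodified.
#'
#' @param contrasts data frame from [build_contrasts()].
#' @return a `pooled_result` with `model_used = "fixed"`; `weights` are the
#'   normalised Mantel-Haenszel weights b_i c_i / n_i. Heterogeneity of the
#'   per-study log odds ratios is attached when k >= 2.
#' @examples
#' pool_mh_fixed(build_contrasts(tox3_dataset("rs8051542"), "allele"))
#' @export
pool_mh_fixed <- function(contrasts) {
  k <- nrow(contrasts)
  if (k < 1L) stop("no studies to pool", call. = FALSE)
  cl <- .corrected_cells(contrasts)
  a <- cl$a; b <- cl$b; c <- cl$c; d <- cl$d
  n <- a + b + c + d
  R <- a * d / n; S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0) {
    stop("all studies degenerate under Mantel-Haenszel pooling", call. = FALSE)
  }
  P <- (a + d) / n; Q <- (b + c) / n
  log_or <- log(sum(R) / sum(S))
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  het <- if (k >= 2L) heterogeneity(estimate_effects(contrasts)) else NULL
  new_pooled_result("fixed", k, log_or, sqrt(v),
                    stats::setNames(S, contrasts$study_id), het,
                    single_study = k == 1L)
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Between-study variance tau2 from the DerSimonian-Laird moment estimator
#' (truncated at 0), random-effects weights 1 / (sei^2 + tau2), and the
#' weighted mean log odds ratio with SE = 1 / sqrt(sum of weights). With
#' tau2 = 0 this reduces exactly to inverse-variance fixed-effect pooling.
#'
#' @param effects data frame from [estimate_effects()].
#' @return a `pooled_result` with `model_used = "random"` and the
#'   heterogeneity summary attached.
#' @examples
#' eff <- estimate_effects(build_contrasts(tox3_dataset("rs3803662"),
#'                                         "homozygote"))
#' pool_dl_random(eff)
#' @export
pool_dl_random <- function(effects) {
  k <- nrow(effects)
  if (k < 2L) stop("random-effects pooling requires at least 2 studies",
                   call. = FALSE)
  het <- heterogeneity(effects)
  w <- 1 / (effects$sei^2 + het$tau2)
  log_or <- sum(w * effects$yi) / sum(w)
  new_pooled_result("random", k, log_or, 1 / sqrt(sum(w)),
                    stats::setNames(w, effects$study_id), het)
}

#' Pool with Q-test-driven model selection
#'
#' Computes Cochran's Q on the per-study log odds ratios; when its P-value
#' exceeds `alpha_het` (conventionally 0.1) heterogeneity is judged absent
#' and the Mantel-Haenszel fixed-effect model is used, otherwise the
#' DerSimonian-Laird random-effects model. Selection is made independently
#' for each contrast and each (sub)group pooled.
#'
#' @param contrasts data frame from [build_contrasts()].
#' @param alpha_het heterogeneity threshold on the Q-test P-value.
#' @return a `pooled_result`; `model_used` records the choice. A single
#'   study is returned as its own (fixed) estimate, flagged `single_study`.
#' @examples
#' pool_auto(build_contrasts(tox3_dataset("rs8051542"), "allele"))
#' @export
pool_auto <- function(contrasts, alpha_het = 0.1) {
  stopifnot(alpha_het > 0, alpha_het < 1)
  k <- nrow(contrasts)
  if (k < 1L) stop("no studies to pool", call. = FALSE)
  if (k == 1L) return(pool_mh_fixed(contrasts))
  het <- heterogeneity(estimate_effects(contrasts))
  if (het$p_q > alpha_het) {
    pool_mh_fixed(contrasts)
  } else {
    pool_dl_random(estimate_effects(contrasts))
  }
}
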