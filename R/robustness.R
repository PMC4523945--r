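#' Subgroup-stratified pooling
#'
#' Splits a panel by a stratification column (ethnicity by default, or any
#' extra label column such as ER or BRCA status) and runs [pool_auto()] per
#' level and genetic model. Studies with a missing label are excluded with a
#' warning; empty levels are dropped. A level holding a single study is
#' reported as that study's own estimate, flagged as such.
#'
#' @param ds a [snp_dataset].
#' @param group_key name of the stratification column in `ds$studies`.
#' @param models character vector of genetic models to run.
#' @param alpha_het heterogeneity threshold passed to [pool_auto()].
#' @return object of class `subgroup_report`: a list with `group_key`,
#'   `table` (tidy data frame: `group`, `model`, `k`, `or`, `ci_low`,
#'   `ci_high`, `q`, `p_q`, `i2`, `tau2`, `model_used`, `single_study`) and
#'   `results` (nested list of `pooled_result`, `results[[level]][[model]]`).
#' @examples
#' rep <- subgroup_analysis(tox3_dataset("rs12443621"), "ethnicity", "allele")
#' rep$table
#' @export
subgroup_analysis <- function(ds, group_key = "ethnicity",
                              models = genetic_models(), alpha_het = 0.1) {
  stopifnot(inherits(ds, "snp_dataset"), length(models) >= 1L)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  if (!group_key %in% names(ds$studies)) {
    stop("no column '", group_key, "' in the dataset", call. = FALSE)
  }
  labels <- ds$studies[[group_key]]
  unlabeled <- is.na(labels) | labels == ""
  if (any(unlabeled)) {
    warning(sum(unlabeled), " study(ies) without a '", group_key,
            "' label excluded from stratification")
  }
  levels_ <- unique(labels[!unlabeled])
  results <- list()
  rows <- list()
  for (lev in levels_) {
    sub <- ds
    sub$studies <- ds$studies[!unlabeled & labels == lev, , drop = FALSE]
    results[[lev]] <- list()
    for (m in models) {
      pr <- pool_auto(build_contrasts(sub, m), alpha_het = alpha_het)
      results[[lev]][[m]] <- pr
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, model = m, k = pr$k, or = pr$or,
        ci_low = pr$ci_low, ci_high = pr$ci_high,
        q = if (is.null(pr$het)) NA_real_ else pr$het$q,
        p_q = if (is.null(pr$het)) NA_real_ else pr$het$p_q,
        i2 = if (is.null(pr$het)) NA_real_ else pr$het$i2,
        tau2 = if (is.null(pr$het)) NA_real_ else pr$het$tau2,
        model_used = pr$model_used, single_study = isTRUE(pr$single_study),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(group_key = group_key,
                 table = do.call(rbind, rows),
                 results = results),
            class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Subgroup analysis by '", x$group_key, "'\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the panel k times, omitting each study in turn, with
#' [pool_auto()] (so the fixed/random choice is remade on every reduced
#' panel). A pooled result that survives every omission with little movement
#' indicates no single dataset drives the conclusion.
#'
#' @param ds a [snp_dataset] with at least 3 studies.
#' @param model one of [genetic_models()].
#' @param alpha_het heterogeneity threshold passed to [pool_auto()].
#' @return object of class `loo_report`: `baseline` (the all-studies
#'   `pooled_result`), `rows` (data frame: `omitted`, `k`, `or`, `ci_low`,
#'   `ci_high`, `log_or`, `model_used`), and `max_abs_shift`, the largest
#'   |log OR - baseline log OR| over the omissions.
#' @examples
#' loo <- leave_one_out(tox3_dataset("rs8051542"), "allele")
#' loo$max_abs_shift
#' @export
leave_one_out <- function(ds, model = genetic_models(), alpha_het = 0.1) {
  stopifnot(inherits(ds, "snp_dataset"))
  model <- match.arg(model)
  contrasts <- build_contrasts(ds, model)
  k <- nrow(contrasts)
  if (k < 3L) stop("leave-one-out requires at least 3 studies", call. = FALSE)
  baseline <- pool_auto(contrasts, alpha_het = alpha_het)
  rows <- lapply(seq_len(k), function(i) {
    pr <- pool_auto(contrasts[-i, , drop = FALSE], alpha_het = alpha_het)
    data.frame(omitted = contrasts$study_id[i], k = pr$k, or = pr$or,
               ci_low = pr$ci_low, ci_high = pr$ci_high, log_or = pr$log_or,
               model_used = pr$model_used, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  structure(list(baseline = baseline, rows = rows,
                 max_abs_shift = max(abs(rows$log_or - baseline$log_or))),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d studies; baseline OR %.3f (%.3f-%.3f)\n",
              nrow(x$rows), x$baseline$or, x$baseline$ci_low,
              x$baseline$ci_high))
  cat(sprintf("Largest |log OR| shift on omission: %.4f\n", x$max_abs_shift))
  invisible(x)
}

#' Egger regression test for funnel-plot asymmetry
#'
#' Quantitative companion to visual funnel-plot inspection: ordinary least
#' squares of the standardised effect y_i / se_i on precision 1 / se_i. A
#' nonzero intercept indicates small-study asymmetry of the kind produced by
#' publication bias; its two-sided t-test uses k - 2 df. The per-study
#' funnel points (log OR against its standard error) are returned for
#' plotting or export.
#'
#' @param effects data frame from [estimate_effects()]; at least 3 studies.
#' @return object of class `funnel_report`: `egger_intercept`, `egger_se`,
#'   `egger_t`, `egger_p`, `df`, and `points` (data frame `study_id`, `yi`,
#'   `sei`).
#' @examples
#' eff <- estimate_effects(build_contrasts(tox3_dataset("rs8051542"),
#'                                         "allele"))
#' egger_test(eff)$egger_p
#' @export
egger_test <- function(effects) {
  k <- nrow(effects)
  if (k < 3L) stop("Egger regression requires at least 3 studies",
                   call. = FALSE)
  precision <- 1 / effects$sei
  if (stats::var(precision) < .Machine$double.eps^0.5) {
    stop("degenerate regression: all studies have identical precision",
         call. = FALSE)
  }
  fit <- stats::lm(I(effects$yi / effects$sei) ~ precision)
  cf <- summary(fit)$coefficients
  structure(
    list(egger_intercept = cf[1L, 1L], egger_se = cf[1L, 2L],
         egger_t = cf[1L, 3L], egger_p = cf[1L, 4L], df = k - 2L,
         points = data.frame(study_id = effects$study_id, yi = effects$yi,
                             sei = effects$sei, stringsAsFactors = FALSE)),
    class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat(sprintf("Egger test: intercept %.4f (SE %.4f), t = %.3f, df = %d, P = %.4f\n",
              x$egger_intercept, x$egger_se, x$egger_t, x$df, x$egger_p))
  invisible(x)
}

#' Export funnel points as delimited text
#'
#' Writes the per-study (log OR, SE) pairs of a [egger_test()] report as a
#' tab-delimited file (`study_id`, `log_or`, `se`) for external plotting.
#'
#' @param report a `funnel_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_funnel_points <- function(report, path) {
  stopifnot(inherits(report, "funnel_report"))
  out <- data.frame(study_id = report$points$study_id,
                    log_or = report$points$yi, se = report$points$sei,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
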