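#' @title Report rendering
#' @description Runs the full pipeline over a panel and writes the report
#'   bundle as delimited text plus a machine-readable run log. Figures are
#'   deliberately not rendered; the funnel/forest data files are the
#'   contract, keeping the package dependency-light.
#' @name report
NULL

format_or <- function(x) sprintf("%.3f", x)

format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

format_or_ci <- function(or, lo, hi) {
  sprintf("%s (%s-%s)", format_or(or), format_or(lo), format_or(hi))
}

.pooled_row <- function(group, model, pr) {
  data.frame(
    group = group, model = model, k = pr$k,
    or = pr$or, ci_low = pr$ci_low, ci_high = pr$ci_high,
    or_ci = format_or_ci(pr$or, pr$ci_low, pr$ci_high),
    q = if (is.null(pr$het)) NA_real_ else pr$het$q,
    p_h = if (is.null(pr$het)) "NA" else format_p(pr$het$p_q),
    i2 = if (is.null(pr$het)) NA_real_ else round(pr$het$i2, 1),
    tau2 = if (is.null(pr$het)) NA_real_ else pr$het$tau2,
    model_used = pr$model_used, stringsAsFactors = FALSE)
}

#' Run the full meta-analysis and write a report bundle
#'
#' For one SNP panel, computes per-study effects, pooled results (overall
#' and, optionally, stratified), leave-one-out sensitivity tables and funnel
#' points for every requested genetic model, and writes them as
#' tab-delimited files under `out_dir` together with a JSON run log
#' recording the configuration and package version. Identical inputs and
#' configuration produce byte-identical outputs.
#'
#' @param ds a [snp_dataset], or the path of a delimited study table (read
#'   with [read_dataset()] under the default schema).
#' @param models genetic models to analyse (default: all five).
#' @param group_key optional stratification column (e.g. `"ethnicity"`);
#'   `NULL` disables subgrouping.
#' @param out_dir output directory, created if absent.
#' @param alpha_het heterogeneity threshold for fixed/random selection.
#' @param alpha significance threshold recorded in the run log.
#' @param snp_id identifier used when `ds` is a file path.
#' @param prefix file-name prefix (default: the panel's SNP id).
#' @return invisibly, a list with the four data frames (`pooled`, `effects`,
#'   `loo`, `funnel`), the `hwe` table, and `paths` of the written files.
#' @examples
#' \donttest{
#' out <- run_analysis(tox3_dataset("rs8051542"), models = "allele",
#'                     group_key = "ethnicity", out_dir = tempdir())
#' out$pooled
#' }
#' @export
run_analysis <- function(ds, models = genetic_models(), group_key = NULL,
                         out_dir = ".", alpha_het = 0.1, alpha = 0.05,
                         snp_id = "snp", prefix = NULL) {
  if (is.character(ds)) ds <- read_dataset(ds, snp_id = snp_id)
  stopifnot(inherits(ds, "snp_dataset"))
  if (nrow(ds$studies) == 0L) stop("empty dataset", call. = FALSE)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  if (is.null(prefix)) prefix <- ds$snp_id
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }

  pooled_rows <- list(); effect_rows <- list()
  loo_rows <- list(); funnel_rows <- list()
  k <- nrow(ds$studies)
  for (m in models) {
    contrasts <- build_contrasts(ds, m)
    eff <- estimate_effects(contrasts)
    effect_rows[[m]] <- cbind(model = m, eff)
    pooled_rows[[m]] <- .pooled_row("Total", m,
                                    pool_auto(contrasts, alpha_het))
    if (k >= 3L) {
      loo <- leave_one_out(ds, m, alpha_het)
      loo_rows[[m]] <- cbind(model = m, loo$rows)
      fr <- egger_test(eff)
      funnel_rows[[m]] <- data.frame(
        model = m, study_id = fr$points$study_id, log_or = fr$points$yi,
        se = fr$points$sei, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(group_key)) {
    sg <- subgroup_analysis(ds, group_key, models, alpha_het)
    for (i in seq_len(nrow(sg$table))) {
      r <- sg$table[i, ]
      pooled_rows[[length(pooled_rows) + 1L]] <-
        .pooled_row(r$group, r$model, sg$results[[r$group]][[r$model]])
    }
  }

  tabs <- list(pooled = do.call(rbind, pooled_rows),
               effects = do.call(rbind, effect_rows),
               loo = if (length(loo_rows)) do.call(rbind, loo_rows) else NULL,
               funnel = if (length(funnel_rows)) do.call(rbind, funnel_rows)
                        else NULL,
               hwe = hwe_controls(ds, alpha))
  paths <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(out_dir, paste0(prefix, "_", nm, ".tsv"))
    utils::write.table(tabs[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- p
  }
  log_path <- file.path(out_dir, paste0(prefix, "_runlog.json"))
  jsonlite::write_json(
    list(snp_id = ds$snp_id, risk_allele = ds$risk_allele,
         ref_allele = ds$ref_allele, n_studies = k, models = models,
         group_key = group_key, alpha_het = alpha_het, alpha = alpha,
         package = "snpmeta",
         version = as.character(utils::packageVersion("snpmeta"))),
    log_path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  paths["runlog"] <- log_path
  tabs$paths <- paths
  invisible(tabs)
}
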