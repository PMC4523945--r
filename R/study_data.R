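#' @title Study panels of genotype counts
#' @description A `snp_dataset` holds one biallelic SNP's case-control panel:
#'   one row per study, with the three genotype counts for each arm ordered
#'   risk-allele homozygote, heterozygote, reference-allele homozygote. The
#'   risk allele is declared once per SNP so every downstream contrast is
#'   orientation-unambiguous.
#' @name snp_dataset
NULL

# canonical column names; any input table is mapped onto these via a schema
.count_cols <- c("case_hom_risk", "case_het", "case_hom_ref",
                 "ctrl_hom_risk", "ctrl_het", "ctrl_hom_ref")
.core_cols <- c("study_id", "ethnicity", .count_cols)

#' Construct a snp_dataset from a data frame of studies
#'
#' @param studies data frame with columns `study_id`, `ethnicity` and the six
#'   genotype-count columns `case_hom_risk`, `case_het`, `case_hom_ref`,
#'   `ctrl_hom_risk`, `ctrl_het`, `ctrl_hom_ref`; any further columns (year,
#'   reported HWE P-values, stratification labels) are carried along.
#' @param snp_id SNP identifier, e.g. `"rs8051542"`.
#' @param risk_allele,ref_allele single-character allele symbols; the counts
#'   must be oriented so that `*_hom_risk` counts `risk_allele` homozygotes.
#' @return A validated `snp_dataset` object.
#' @examples
#' ds <- snp_dataset(
#'   data.frame(study_id = "Toy 2020", ethnicity = "Asian",
#'              case_hom_risk = 30, case_het = 80, case_hom_ref = 90,
#'              ctrl_hom_risk = 20, ctrl_het = 85, ctrl_hom_ref = 95),
#'   snp_id = "rs0001", risk_allele = "T", ref_allele = "C")
#' summary(ds)
#' @export
snp_dataset <- function(studies, snp_id, risk_allele = NA_character_,
                        ref_allele = NA_character_) {
  stopifnot(is.data.frame(studies), is.character(snp_id), length(snp_id) == 1L)
  missing_cols <- setdiff(.core_cols, names(studies))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  rownames(studies) <- NULL
  validate_studies(studies)
  structure(
    list(snp_id = snp_id,
         risk_allele = as.character(risk_allele),
         ref_allele = as.character(ref_allele),
         studies = studies),
    class = "snp_dataset")
}

# row-level validation with diagnostics naming the offending row
validate_studies <- function(studies) {
  for (col in .count_cols) {
    v <- studies[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(is.na(v) | v < 0 | v != trunc(v))
    if (length(bad)) {
      stop("row ", bad[1L], " (", studies$study_id[bad[1L]], "): column '",
           col, "' must be a non-negative integer, got ", v[bad[1L]],
           call. = FALSE)
    }
  }
  ct <- studies$case_hom_risk + studies$case_het + studies$case_hom_ref
  nt <- studies$ctrl_hom_risk + studies$ctrl_het + studies$ctrl_hom_ref
  bad <- which(ct == 0 | nt == 0)
  if (length(bad)) {
    stop("row ", bad[1L], " (", studies$study_id[bad[1L]],
         "): both arms must have at least one subject", call. = FALSE)
  }
  dup <- studies$study_id[duplicated(studies$study_id)]
  if (length(dup)) {
    stop("duplicated study_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  invisible(studies)
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat("<snp_dataset> ", x$snp_id,
      if (!is.na(x$risk_allele)) paste0(" (risk allele ", x$risk_allele,
                                        ", reference ", x$ref_allele, ")"),
      "\n", sep = "")
  s <- dataset_summary(x)
  cat("  ", s$n_datasets, " studies, ", s$total_cases, " cases / ",
      s$total_controls, " controls\n", sep = "")
  invisible(x)
}

#' Totals over a study panel
#'
#' Number of studies and the exact integer sums of case and control subjects.
#'
#' @param ds a [snp_dataset].
#' @return list with `n_datasets`, `total_cases`, `total_controls`.
#' @examples
#' dataset_summary(tox3_dataset("rs8051542"))
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "snp_dataset"))
  s <- ds$studies
  list(n_datasets = nrow(s),
       total_cases = sum(s$case_hom_risk + s$case_het + s$case_hom_ref),
       total_controls = sum(s$ctrl_hom_risk + s$ctrl_het + s$ctrl_hom_ref))
}

#' @export
summary.snp_dataset <- function(object, ...) {
  s <- dataset_summary(object)
  cat(object$snp_id, ": ", s$n_datasets, " studies, ", s$total_cases,
      " cases, ", s$total_controls, " controls\n", sep = "")
  invisible(s)
}

#' Default column schema for delimited study tables
#'
#' A schema maps the canonical field names to the column names found in a
#' particular input file, so arbitrary published tables can be ingested
#' without renaming. The default schema is the identity mapping.
#'
#' @return named character vector (canonical field -> column name).
#' @export
default_schema <- function() {
  stats::setNames(.core_cols, .core_cols)
}

#' Read a study panel from delimited text
#'
#' Reads a comma- or tab-delimited table (header required, one row per
#' study), maps its columns onto the canonical fields through `schema`, and
#' returns a validated [snp_dataset]. Rows violating the count invariants are
#' rejected with a diagnostic naming the row.
#'
#' @param path file path.
#' @param snp_id SNP identifier for the panel.
#' @param schema named character vector mapping canonical fields
#'   (see [default_schema()]) to the file's column names, or the path to a
#'   JSON file holding such a mapping. Fields omitted from the schema keep
#'   their canonical names.
#' @param risk_allele,ref_allele allele symbols (optional metadata).
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return a [snp_dataset]; extra columns in the file are preserved.
#' @examples
#' path <- system.file("extdata", "rs8051542.tsv", package = "snpmeta")
#' ds <- read_dataset(path, snp_id = "rs8051542",
#'                    risk_allele = "T", ref_allele = "C")
#' @export
read_dataset <- function(path, snp_id, schema = default_schema(),
                         risk_allele = NA_character_,
                         ref_allele = NA_character_, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema) &&
      is.null(names(schema))) {
    schema <- unlist(jsonlite::read_json(schema, simplifyVector = TRUE))
  }
  full <- default_schema()
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), .core_cols)
    if (length(unknown)) {
      stop("schema names unknown field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full[names(schema)] <- schema
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  missing_cols <- setdiff(unname(full), names(raw))
  if (length(missing_cols)) {
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    empty <- as.data.frame(stats::setNames(
      c(list(character(0), character(0)), rep(list(integer(0)), 6L)),
      .core_cols))
    return(snp_dataset(empty, snp_id, risk_allele, ref_allele))
  }
  out <- raw
  names(out)[match(unname(full), names(raw))] <- names(full)
  for (col in .count_cols) {
    v <- out[[col]]
    if (is.character(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("row ", bad[1L], ": non-numeric count '", v[bad[1L]],
             "' in column '", col, "'", call. = FALSE)
      }
      v <- vn
    }
    if (any(!is.na(v) & v != trunc(v))) {
      bad <- which(!is.na(v) & v != trunc(v))
      stop("row ", bad[1L], ": non-integer count ", v[bad[1L]],
           " in column '", col, "'", call. = FALSE)
    }
    out[[col]] <- as.integer(v)
  }
  snp_dataset(out, snp_id, risk_allele, ref_allele)
}

#' Write a study panel as tab-delimited text
#'
#' Inverse of [read_dataset()] under the default schema: a written panel
#' reads back with identical counts and labels.
#'
#' @param ds a [snp_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "snp_dataset"))
  utils::write.table(ds$studies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# risk/reference orientation of the bundled TOX3 panels
.tox3_alleles <- list(
  rs3803662  = c(risk = "T", ref = "C"),
  rs12443621 = c(risk = "G", ref = "A"),
  rs8051542  = c(risk = "T", ref = "C"))

#' Bundled TOX3 breast-cancer study panels
#'
#' Published per-study genotype counts for three TOX3 SNPs genotyped in
#' breast-cancer case-control studies: rs3803662 (C>T, 42 datasets),
#' rs12443621 (A>G, 15 datasets) and rs8051542 (C>T, 15 datasets). Studies
#' that reported genotype frequencies separately by ethnic group appear as
#' separate rows. The `p_hwe_reported` column carries the control-group HWE
#' P-values as printed in the source tables (a character column: two values
#' are bounds such as `"<0.0001"`); it is reference metadata, not an input
#' to any computation, and can be compared against [hwe_controls()].
#'
#' @param snp one of `"rs3803662"`, `"rs12443621"`, `"rs8051542"`.
#' @return a [snp_dataset] with the risk allele declared (T, G and T
#'   respectively).
#' @examples
#' ds <- tox3_dataset("rs12443621")
#' dataset_summary(ds)
#' @export
tox3_dataset <- function(snp = c("rs3803662", "rs12443621", "rs8051542")) {
  snp <- match.arg(snp)
  path <- system.file("extdata", paste0(snp, ".tsv"), package = "snpmeta",
                      mustWork = TRUE)
  al <- .tox3_alleles[[snp]]
  read_dataset(path, snp_id = snp, risk_allele = al[["risk"]],
               ref_allele = al[["ref"]], sep = "\t")
}
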