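#' Per-study odds ratio with Woolf standard error
#'
#' For a 2x2 table (a exposed cases, b unexposed cases, c exposed controls,
#' d unexposed controls): OR = ad / bc, with the Woolf log-scale variance
#' 1/a + 1/b + 1/c + 1/d. When any cell is zero, 0.5 is added to all four
#' cells before both computations (the Review Manager continuity
#' convention) and the estimate is flagged `corrected`.
#'
#' @param a,b,c,d the four table cells.
#' @param study_id label propagated into the result.
#' @return one-row data frame: `study_id`, `yi` (log OR), `sei`, `or`,
#'   `ci_low`, `ci_high` (95% bounds on the OR scale), `corrected`.
#' @examples
#' estimate_effect(20, 10, 10, 20)     # OR 4, se sqrt(0.3)
#' estimate_effect(5, 0, 3, 7)         # zero cell -> 0.5 correction
#' @export
estimate_effect <- function(a, b, c, d, study_id = "study") {
  estimate_effects(data.frame(study_id = study_id, a = a, b = b, c = c, d = d,
                              stringsAsFactors = FALSE))
}

#' Per-study effects for a table of contrasts
#'
#' Vectorised [estimate_effect()] over the output of [build_contrasts()].
#'
#' @param contrasts data frame with columns `study_id`, `a`, `b`, `c`, `d`.
#' @return data frame with one row per study: `study_id`, `yi`, `sei`, `or`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @examples
#' estimate_effects(build_contrasts(tox3_dataset("rs8051542"), "allele"))
#' @export
estimate_effects <- function(contrasts) {
  stopifnot(is.data.frame(contrasts),
            all(c("a", "b", "c", "d") %in% names(contrasts)))
  a <- contrasts$a; b <- contrasts$b; c <- contrasts$c; d <- contrasts$d
  if (any(bad <- (a + b == 0 | c + d == 0))) {
    stop("degenerate table (an empty arm) for study ",
         contrasts$study_id[which(bad)[1L]], call. = FALSE)
  }
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  cc <- 0.5 * corrected
  a <- a + cc; b <- b + cc; c <- c + cc; d <- d + cc
  yi <- log(a * d / (b * c))
  sei <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  data.frame(study_id = if (is.null(contrasts$study_id))
               paste0("study", seq_along(a)) else contrasts$study_id,
             yi = yi, sei = sei, or = exp(yi),
             ci_low = exp(yi - Z95 * sei), ci_high = exp(yi + Z95 * sei),
             corrected = corrected, stringsAsFactors = FALSE)
}
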