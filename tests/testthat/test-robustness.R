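test_that("subgroup analysis partitions the labeled studies exactly", {
  ds <- tox3_dataset("rs12443621")
  rep <- subgroup_analysis(ds, "ethnicity", models = "allele")
  tab <- rep$table
  expect_setequal(tab$group, c("Asian", "Caucasian", "African"))
  expect_equal(tab$k[tab$group == "Asian"], 7L)
  expect_equal(tab$k[tab$group == "Caucasian"], 6L)
  expect_equal(tab$k[tab$group == "African"], 2L)
  expect_equal(sum(tab$k), nrow(ds$studies))

  # published Table values: Asian G-vs-A OR about 1.000, Caucasian 1.125
  expect_equal(tab$or[tab$group == "Asian"], 1.000, tolerance = 0.03)
  expect_equal(tab$or[tab$group == "Caucasian"], 1.125, tolerance = 0.03)
})

test_that("single-level grouping reproduces the whole-panel pooling", {
  ds <- toy_panel()
  ds$studies$all <- "everyone"
  rep <- subgroup_analysis(ds, "all", models = "dominant")
  whole <- pool_auto(build_contrasts(ds, "dominant"))
  expect_equal(rep$results$everyone$dominant$or, whole$or)
  expect_equal(rep$results$everyone$dominant$ci_low, whole$ci_low)
})

test_that("unlabeled studies are excluded with a warning; k = 1 flagged", {
  ds <- toy_panel()
  ds$studies$ethnicity[4] <- NA
  expect_warning(rep <- subgroup_analysis(ds, "ethnicity", "allele"),
                 "without")
  expect_equal(sum(rep$table$k), 3L)
  expect_true(rep$table$single_study[rep$table$group == "Caucasian"])
  expect_error(subgroup_analysis(ds, "no_such_column", "allele"),
               "no column")
})

test_that("leave-one-out structure and stability on the bundled panel", {
  ds <- tox3_dataset("rs8051542")
  loo <- leave_one_out(ds, "allele")
  expect_equal(nrow(loo$rows), 15L)
  expect_true(all(loo$rows$k == 14L))
  expect_setequal(loo$rows$omitted, ds$studies$study_id)
  # every omission OR stays inside the baseline 95% CI
  expect_true(all(loo$rows$or > loo$baseline$ci_low &
                  loo$rows$or < loo$baseline$ci_high))
  expect_equal(loo$max_abs_shift,
               max(abs(loo$rows$log_or - loo$baseline$log_or)))

  # identical studies: every omission returns the same OR
  rep5 <- replicated_panel(5)
  loo5 <- leave_one_out(rep5, "allele")
  expect_equal(length(unique(round(loo5$rows$or, 12))), 1L)
  expect_equal(loo5$max_abs_shift, 0, tolerance = 1e-12)
  expect_error(leave_one_out(replicated_panel(2), "allele"), "at least 3")
})

test_that("omitting the study at the pooled mean moves the estimate least", {
  # three studies at equal precision: one sits exactly on the mean effect
  eff_template <- data.frame(
    study_id = c("low", "mid", "high"),
    a = c(80, 100, 125), b = c(100, 100, 100),
    c = c(100, 100, 100), d = c(100, 100, 100))
  base <- pool_auto(eff_template)
  shifts <- vapply(1:3, function(i) {
    abs(pool_auto(eff_template[-i, ])$log_or - base$log_or)
  }, numeric(1))
  mid_is_mean <- which.min(abs(estimate_effects(eff_template)$yi -
                               base$log_or))
  expect_equal(which.min(shifts), mid_is_mean)
})

test_that("Egger regression: symmetric sets give a zero intercept", {
  # pairs y = +/- delta at equal se around 0, with varying precision
  eff <- data.frame(study_id = letters[1:6],
                    yi = c(0.2, -0.2, 0.1, -0.1, 0.05, -0.05),
                    sei = rep(c(0.2, 0.3, 0.4), each = 2))
  fr <- egger_test(eff)
  expect_equal(fr$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(fr$df, 4L)
  expect_equal(nrow(fr$points), 6L)

  # identical precisions make the regression rank deficient
  flat <- data.frame(study_id = letters[1:3], yi = c(0.1, 0.2, 0.3),
                     sei = c(0.2, 0.2, 0.2))
  expect_error(egger_test(flat), "degenerate")
  expect_error(egger_test(eff[1:2, ]), "at least 3")
})

test_that("suppressing small negative studies induces a positive intercept", {
  # simulation oracle: censor small studies with y below the mean and
  # check the intercept is usually significantly positive at alpha = 0.1
  set.seed(303)
  reps <- 60
  hits <- 0L
  for (r in seq_len(reps)) {
    k <- 40
    sei <- exp(runif(k, log(0.08), log(0.6)))
    yi <- rnorm(k, 0, sei)
    keep <- sei < 0.2 | yi > 0          # small studies published only if positive
    eff <- data.frame(study_id = paste0("s", seq_len(k)),
                      yi = yi, sei = sei)[keep, ]
    if (nrow(eff) < 5) next
    fr <- egger_test(eff)
    hits <- hits + (fr$egger_intercept > 0 && fr$egger_p < 0.1)
  }
  expect_gt(hits / reps, 0.5)
})

test_that("funnel points export round-trips through delimited text", {
  eff <- estimate_effects(build_contrasts(toy_panel(), "allele"))
  fr <- egger_test(eff)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_funnel_points(fr, path)
  back <- read.delim(path)
  expect_equal(back$study_id, fr$points$study_id)
  expect_equal(back$log_or, fr$points$yi)
  expect_equal(back$se, fr$points$sei)
})
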