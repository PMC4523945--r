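test_that("Mantel-Haenszel identities: k = 1 and replicated studies", {
  single <- build_contrasts(replicated_panel(1), "allele")
  pr <- pool_mh_fixed(single)
  e <- estimate_effects(single)
  expect_equal(pr$or, e$or)
  expect_equal(pr$k, 1L)
  expect_true(pr$single_study)

  dup <- data.frame(study_id = c("s1", "s2"), a = 20, b = 10, c = 10, d = 20)
  pr2 <- pool_mh_fixed(dup)
  expect_equal(pr2$or, 4)
  expect_equal(unname(pr2$weights), c(0.5, 0.5))
  expect_equal(sum(pr2$weights), 1)
  expect_error(pool_mh_fixed(dup[0, ]), "no studies")
})

test_that("MH pooled OR is invariant to scaling every cell", {
  contrasts <- build_contrasts(toy_panel(), "allele")
  base <- pool_mh_fixed(contrasts)$or
  for (m in c(2, 5)) {
    scaled <- contrasts
    scaled[, c("a", "b", "c", "d")] <- contrasts[, c("a", "b", "c", "d")] * m
    expect_equal(pool_mh_fixed(scaled)$or, base)
  }
})

test_that("DerSimonian-Laird moment estimator matches the hand oracle", {
  eff <- data.frame(study_id = c("s1", "s2"), yi = c(0, 0.5),
                    sei = c(0.1, 0.1))
  het <- heterogeneity(eff)
  # oracle: w = 100 each, weighted mean 0.25, Q = 100*(0.25^2)*2 = 12.5,
  # tau2 = (12.5 - 1) / (200 - 20000/200) = 0.115
  expect_equal(het$q, 12.5)
  expect_equal(het$tau2, 0.115)
  pr <- pool_dl_random(eff)
  w_star <- 1 / (0.01 + 0.115)
  expect_equal(pr$log_or, 0.25)
  expect_equal(pr$se, 1 / sqrt(2 * w_star))
  expect_equal(pr$model_used, "random")
  expect_error(pool_dl_random(eff[1, ]), "at least 2")
})

test_that("with tau2 = 0 DL equals inverse-variance fixed pooling", {
  # heterogeneous-looking but homogeneous effects: Q < df forces tau2 = 0
  eff <- data.frame(study_id = c("s1", "s2", "s3"),
                    yi = c(0.10, 0.11, 0.105), sei = c(0.3, 0.25, 0.4))
  het <- heterogeneity(eff)
  expect_equal(het$tau2, 0)
  pr <- pool_dl_random(eff)
  iv <- oracle_iv_fixed(eff$yi, eff$sei)
  expect_equal(pr$log_or, unname(iv["log_or"]))
  expect_equal(pr$se, unname(iv["se"]))

  # identical effects: Q = 0, P = 1
  same <- data.frame(study_id = c("a", "b"), yi = c(0.2, 0.2),
                     sei = c(0.1, 0.1))
  h0 <- heterogeneity(same)
  expect_equal(h0$q, 0)
  expect_equal(h0$p_q, 1)
})

test_that("I-squared follows its truncated formula and bands", {
  mk <- function(q, df) {
    # synthetic effects are irrelevant here; check the formula directly
    # through heterogeneity() on constructed inputs is impractical for a
    # target Q, so assert the algebra on the returned object instead
    list(i2 = if (q > 0) max(0, 100 * (q - df) / q) else 0)
  }
  expect_equal(mk(28, 14)$i2, 50)
  expect_equal(mk(10, 14)$i2, 0)
  # and that heterogeneity() agrees with the same algebra on real effects
  eff <- estimate_effects(build_contrasts(tox3_dataset("rs8051542"),
                                          "allele"))
  het <- heterogeneity(eff)
  expect_equal(het$i2, max(0, 100 * (het$q - het$df) / het$q))
  expect_equal(het$label, "mild")
  expect_gte(het$tau2, 0)
})

test_that("pool_auto applies the Q-test rule at alpha_het = 0.1", {
  # bundled rs8051542 allele panel: P_Q about 0.39, fixed model selected
  c8 <- build_contrasts(tox3_dataset("rs8051542"), "allele")
  pr8 <- pool_auto(c8)
  expect_equal(pr8$model_used, "fixed")
  expect_gt(pr8$het$p_q, 0.1)

  # bundled rs3803662 panel: massive heterogeneity, random selected
  c3 <- build_contrasts(tox3_dataset("rs3803662"), "homozygote")
  pr3 <- pool_auto(c3)
  expect_equal(pr3$model_used, "random")
  expect_lt(pr3$het$p_q, 0.001)

  # duplicated studies are homogeneous: fixed, common OR
  dup <- data.frame(study_id = c("s1", "s2"), a = 20, b = 10, c = 10, d = 20)
  pra <- pool_auto(dup)
  expect_equal(pra$model_used, "fixed")
  expect_equal(pra$or, 4)
  expect_error(pool_auto(dup, alpha_het = 0))
})

test_that("fixed CI is never wider than random CI when tau2 > 0", {
  c3 <- build_contrasts(tox3_dataset("rs3803662"), "homozygote")
  eff <- estimate_effects(c3)
  expect_gt(heterogeneity(eff)$tau2, 0)
  fixed <- pool_mh_fixed(c3)
  random <- pool_dl_random(eff)
  expect_lte(log(fixed$ci_high) - log(fixed$ci_low),
             log(random$ci_high) - log(random$ci_low))
})

test_that("pooling recovers a known per-allele OR from simulated panels", {
  # 500 panels of 20 studies, true OR 1.15, no heterogeneity
  set.seed(909)
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    ds <- simulate_panel(sim_config(k = 20, p_risk = 0.3, or_allele = 1.15,
                                    tau = 0, n_cases = 1000,
                                    n_controls = 1000))
    pr <- pool_auto(build_contrasts(ds, "allele"))
    hits <- hits + (pr$ci_low < 1.15 && 1.15 < pr$ci_high)
  }
  expect_gte(hits / reps, 0.93)
})
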