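# Stepwise covariate selection mechanics on small cohorts (power/recovery
# rates over seeds live in the acceptance suite).

test_that("forward step returns the base model when nothing qualifies", {
  co <- small_cohort(n = 15, seed = 3)
  base <- reference_popmodel("pk")
  base$covariates <- list()
  f0 <- fit_stage_pk(co, base, ctrl1())
  # absurdly high threshold: nothing can enter
  fw <- forward_include(co, f0,
                        covariate_candidates("pk")[1:4],
                        dofv_in = 1e6, control = ctrl1())
  expect_equal(length(fw$fit$model$covariates), 0)
  expect_equal(fw$fit$ofv, f0$ofv)
  expect_true(all(fw$audit$decision != "included"))
})

test_that("backward deletion leaves a covariate-free model untouched", {
  co <- small_cohort(n = 15, seed = 3)
  base <- reference_popmodel("pk")
  base$covariates <- list()
  f0 <- fit_stage_pk(co, base, ctrl1())
  bw <- backward_delete(co, f0, control = ctrl1())
  expect_equal(length(bw$fit$model$covariates), 0)
  expect_null(bw$audit)
})

test_that("a strong generating effect is found and survives deletion", {
  # boost the CYP2C9*3 carrier fraction so the small cohort has power
  sp <- cohort_spec(n_patients = 40, missing_npt0 = 0,
                    maf = c(cyp2c9_star3 = 0.3, vkorc1_star1 = 0.096,
                            cyp4f2_star3 = 0.278))
  co <- simulate_cohort(sp, seed = 19)
  cands <- list(list(param = "cl", name = "cyp2c9_star3",
                     kind = "categorical"),
                list(param = "cl", name = "sex", kind = "categorical"))
  sr <- covariate_search(co, "pk", candidates = cands, control = ctrl1())
  expect_true("cyp2c9_star3" %in% sr$selected)
  # audit: every retained covariate survived a tested deletion
  expect_true(all(c("forward", "backward") %in% sr$audit$phase))
  # final model OFV does not exceed the base fit
  base <- reference_popmodel("pk"); base$covariates <- list()
  f0 <- fit_stage_pk(co, base, ctrl1())
  expect_lte(sr$fit$ofv, f0$ofv)
})

test_that("degenerate candidates are skipped with a log entry", {
  co <- small_cohort(n = 15, seed = 3)
  co$covariates$constant_flag <- 0
  base <- reference_popmodel("pk"); base$covariates <- list()
  f0 <- fit_stage_pk(co, base, ctrl1())
  fw <- forward_include(co, f0,
                        list(list(param = "cl", name = "constant_flag",
                                  kind = "categorical")),
                        control = ctrl1())
  expect_true(any(grepl("degenerate", fw$audit$decision)))
  expect_equal(length(fw$fit$model$covariates), 0)
})
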