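# Small synthetic window scenario: children with one visit per window.
window_scenario <- function(n = 300, nw = 4, beta_f = 0.5, beta_m = beta_f,
                            sd_noise = 1, seed = 13) {
  set.seed(seed)
  sex <- sample(c("F", "M"), n, TRUE)
  met <- rnorm(n)
  growth <- purrr::map_dfr(seq_len(nw), function(w) {
    b <- ifelse(sex == "F", beta_f, beta_m)
    tibble::tibble(
      child_id = sprintf("c%04d", seq_len(n)),
      sex = sex,
      age_months = (w - 1) * 12 + runif(n, 1, 11),
      bmi = 16 + 0.1 * w + b * met + rnorm(n, 0, sd_noise))
  })
  windows <- tibble::tibble(index = seq_len(nw),
                            age_lo = (seq_len(nw) - 1) * 12,
                            age_hi = seq_len(nw) * 12,
                            width = 12, n_children = n)
  exposures <- tibble::tibble(child_id = sprintf("c%04d", seq_len(n)),
                              met = met)
  list(growth = growth, windows = windows, exposures = exposures,
       sex = sex, met = met)
}

test_that("window models recover a planted sex-neutral effect", {
  sc <- window_scenario(beta_f = 0.5)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures)
  expect_equal(nrow(ef), 4)
  expect_true(all(abs(ef$beta_F - 0.5) < 0.2))
  expect_true(all(abs(ef$beta_M - 0.5) < 0.2))
  # no planted sex difference: most interaction tests stay null
  expect_gte(sum(ef$int_p > 0.05), 3)
  # overall effect overwhelmingly significant
  expect_true(all(ef$lrt_p < 1e-6))
  expect_true(all(ef$lrt_stat >= 0))
})

test_that("OLS slopes match the normal-equations closed form", {
  sc <- window_scenario(n = 60, nw = 1, seed = 14)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures)
  # rebuild the design by hand for window 1
  d <- sc$growth
  X <- model.matrix(~ met + sex + met:sex + age,
    data = data.frame(met = sc$met, sex = factor(sc$sex),
                      age = d$age_months, check.names = FALSE))
  beta_hat <- solve(crossprod(X), crossprod(X, d$bmi))
  expect_equal(ef$beta_F, unname(beta_hat["met", 1]), tolerance = 1e-8)
  expect_equal(ef$beta_M,
               unname(beta_hat["met", 1] + beta_hat["met:sexM", 1]),
               tolerance = 1e-8)
})

test_that("standardized effects divide by within-sex BMI spread", {
  sc <- window_scenario(n = 200, nw = 2, beta_f = 0.4, seed = 15)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures)
  wm <- window_average(sc$growth, sc$windows, "bmi")
  sd_f <- sd(wm$values[sc$sex == "F", 1])
  expect_equal(ef$std_beta_F[1], ef$beta_F[1] / sd_f, tolerance = 1e-10)
  # common rescaling of BMI leaves standardized betas unchanged
  sc2 <- sc
  sc2$growth$bmi <- sc$growth$bmi * 2
  ef2 <- window_effects(sc2$growth, sc$windows, sc$exposures)
  expect_equal(ef2$std_beta_F, ef$std_beta_F, tolerance = 1e-8)
  expect_equal(ef2$std_beta_M, ef$std_beta_M, tolerance = 1e-8)
  # zero slope standardizes to zero
  expect_equal(0 / sd_f, 0)
})

test_that("null exposures give calibrated LRT p-values", {
  sc <- window_scenario(n = 250, nw = 4, beta_f = 0, seed = 16)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures)
  expect_true(all(ef$lrt_p > 1e-4)) # no spurious extreme significance
})

test_that("the birthweight adjuster is skipped in the first window", {
  sc <- window_scenario(n = 100, nw = 3, seed = 17)
  cov <- tibble::tibble(child_id = sc$exposures$child_id,
                        birthweight = rnorm(100, 3100, 500))
  ef <- window_effects(sc$growth, sc$windows, sc$exposures,
                       covariate_data = cov,
                       extra_adjust = "birthweight")
  expect_match(ef$flag[ef$window == 1], "birthweight_skipped")
  expect_false(any(grepl("birthweight_skipped", ef$flag[ef$window > 1])))
  # a pure-noise adjuster barely moves the estimates
  ef0 <- window_effects(sc$growth, sc$windows, sc$exposures)
  expect_lt(max(abs(ef$beta_F[-1] - ef0$beta_F[-1])), 0.1)
})

test_that("under-populated and single-sex windows are flagged", {
  sc <- window_scenario(n = 30, nw = 2, seed = 18)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures, min_n = 50)
  expect_true(all(grepl("too_few_cases", ef$flag)))
  expect_true(all(is.na(ef$beta_F)))
  g_f <- sc$growth[sc$growth$sex == "F", ]
  ef_f <- window_effects(g_f, sc$windows, sc$exposures, min_n = 5)
  expect_true(all(grepl("single_sex", ef_f$flag)))
  expect_equal(ef_f$beta_F, ef_f$beta_M)
})

test_that("significance counts and the heatmap mask are consistent", {
  sc <- window_scenario(n = 250, nw = 5, beta_f = 0.6, seed = 19)
  # add a null exposure alongside the planted one
  sc$exposures$null_met <- rnorm(250)
  ef <- window_effects(sc$growth, sc$windows, sc$exposures)
  counts <- count_significant(ef, "lrt")
  expect_equal(nrow(counts), 5)
  expect_equal(counts$n_tested, rep(2L, 5))
  expect_true(all(counts$n_significant >= 1)) # planted effect found
  # empty effect table -> zero rows
  expect_equal(nrow(count_significant(ef[0, ], "lrt")), 0)
  ann <- tibble::tibble(metabolite = c("met", "null_met"),
                        type = c("TAG", "AC"),
                        platform = c("C8-pos", "HILIC-pos"))
  hm <- effect_heatmap_matrix(ef, sex = "F", mask = "lrt",
                              annotation = ann)
  expect_equal(hm$row_order, c("met", "null_met")) # platform then type
  expect_equal(dim(hm$values), c(2, 5))
  # mask agrees with the q-values and masked cells keep their raw values
  for (w in 1:5) {
    q <- ef$lrt_q[ef$exposure == "met" & ef$window == w]
    expect_equal(hm$masked["met", w], is.na(q) || q > 0.05)
    expect_equal(hm$values["met", w],
                 ef$std_beta_F[ef$exposure == "met" & ef$window == w])
  }
})
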