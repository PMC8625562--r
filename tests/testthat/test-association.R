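test_that("saturated 2x3 fit reproduces closed-form odds ratios", {
  d <- data.frame(
    y = c(rep(c("a", "b", "c"), c(10, 10, 10)),
          rep(c("a", "b", "c"), c(10, 20, 5))),
    x = rep(c(0, 1), c(30, 35)))
  fit <- fit_multinomial(d, "y", "x", reference = "a")
  td <- tidy(fit)
  or_b <- td$or[td$term == "x" & td$contrast == "b vs a"]
  or_c <- td$or[td$term == "x" & td$contrast == "c vs a"]
  expect_equal(or_b, 2, tolerance = 1e-6) # (20/10)/(10/10)
  expect_equal(or_c, 0.5, tolerance = 1e-6) # (5/10)/(10/10)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # intercepts reproduce the x = 0 cell ratios (all equal -> 0)
  expect_equal(unname(fit$coefficients[, "(Intercept)"]), c(0, 0),
               tolerance = 1e-6)
})

test_that("the Newton-Raphson fit agrees with an independent optimizer", {
  skip_if_not_installed("nnet")
  set.seed(31)
  n <- 400
  d <- data.frame(
    x = rnorm(n), z = rnorm(n),
    g = factor(sample(c("p", "q", "r"), n, TRUE)))
  fit <- fit_multinomial(d, "g", "x", covariates = "z", reference = "p")
  ref <- nnet::multinom(g ~ x + z, data = d, trace = FALSE,
                        reltol = 1e-14, maxit = 500)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-5)
  expect_equal(fit$loglik, -ref$value, tolerance = 1e-8)
})

test_that("odds ratio per SD is invariant to affine exposure rescaling", {
  set.seed(32)
  n <- 500
  d <- data.frame(x = rnorm(n, 10, 3),
                  g = factor(sample(c("p", "q", "r"), n, TRUE)))
  d$x2 <- (d$x - mean(d$x)) / sd(d$x)
  f1 <- fit_multinomial(d, "g", "x", reference = "p")
  f2 <- fit_multinomial(d, "g", "x2", reference = "p")
  b1 <- f1$coefficients[, "x"] * sd(d$x)
  b2 <- f2$coefficients[, "x2"] * sd(d$x2)
  expect_equal(unname(b1), unname(b2), tolerance = 1e-6)
})

test_that("planted per-SD log-odds are recovered without bias", {
  set.seed(5)
  n <- 400
  beta <- 0.4
  reps <- 40
  est <- replicate(reps, {
    x <- rnorm(n)
    # baseline-category logits: class 2 loaded on x, class 3 flat
    e2 <- exp(beta * x)
    p <- cbind(1, e2, 1)
    p <- p / rowSums(p)
    y <- apply(p, 1, function(pr) sample(3, 1, prob = pr))
    d <- data.frame(y = factor(y), x = x)
    fit <- fit_multinomial(d, "y", "x", reference = "1")
    fit$coefficients["2", "x"]
  })
  mcse <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - beta), 3 * mcse + 1e-8)
})

test_that("degenerate exposures are flagged, not silently dropped", {
  set.seed(33)
  d <- data.frame(g = factor(rep(c("p", "q", "r"), each = 30)))
  d$sep <- as.numeric(d$g == "q") # perfect separation
  fit <- fit_multinomial(d, "g", "sep", reference = "p")
  expect_true(fit$separation)
  # constant-zero exposure leaves the intercept-only likelihood
  d$zero <- 0
  fit0 <- fit_multinomial(d, "g", "zero", reference = "p")
  expect_equal(unname(fit0$coefficients[, "zero"]), c(0, 0))
  expect_equal(fit0$loglik, 90 * log(1 / 3), tolerance = 1e-6)
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(c(1, 3), 1)
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("module association orders by early-contrast FDR and dedupes", {
  coh <- shared_cohort()
  asg <- truth_group3(coh$truth$classes)
  pan <- prepare_metabolome(coh$panel)
  part <- detect_modules(pan)
  res <- module_association(part$eigenscores, asg, coh$covariates,
                            covariates = covariate_set())
  expect_setequal(unique(res$contrast),
                  c("early-OWO vs NW", "late-OWO vs NW"))
  early <- res[res$contrast == "early-OWO vs NW", ]
  expect_true(!is.unsorted(early$q))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$or, exp(res$beta))
  expect_equal(res$ci_lo, exp(res$beta - 1.96 * res$se))
  # an identical duplicated module yields identical rows
  scores2 <- part$eigenscores[, c("child_id", part$modules$module[1])]
  scores2$copy <- scores2[[2]]
  res2 <- module_association(scores2, asg, coh$covariates,
                             covariates = covariate_set())
  a <- res2[res2$exposure == part$modules$module[1], c("beta", "se", "p")]
  b <- res2[res2$exposure == "copy", c("beta", "se", "p")]
  expect_equal(a, b)
})

test_that("four-group screen recommends the collapse seen in the cohort", {
  coh <- shared_cohort()
  pct <- bmi_percentile(coh$growth, coh$reference)
  wm <- impute_adjacent(window_average(pct, build_windows(pct), "bmipct"))
  asg <- classify_trajectories(wm, seed = 1)
  pan <- prepare_metabolome(coh$panel)
  # subset of metabolites keeps the runtime small; family = tested set
  mets <- panel_matrix(pan)
  sub <- colnames(mets)[c(1:20, 150:169, 300:319)]
  res <- suppressWarnings(metabolite_association(
    pan, asg, group_col = "group4", covariate_data = coh$covariates,
    covariates = covariate_set(), reference = "NW-A", metabolites = sub))
  expect_equal(nrow(res), 3 * length(sub))
  # NW-B is small at this cohort size; the per-fit warning is expected
  ex <- suppressWarnings(explore_four_groups(pan, asg, coh$covariates,
                                             covariates = covariate_set()))
  expect_true(ex$collapse_recommended)
  nwb <- ex$counts[grepl("^NW-B", ex$counts$contrast), ]
  expect_equal(nwb$n_q05, 0L)
})

test_that("member follow-up restricts the FDR family to selected modules", {
  coh <- shared_cohort()
  asg <- truth_group3(coh$truth$classes)
  pan <- prepare_metabolome(coh$panel)
  part <- detect_modules(pan)
  res <- module_association(part$eigenscores, asg, coh$covariates,
                            covariates = covariate_set())
  fol <- member_followup(pan, part, res, asg, coh$covariates,
                         covariates = covariate_set())
  sel <- unique(res$exposure[res$p <= 0.05])
  members <- part$membership$metabolite[part$membership$module %in% sel]
  expect_setequal(unique(fol$exposure), members)
  expect_equal(sum(fol$contrast == "early-OWO vs NW"), length(members))
  # no module selected -> empty table
  res_none <- res
  res_none$p <- 1
  expect_equal(nrow(member_followup(pan, part, res_none, asg,
                                    coh$covariates,
                                    covariates = covariate_set())), 0)
})

test_that("sex-interaction LRT has the right dimension and detects effects", {
  set.seed(41)
  n <- 900
  sex <- sample(c("F", "M"), n, TRUE)
  x <- rnorm(n)
  # female-only exposure effect on class q
  lp <- ifelse(sex == "F", 0.5, 0) * x
  p <- cbind(1, exp(lp), 1)
  p <- p / rowSums(p)
  y <- apply(p, 1, function(pr) sample(c("nw", "q", "r"), 1, prob = pr))
  d <- data.frame(y = y, x = x, sex = sex)
  res <- sex_interaction_lrt(d, "y", "x", reference = "nw")
  expect_equal(res$lrt$df, 4) # 2 contrasts x (main + interaction)
  expect_lt(res$lrt$p, 0.01)
  expect_equal(nrow(res$interaction), 2)
  expect_gte(res$lrt$stat, 0)
  # single-sex input errors
  expect_error(
    sex_interaction_lrt(d[d$sex == "M", ], "y", "x", reference = "nw"),
    "both sexes")
})
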