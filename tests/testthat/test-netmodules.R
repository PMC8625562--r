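test_that("scale-free fit index scores an exact power law as 1", {
  # connectivities 1, 2, 5, 10 with frequencies proportional to k^-2
  # (counts 100, 25, 4, 1 are exactly proportional), each in its own bin
  k <- rep(c(1, 2, 5, 10), times = c(100, 25, 4, 1))
  expect_equal(scale_free_fit(k), 1, tolerance = 1e-6)
  # uniform connectivity: single bin, undefined
  expect_true(is.na(scale_free_fit(rep(3, 50))))
  # Poisson (random-graph-like) connectivity is far from scale-free
  set.seed(11)
  expect_lt(scale_free_fit(rpois(300, 20) + 1), 0.5)
  expect_error(scale_free_fit(c(-1, 2)), "positive")
})

test_that("power selection reaches the plateau target on block structure", {
  coh <- shared_cohort()
  pan <- prepare_metabolome(coh$panel)
  p <- pick_power(cor(panel_matrix(pan)))
  d <- attr(p, "diagnostics")
  expect_true(is.finite(p) && p %in% d$power)
  expect_gte(max(d$r_squared, na.rm = TRUE), 0.80)
  expect_gte(d$r_squared[d$power == p], 0.80)
  # identity correlation: no plateau, fallback path
  p0 <- pick_power(diag(30))
  expect_true(is.finite(p0))
  # config override wins (the conventional choice is 7)
  expect_equal(as.integer(pick_power(diag(30), override = 7)), 7L)
})

test_that("TOM matches the double-loop oracle and stays in [0, 1]", {
  set.seed(5)
  x <- matrix(rnorm(60 * 50), 60, 50)
  adj <- soft_adjacency(cor(x), 7)
  tom <- tom_similarity(adj)
  expect_lt(max(abs(tom - tom_oracle(adj))), 1e-10)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(unname(diag(tom)), rep(1, 50))
})

test_that("planted blocks are recovered exactly at high correlation", {
  skip_if_not_installed("mclust")
  truth <- toy_truth(300, seed = 3)
  blocks <- tibble::tibble(
    block = paste0("b", 1:5), type = "TAG", platform = "C8-pos",
    size = c(20L, 18L, 16L, 15L, 22L),
    shift_early = 0, shift_late = 0)
  set.seed(103)
  met <- generate_metabolome(truth, blocks = blocks, rho = 0.7,
                             n_singles = 0, n_junk = 0)
  pan <- prepare_metabolome(met$panel)
  part <- detect_modules(pan, power = 7, min_size = 15)
  memb <- dplyr::inner_join(part$membership, met$membership,
                            by = "metabolite")
  expect_equal(nrow(part$modules), 5)
  expect_true(all(memb$module != "grey"))
  expect_equal(mclust::adjustedRandIndex(memb$module, memb$block), 1)
})

test_that("independent metabolites and under-sized blocks go grey", {
  set.seed(8)
  x <- matrix(rnorm(200 * 60), 200, 60,
              dimnames = list(sprintf("c%03d", 1:200),
                              sprintf("m%02d", 1:60)))
  part <- detect_modules(x, power = 7, min_size = 15)
  expect_true(all(part$membership$module == "grey"))
  expect_equal(nrow(part$modules), 0)
  # a planted block of 10 (< min_size) stays grey
  truth <- toy_truth(300, seed = 9)
  blocks <- tibble::tibble(
    block = c("big", "small"), type = "TAG", platform = "C8-pos",
    size = c(20L, 10L), shift_early = 0, shift_late = 0)
  set.seed(109)
  met <- generate_metabolome(truth, blocks = blocks, rho = 0.7,
                             n_singles = 0, n_junk = 0)
  part2 <- detect_modules(prepare_metabolome(met$panel),
                          power = 7, min_size = 15)
  memb <- dplyr::inner_join(part2$membership, met$membership,
                            by = "metabolite")
  expect_true(all(memb$module[memb$block == "small"] == "grey"))
  expect_true(all(memb$module[memb$block == "big"] != "grey"))
})

test_that("partition is invariant to column order and column sign flips", {
  truth <- toy_truth(250, seed = 12)
  blocks <- tibble::tibble(
    block = c("u", "v"), type = "TAG", platform = "C8-pos",
    size = c(18L, 16L), shift_early = 0, shift_late = 0)
  set.seed(112)
  met <- generate_metabolome(truth, blocks = blocks, rho = 0.7,
                             n_singles = 5, n_junk = 0)
  m <- panel_matrix(prepare_metabolome(met$panel))
  base <- detect_modules(m, power = 7, min_size = 15)$membership
  # permute columns
  perm <- sample(ncol(m))
  permuted <- detect_modules(m[, perm], power = 7, min_size = 15)$membership
  j <- dplyr::inner_join(base, permuted, by = "metabolite",
                         suffix = c("_a", "_b"))
  expect_equal(j$module_a, j$module_b)
  # unsigned network: negating whole columns changes nothing
  flip <- m
  flip[, seq(1, ncol(m), by = 2)] <- -flip[, seq(1, ncol(m), by = 2)]
  flipped <- detect_modules(flip, power = 7, min_size = 15)$membership
  expect_equal(base$module, flipped$module)
  # zero-variance column is rejected
  bad <- m
  bad[, 1] <- 1
  expect_error(detect_modules(bad, power = 7), "zero-variance")
})

test_that("eigen-metabolite scores are unit variance, oriented, and sized", {
  set.seed(21)
  n <- 900
  # two perfectly correlated members
  base <- rnorm(n)
  m2 <- cbind(a = base, b = 2 * base + 5)
  rownames(m2) <- sprintf("c%03d", 1:n)
  s <- module_eigenscore(m2, c("a", "b"))
  expect_equal(sd(s), 1)
  expect_gt(cor(s, base), 0.999)
  # equicorrelated block of 20 at rho = 0.7: PC1 variance fraction
  # approaches (1 + 19 * 0.7) / 20 = 0.715
  f <- rnorm(n)
  m20 <- sapply(1:20, function(i) sqrt(0.7) * f + sqrt(0.3) * rnorm(n))
  colnames(m20) <- paste0("m", 1:20)
  rownames(m20) <- rownames(m2)
  s20 <- module_eigenscore(m20, colnames(m20))
  expect_equal(attr(s20, "var_explained"), 0.715, tolerance = 0.05)
  # orientation survives negating one member (average-dominated module)
  m20_neg <- m20
  m20_neg[, 3] <- -m20_neg[, 3]
  s_neg <- module_eigenscore(m20_neg, colnames(m20))
  expect_gt(cor(s20, s_neg), 0.95)
  expect_error(module_eigenscore(m20, "m1"), "at least 2")
})
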