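test_that("window construction respects population and width constraints", {
  # all children measured at one age: a single window containing that age
  g1 <- tibble::tibble(child_id = sprintf("c%03d", 1:60), sex = "F",
                       age_months = 6.2, bmi = 16)
  w1 <- build_windows(g1)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$n_children, 60L)
  expect_true(w1$age_lo <= 6.2 && w1$age_hi > 6.2)
  # a 24-month empty gap forces at least two windows
  g2 <- dplyr::bind_rows(
    tibble::tibble(child_id = sprintf("a%03d", 1:60), age_months = 6, bmi = 16),
    tibble::tibble(child_id = sprintf("b%03d", 1:60), age_months = 30, bmi = 16))
  w2 <- build_windows(g2)
  expect_gte(nrow(w2), 2)
  expect_true(all(w2$width <= 12))
  expect_true(all(w2$n_children >= 30))
  # too small a cohort errors
  g3 <- tibble::tibble(child_id = sprintf("c%02d", 1:10), age_months = 6,
                       bmi = 16)
  expect_error(build_windows(g3), "fewer than")
})

test_that("windows on a generated cohort satisfy both constraints", {
  coh <- shared_cohort()
  wb <- build_windows(coh$growth)
  expect_true(all(wb$n_children >= 30))
  expect_true(all(wb$width <= 12))
  # disjoint and ordered
  expect_true(all(diff(wb$age_lo) > 0))
  expect_true(all(wb$age_hi[-nrow(wb)] <= wb$age_lo[-1] + 1e-9))
  # percentile-scale windows only span age >= 2 y
  pct <- bmi_percentile(coh$growth, coh$reference)
  wp <- build_windows(pct)
  expect_gte(min(wp$age_lo), 24)
  expect_true(all(wp$n_children >= 30) && all(wp$width <= 12))
})

test_that("window averaging fills cells with per-child means", {
  w <- tibble::tibble(index = 1:2, age_lo = c(0, 12), age_hi = c(12, 24))
  g <- tibble::tibble(
    child_id = c("a", "a", "b"), sex = "F",
    age_months = c(3, 9, 15),
    bmi = c(30.2, 29.8, 17))
  wm <- window_average(g, w, "bmi")
  expect_equal(wm$values["a", ], c(w1 = 30, w2 = NA_real_))
  expect_equal(wm$values["b", ], c(w1 = NA_real_, w2 = 17))
  expect_equal(wm$mask["a", ], c(w1 = TRUE, w2 = FALSE))
  expect_equal(wm$provenance["b", "w1"], "missing")
})

test_that("adjacent imputation averages bracketing values and carries edges", {
  w <- tibble::tibble(index = 1:5, age_lo = 0:4 * 12, age_hi = 1:5 * 12)
  mk <- function(rows) {
    g <- purrr::imap_dfr(rows, function(v, id) {
      obs <- which(!is.na(v))
      tibble::tibble(child_id = id, sex = "F",
                     age_months = (obs - 1) * 12 + 6, bmi = v[obs])
    })
    window_average(g, w, "bmi")
  }
  wm <- mk(list(r1 = c(NA, 40, NA, 60, NA),
                r2 = c(70, NA, NA, 30, 10)))
  out <- impute_adjacent(wm)
  expect_equal(unname(out$values["r1", ]), c(40, 40, 50, 60, 60))
  expect_equal(unname(out$provenance["r1", ]),
               c("edge_filled", "observed", "interpolated", "observed",
                 "edge_filled"))
  # both interior gaps bracket the same pair
  expect_equal(unname(out$values["r2", ]), c(70, 50, 50, 30, 10))
  # idempotent, observed cells untouched
  out2 <- impute_adjacent(out)
  expect_identical(out2$values, out$values)
  expect_equal(out$values["r1", 2], wm$values["r1", 2])
  # fully observed row unchanged
  wm3 <- mk(list(r3 = c(1, 2, 3, 4, 5)))
  expect_equal(unname(impute_adjacent(wm3)$values["r3", ]), 1:5)
  # all-missing row errors
  wm4 <- mk(list(r4 = c(1, 2, 3, 4, 5)))
  wm4$values["r4", ] <- NA_real_
  expect_error(impute_adjacent(wm4), "no observed window")
})

make_flat_wm <- function(levels, n_per, nw = 10, noise = 2, seed = 99) {
  set.seed(seed)
  vals <- do.call(rbind, purrr::imap(levels, function(l, i) {
    matrix(l + rnorm(n_per * nw, 0, noise), n_per, nw)
  }))
  rownames(vals) <- sprintf("c%04d", seq_len(nrow(vals)))
  colnames(vals) <- paste0("w", seq_len(nw))
  w <- tibble::tibble(index = seq_len(nw), age_lo = (seq_len(nw) - 1) * 12,
                      age_hi = seq_len(nw) * 12)
  structure(list(values = vals, mask = vals > -Inf,
                 provenance = matrix("observed", nrow(vals), nw,
                                     dimnames = dimnames(vals)),
                 windows = w, kind = "BMIPCT"),
            class = "windowed_matrix")
}

test_that("well-separated flat trajectories are clustered exactly", {
  wm <- make_flat_wm(c(90, 30), n_per = 60)
  asg <- classify_trajectories(wm, seed = 1)
  expect_equal(unname(asg$kmeans_cluster),
               rep(c(1L, 2L), each = 60)) # cluster 1 = higher grand mean
  ve <- attr(asg, "var_explained")
  expect_gt(ve[["pc1"]], 0.8)
  expect_true(all(asg$group3[asg$kmeans_cluster == 2] == "NW"))
})

test_that("classification is invariant to child order and scale duplication", {
  coh <- shared_cohort()
  pct <- bmi_percentile(coh$growth, coh$reference)
  wp <- build_windows(pct)
  wm <- impute_adjacent(window_average(pct, wp, "bmipct"))
  asg <- classify_trajectories(wm, seed = 1)
  # permuting children leaves each child's labels unchanged
  perm <- sample(nrow(wm$values))
  wm_p <- wm
  wm_p$values <- wm$values[perm, ]
  wm_p$mask <- wm$mask[perm, ]
  wm_p$provenance <- wm$provenance[perm, ]
  asg_p <- classify_trajectories(wm_p, seed = 1)
  m <- match(asg$child_id, asg_p$child_id)
  expect_equal(asg$group4, asg_p$group4[m])
  # duplicating every child reproduces the same assignment per child
  wm_d <- wm
  dup <- rbind(wm$values, `rownames<-`(wm$values,
               paste0(rownames(wm$values), "_dup")))
  wm_d$values <- dup
  wm_d$mask <- dup > -Inf
  wm_d$provenance <- matrix("observed", nrow(dup), ncol(dup),
                            dimnames = dimnames(dup))
  asg_d <- classify_trajectories(wm_d, seed = 1)
  md <- match(asg$child_id, asg_d$child_id)
  expect_equal(asg$group4, asg_d$group4[md])
})

test_that("group collapse folds the normal-weight shapes into NW", {
  expect_equal(collapse_groups(c("NW-A", "NW-B", "early-OWO", "late-OWO")),
               c("NW", "NW", "early-OWO", "late-OWO"))
})

test_that("lowess curves reproduce flat and linear signals", {
  x <- seq(0, 100, length.out = 50)
  expect_true(all(abs(lowess_curve(x, rep(50, 50))$value - 50) < 1e-9))
  lin <- lowess_curve(x, 2 + 0.3 * x)
  expect_lt(max(abs(lin$value - (2 + 0.3 * lin$age))), 1e-6)
  expect_error(lowess_curve(1:3, 1:3), "at least 5")
})

test_that("lowess tracks a noisy sigmoid within 3 percentile points", {
  set.seed(7)
  n <- 500
  x <- sort(runif(n, 0, 192))
  truth <- 40 + 45 / (1 + exp(-(x - 96) / 18))
  y <- truth + rnorm(n, 0, 4)
  sm <- lowess_curve(x, y, frac = 0.3)
  inner <- sm$age > 15 & sm$age < 180 # away from edge effects
  truth_at <- 40 + 45 / (1 + exp(-(sm$age - 96) / 18))
  expect_lt(max(abs(sm$value - truth_at)[inner]), 3)
})
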