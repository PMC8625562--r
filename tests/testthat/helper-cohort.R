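# Shared fixtures, generated once per test run.

.fixtures <- new.env(parent = emptyenv())

# Mid-size default-condition cohort reused by several test files.
shared_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(n_children = 400, seed = 42)
  }
  .fixtures$cohort
}

# Simple analytic LMS reference: exact parameter curves for oracle tests.
toy_reference <- function() {
  ages <- seq(0, 216, by = 12)
  purrr::map_dfr(c("F", "M"), function(s) {
    tibble::tibble(sex = s, age_months = ages,
                   L = ifelse(s == "F", 1, -0.5),
                   M = 15 + ages / 100, S = 0.1)
  })
}

# Latent-class truth table without growth data.
toy_truth <- function(n, seed = 1,
                      probs = c(0.41, 0.27, 0.32)) {
  set.seed(seed)
  tibble::tibble(
    child_id = sprintf("c%04d", seq_len(n)),
    sex = sample(c("F", "M"), n, TRUE, prob = c(0.45, 0.55)),
    class = sample(c("early-OWO", "late-OWO", "NW"), n, TRUE, prob = probs)
  )
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Brute-force double-loop topological overlap oracle.
tom_oracle <- function(adj) {
  a <- adj
  diag(a) <- 0
  p <- nrow(a)
  k <- rowSums(a)
  tom <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) { tom[i, j] <- 1; next }
      num <- sum(a[i, ] * a[j, ]) + a[i, j]
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

covariate_set <- function() {
  c("race", "preterm", "smoking", "maternal_owo", "maternal_edu_hs", "sex")
}

truth_group3 <- function(truth) {
  out <- truth
  out$group3 <- ifelse(out$class == "NW", "NW", out$class)
  out
}
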