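#' Synthetic LMS growth reference
#'
#' Smooth, fully deterministic L/M/S curves per sex on a 6-month age grid
#' from birth to 18 years: median BMI rises monotonically with age, the
#' Box-Cox power drifts slowly, and the coefficient of variation widens
#' through adolescence. A synthetic stand-in for a national growth
#' reference, shaped like one but not derived from any published table.
#'
#' @param age_grid Ages (months) at which rows are emitted.
#' @return Tibble `sex, age_months, L, M, S` for sexes `F` and `M`.
#' @export
generate_reference <- function(age_grid = seq(0, 216, by = 6)) {
  purrr::map_dfr(c("F", "M"), function(s) {
    off <- if (s == "F") -0.3 else 0
    tibble::tibble(
      sex = s,
      age_months = age_grid,
      L = -1.2 + 0.4 * age_grid / 216,
      M = 15 + off + 4.2 * (age_grid / 216)^1.3,
      S = 0.10 + 0.04 * age_grid / 216
    )
  })
}

# Mean BMI-percentile curve of each latent trajectory class, by age in
# months: NW flat around 40; early-OWO rising to ~85 by age 4 then slowly
# to ~90; late-OWO flat ~50 until age 6 then rising to ~88 by age 12.
class_percentile_curve <- function(class, age_months) {
  a <- age_months
  switch(class,
    "NW" = rep(40, length(a)),
    "early-OWO" = 50 + 35 * pmin(a, 48) / 48 + 5 * pmax(a - 48, 0) / 168,
    "late-OWO" = 50 + 38 * pmin(pmax(a - 72, 0) / 72, 1),
    stop("unknown class ", class)
  )
}

# Clinic-like visit schedule: dense in infancy, then roughly annual with
# jitter, subject to per-visit missingness and an age-increasing dropout
# (each child has a maximum follow-up age).
visit_schedule <- function(max_age, miss_rate = 0.12) {
  sched <- c(1, 2, 4, 6, 9, 12, 15, 18, 21, 24, seq(36, 216, by = 12))
  sched <- sched[sched <= max_age]
  ages <- sched + stats::runif(length(sched), -1, 1)
  ages <- pmax(ages, 0.2)
  keep <- stats::runif(length(ages)) > miss_rate
  keep[1] <- TRUE # birth-side anchor visit always observed
  sort(ages[keep])
}

#' Simulate longitudinal growth for a cohort with known classes
#'
#' Each child follows their latent class's mean percentile curve plus a
#' child-level random intercept (SD `sd_child` percentile points) and
#' per-visit noise (SD `sd_visit`); percentiles are truncated to (1, 99)
#' and mapped to raw BMI through the LMS reference. Visits follow a
#' clinic-like schedule (dense before age 2, roughly annual after) with
#' per-visit missingness and a per-child maximum follow-up age: a fraction
#' `p_full` of children are followed to 18 years, the rest drop out at an
#' age uniform between `dropout_min` months and 18 years.
#'
#' @param truth Tibble `child_id, sex, class` of latent assignments.
#' @param ref LMS reference (see [generate_reference()]).
#' @param sd_child Child-level intercept SD in percentile points
#'   (default 5).
#' @param sd_visit Visit-level noise SD in percentile points (default 4).
#' @param p_full Fraction followed to 18 y (default 0.25).
#' @param dropout_min Earliest dropout age in months (default 120, i.e.
#'   every child is followed at least 10 years so the latent trajectory
#'   shapes stay identifiable from the observed span).
#' @param miss_rate Per-visit missingness (default 0.12).
#' @return Long growth tibble `child_id, sex, age_months, bmi`.
#' @export
generate_growth <- function(truth, ref, sd_child = 5, sd_visit = 4,
                            p_full = 0.25, dropout_min = 120,
                            miss_rate = 0.12) {
  n <- nrow(truth)
  max_age <- ifelse(stats::runif(n) < p_full, 216,
                    stats::runif(n, dropout_min, 216))
  intercept <- stats::rnorm(n, 0, sd_child)
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    ages <- visit_schedule(max_age[i], miss_rate)
    pct <- class_percentile_curve(truth$class[i], ages) +
      intercept[i] + stats::rnorm(length(ages), 0, sd_visit)
    pct <- pmin(pmax(pct, 1), 99)
    tibble::tibble(child_id = truth$child_id[i], sex = truth$sex[i],
                   age_months = ages, pct = pct)
  })
  rows$bmi <- percentile_to_bmi(rows$pct, rows$sex, rows$age_months, ref)
  rows[, c("child_id", "sex", "age_months", "bmi")]
}

# Default block design of the synthetic metabolome: seven correlated
# blocks (two TAG-like, one DAG-like, one CE-like, plus three neutral
# lipid/polar blocks) and unassigned singles, partitioned over the two
# LC-MS platforms so the C8-pos lipid panel comes to 194 metabolites and
# the HILIC-pos panel to 182.
default_blocks <- function() {
  tibble::tibble(
    block = c("tag1", "tag2", "dag", "ce", "pc", "ac", "sm"),
    type = c("TAG", "TAG", "DAG", "CE", "PC", "AC", "SM"),
    platform = c(rep("C8-pos", 5), "HILIC-pos", "HILIC-pos"),
    size = c(60L, 45L, 25L, 20L, 40L, 30L, 25L),
    shift_early = c(-0.25, -0.25, -0.25, 0.25, 0, 0, 0),
    shift_late = c(-0.125, -0.125, -0.125, 0.125, 0, 0, 0)
  )
}

#' Simulate the cord-plasma metabolite panel with planted block structure
#'
#' Metabolites come in correlated blocks sharing a child-level latent
#' factor: `x = sqrt(rho) * f_block + sqrt(1 - rho) * noise`, with the
#' factor mean shifted by trajectory class (TAG/DAG-like blocks lower and
#' the CE-like block higher in early-OWO, half-sized shifts in late-OWO,
#' none in NW). Unassigned singleton metabolites are pure noise.
#' Log-intensities are exponentiated to a positive raw scale; values below
#' each metabolite's detection quantile become non-detects; `n_junk`
#' high-variance junk metabolites are appended to exercise the CV filter.
#'
#' @param truth Tibble `child_id, class`.
#' @param blocks Block design tibble (see `default_blocks`): `block, type,
#'   platform, size, shift_early, shift_late`.
#' @param rho Within-block correlation (default 0.5).
#' @param n_singles Number of unassigned singleton metabolites
#'   (default 131, split across platforms to reach the panel totals).
#' @param n_junk High-CV junk metabolites appended (default 19).
#' @param nondetect_q Per-metabolite detection quantile (default 0.02).
#' @param sigma_log Log-scale SD of retained metabolites (default 0.1,
#'   i.e. a CV near 10%).
#' @param sigma_junk Log-scale SD of junk metabolites (default 0.8).
#' @param null_effects Zero out all planted class shifts (default FALSE).
#' @return List: `panel` (raw `metabolite_panel`), `factors` (children x
#'   blocks matrix of latent factors), `membership` (tibble `metabolite,
#'   block`).
#' @export
generate_metabolome <- function(truth, blocks = default_blocks(),
                                rho = 0.5, n_singles = 131, n_junk = 19,
                                nondetect_q = 0.02, sigma_log = 0.1,
                                sigma_junk = 0.8, null_effects = FALSE) {
  n <- nrow(truth)
  if (null_effects) {
    blocks$shift_early <- 0
    blocks$shift_late <- 0
  }
  shift <- function(b) {
    ifelse(truth$class == "early-OWO", blocks$shift_early[b],
           ifelse(truth$class == "late-OWO", blocks$shift_late[b], 0))
  }
  factors <- sapply(seq_len(nrow(blocks)), function(b) {
    stats::rnorm(n, mean = shift(b), sd = 1)
  })
  colnames(factors) <- blocks$block

  met_names <- character(0)
  ann_type <- character(0)
  ann_platform <- character(0)
  member_block <- character(0)
  cols <- list()
  for (b in seq_len(nrow(blocks))) {
    for (j in seq_len(blocks$size[b])) {
      x <- sqrt(rho) * factors[, b] +
        sqrt(1 - rho) * stats::rnorm(n)
      cols[[length(cols) + 1]] <- x
      met_names <- c(met_names,
                     sprintf("%s_%s_%02d", blocks$type[b], blocks$block[b], j))
      ann_type <- c(ann_type, blocks$type[b])
      ann_platform <- c(ann_platform, blocks$platform[b])
      member_block <- c(member_block, blocks$block[b])
    }
  }
  n_c8_single <- max(0L, 194L - sum(blocks$size[blocks$platform == "C8-pos"]))
  single_types <- c("LPC", "LPE", "PI", "PC_P", "PE_P", "PE", "other")
  for (j in seq_len(n_singles)) {
    cols[[length(cols) + 1]] <- stats::rnorm(n)
    met_names <- c(met_names, sprintf("single_%03d", j))
    ann_type <- c(ann_type, single_types[1 + (j %% length(single_types))])
    ann_platform <- c(ann_platform,
                      if (j <= n_c8_single) "C8-pos" else "HILIC-pos")
    member_block <- c(member_block, "none")
  }
  sig <- rep(sigma_log, length(cols))
  for (j in seq_len(n_junk)) {
    cols[[length(cols) + 1]] <- stats::rnorm(n)
    met_names <- c(met_names, sprintf("junk_%02d", j))
    ann_type <- c(ann_type, "other")
    ann_platform <- c(ann_platform, "HILIC-pos")
    member_block <- c(member_block, "junk")
    sig <- c(sig, sigma_junk)
  }
  mu <- stats::runif(length(cols), 4, 8)
  mat <- vapply(seq_along(cols), function(j) exp(mu[j] + sig[j] * cols[[j]]),
                numeric(n))
  colnames(mat) <- met_names
  # plant non-detects below the per-metabolite detection quantile
  for (j in seq_len(ncol(mat))) {
    thr <- stats::quantile(mat[, j], nondetect_q)
    mat[mat[, j] < thr, j] <- NA_real_
  }
  intens <- tibble::as_tibble(as.data.frame(mat))
  intens <- dplyr::bind_cols(tibble::tibble(child_id = truth$child_id),
                             intens)
  ann <- tibble::tibble(metabolite = met_names, type = ann_type,
                       platform = ann_platform)
  list(
    panel = metabolite_panel(intens, ann),
    factors = factors,
    membership = tibble::tibble(metabolite = met_names,
                                block = member_block)
  )
}

#' Simulate perinatal covariates tied to the planted structure
#'
#' Marginals emulate a US urban, low-income, predominantly Black and
#' Hispanic birth cohort (about 45% female, 60% Black). Maternal
#' overweight/obesity is mildly more common in OWO-trajectory classes, and
#' synthetic birthweight is correlated with both the early-OWO class and
#' the TAG-like block factor so that adjusting for it attenuates
#' early-window metabolite effects (the mediator-like behaviour probed by
#' the sensitivity analysis).
#'
#' @param truth Tibble `child_id, sex, class`.
#' @param f_tag Per-child TAG-block latent factor (from
#'   [generate_metabolome()]).
#' @param early_bmi Per-child BMI near birth (kg/m^2), aligned with
#'   `truth`; birthweight loads on it strongly (so that adjusting for
#'   birthweight absorbs most of the metabolite-BMI signal in the earliest
#'   windows). Defaults to a neutral constant when not supplied.
#' @return Tibble of covariates keyed by `child_id`.
#' @export
generate_covariates <- function(truth, f_tag,
                                early_bmi = rep(15, nrow(truth))) {
  n <- nrow(truth)
  early <- truth$class == "early-OWO"
  late <- truth$class == "late-OWO"
  tibble::tibble(
    child_id = truth$child_id,
    sex = truth$sex,
    race = sample(c("Black", "Hispanic", "White", "Others"), n,
                  replace = TRUE, prob = c(0.60, 0.22, 0.05, 0.13)),
    preterm = stats::rbinom(n, 1, 0.18),
    smoking = sample(c("never", "intermittent", "continuous"), n,
                     replace = TRUE, prob = c(0.82, 0.07, 0.11)),
    maternal_owo = stats::rbinom(n, 1, 0.45 + 0.10 * early + 0.05 * late),
    maternal_edu_hs = stats::rbinom(n, 1, 0.72),
    cesarean = stats::rbinom(n, 1, 0.34),
    breastfeeding = sample(c("both", "bottle", "breast"), n,
                           replace = TRUE, prob = c(0.66, 0.26, 0.08)),
    birthweight = 3100 + 1500 * (early_bmi - mean(early_bmi)) -
      40 * f_tag + stats::rnorm(n, 0, 450)
  )
}

#' Generate a complete synthetic birth cohort with known ground truth
#'
#' Seeded end-to-end generator: latent trajectory classes, LMS reference,
#' irregular growth visits, the raw metabolite panel with planted block
#' structure and class shifts, covariates, and an overweight/obesity flag
#' at the last visit (last observed BMI percentile at or above 85). The
#' same seed and configuration reproduce the cohort exactly.
#'
#' @param n_children Cohort size (default 900).
#' @param seed RNG seed (default 1).
#' @param class_probs Probabilities of `early-OWO, late-OWO, NW`
#'   (default `c(0.41, 0.27, 0.32)`).
#' @param p_female Probability of female sex (default 0.45).
#' @param rho Within-block metabolite correlation (default 0.5).
#' @param null_effects Zero all planted metabolome class shifts.
#' @param blocks Block design override (see [generate_metabolome()]).
#' @param ... Passed on to [generate_growth()] and
#'   [generate_metabolome()].
#' @return List with `growth`, `panel`, `covariates`, `reference`,
#'   `owo_flags`, and `truth` (classes, factors, membership, blocks,
#'   config).
#' @export
generate_cohort <- function(n_children = 900, seed = 1,
                            class_probs = c(0.41, 0.27, 0.32),
                            p_female = 0.45, rho = 0.5,
                            null_effects = FALSE,
                            blocks = default_blocks(), ...) {
  set.seed(seed)
  truth <- tibble::tibble(
    child_id = sprintf("child_%04d", seq_len(n_children)),
    sex = sample(c("F", "M"), n_children, replace = TRUE,
                 prob = c(p_female, 1 - p_female)),
    class = sample(c("early-OWO", "late-OWO", "NW"), n_children,
                   replace = TRUE, prob = class_probs)
  )
  ref <- generate_reference()
  dots <- list(...)
  growth_args <- dots[names(dots) %in%
    names(formals(generate_growth))]
  metab_args <- dots[names(dots) %in%
    names(formals(generate_metabolome))]
  growth <- do.call(generate_growth,
                    c(list(truth = truth, ref = ref), growth_args))
  metab <- do.call(generate_metabolome,
                   c(list(truth = truth, blocks = blocks, rho = rho,
                          null_effects = null_effects), metab_args))
  first_bmi <- growth |>
    dplyr::group_by(.data$child_id) |>
    dplyr::slice_min(.data$age_months, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  early_bmi <- first_bmi$bmi[match(truth$child_id, first_bmi$child_id)]
  covariates <- generate_covariates(truth, metab$factors[, "tag1"],
                                    early_bmi)
  pct <- bmi_percentile(growth, ref)
  owo_flags <- pct |>
    dplyr::group_by(.data$child_id) |>
    dplyr::slice_max(.data$age_months, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$child_id, owo_last_visit = .data$bmipct >= 85)
  list(
    growth = growth,
    panel = metab$panel,
    covariates = covariates,
    reference = ref,
    owo_flags = owo_flags,
    truth = list(
      classes = truth,
      factors = metab$factors,
      membership = metab$membership,
      blocks = blocks,
      config = list(n_children = n_children, seed = seed,
                    class_probs = class_probs, p_female = p_female,
                    rho = rho, null_effects = null_effects)
    )
  )
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `growth.csv`, `metabolome.csv`, `annotation.csv`,
#' `covariates.csv`, `reference.csv` and `truth.json` under `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$growth, file.path(dir, "growth.csv"))
  readr::write_csv(cohort$panel$intensities,
                   file.path(dir, "metabolome.csv"))
  readr::write_csv(cohort$panel$annotation,
                   file.path(dir, "annotation.csv"))
  readr::write_csv(cohort$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(cohort$reference, file.path(dir, "reference.csv"))
  truth <- cohort$truth
  truth$factors <- NULL # regenerable from config + seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
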