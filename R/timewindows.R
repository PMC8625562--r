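#' Per-time-window linear models of BMI on exposures
#'
#' For every window and every exposure (metabolite or module eigen-score),
#' fits the ordinary least squares model
#' `BMI_w ~ exposure + sex + exposure:sex + mean_age + covariates` over the
#' children with an *observed* (never imputed) window average, derives
#' sex-specific slopes (reference sex female: `beta_F` is the main effect,
#' `beta_M = beta_F + interaction`), standardizes each slope by the
#' within-sex standard deviation of BMI in that window, and screens the
#' exposure's overall effect (main + interaction) with a 2-df likelihood
#' ratio test. q-values are BH-adjusted within each window over the
#' exposures tested there.
#'
#' Sensitivity variants add one extra adjuster: `"cesarean"`,
#' `"breastfeeding"`, or `"birthweight"` (the latter skipped by
#' construction in the first window, which is the at-birth window that
#' birthweight itself defines).
#'
#' @param growth Long growth table (`child_id, sex, age_months, bmi`).
#' @param windows Window table from [build_windows()].
#' @param exposures Tibble `child_id` plus one numeric column per exposure
#'   (e.g. `partition$eigenscores`), or a children-by-exposure matrix with
#'   rownames.
#' @param covariate_data Data frame keyed by `child_id` with adjustment
#'   columns (and the extra-adjuster column when requested).
#' @param covariates Character vector of adjustment column names (sex is
#'   handled separately and must not be listed).
#' @param extra_adjust One of `"none"`, `"cesarean"`, `"breastfeeding"`,
#'   `"birthweight"`.
#' @param min_n Minimum complete cases per window model (default 20);
#'   smaller windows are flagged and skipped.
#' @return Tibble with one row per window-by-exposure fit: `window,
#'   age_mid, exposure, n, beta_F, beta_M, std_beta_F, std_beta_M,
#'   lrt_stat, lrt_df, lrt_p, lrt_q, int_p, int_q, flag`.
#' @export
window_effects <- function(growth, windows, exposures,
                           covariate_data = NULL,
                           covariates = character(),
                           extra_adjust = c("none", "cesarean",
                                            "breastfeeding", "birthweight"),
                           min_n = 20) {
  extra_adjust <- match.arg(extra_adjust)
  growth <- tibble::as_tibble(growth)
  if (!is.data.frame(exposures)) {
    exposures <- tibble::as_tibble(as.data.frame(exposures),
                                   rownames = "child_id")
  }
  expo_names <- setdiff(names(exposures), "child_id")
  wm_bmi <- window_average(growth, windows, "bmi")
  wm_age <- window_average(growth, windows, "age_months")
  sex_tbl <- dplyr::distinct(growth, .data$child_id, .data$sex)

  base <- tibble::tibble(child_id = rownames(wm_bmi$values))
  base <- dplyr::left_join(base, sex_tbl, by = "child_id")
  base <- dplyr::left_join(base, tibble::as_tibble(exposures),
                           by = "child_id")
  if (!is.null(covariate_data)) {
    extra_cols <- if (extra_adjust == "none") character() else extra_adjust
    cd <- tibble::as_tibble(covariate_data)
    keep <- unique(c("child_id", covariates, extra_cols))
    base <- dplyr::left_join(base, cd[, keep, drop = FALSE],
                             by = "child_id")
  }

  res <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    obs <- wm_bmi$mask[, w]
    d <- base[obs, , drop = FALSE]
    d$bmi_w <- wm_bmi$values[obs, w]
    d$mean_age <- wm_age$values[obs, w]
    extra <- if (extra_adjust == "none") character() else extra_adjust
    skip_extra <- extra_adjust == "birthweight" && w == 1
    if (skip_extra) extra <- character()
    purrr::map_dfr(expo_names, function(e) {
      fit_one_window(d, e, covariates, extra, w,
                     age_mid = (windows$age_lo[w] + windows$age_hi[w]) / 2,
                     min_n = min_n,
                     flag0 = if (skip_extra) "birthweight_skipped" else "")
    })
  })
  res |>
    dplyr::group_by(.data$window) |>
    dplyr::mutate(lrt_q = ifelse(is.na(.data$lrt_p), NA_real_,
                                 bh_fdr_na(.data$lrt_p)),
                  int_q = ifelse(is.na(.data$int_p), NA_real_,
                                 bh_fdr_na(.data$int_p))) |>
    dplyr::ungroup()
}

# BH over the non-missing entries of p, preserving positions.
bh_fdr_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- bh_fdr(p[ok])
  q
}

fit_one_window <- function(d, exposure, covariates, extra, w, age_mid,
                           min_n, flag0 = "") {
  out <- tibble::tibble(
    window = w, age_mid = age_mid, exposure = exposure,
    n = NA_integer_, beta_F = NA_real_, beta_M = NA_real_,
    std_beta_F = NA_real_, std_beta_M = NA_real_,
    lrt_stat = NA_real_, lrt_df = 2L, lrt_p = NA_real_,
    int_p = NA_real_, flag = flag0
  )
  vars <- c("bmi_w", exposure, "sex", "mean_age", covariates, extra)
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  out$n <- nrow(d)
  if (nrow(d) < min_n) {
    out$flag <- paste0(out$flag, ";too_few_cases")
    return(out)
  }
  both_sexes <- length(unique(d$sex)) == 2
  d$sex <- factor(d$sex, levels = sort(unique(as.character(d$sex))))
  # female reference when both sexes: levels sorted => "F" first
  adj <- c("mean_age", covariates, extra)
  rhs_full <- if (both_sexes) {
    c(exposure, "sex", paste0(exposure, ":sex"), adj)
  } else {
    c(exposure, adj)
  }
  rhs_null <- if (both_sexes) c("sex", adj) else adj
  full <- stats::lm(stats::reformulate(rhs_full, response = "bmi_w"),
                    data = d)
  null <- stats::lm(stats::reformulate(rhs_null, response = "bmi_w"),
                    data = d)
  if (any(is.na(stats::coef(full)))) {
    out$flag <- paste0(out$flag, ";rank_deficient")
    return(out)
  }
  cf <- stats::coef(full)
  beta_f <- unname(cf[exposure])
  if (both_sexes) {
    int_term <- grep(paste0("^", exposure, ":sex"), names(cf), value = TRUE)
    beta_m <- beta_f + unname(cf[int_term])
    out$int_p <- summary(full)$coefficients[int_term, 4]
    ll_full <- as.numeric(stats::logLik(full))
    ll_null <- as.numeric(stats::logLik(null))
    out$lrt_stat <- 2 * (ll_full - ll_null)
    out$lrt_df <- 2L
  } else {
    beta_m <- beta_f
    ll_full <- as.numeric(stats::logLik(full))
    ll_null <- as.numeric(stats::logLik(null))
    out$lrt_stat <- 2 * (ll_full - ll_null)
    out$lrt_df <- 1L
    out$flag <- paste0(out$flag, ";single_sex")
  }
  out$lrt_p <- stats::pchisq(out$lrt_stat, out$lrt_df, lower.tail = FALSE)
  out$beta_F <- beta_f
  out$beta_M <- beta_m
  sd_f <- stats::sd(d$bmi_w[d$sex == levels(d$sex)[1]])
  sd_m <- if (both_sexes) stats::sd(d$bmi_w[d$sex == levels(d$sex)[2]])
          else sd_f
  out$std_beta_F <- if (isTRUE(sd_f > 0)) beta_f / sd_f else NA_real_
  out$std_beta_M <- if (isTRUE(sd_m > 0)) beta_m / sd_m else NA_real_
  if ((!isTRUE(sd_f > 0)) || (!isTRUE(sd_m > 0))) {
    out$flag <- paste0(out$flag, ";zero_sd")
  }
  out
}

#' Standardize window-model slopes by within-sex BMI spread
#'
#' Divides each sex-specific slope by the standard deviation of the
#' observed window-averaged BMI of that sex, making effects comparable
#' across ages where BMI variance differs. [window_effects()] already does
#' this; this helper re-derives the standardized columns, e.g. after
#' manual edits to the effect table.
#'
#' @param effects Effect table from [window_effects()].
#' @param growth,windows Inputs used to rebuild the observed window BMI.
#' @return `effects` with `std_beta_F`, `std_beta_M` recomputed.
#' @export
standardize_effects <- function(effects, growth, windows) {
  wm <- window_average(growth, windows, "bmi")
  sex_tbl <- dplyr::distinct(tibble::as_tibble(growth),
                             .data$child_id, .data$sex)
  sexes <- sex_tbl$sex[match(rownames(wm$values), sex_tbl$child_id)]
  sds <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    v <- wm$values[, w]; obs <- wm$mask[, w]
    tibble::tibble(
      window = w,
      sd_F = stats::sd(v[obs & sexes == "F"]),
      sd_M = stats::sd(v[obs & sexes == "M"])
    )
  })
  effects <- dplyr::left_join(
    effects[, setdiff(names(effects), c("std_beta_F", "std_beta_M"))],
    sds, by = "window")
  effects$std_beta_F <- ifelse(effects$sd_F > 0,
                               effects$beta_F / effects$sd_F, NA_real_)
  effects$std_beta_M <- ifelse(effects$sd_M > 0,
                               effects$beta_M / effects$sd_M, NA_real_)
  effects[, setdiff(names(effects), c("sd_F", "sd_M"))]
}

#' Count significant exposures per time-window
#'
#' Tallies, per window, the exposures passing the chosen FDR criterion and
#' overlays a LOWESS curve over window mid-ages — the "critical growth
#' ages" summary.
#'
#' @param effects Effect table from [window_effects()].
#' @param criterion `"lrt"` (overall effect) or `"interaction"`
#'   (sex-modification).
#' @param alpha Significance level on the q-value (default 0.05).
#' @param frac LOWESS span (default 0.3).
#' @return Tibble `window, age_mid, n_tested, n_significant, smooth`.
#' @export
count_significant <- function(effects, criterion = c("lrt", "interaction"),
                              alpha = 0.05, frac = 0.3) {
  criterion <- match.arg(criterion)
  qcol <- if (criterion == "lrt") "lrt_q" else "int_q"
  counts <- effects |>
    dplyr::group_by(.data$window, .data$age_mid) |>
    dplyr::summarise(
      n_tested = sum(!is.na(.data[[qcol]])),
      n_significant = sum(.data[[qcol]] <= alpha, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::arrange(.data$window)
  if (nrow(counts) >= 5) {
    sm <- stats::lowess(counts$age_mid, counts$n_significant, f = frac,
                        delta = 0)
    counts$smooth <- sm$y
  } else {
    counts$smooth <- counts$n_significant
  }
  counts
}

#' Exposure-by-window matrix of standardized effects with FDR mask
#'
#' Builds the heatmap matrix of standardized sex-specific effect sizes,
#' with cells failing the FDR criterion flagged in a parallel mask (shown
#' grey when plotted). Rows are ordered by platform then metabolite type
#' when an annotation is supplied.
#'
#' @param effects Effect table from [window_effects()].
#' @param sex `"F"` or `"M"`: which sex's standardized slopes to show.
#' @param mask `"lrt"` or `"interaction"`: which q-value masks cells.
#' @param annotation Optional tibble `metabolite, type, platform` used to
#'   order rows (platform, then type, then name).
#' @param alpha Mask level (default 0.05).
#' @return List with `values` (exposures x windows matrix of std betas),
#'   `masked` (logical matrix, `TRUE` where the criterion fails), and
#'   `row_order`.
#' @export
effect_heatmap_matrix <- function(effects, sex = c("F", "M"),
                                  mask = c("lrt", "interaction"),
                                  annotation = NULL, alpha = 0.05) {
  sex <- match.arg(sex)
  mask <- match.arg(mask)
  bcol <- paste0("std_beta_", sex)
  qcol <- if (mask == "lrt") "lrt_q" else "int_q"
  wide_b <- tidyr::pivot_wider(effects[, c("exposure", "window", bcol)],
                               names_from = "window",
                               values_from = dplyr::all_of(bcol))
  wide_q <- tidyr::pivot_wider(effects[, c("exposure", "window", qcol)],
                               names_from = "window",
                               values_from = dplyr::all_of(qcol))
  rows <- wide_b$exposure
  if (!is.null(annotation)) {
    ann <- tibble::as_tibble(annotation)
    ord <- ann[match(rows, ann$metabolite), ]
    rows <- rows[order(ord$platform, ord$type, rows)]
    wide_b <- wide_b[match(rows, wide_b$exposure), ]
    wide_q <- wide_q[match(rows, wide_q$exposure), ]
  }
  vals <- as.matrix(wide_b[, -1])
  qs <- as.matrix(wide_q[, -1])
  rownames(vals) <- rownames(qs) <- rows
  masked <- is.na(qs) | qs > alpha
  list(values = vals, masked = masked, row_order = rows)
}

#' Plot per-window significance counts
#'
#' @param counts Output of [count_significant()].
#' @return A ggplot object: counts by age with the LOWESS overlay.
#' @export
plot_significance_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$age_mid / 12)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_significant)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), colour = "darkgreen") +
    ggplot2::labs(x = "Age (years)", y = "Significant exposures")
}

#' Plot a standardized-effect heatmap
#'
#' @param hm Output of [effect_heatmap_matrix()].
#' @return A ggplot object; masked cells are grey.
#' @export
plot_effect_heatmap <- function(hm) {
  d <- tibble::tibble(
    exposure = rep(rownames(hm$values), times = ncol(hm$values)),
    window = rep(as.integer(colnames(hm$values)), each = nrow(hm$values)),
    value = ifelse(as.vector(hm$masked), NA_real_, as.vector(hm$values))
  )
  d$exposure <- factor(d$exposure, levels = rev(hm$row_order))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$exposure,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey80") +
    ggplot2::labs(x = "Time-window", y = NULL, fill = "Std. effect")
}
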