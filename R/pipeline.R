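#' Default pipeline parameters
#'
#' All tunable parameters of the end-to-end analysis in one list:
#' window construction (`min_n`, `max_width`), percentile floor
#' (`min_age_months`), clustering (`kmeans_seed`, `kmeans_nstart`),
#' network detection (`power`, `min_module_size`, `cut_height`), QC
#' (`cv_threshold`, `int_offset`), modelling (`covariates`,
#' `window_min_n`, `fdr_alpha`) and sensitivity toggles
#' (`extra_adjust`).
#'
#' @param ... Overrides of individual defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_n = 30, max_width = 12, min_age_months = 24,
    kmeans_seed = 1L, kmeans_nstart = 25,
    cv_threshold = 20, int_offset = 3 / 8,
    power = 7, min_module_size = 15, cut_height = 0.996,
    covariates = c("race", "preterm", "smoking", "maternal_owo",
                   "maternal_edu_hs", "sex"),
    window_covariates = c("race", "preterm", "smoking", "maternal_owo",
                          "maternal_edu_hs"),
    window_min_n = 20, fdr_alpha = 0.05,
    extra_adjust = "none",
    window_exposures = "modules"
  )
  dots <- list(...)
  p[names(dots)] <- dots
  p
}

#' Validate the four pipeline input tables
#'
#' Checks column presence and basic types of the growth, metabolome,
#' covariate and LMS-reference tables, and cross-references child ids
#' (children present in the metabolome but absent from growth, and vice
#' versa, are listed as orphans).
#'
#' @param growth,panel,covariates,reference The four inputs (`panel` a
#'   `metabolite_panel` or intensity data frame).
#' @return List `ok` (logical), `problems` (character vector),
#'   `orphans` (list of id vectors).
#' @export
validate_inputs <- function(growth, panel, covariates, reference) {
  problems <- character(0)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      problems <<- c(problems,
        paste0(what, ": missing column(s) ", paste(miss, collapse = ", ")))
    }
  }
  growth <- tibble::as_tibble(growth)
  need(growth, c("child_id", "sex", "age_months", "bmi"), "growth")
  if ("bmi" %in% names(growth) && any(growth$bmi <= 0, na.rm = TRUE)) {
    problems <- c(problems, "growth: non-positive BMI values")
  }
  intens <- if (inherits(panel, "metabolite_panel")) panel$intensities
            else tibble::as_tibble(panel)
  need(intens, "child_id", "metabolome")
  need(tibble::as_tibble(covariates), "child_id", "covariates")
  need(tibble::as_tibble(reference),
       c("sex", "age_months", "L", "M", "S"), "reference")
  g_ids <- unique(growth$child_id)
  m_ids <- unique(intens$child_id)
  orphans <- list(
    metabolome_only = setdiff(m_ids, g_ids),
    growth_only = setdiff(g_ids, m_ids)
  )
  list(ok = length(problems) == 0, problems = problems, orphans = orphans)
}

#' Run the full cord-metabolome / BMI-trajectory analysis
#'
#' Executes every stage in order: metabolite QC and transformation, BMI
#' percentile conversion, time-window construction and averaging (36-ish
#' BMI windows from birth, 28-ish BMIPCT windows from age 2), adjacent
#' imputation, trajectory classification, network module detection,
#' module- and member-level trajectory associations with sex-interaction
#' screening, per-window linear models, and group-stratified descriptives.
#'
#' @param growth Long growth table.
#' @param panel Raw `metabolite_panel`.
#' @param covariates Covariate table keyed by `child_id`.
#' @param reference LMS reference table.
#' @param owo_flags Optional `child_id, owo_last_visit` table for the
#'   descriptive overweight/obesity summary.
#' @param params Parameter list from [pipeline_params()].
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as delimited text plus a JSON parameter echo.
#' @return Named list of stage outputs: `panel, percentiles,
#'   windows_bmi, windows_pct, wm_pct, assignments, curves, partition,
#'   module_results, member_results, sex_lrt, window_fits, counts,
#'   group_table, owo_table, params`.
#' @export
run_pipeline <- function(growth, panel, covariates, reference,
                         owo_flags = NULL, params = pipeline_params(),
                         out_dir = NULL) {
  chk <- validate_inputs(growth, panel, covariates, reference)
  if (!chk$ok) {
    stop("input validation failed:\n  ",
         paste(chk$problems, collapse = "\n  "), call. = FALSE)
  }
  panel <- prepare_metabolome(panel, threshold = params$cv_threshold,
                              offset = params$int_offset)
  pct <- bmi_percentile(growth, reference,
                        min_age_months = params$min_age_months)
  windows_bmi <- build_windows(growth, min_n = params$min_n,
                               max_width = params$max_width)
  windows_pct <- build_windows(pct, min_n = params$min_n,
                               max_width = params$max_width)
  wm_pct <- window_average(pct, windows_pct, "bmipct") |>
    impute_adjacent()
  assignments <- classify_trajectories(wm_pct, seed = params$kmeans_seed,
                                       nstart = params$kmeans_nstart)
  curves <- trajectory_curves(wm_pct, assignments)
  partition <- detect_modules(panel, power = params$power,
                              min_size = params$min_module_size,
                              cut_height = params$cut_height)
  module_results <- module_association(
    partition$eigenscores, assignments, covariates,
    covariates = params$covariates)
  member_results <- member_followup(
    panel, partition, module_results, assignments, covariates,
    covariates = params$covariates)
  scores_cov <- dplyr::inner_join(
    partition$eigenscores,
    dplyr::inner_join(assignments[, c("child_id", "group3")],
                      tibble::as_tibble(covariates), by = "child_id"),
    by = "child_id")
  sex_lrt <- purrr::map_dfr(
    setdiff(names(partition$eigenscores), "child_id"),
    function(mod) {
      res <- sex_interaction_lrt(
        scores_cov, "group3", mod, sex = "sex",
        covariates = setdiff(params$covariates, "sex"),
        reference = "NW")
      dplyr::mutate(res$lrt, module = mod, .before = 1)
    })
  sex_lrt$q <- bh_fdr(sex_lrt$p)
  expo <- if (identical(params$window_exposures, "modules")) {
    partition$eigenscores
  } else {
    m <- panel_matrix(panel)
    dplyr::bind_cols(tibble::tibble(child_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m)))
  }
  window_fits <- window_effects(
    growth, windows_bmi, expo, covariates,
    covariates = params$window_covariates,
    extra_adjust = params$extra_adjust,
    min_n = params$window_min_n)
  counts <- count_significant(window_fits, "lrt",
                              alpha = params$fdr_alpha)
  group_table <- summarize_groups(
    covariates, assignments[, c("child_id", "group4")],
    skewed = character())
  owo_table <- if (!is.null(owo_flags)) {
    owo_percentages(assignments, owo_flags)
  }
  out <- list(panel = panel, percentiles = pct,
              windows_bmi = windows_bmi, windows_pct = windows_pct,
              wm_pct = wm_pct, assignments = assignments, curves = curves,
              partition = partition, module_results = module_results,
              member_results = member_results, sex_lrt = sex_lrt,
              window_fits = window_fits, counts = counts,
              group_table = group_table, owo_table = owo_table,
              params = params)
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# Persist the tabular stage outputs of run_pipeline() as delimited text.
write_pipeline <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) readr::write_csv(x, file.path(dir, f))
  wr(out$windows_bmi, "windows_bmi.csv")
  wr(out$windows_pct, "windows_bmipct.csv")
  wr(tibble::as_tibble(out$assignments), "trajectory_assignments.csv")
  wr(out$curves, "trajectory_curves.csv")
  wr(out$partition$membership, "module_membership.csv")
  wr(out$partition$eigenscores, "module_eigenscores.csv")
  wr(out$module_results, "module_associations.csv")
  wr(out$member_results, "member_associations.csv")
  wr(out$sex_lrt, "sex_interaction_lrt.csv")
  wr(out$window_fits, "window_effects.csv")
  wr(out$counts, "window_significance_counts.csv")
  wr(out$group_table, "group_summary.csv")
  if (!is.null(out$owo_table)) wr(out$owo_table, "owo_percentages.csv")
  jsonlite::write_json(
    c(out$params,
      list(var_explained = as.list(attr(out$assignments, "var_explained")),
           network = out$partition$diagnostics)),
    file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
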