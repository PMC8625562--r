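# Round half away from zero (printed-table convention), to `digits`.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Group-stratified descriptive summary table
#'
#' Summarizes each variable within trajectory groups and tests for a group
#' difference: approximately normal continuous variables get mean +/- SD
#' and one-way ANOVA; variables listed in `skewed` get median (IQR) and
#' Kruskal-Wallis; categorical variables get count (%) and Pearson's
#' chi-squared test without continuity correction. An explicit `"Unknown"`
#' category is displayed but excluded from the chi-squared test by default
#' (structurally missing categories are not part of the group-difference
#' hypothesis).
#'
#' @param data Data frame of per-child variables, keyed by `child_id`.
#' @param groups Data frame `child_id, group` (e.g. an assignment table
#'   with `group = group4`), or a vector aligned with `data`.
#' @param variables Character vector of columns of `data` to summarize
#'   (default: all except `child_id`).
#' @param skewed Character vector of continuous variables to summarize as
#'   median (IQR) with Kruskal-Wallis.
#' @param include_unknown Include `"Unknown"` rows in the chi-squared test
#'   (default `FALSE`).
#' @return Tibble `variable, level, <one column per group>, test, p`;
#'   continuous variables occupy a single row with `level = NA`.
#' @export
summarize_groups <- function(data, groups, variables = NULL,
                             skewed = character(),
                             include_unknown = FALSE) {
  data <- tibble::as_tibble(data)
  if (is.data.frame(groups)) {
    gcol <- setdiff(names(groups), "child_id")[1]
    data <- dplyr::inner_join(data,
      stats::setNames(groups[, c("child_id", gcol)],
                      c("child_id", ".group")), by = "child_id")
  } else {
    data$.group <- groups
  }
  if (any(table(data$.group) == 0) || length(unique(data$.group)) < 2) {
    stop("every group must be non-empty (and at least two groups)",
         call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(data), c("child_id", ".group"))
  }
  glev <- sort(unique(as.character(data$.group)))

  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    g <- data$.group
    ok <- !is.na(x)
    if (is.numeric(x) && !(v %in% skewed)) {
      cells <- vapply(glev, function(l) {
        xi <- x[ok & g == l]
        sprintf("%.1f ± %.1f", mean(xi), stats::sd(xi))
      }, character(1))
      p <- summary(stats::aov(x[ok] ~ factor(g[ok])))[[1]][["Pr(>F)"]][1]
      test <- "anova"
      lev <- NA_character_
      row <- c(list(variable = v, level = lev), as.list(cells),
               list(test = test, p = p))
      return(tibble::as_tibble(row, .name_repair = "minimal"))
    }
    if (is.numeric(x) && v %in% skewed) {
      cells <- vapply(glev, function(l) {
        xi <- x[ok & g == l]
        qs <- stats::quantile(xi, c(0.25, 0.5, 0.75))
        sprintf("%.1f (%.1f-%.1f)", qs[2], qs[1], qs[3])
      }, character(1))
      p <- stats::kruskal.test(x[ok], factor(g[ok]))$p.value
      row <- c(list(variable = v, level = NA_character_), as.list(cells),
               list(test = "kruskal-wallis", p = p))
      return(tibble::as_tibble(row, .name_repair = "minimal"))
    }
    # categorical: one row per level, shared chi-squared p
    x <- as.character(x)
    x[is.na(x)] <- "Unknown"
    levs <- sort(unique(x))
    levs <- c(setdiff(levs, "Unknown"),
              if ("Unknown" %in% x) "Unknown")
    test_keep <- if (include_unknown) rep(TRUE, length(x))
                 else x != "Unknown"
    tab <- table(factor(x[test_keep]), factor(g[test_keep]))
    p <- if (nrow(tab) >= 2) {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else NA_real_
    purrr::map_dfr(seq_along(levs), function(i) {
      l <- levs[i]
      cells <- vapply(glev, function(gl) {
        nn <- sum(x == l & g == gl)
        sprintf("%d (%.1f%%)", nn,
                round_half_up(100 * nn / sum(g == gl), 1))
      }, character(1))
      row <- c(list(variable = v, level = l), as.list(cells),
               list(test = "chi-squared",
                    p = if (i == 1) p else NA_real_))
      tibble::as_tibble(row, .name_repair = "minimal")
    })
  })
}

#' Pearson chi-squared statistic for a contingency table
#'
#' `sum((O - E)^2 / E)` without continuity correction; the arithmetic
#' behind the categorical rows of [summarize_groups()].
#'
#' @param tab Contingency table (matrix of counts).
#' @return List `statistic, df, p`.
#' @export
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Overweight/obesity percentages by trajectory group and cluster
#'
#' Percent of children flagged clinically overweight or obese at their last
#' visit, reported per four-level trajectory group and per k-means cluster
#' (cluster 1 = early-OWO + late-OWO, cluster 2 = NW-A + NW-B), rounded
#' half-up to `digits` decimals.
#'
#' @param assignments A `trajectory_assignment` (or any table with
#'   `child_id` and `group4`).
#' @param owo_flags Data frame `child_id, owo_last_visit` (logical/0-1).
#' @param digits Decimals to round to (default 1).
#' @return Tibble `unit, label, n, n_owo, pct`.
#' @export
owo_percentages <- function(assignments, owo_flags, digits = 1) {
  d <- dplyr::inner_join(
    tibble::as_tibble(assignments)[, c("child_id", "group4")],
    tibble::as_tibble(owo_flags), by = "child_id")
  d$owo <- as.logical(d$owo_last_visit)
  per_group <- d |>
    dplyr::group_by(label = .data$group4) |>
    dplyr::summarise(n = dplyr::n(), n_owo = sum(.data$owo),
                     .groups = "drop") |>
    dplyr::mutate(unit = "group4")
  d$cluster <- ifelse(d$group4 %in% c("early-OWO", "late-OWO"),
                      "cluster 1", "cluster 2")
  per_cluster <- d |>
    dplyr::group_by(label = .data$cluster) |>
    dplyr::summarise(n = dplyr::n(), n_owo = sum(.data$owo),
                     .groups = "drop") |>
    dplyr::mutate(unit = "cluster")
  out <- dplyr::bind_rows(per_group, per_cluster)
  out$pct <- round_half_up(100 * out$n_owo / out$n, digits)
  out[, c("unit", "label", "n", "n_owo", "pct")]
}

#' Overweight/obesity percentages from published group counts
#'
#' Pure count arithmetic over a table of group sizes and
#' overweight-or-obese counts: per-group percentages plus the two k-means
#' cluster aggregates (cluster 1 = early-OWO + late-OWO, cluster 2 =
#' NW-A + NW-B).
#'
#' @param counts Data frame `group, n, n_owo` with groups `early-OWO,
#'   late-OWO, NW-A, NW-B`.
#' @param digits Decimals for rounding (default 1); use 2 for the small
#'   cluster-2 fraction.
#' @return Tibble `unit, label, n, n_owo, pct`.
#' @export
owo_percentages_from_counts <- function(counts, digits = 1) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("group", "n", "n_owo") %in% names(counts)))
  per_group <- tibble::tibble(
    unit = "group4", label = counts$group,
    n = counts$n, n_owo = counts$n_owo
  )
  c1 <- counts$group %in% c("early-OWO", "late-OWO")
  per_cluster <- tibble::tibble(
    unit = "cluster", label = c("cluster 1", "cluster 2"),
    n = c(sum(counts$n[c1]), sum(counts$n[!c1])),
    n_owo = c(sum(counts$n_owo[c1]), sum(counts$n_owo[!c1]))
  )
  out <- dplyr::bind_rows(per_group, per_cluster)
  out$pct <- round_half_up(100 * out$n_owo / out$n, digits)
  out
}
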