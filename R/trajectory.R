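#' Build time-windows over irregular growth visits
#'
#' Partitions the age axis into ordered, disjoint, half-open windows
#' `[lo, hi)` based on the available samples in each age group. Visits are
#' grouped by completed month of age, and a greedy left-to-right sweep
#' extends the current window month-group by month-group, closing it once
#' it holds measurements from at least `min_n` distinct children *and*
#' either (a) a gap of `gap` months or more follows (the clinic schedule's
#' natural boundaries), or (b) the window has reached the target width
#' implied by `n_windows_hint` (total span divided by the hint). A window
#' is force-closed at `max_width` months even if under-populated; age
#' spans with no visits are skipped; an under-populated terminal window is
#' merged into its predecessor, and any interior under-populated window is
#' merged with a neighbour when the combined width allows.
#'
#' @param growth Long growth table (`child_id`, `age_months`, ...).
#' @param min_n Minimum number of distinct children per window (default 30).
#' @param max_width Maximum window width in months (default 12).
#' @param n_windows_hint Desired order of magnitude of the window count;
#'   sets the target width (default 36, i.e. ~6-month windows over
#'   birth-18 y).
#' @param gap Months of empty age axis treated as a window boundary
#'   (default 3).
#' @return Tibble of window specs: `index, age_lo, age_hi, width,
#'   n_children`.
#' @export
build_windows <- function(growth, min_n = 30, max_width = 12,
                          n_windows_hint = 36, gap = 3) {
  growth <- tibble::as_tibble(growth)
  if (length(unique(growth$child_id)) < min_n) {
    stop("fewer than `min_n` children in the cohort", call. = FALSE)
  }
  month <- floor(growth$age_months)
  ids <- match(growth$child_id, unique(growth$child_id))
  ord <- order(month)
  month <- month[ord]; ids <- ids[ord]
  groups <- unique(month) # sorted ascending
  span <- max(month) + 1 - min(month)
  target <- max(1, ceiling(span / n_windows_hint))

  windows <- list()
  seen <- logical(max(ids))
  lo <- NA_real_
  count <- 0L
  hi_cur <- NA_real_

  close_window <- function(hi) {
    windows[[length(windows) + 1L]] <<- c(lo = lo, hi = hi, n = count)
    seen[] <<- FALSE
    count <<- 0L
    lo <<- NA_real_
  }

  for (gi in seq_along(groups)) {
    m <- groups[gi]
    if (is.na(lo)) lo <- m
    if (m + 1 - lo > max_width) close_window(hi_cur) # forced close
    if (is.na(lo)) lo <- m
    members <- unique(ids[month == m])
    count <- count + sum(!seen[members])
    seen[members] <- TRUE
    hi_cur <- m + 1
    nxt <- if (gi < length(groups)) groups[gi + 1] else NA_real_
    boundary <- is.na(nxt) || (nxt - hi_cur) >= gap ||
      (hi_cur - lo) >= target
    if (count >= min_n && boundary) close_window(hi_cur)
    if (count > 0L && !is.na(nxt) && (nxt - hi_cur) >= gap) {
      close_window(hi_cur) # under-populated but a gap follows
    }
  }
  if (count > 0L) close_window(hi_cur)
  w <- do.call(rbind, windows)

  # merge under-populated windows into an adjacent window where width allows
  recount <- function(lo, hi) {
    length(unique(ids[month >= lo & month < hi]))
  }
  i <- 1L
  while (nrow(w) > 1L && i <= nrow(w)) {
    if (w[i, "n"] >= min_n) { i <- i + 1L; next }
    merged <- FALSE
    if (i > 1L && w[i, "hi"] - w[i - 1L, "lo"] <= max_width) {
      w[i - 1L, "hi"] <- w[i, "hi"]
      w[i - 1L, "n"] <- recount(w[i - 1L, "lo"], w[i - 1L, "hi"])
      w <- w[-i, , drop = FALSE]; merged <- TRUE
    } else if (i < nrow(w) && w[i + 1L, "hi"] - w[i, "lo"] <= max_width) {
      w[i + 1L, "lo"] <- w[i, "lo"]
      w[i + 1L, "n"] <- recount(w[i + 1L, "lo"], w[i + 1L, "hi"])
      w <- w[-i, , drop = FALSE]; merged <- TRUE
    }
    if (!merged) i <- i + 1L
  }
  if (nrow(w) == 1L && w[1, "n"] < min_n) {
    stop("cohort cannot populate a single window", call. = FALSE)
  }
  tibble::tibble(
    index = seq_len(nrow(w)),
    age_lo = unname(w[, "lo"]), age_hi = unname(w[, "hi"]),
    width = unname(w[, "hi"] - w[, "lo"]),
    n_children = as.integer(w[, "n"])
  )
}

#' Average growth values within time-windows
#'
#' Builds the children-by-window matrix whose cell (i, w) is the mean of
#' child i's values falling in window w; cells with no visit are missing
#' with a `FALSE` observed mask.
#'
#' @param growth Long growth table containing `child_id`, `age_months` and
#'   the value column.
#' @param windows Window table from [build_windows()].
#' @param value Name of the value column to average (`"bmi"` or
#'   `"bmipct"`).
#' @param kind Label stored on the result; defaults to upper-case `value`.
#' @return A `windowed_matrix`: list of `values` (matrix), `mask` (logical,
#'   observed), `provenance` (character), `windows`, `kind`.
#' @export
window_average <- function(growth, windows, value = "bmi",
                           kind = toupper(value)) {
  growth <- tibble::as_tibble(growth)
  stopifnot(value %in% names(growth))
  children <- unique(growth$child_id)
  nw <- nrow(windows)
  m <- matrix(NA_real_, length(children), nw,
              dimnames = list(children, paste0("w", windows$index)))
  idx <- rep(NA_integer_, nrow(growth))
  for (w in seq_len(nw)) {
    idx[growth$age_months >= windows$age_lo[w] &
        growth$age_months < windows$age_hi[w]] <- w
  }
  keep <- !is.na(idx)
  sums <- tapply(growth[[value]][keep],
                 list(growth$child_id[keep], idx[keep]), mean)
  m[rownames(sums), as.integer(colnames(sums))] <- sums
  mask <- !is.na(m)
  prov <- matrix(ifelse(mask, "observed", "missing"), nrow(m), ncol(m),
                 dimnames = dimnames(m))
  structure(list(values = m, mask = mask, provenance = prov,
                 windows = tibble::as_tibble(windows), kind = kind),
            class = "windowed_matrix")
}

#' @export
print.windowed_matrix <- function(x, ...) {
  cat("<windowed_matrix> ", nrow(x$values), " children x ",
      ncol(x$values), " windows (", x$kind, "); ",
      round(100 * mean(x$mask), 1), "% observed\n", sep = "")
  invisible(x)
}

#' Long-format view of a windowed matrix
#'
#' @param x A `windowed_matrix`.
#' @param ... Unused.
#' @return Tibble `child_id, window, age_mid, value, provenance`.
#' @export
tidy.windowed_matrix <- function(x, ...) {
  mid <- (x$windows$age_lo + x$windows$age_hi) / 2
  tibble::tibble(
    child_id = rep(rownames(x$values), times = ncol(x$values)),
    window = rep(x$windows$index, each = nrow(x$values)),
    age_mid = rep(mid, each = nrow(x$values)),
    value = as.vector(x$values),
    provenance = as.vector(x$provenance)
  )
}

#' Fill missing window cells from adjacent observed windows
#'
#' Interior gaps (missing cells with an observed value on both sides) are
#' filled with the average of the last and next observed values, whatever
#' the gap length. Leading gaps carry the first observed value backward and
#' trailing gaps carry the last observed value forward; those edge fills are
#' recorded as `edge_filled` in the provenance so downstream sensitivity to
#' the edge rule stays visible.
#'
#' @param wm A `windowed_matrix`.
#' @return The matrix with every cell filled and provenance updated.
#' @export
impute_adjacent <- function(wm) {
  stopifnot(inherits(wm, "windowed_matrix"))
  m <- wm$values
  prov <- wm$provenance
  for (i in seq_len(nrow(m))) {
    obs <- which(!is.na(m[i, ]))
    if (length(obs) == 0) {
      stop("child '", rownames(m)[i], "' has no observed window",
           call. = FALSE)
    }
    first <- obs[1]; last <- obs[length(obs)]
    if (first > 1) {
      m[i, 1:(first - 1)] <- m[i, first]
      prov[i, 1:(first - 1)] <- "edge_filled"
    }
    if (last < ncol(m)) {
      m[i, (last + 1):ncol(m)] <- m[i, last]
      prov[i, (last + 1):ncol(m)] <- "edge_filled"
    }
    gaps <- which(is.na(m[i, ]))
    for (g in gaps) {
      prev_obs <- max(obs[obs < g])
      next_obs <- min(obs[obs > g])
      m[i, g] <- (wm$values[i, prev_obs] + wm$values[i, next_obs]) / 2
      prov[i, g] <- "interpolated"
    }
  }
  wm$values <- m
  wm$provenance <- prov
  wm
}

#' Classify longitudinal BMI-percentile trajectories
#'
#' Groups children by the shape of their windowed BMIPCT profiles in two
#' deterministic steps. (1) k-means with k = 2 (Euclidean, `nstart`
#' restarts under a fixed seed) splits the cohort by overall level; the
#' cluster with the higher grand-mean BMIPCT is relabeled cluster 1.
#' (2) A single PCA of the column-mean-centered matrix over all children
#' provides PC2, which separates profile shapes; each cluster is
#' dichotomized at PC2 = 0, yielding four groups. PC signs are fixed by
#' data-independent rules so labels never depend on the eigendecomposition
#' basis: PC1 is oriented to correlate positively with row means, and PC2
#' is oriented so its mean loading over the earliest third of windows
#' exceeds its mean loading over the latest third (children already at a
#' high percentile in the earliest windows then score positive).
#'
#' Group labels: cluster 1 with PC2 >= 0 is `early-OWO` (high percentile
#' from the earliest observed ages), cluster 1 with PC2 < 0 is `late-OWO`
#' (rising later in childhood), cluster 2 splits into `NW-A` / `NW-B`
#' (normal-weight shapes). The three-level analysis grouping collapses
#' NW-A and NW-B into `NW`.
#'
#' @param wm A complete (imputed) `windowed_matrix` of BMIPCT.
#' @param seed Seed fixing the k-means restarts.
#' @param nstart Number of k-means restarts (default 25).
#' @return A tibble (class `trajectory_assignment`) with columns
#'   `child_id, kmeans_cluster, pc1_score, pc2_score, group4, group3`, and
#'   attributes `var_explained` (PC1/PC2 variance fractions) and `windows`.
#' @export
classify_trajectories <- function(wm, seed = 1L, nstart = 25) {
  stopifnot(inherits(wm, "windowed_matrix"))
  m <- wm$values
  if (anyNA(m)) stop("matrix has missing cells; run impute_adjacent() first",
                     call. = FALSE)
  if (all(apply(m, 2, stats::sd) == 0)) {
    stop("degenerate matrix: no variance across children", call. = FALSE)
  }
  set.seed(seed)
  km <- stats::kmeans(m, centers = 2, nstart = nstart, iter.max = 100)
  grand <- tapply(rowMeans(m), km$cluster, mean)
  high <- as.integer(names(grand)[which.max(grand)])
  cluster <- ifelse(km$cluster == high, 1L, 2L)

  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  s1 <- pc$x[, 1]; s2 <- pc$x[, 2]
  r1 <- pc$rotation[, 1]; r2 <- pc$rotation[, 2]
  if (stats::cor(s1, rowMeans(m)) < 0) { s1 <- -s1; r1 <- -r1 }
  nw <- ncol(m)
  third <- max(1L, floor(nw / 3))
  contrast <- mean(r2[seq_len(third)]) - mean(r2[(nw - third + 1):nw])
  if (contrast < 0) { s2 <- -s2; r2 <- -r2 }

  group4 <- dplyr::case_when(
    cluster == 1L & s2 >= 0 ~ "early-OWO",
    cluster == 1L & s2 < 0 ~ "late-OWO",
    cluster == 2L & s2 >= 0 ~ "NW-A",
    TRUE ~ "NW-B"
  )
  out <- tibble::tibble(
    child_id = rownames(m),
    kmeans_cluster = cluster,
    pc1_score = unname(s1),
    pc2_score = unname(s2),
    group4 = group4,
    group3 = collapse_groups(group4)
  )
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- c(pc1 = ve[1], pc2 = ve[2])
  attr(out, "windows") <- wm$windows
  class(out) <- c("trajectory_assignment", class(out))
  out
}

#' Collapse the four trajectory groups to the three analysis groups
#'
#' NW-A and NW-B fold into a single NW group; early-OWO and late-OWO are
#' unchanged.
#'
#' @param group4 Character vector of four-level labels (or a
#'   `trajectory_assignment`, whose `group3` column is refreshed).
#' @return Character vector of three-level labels, or the updated
#'   assignment table.
#' @export
collapse_groups <- function(group4) {
  if (inherits(group4, "trajectory_assignment")) {
    group4$group3 <- collapse_groups(group4$group4)
    return(group4)
  }
  ifelse(group4 %in% c("NW-A", "NW-B"), "NW", group4)
}

#' LOWESS smoothing curve through pooled trajectory points
#'
#' Tricube-weighted local linear smoother (robustified, via
#' [stats::lowess()]) over pooled (age, value) points, typically one group
#' of children at a time.
#'
#' @param age,value Paired numeric vectors (at least 5 points).
#' @param frac Smoother span: fraction of points in each local fit
#'   (default 0.3).
#' @return Tibble `age, value` of the smoothed polyline.
#' @export
lowess_curve <- function(age, value, frac = 0.3) {
  if (length(age) < 5) stop("need at least 5 points", call. = FALSE)
  sm <- stats::lowess(age, value, f = frac, delta = 0)
  tibble::tibble(age = sm$x, value = sm$y)
}

#' Group-wise LOWESS curves for a windowed matrix
#'
#' @param wm A `windowed_matrix`.
#' @param assignments A `trajectory_assignment`.
#' @param group Column of `assignments` to pool by (`"group4"` or
#'   `"group3"`).
#' @param frac Smoother span (see [lowess_curve()]).
#' @return Tibble `group, age, value`, one polyline per group.
#' @export
trajectory_curves <- function(wm, assignments, group = "group4",
                              frac = 0.3) {
  long <- tidy(wm)
  long <- dplyr::inner_join(long,
    assignments[, c("child_id", group)], by = "child_id")
  long <- dplyr::rename(long, group = dplyr::all_of(group))
  long <- dplyr::filter(long, !is.na(.data$value))
  long |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ lowess_curve(.x$age_mid, .x$value, frac = frac)) |>
    dplyr::ungroup()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trajectory plot: individual profiles with group smoothing curves
#'
#' @param object A `trajectory_assignment`.
#' @param wm The `windowed_matrix` the assignment was computed from.
#' @param group `"group4"` (default) or `"group3"`.
#' @param frac LOWESS span.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_assignment <- function(object, wm, group = "group4",
                                           frac = 0.3, ...) {
  long <- tidy(wm)
  long <- dplyr::inner_join(long, object[, c("child_id", group)],
                            by = "child_id")
  long <- dplyr::rename(long, group = dplyr::all_of(group))
  curves <- trajectory_curves(wm, object, group = group, frac = frac)
  ggplot2::ggplot(long,
      ggplot2::aes(x = .data$age_mid / 12, y = .data$value,
                   colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$child_id),
                       alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_line(data = curves,
      ggplot2::aes(x = .data$age / 12, y = .data$value,
                   colour = .data$group),
      inherit.aes = FALSE, linewidth = 1.2) +
    ggplot2::labs(x = "Age (years)", y = wm$kind, colour = "Trajectory")
}
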