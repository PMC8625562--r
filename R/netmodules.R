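# Standard module color vocabulary, in decreasing module-size order.
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
)

#' Signed scale-free topology fit index
#'
#' Bins per-node connectivities, regresses `log10` bin frequency on `log10`
#' mean bin connectivity over non-empty bins, and returns the squared
#' correlation, negated when the log-log slope is positive (so only a
#' *decreasing* frequency-connectivity relationship — the scale-free
#' signature — scores high).
#'
#' @param k Positive per-node connectivities (row sums of the adjacency
#'   minus the self term).
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return Signed R-squared in `[-1, 1]`, or `NA` when fewer than 3
#'   non-empty bins exist.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (any(k <= 0)) stop("connectivities must be positive", call. = FALSE)
  if (diff(range(k)) == 0) return(NA_real_) # single bin: fit undefined
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-12
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  ok <- !is.na(dk) & !is.na(pk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- log10(dk[ok]); y <- log10(pk[ok])
  fit <- stats::lm(y ~ x)
  # an exact log-log line is legitimate input; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned weighted-network adjacency `a_ij = |cor_ij|^beta`.
#'
#' @param corr Square symmetric correlation matrix.
#' @param power Soft-thresholding exponent beta.
#' @return Adjacency matrix with unit diagonal.
#' @export
soft_adjacency <- function(corr, power) {
  a <- abs(corr)^power
  diag(a) <- 1
  a
}

#' Choose the soft-thresholding power by the scale-free plateau rule
#'
#' Evaluates the signed scale-free fit index over candidate powers and
#' returns the smallest power whose fit reaches `target_r2` while its
#' increment over the previous power is below 0.02 (a plateau); when no
#' candidate qualifies, falls back to the power with the largest fit. A
#' fixed `override` short-circuits the search (the conventional choice for
#' this metabolite panel size is 7).
#'
#' @param corr Correlation matrix of the (transformed) metabolite panel.
#' @param powers Candidate integer powers (default 1:20).
#' @param target_r2 Plateau height (default 0.80).
#' @param n_bins Connectivity bins for [scale_free_fit()].
#' @param override If non-NULL, returned as-is (with diagnostics still
#'   computed).
#' @return Integer power with attribute `diagnostics`: a tibble
#'   `power, r_squared, mean_k`.
#' @export
pick_power <- function(corr, powers = 1:20, target_r2 = 0.80, n_bins = 10,
                       override = NULL) {
  diag_tbl <- purrr::map_dfr(powers, function(b) {
    a <- soft_adjacency(corr, b)
    k <- rowSums(a) - 1
    k <- pmax(k, .Machine$double.eps)
    tibble::tibble(power = b, r_squared = scale_free_fit(k, n_bins),
                   mean_k = mean(k))
  })
  chosen <- NULL
  r2 <- diag_tbl$r_squared
  for (i in seq_along(powers)) {
    if (is.na(r2[i]) || r2[i] < target_r2) next
    inc <- if (i == 1) 0 else r2[i] - r2[i - 1]
    if (is.na(inc) || inc < 0.02) { chosen <- powers[i]; break }
  }
  if (is.null(chosen)) {
    chosen <- if (all(is.na(r2))) powers[1] else powers[which.max(r2)]
  }
  if (!is.null(override)) chosen <- override
  structure(as.integer(chosen), diagnostics = diag_tbl)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal, where `k_i` is node i's connectivity excluding the self
#' term. Shared-neighbor smoothing of the adjacency: two nodes overlap
#' strongly when they are directly connected *and* connect to the same
#' neighbors.
#'
#' @param adj Adjacency matrix from [soft_adjacency()] (entries in
#'   `[0, 1]`, unit diagonal).
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Detect metabolite co-abundance modules
#'
#' Weighted correlation-network module detection: unsigned Pearson
#' soft-threshold adjacency, topological overlap, average-linkage
#' hierarchical clustering of `1 - TOM`, and a dendrogram cut at
#' `cut_height` on the dissimilarity scale. Branches below the cut with at
#' least `min_size` members become modules, colored in decreasing size
#' order from the standard module color sequence; everything else —
#' including all members of under-sized branches — is `grey`. Each module
#' is summarized by its eigen-metabolite, the first principal component of
#' the standardized member columns (see [module_eigenscore()]).
#'
#' @param x A processed `metabolite_panel` or a numeric children-by-
#'   metabolite matrix without missing values.
#' @param power Soft-thresholding exponent; `NULL` picks it via
#'   [pick_power()]. The conventional value for this panel is 7.
#' @param min_size Minimum module size (default 15).
#' @param cut_height Dendrogram cut height on the `1 - TOM` scale
#'   (default 0.996); branches completing above it stay unassigned.
#' @return A `module_partition`: list with `membership` (tibble
#'   `metabolite, module`), `eigenscores` (tibble, `child_id` plus one
#'   column per module), `modules` (per-module size and PC1 variance
#'   explained), and `diagnostics` (power, scale-free fit, parameters).
#' @export
detect_modules <- function(x, power = 7, min_size = 15, cut_height = 0.996) {
  m <- if (inherits(x, "metabolite_panel")) panel_matrix(x) else as.matrix(x)
  if (anyNA(m)) stop("input contains missing values", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance metabolite(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  corr <- stats::cor(m)
  if (is.null(power)) power <- pick_power(corr)
  adj <- soft_adjacency(corr, power)
  k <- rowSums(adj) - 1
  sf <- scale_free_fit(pmax(k, .Machine$double.eps))
  tom <- tom_similarity(adj)
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep("grey", ncol(m))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[keep])]
    for (i in seq_along(ord)) {
      module[raw == as.integer(ord[i])] <- wgcna_colors[i]
    }
  }
  membership <- tibble::tibble(metabolite = colnames(m), module = module)
  mods <- setdiff(unique(module), "grey")
  mods <- mods[order(match(mods, wgcna_colors))]
  scores <- tibble::tibble(child_id = rownames(m))
  modtbl <- purrr::map_dfr(mods, function(col) {
    members <- membership$metabolite[membership$module == col]
    es <- module_eigenscore(m, members)
    scores[[col]] <<- es
    tibble::tibble(module = col, size = length(members),
                   var_explained = attr(es, "var_explained"))
  })
  structure(list(
    membership = membership,
    eigenscores = scores,
    modules = modtbl,
    dendrogram = hc,
    diagnostics = list(power = as.integer(power), scale_free_r2 = sf,
                       min_size = min_size, cut_height = cut_height)
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", nrow(x$membership), " metabolites, ",
      nrow(x$modules), " modules (power ", x$diagnostics$power,
      ", scale-free R^2 ", round(x$diagnostics$scale_free_r2, 2), ", ",
      sum(x$membership$module == "grey"), " grey)\n", sep = "")
  invisible(x)
}

#' Membership table of a module partition
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble `metabolite, module`.
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' One-row summary of a module partition
#'
#' @param x A `module_partition`.
#' @param ... Unused.
#' @return Tibble with module counts and network diagnostics.
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(
    n_metabolites = nrow(x$membership),
    n_modules = nrow(x$modules),
    n_grey = sum(x$membership$module == "grey"),
    power = x$diagnostics$power,
    scale_free_r2 = x$diagnostics$scale_free_r2
  )
}

#' Eigen-metabolite score of a module
#'
#' First principal component of the standardized member columns, rescaled
#' to unit variance and sign-oriented to correlate positively with the
#' member-average profile, so a high score always means high module-wide
#' intensity.
#'
#' @param m Children-by-metabolite numeric matrix.
#' @param members Column names (at least 2) forming the module.
#' @return Numeric per-child score with attribute `var_explained`, the
#'   fraction of member variance captured by PC1.
#' @export
module_eigenscore <- function(m, members) {
  if (length(members) < 2) stop("a module needs at least 2 members",
                                call. = FALSE)
  sub <- scale(m[, members, drop = FALSE])
  pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  if (stats::cor(s, rowMeans(sub)) < 0) s <- -s
  s <- s / stats::sd(s)
  attr(s, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  unname_keep_attr <- s
  names(unname_keep_attr) <- NULL
  unname_keep_attr
}

#' Module size bar chart
#'
#' @param object A `module_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_partition <- function(object, ...) {
  d <- object$modules
  d$module <- factor(d$module, levels = d$module[order(-d$size)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$module, y = .data$size,
                                  fill = .data$module)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "Module", y = "Members")
}
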