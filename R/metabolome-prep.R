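#' Construct a metabolite panel
#'
#' Bundles a children-by-metabolite intensity table with per-metabolite
#' annotation and a QC ledger. Intensities are raw positive values;
#' non-detects are `NA`. The QC ledger records, per metabolite, the
#' coefficient of variation, the non-detect count, the processing status and
#' which transform (if any) has been applied.
#'
#' @param intensities Data frame whose first column is `child_id` and whose
#'   remaining columns are metabolite intensities (positive or `NA`).
#' @param annotation Optional data frame `metabolite, type, platform`;
#'   missing metabolites are annotated `other` / `unknown`. Lipid class
#'   codes follow the field's shorthand (TAG, DAG, CE, PC, PE, LPC, LPE,
#'   AC, SM, PI, PC_P, PE_P).
#' @return An object of class `metabolite_panel`: a list with elements
#'   `intensities` (tibble), `annotation` (tibble) and `qc` (tibble with
#'   columns `metabolite, cv, n_nondetect, status, transform`).
#' @export
metabolite_panel <- function(intensities, annotation = NULL) {
  intensities <- tibble::as_tibble(intensities)
  if (names(intensities)[1] != "child_id") {
    stop("first column of `intensities` must be `child_id`", call. = FALSE)
  }
  mets <- names(intensities)[-1]
  vals <- as.matrix(intensities[, -1, drop = FALSE])
  if (any(vals <= 0, na.rm = TRUE)) {
    stop("observed intensities must be positive; encode non-detects as NA",
         call. = FALSE)
  }
  if (is.null(annotation)) {
    annotation <- tibble::tibble(metabolite = mets, type = "other",
                                 platform = "unknown")
  } else {
    annotation <- tibble::as_tibble(annotation)
    annotation <- dplyr::left_join(tibble::tibble(metabolite = mets),
                                   annotation, by = "metabolite")
    annotation$type[is.na(annotation$type)] <- "other"
    annotation$platform[is.na(annotation$platform)] <- "unknown"
  }
  qc <- tibble::tibble(
    metabolite = mets,
    cv = NA_real_,
    n_nondetect = colSums(is.na(vals)),
    status = "retained",
    transform = "none"
  )
  structure(list(intensities = intensities, annotation = annotation,
                 qc = qc), class = "metabolite_panel")
}

#' @export
print.metabolite_panel <- function(x, ...) {
  n_ret <- sum(x$qc$status == "retained")
  cat("<metabolite_panel> ", nrow(x$intensities), " children x ",
      nrow(x$qc), " metabolites (", n_ret, " retained; transform: ",
      x$qc$transform[1], ")\n", sep = "")
  invisible(x)
}

#' Retained intensity matrix of a panel
#'
#' @param panel A `metabolite_panel`.
#' @param retained_only Drop QC-excluded metabolites (default `TRUE`).
#' @return Numeric matrix, rows named by `child_id`.
#' @export
panel_matrix <- function(panel, retained_only = TRUE) {
  stopifnot(inherits(panel, "metabolite_panel"))
  keep <- if (retained_only) panel$qc$metabolite[panel$qc$status == "retained"]
          else panel$qc$metabolite
  m <- as.matrix(panel$intensities[, keep, drop = FALSE])
  rownames(m) <- panel$intensities$child_id
  m
}

#' Flag metabolites with excessive coefficient of variation
#'
#' Computes, per metabolite, the coefficient of variation `100 * sd / mean`
#' over observed (non-missing) raw intensities with the sample (n - 1)
#' standard deviation, and marks metabolites whose CV is *strictly greater*
#' than the threshold as `excluded_cv` (a CV exactly at the threshold is
#' retained). Metabolites with fewer than two observed values cannot have a
#' CV and are marked `excluded_insufficient`.
#'
#' @param panel A `metabolite_panel` of raw intensities.
#' @param threshold CV threshold in percent (default 20).
#' @return The panel with an updated QC ledger.
#' @export
cv_filter <- function(panel, threshold = 20) {
  stopifnot(inherits(panel, "metabolite_panel"))
  m <- as.matrix(panel$intensities[, -1, drop = FALSE])
  n_obs <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  cv <- 100 * sdv / mu
  panel$qc$cv <- unname(cv)
  status <- panel$qc$status
  status[n_obs < 2] <- "excluded_insufficient"
  status[n_obs >= 2 & cv > threshold] <- "excluded_cv"
  panel$qc$status <- status
  panel
}

#' Impute non-detects as half the per-metabolite minimum
#'
#' Replaces every missing value in a retained metabolite column by half the
#' minimum observed intensity of that column. A retained column with no
#' observed value at all has no minimum and is an error.
#'
#' @param panel A `metabolite_panel` (typically after [cv_filter()]).
#' @return The panel with non-detects filled in.
#' @export
impute_nondetects <- function(panel) {
  stopifnot(inherits(panel, "metabolite_panel"))
  keep <- panel$qc$metabolite[panel$qc$status == "retained"]
  for (j in keep) {
    v <- panel$intensities[[j]]
    if (all(is.na(v))) {
      stop("metabolite '", j, "' is entirely non-detect; no minimum exists",
           call. = FALSE)
    }
    v[is.na(v)] <- 0.5 * min(v, na.rm = TRUE)
    panel$intensities[[j]] <- v
  }
  panel
}

#' Rank-based inverse normal transform of a vector
#'
#' Maps values onto standard-normal quantiles through their ranks:
#' `qnorm((r - c) / (n - 2c + 1))` with offset `c` (Blom's 3/8 by default).
#' Ties receive the average rank, so tied inputs stay tied after transform.
#'
#' @param x Numeric vector without missing values.
#' @param offset Rank offset `c`; 3/8 (Blom) by default.
#' @return Transformed vector, a monotone function of the ranks of `x`.
#' @export
inverse_normal <- function(x, offset = 3 / 8) {
  if (anyNA(x)) stop("`x` must not contain missing values", call. = FALSE)
  n <- length(x)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Inverse normal transformation of every retained metabolite
#'
#' Applies [inverse_normal()] column-wise to the retained metabolites of a
#' panel. Requires imputation to have run first (no remaining non-detects).
#'
#' @inheritParams impute_nondetects
#' @param offset Rank offset passed to [inverse_normal()].
#' @return The panel with transformed retained columns and
#'   `transform = "inverse_normal"` in the QC ledger.
#' @export
inverse_normal_transform <- function(panel, offset = 3 / 8) {
  stopifnot(inherits(panel, "metabolite_panel"))
  keep <- panel$qc$metabolite[panel$qc$status == "retained"]
  if (anyNA(panel$intensities[, keep, drop = FALSE])) {
    stop("non-detects remain; run impute_nondetects() first", call. = FALSE)
  }
  for (j in keep) {
    panel$intensities[[j]] <- inverse_normal(panel$intensities[[j]], offset)
  }
  panel$qc$transform[panel$qc$status == "retained"] <- "inverse_normal"
  panel
}

#' Full metabolite preprocessing pipeline
#'
#' CV filter, then half-minimum imputation of non-detects, then rank-based
#' inverse normal transformation, in that fixed order.
#'
#' @inheritParams cv_filter
#' @inheritParams inverse_normal_transform
#' @return The processed `metabolite_panel`.
#' @export
prepare_metabolome <- function(panel, threshold = 20, offset = 3 / 8) {
  panel |>
    cv_filter(threshold = threshold) |>
    impute_nondetects() |>
    inverse_normal_transform(offset = offset)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a metabolite panel
#'
#' @param x A `metabolite_panel`.
#' @param ... Unused.
#' @return Tibble `child_id, metabolite, intensity, type, platform, status`.
#' @export
tidy.metabolite_panel <- function(x, ...) {
  long <- tidyr::pivot_longer(x$intensities, -"child_id",
                              names_to = "metabolite",
                              values_to = "intensity")
  long <- dplyr::left_join(long, x$annotation, by = "metabolite")
  dplyr::left_join(long, x$qc[, c("metabolite", "status")], by = "metabolite")
}

#' One-row QC summary of a metabolite panel
#'
#' @param x A `metabolite_panel`.
#' @param ... Unused.
#' @return Tibble with children, metabolite and QC-status counts.
#' @export
glance.metabolite_panel <- function(x, ...) {
  tibble::tibble(
    n_children = nrow(x$intensities),
    n_metabolites = nrow(x$qc),
    n_retained = sum(x$qc$status == "retained"),
    n_excluded_cv = sum(x$qc$status == "excluded_cv"),
    n_nondetect_total = sum(x$qc$n_nondetect),
    transform = x$qc$transform[match("retained", x$qc$status)]
  )
}

#' Read a metabolite intensity matrix and annotation from delimited text
#'
#' @param path Intensity file: header row, first column `child_id`,
#'   remaining columns metabolite ids; empty cells (or `sentinel`) are
#'   non-detects.
#' @param annotation_path Optional annotation file `metabolite, type,
#'   platform`.
#' @param sentinel Extra string(s) to treat as non-detect (besides empty
#'   cells). Default `c("", "ND")`.
#' @return A `metabolite_panel`.
#' @export
read_metabolome <- function(path, annotation_path = NULL,
                            sentinel = c("", "ND")) {
  raw <- readr::read_csv(path, na = c(sentinel, "NA"),
                         show_col_types = FALSE)
  ann <- if (!is.null(annotation_path)) {
    readr::read_csv(annotation_path, show_col_types = FALSE)
  }
  metabolite_panel(raw, ann)
}
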