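#' LMS z-score for a measurement against reference parameters
#'
#' Converts a BMI value to an age- and sex-specific z-score using the LMS
#' (lambda-mu-sigma) method of growth-reference construction: `L` is the
#' Box-Cox power that normalizes the skewed BMI distribution, `M` the median
#' and `S` the coefficient of variation at a given age.
#'
#' For `L != 0` the transform is `z = ((x/M)^L - 1) / (L * S)`; as `L -> 0`
#' it degenerates continuously to `z = log(x/M) / S`, and the log form is
#' used whenever `|L| < 1e-6` so the function is numerically continuous in
#' `L`.
#'
#' @param bmi Measurement (kg/m^2), positive. Vectorized.
#' @param L Box-Cox power (unitless).
#' @param M Median of the reference distribution (kg/m^2), positive.
#' @param S Coefficient of variation of the reference (unitless), positive.
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' lms_zscore(17.6, L = 1, M = 16, S = 0.1) # exactly 1
lms_zscore <- function(bmi, L, M, S) {
  n <- max(length(bmi), length(L), length(M), length(S))
  bmi <- rep_len(bmi, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("`bmi` must be positive and finite", call. = FALSE)
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop("LMS parameters require M > 0 and S > 0", call. = FALSE)
  }
  z <- ifelse(abs(L) < 1e-6,
    log(bmi / M) / S,
    ((bmi / M)^L - 1) / (L * S)
  )
  z
}

#' Invert an LMS z-score back to the measurement scale
#' @param z z-score.
#' @inheritParams lms_zscore
#' @return BMI (kg/m^2).
#' @keywords internal
lms_inverse <- function(z, L, M, S) {
  ifelse(abs(L) < 1e-6,
    M * exp(S * z),
    M * (1 + L * S * z)^(1 / L)
  )
}

# Interpolate L, M, S linearly in age within one sex stratum of the
# reference. Ages outside the table are clamped to the boundary row
# (out_of_range = "clamp") or rejected.
interpolate_lms <- function(ref, sex, age_months,
                            out_of_range = c("clamp", "error")) {
  out_of_range <- match.arg(out_of_range)
  ref <- as.data.frame(ref)
  need <- c("sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(ref))) {
    stop("LMS reference must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(sex), length(age_months))
  sex <- rep_len(as.character(sex), n)
  age_months <- rep_len(age_months, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex)) {
    sub <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(sub) < 2) {
      stop("LMS reference does not cover sex '", s, "'", call. = FALSE)
    }
    sub <- sub[order(sub$age_months), , drop = FALSE]
    idx <- which(sex == s)
    a <- age_months[idx]
    if (out_of_range == "error" &&
        any(a < min(sub$age_months) | a > max(sub$age_months))) {
      stop("visit age outside the LMS reference range", call. = FALSE)
    }
    a <- pmin(pmax(a, min(sub$age_months)), max(sub$age_months))
    for (p in c("L", "M", "S")) {
      out[idx, p] <- stats::approx(sub$age_months, sub[[p]], xout = a,
                                   rule = 2)$y
    }
  }
  tibble::as_tibble(as.data.frame(out))
}

#' BMI-for-age percentiles from a growth table
#'
#' Converts each visit in a long-format growth table to a BMI percentile
#' (BMIPCT) against an LMS reference, interpolating L, M and S linearly in
#' age between the bracketing reference rows for the child's sex. BMIPCT is
#' `100 * pnorm(z)`. Reference percentiles are defined only from age 2 years
#' onward, so visits younger than `min_age_months` are dropped from the
#' output.
#'
#' @param growth Data frame with columns `child_id`, `sex`, `age_months`,
#'   `bmi`.
#' @param ref LMS reference data frame with columns `sex`, `age_months`,
#'   `L`, `M`, `S`.
#' @param min_age_months Youngest age (months) at which percentiles are
#'   defined; earlier visits are dropped. Default 24.
#' @param out_of_range `"clamp"` (default) evaluates ages beyond the
#'   reference at the boundary row; `"error"` rejects them.
#' @return A tibble `child_id, sex, age_months, bmi, z, bmipct` with one row
#'   per retained visit; `bmipct` lies strictly inside (0, 100).
#' @export
bmi_percentile <- function(growth, ref, min_age_months = 24,
                           out_of_range = c("clamp", "error")) {
  out_of_range <- match.arg(out_of_range)
  growth <- tibble::as_tibble(growth)
  need <- c("child_id", "sex", "age_months", "bmi")
  if (!all(need %in% names(growth))) {
    stop("`growth` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  kept <- dplyr::filter(growth, .data$age_months >= min_age_months)
  if (nrow(kept) == 0) {
    return(dplyr::mutate(kept, z = numeric(0), bmipct = numeric(0)))
  }
  lms <- interpolate_lms(ref, kept$sex, kept$age_months, out_of_range)
  kept$z <- lms_zscore(kept$bmi, lms$L, lms$M, lms$S)
  kept$bmipct <- 100 * stats::pnorm(kept$z)
  kept
}

#' Convert a BMI percentile back to a BMI value
#'
#' Inverse of the percentile mapping used by [bmi_percentile()]: the
#' synthetic-cohort generator simulates trajectories on the percentile scale
#' and maps them to raw BMI through this function. Round-tripping through
#' [bmi_percentile()] recovers the input percentile to well below 1e-8.
#'
#' @param pct Percentile(s), strictly inside (0, 100).
#' @param sex Sex code(s) matching the reference (`"F"`/`"M"`).
#' @param age_months Age(s) in months.
#' @param ref LMS reference table (see [bmi_percentile()]).
#' @param out_of_range Boundary handling as in [bmi_percentile()].
#' @return BMI values (kg/m^2).
#' @export
percentile_to_bmi <- function(pct, sex, age_months, ref,
                              out_of_range = c("clamp", "error")) {
  if (any(pct <= 0 | pct >= 100)) {
    stop("`pct` must lie strictly between 0 and 100", call. = FALSE)
  }
  out_of_range <- match.arg(out_of_range)
  n <- max(length(pct), length(sex), length(age_months))
  pct <- rep_len(pct, n)
  lms <- interpolate_lms(ref, sex, age_months, out_of_range)
  z <- stats::qnorm(pct / 100)
  lms_inverse(z, lms$L, lms$M, lms$S)
}

#' Read an LMS growth reference from delimited text
#'
#' @param path File with header columns `sex`, `age_months`, `L`, `M`, `S`.
#' @return Tibble sorted by sex then age.
#' @export
read_lms_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sex", "age_months", "L", "M", "S")
  if (!all(need %in% names(ref))) {
    stop("LMS reference file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(ref, .data$sex, .data$age_months)
}

#' Read a long-format growth table from delimited text
#'
#' @param path File with header columns `child_id`, `sex`, `age_months`,
#'   `bmi`.
#' @param ages Unit of the age column: `"months"` (default) or `"years"`
#'   (converted to months by multiplying by 12).
#' @return Tibble sorted by child then age.
#' @export
read_growth <- function(path, ages = c("months", "years")) {
  ages <- match.arg(ages)
  g <- readr::read_csv(path, show_col_types = FALSE)
  if (ages == "years" && "age_years" %in% names(g)) {
    g$age_months <- g$age_years * 12
    g$age_years <- NULL
  } else if (ages == "years") {
    g$age_months <- g$age_months * 12
  }
  need <- c("child_id", "sex", "age_months", "bmi")
  if (!all(need %in% names(g))) {
    stop("growth file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(g, .data$child_id, .data$age_months)
}
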