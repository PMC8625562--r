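#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over the declared family (the
#' whole input vector). Thin validated wrapper around
#' `p.adjust(method = "BH")`.
#'
#' @param p P-values in `[0, 1]`; the family size is `length(p)`.
#' @return q-values, monotone-consistent with the BH step-up rule and never
#'   below the input p-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Fit the baseline-category (multinomial) logit by Newton-Raphson on the
# multinomial log-likelihood. y: factor, first level = reference; X: model
# matrix. Returns coefficient matrix B ((K-1) x p), vcov of vec(B') in
# contrast-major order, loglik, convergence and separation flags.
multinom_nr <- function(y, X, maxit = 100, score_tol = 1e-8,
                        ll_tol = 1e-10) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  if (K < 2) stop("outcome needs at least 2 levels", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == levels(y)[k])
  B <- matrix(0, p, K - 1)

  loglik <- function(B) {
    eta <- X %*% B
    denom <- log1p(rowSums(exp(eta)))
    sum(rowSums(Y * eta)) - sum(denom)
  }
  probs <- function(B) {
    eta <- X %*% B
    e <- exp(eta)
    e / (1 + rowSums(e))
  }

  ll_old <- loglik(B)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- probs(B)
    score <- as.vector(crossprod(X, Y - P)) # p*(K-1), column-major by contrast
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) {
      for (l in seq_len(K - 1)) {
        w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
        H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
          crossprod(X, X * w)
      }
    }
    step <- tryCatch(solve(H, score), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), score)
    })
    # step-halving if the full Newton step decreases the log-likelihood
    for (half in 0:20) {
      Bnew <- B + matrix(step * 0.5^half, p, K - 1)
      ll_new <- loglik(Bnew)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    B <- Bnew
    done <- max(abs(score)) < score_tol ||
      abs(ll_new - ll_old) < ll_tol * (abs(ll_old) + ll_tol)
    ll_old <- ll_new
    if (done) { converged <- TRUE; break }
  }
  P <- probs(B)
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (k in seq_len(K - 1)) {
    for (l in seq_len(K - 1)) {
      w <- if (k == l) P[, k] * (1 - P[, k]) else -P[, k] * P[, l]
      H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
        crossprod(X, X * w)
    }
  }
  vcov <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, nrow(H), ncol(H))
  })
  coefs <- t(B) # (K-1) x p, rows = non-reference levels
  dimnames(coefs) <- list(levels(y)[-1], colnames(X))
  list(
    coefficients = coefs,
    vcov = vcov,
    loglik = ll_old,
    levels = levels(y),
    converged = converged,
    separation = any(abs(B) > 20),
    n = n,
    iterations = it
  )
}

#' Multinomial logistic regression of trajectory group on an exposure
#'
#' Maximum-likelihood fit of the baseline-category logit model by
#' Newton-Raphson, with standard errors from the inverse observed
#' information. One logit is fitted per non-reference outcome level
#' ("contrast"), each comparing that level against the reference.
#' Complete cases only.
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Name of the outcome column (3- or 4-level labels).
#' @param exposure Name of the exposure column (numeric score or
#'   metabolite).
#' @param covariates Character vector of adjustment columns (factors are
#'   dummy-coded; an explicit `"Unknown"` category is kept as its own
#'   level). Default none.
#' @param reference Outcome level used as the baseline (default: first
#'   level of `factor(outcome)`).
#' @param interaction Optional column name whose multiplicative interaction
#'   with the exposure enters the model (used for sex-interaction fits).
#' @return An object of class `multinom_fit`: coefficients, vcov, loglik,
#'   contrasts, convergence/separation flags.
#' @export
fit_multinomial <- function(data, outcome, exposure, covariates = character(),
                            reference = NULL, interaction = NULL) {
  data <- as.data.frame(data)
  vars <- c(outcome, exposure, covariates, interaction)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  y <- factor(data[[outcome]])
  if (!is.null(reference)) y <- stats::relevel(y, ref = reference)
  if (any(table(y) < 10)) {
    warning("an outcome level has fewer than 10 observations",
            call. = FALSE)
  }
  rhs <- c(exposure, covariates)
  if (!is.null(interaction)) {
    rhs <- c(rhs, interaction, paste0(exposure, ":", interaction))
  }
  f <- stats::reformulate(rhs)
  X <- stats::model.matrix(f, data = data)
  fit <- multinom_nr(y, X)
  fit$terms <- colnames(X)
  fit$exposure <- exposure
  fit$outcome <- outcome
  fit$reference <- levels(y)[1]
  fit$contrasts <- paste(levels(y)[-1], "vs", levels(y)[1])
  class(fit) <- "multinom_fit"
  fit
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("<multinom_fit> ", x$outcome, " (ref ", x$reference, ") ~ ",
      x$exposure, "; n = ", x$n, ", loglik = ", round(x$loglik, 2),
      if (!x$converged) " [NOT CONVERGED]",
      if (x$separation) " [SEPARATION]", "\n", sep = "")
  invisible(x)
}

#' Per-contrast coefficient table of a multinomial fit
#'
#' @param x A `multinom_fit`.
#' @param ... Unused.
#' @return Tibble `contrast, term, beta, se, or, ci_lo, ci_hi, p` with Wald
#'   tests; `or = exp(beta)` and the CI is `exp(beta +/- 1.96 se)`.
#' @export
tidy.multinom_fit <- function(x, ...) {
  p <- length(x$terms)
  K1 <- length(x$contrasts)
  out <- purrr::map_dfr(seq_len(K1), function(k) {
    idx <- ((k - 1) * p + 1):(k * p)
    beta <- x$coefficients[k, ]
    se <- sqrt(diag(x$vcov)[idx])
    tibble::tibble(
      contrast = x$contrasts[k],
      term = x$terms,
      beta = unname(beta),
      se = unname(se),
      or = exp(unname(beta)),
      ci_lo = exp(unname(beta) - 1.96 * unname(se)),
      ci_hi = exp(unname(beta) + 1.96 * unname(se)),
      p = 2 * stats::pnorm(-abs(unname(beta) / unname(se)))
    )
  })
  out
}

#' One-row summary of a multinomial fit
#'
#' @param x A `multinom_fit`.
#' @param ... Unused.
#' @return Tibble `loglik, n, n_terms, converged, separation, iterations`.
#' @export
glance.multinom_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n = x$n, n_terms = length(x$terms),
    converged = x$converged, separation = x$separation,
    iterations = x$iterations
  )
}

# Exposure-row association table for one fitted exposure.
exposure_rows <- function(fit, id) {
  td <- tidy(fit)
  td <- td[td$term == fit$exposure, , drop = FALSE]
  tibble::tibble(
    exposure = id, contrast = td$contrast, beta = td$beta, se = td$se,
    or = td$or, ci_lo = td$ci_lo, ci_hi = td$ci_hi, p = td$p,
    n = fit$n, converged = fit$converged, separation = fit$separation
  )
}

#' Module eigen-score associations with the three trajectory groups
#'
#' Fits one multinomial logistic regression per module: trajectory group
#' (early-OWO, late-OWO vs NW reference) on the module eigen-score with
#' covariate adjustment. q-values are BH-adjusted within each contrast over
#' the family of modules, and rows are ordered by the early-OWO-vs-NW
#' q-value.
#'
#' @param scores Eigen-score tibble (`child_id` plus one column per
#'   module), e.g. `partition$eigenscores`.
#' @param assignments A `trajectory_assignment` (uses `group3`).
#' @param covariate_data Data frame keyed by `child_id` with the adjustment
#'   columns.
#' @param covariates Character vector of adjustment column names.
#' @param reference Reference group (default `"NW"`).
#' @return Association tibble with per-contrast `beta, se, or, ci_lo,
#'   ci_hi, p, q, n` and fit flags.
#' @export
module_association <- function(scores, assignments, covariate_data = NULL,
                               covariates = character(),
                               reference = "NW") {
  mods <- setdiff(names(scores), "child_id")
  if (length(mods) == 0) {
    return(tibble::tibble(exposure = character(), contrast = character(),
                          beta = numeric(), se = numeric(), or = numeric(),
                          ci_lo = numeric(), ci_hi = numeric(),
                          p = numeric(), q = numeric(), n = integer(),
                          converged = logical(), separation = logical()))
  }
  base <- dplyr::inner_join(
    tibble::as_tibble(scores),
    assignments[, c("child_id", "group3")], by = "child_id")
  if (!is.null(covariate_data)) {
    base <- dplyr::inner_join(base, tibble::as_tibble(covariate_data),
                              by = "child_id")
  }
  res <- purrr::map_dfr(mods, function(mod) {
    fit <- fit_multinomial(base, "group3", mod, covariates = covariates,
                           reference = reference)
    exposure_rows(fit, mod)
  })
  res <- res |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(q = bh_fdr(.data$p)) |>
    dplyr::ungroup()
  early <- res[grepl("^early-OWO", res$contrast),
               c("exposure", "q")]
  ord <- early$exposure[order(early$q)]
  res$exposure <- factor(res$exposure, levels = ord)
  res <- dplyr::arrange(res, .data$exposure, .data$contrast)
  res$exposure <- as.character(res$exposure)
  res
}

#' Single-metabolite associations against a chosen grouping
#'
#' Fits one multinomial logistic regression per metabolite column; used for
#' both the exploratory four-group screen and member follow-up.
#'
#' @param panel Processed `metabolite_panel` (or children-by-metabolite
#'   matrix with rownames).
#' @param assignments `trajectory_assignment`.
#' @param group_col `"group4"` or `"group3"`.
#' @param covariate_data,covariates Adjustment data and column names.
#' @param reference Reference group label.
#' @param metabolites Subset of metabolite columns (default all retained).
#' @return Association tibble with `q` BH-adjusted within contrast across
#'   the tested metabolites.
#' @export
metabolite_association <- function(panel, assignments, group_col = "group3",
                                   covariate_data = NULL,
                                   covariates = character(),
                                   reference = "NW",
                                   metabolites = NULL) {
  m <- if (inherits(panel, "metabolite_panel")) panel_matrix(panel)
       else as.matrix(panel)
  if (is.null(metabolites)) metabolites <- colnames(m)
  base <- tibble::tibble(child_id = rownames(m))
  base <- dplyr::inner_join(base,
    assignments[, c("child_id", group_col)], by = "child_id")
  if (!is.null(covariate_data)) {
    base <- dplyr::inner_join(base, tibble::as_tibble(covariate_data),
                              by = "child_id")
  }
  res <- purrr::map_dfr(metabolites, function(met) {
    d <- base
    d$.met <- m[d$child_id, met]
    names(d)[names(d) == ".met"] <- "metabolite_value"
    fit <- fit_multinomial(d, group_col, "metabolite_value",
                           covariates = covariates, reference = reference)
    exposure_rows(fit, met)
  })
  res |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(q = bh_fdr(.data$p)) |>
    dplyr::ungroup()
}

#' Exploratory four-group metabolite screen and collapse decision
#'
#' Regresses the four-level trajectory grouping (reference NW-A) on each
#' metabolite, counts findings per contrast at `p <= 0.05` and
#' `q <= 0.05`, and recommends collapsing NW-B into NW-A when the
#' NW-B-vs-NW-A contrast yields no FDR-significant metabolite — the
#' empirical justification for analysing three groups.
#'
#' @inheritParams metabolite_association
#' @return List: `results` (association tibble), `counts` (per-contrast
#'   significance counts), `collapse_recommended` (logical).
#' @export
explore_four_groups <- function(panel, assignments, covariate_data = NULL,
                                covariates = character()) {
  res <- metabolite_association(panel, assignments, group_col = "group4",
                                covariate_data = covariate_data,
                                covariates = covariates,
                                reference = "NW-A")
  counts <- res |>
    dplyr::group_by(.data$contrast) |>
    dplyr::summarise(n_p05 = sum(.data$p <= 0.05),
                     n_q05 = sum(.data$q <= 0.05), .groups = "drop")
  nwb <- counts[grepl("^NW-B", counts$contrast), ]
  list(
    results = res,
    counts = counts,
    collapse_recommended = nrow(nwb) == 1 && nwb$n_q05 == 0
  )
}

#' Follow up members of significant modules individually
#'
#' Selects modules whose module-level association reached `p <= 0.05` on
#' either contrast and tests each member metabolite against the three
#' trajectory groups, with BH-FDR over the union of all selected-module
#' members (per contrast).
#'
#' @param panel Processed `metabolite_panel`.
#' @param partition `module_partition`.
#' @param module_results Output of [module_association()].
#' @param assignments `trajectory_assignment`.
#' @inheritParams module_association
#' @return Association tibble (empty when no module is selected), with a
#'   `module` column.
#' @export
member_followup <- function(panel, partition, module_results, assignments,
                            covariate_data = NULL,
                            covariates = character(),
                            reference = "NW") {
  sel <- unique(module_results$exposure[module_results$p <= 0.05])
  if (length(sel) == 0) {
    return(tibble::tibble(exposure = character(), module = character(),
                          contrast = character(), beta = numeric(),
                          se = numeric(), or = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), p = numeric(), q = numeric(),
                          n = integer()))
  }
  members <- partition$membership$metabolite[
    partition$membership$module %in% sel]
  res <- metabolite_association(panel, assignments, group_col = "group3",
                                covariate_data = covariate_data,
                                covariates = covariates,
                                reference = reference,
                                metabolites = members)
  dplyr::left_join(res, partition$membership,
                   by = c(exposure = "metabolite")) |>
    dplyr::relocate("module", .after = "exposure")
}

#' Likelihood-ratio test for sex modification of an exposure effect
#'
#' Compares the multinomial model with exposure and exposure-by-sex
#' interaction against the model with neither (covariates, including sex,
#' in both). The LRT has `2 * (levels - 1)` degrees of freedom and tests
#' the exposure's overall effect including its sex modification;
#' interaction-term Wald p-values are reported alongside.
#'
#' @inheritParams fit_multinomial
#' @param sex Name of the sex column (must have both levels present).
#' @return List: `lrt` (one-row tibble `stat, df, p`), `interaction`
#'   (per-contrast Wald rows for the interaction terms), `full`, `null`
#'   (the two fits).
#' @export
sex_interaction_lrt <- function(data, outcome, exposure, sex = "sex",
                                covariates = character(),
                                reference = NULL) {
  data <- as.data.frame(data)
  vars <- c(outcome, exposure, sex, covariates)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  if (length(unique(data[[sex]])) < 2) {
    stop("both sexes must be present", call. = FALSE)
  }
  covs <- union(covariates, sex)
  full <- fit_multinomial(data, outcome, exposure, covariates = covs,
                          reference = reference, interaction = sex)
  null <- local({
    y <- factor(data[[outcome]])
    if (!is.null(reference)) y <- stats::relevel(y, ref = reference)
    X <- stats::model.matrix(stats::reformulate(covs), data = data)
    fit <- multinom_nr(y, X)
    fit$terms <- colnames(X)
    fit$exposure <- "(none)"
    fit$outcome <- outcome
    fit$reference <- levels(y)[1]
    fit$contrasts <- paste(levels(y)[-1], "vs", levels(y)[1])
    class(fit) <- "multinom_fit"
    fit
  })
  K1 <- length(full$contrasts)
  stat <- 2 * (full$loglik - null$loglik)
  df <- 2 * K1
  td <- tidy(full)
  inter <- td[grepl(":", td$term) & grepl(exposure, td$term, fixed = TRUE), ]
  list(
    lrt = tibble::tibble(stat = stat, df = df,
                         p = stats::pchisq(stat, df, lower.tail = FALSE)),
    interaction = inter,
    full = full,
    null = null
  )
}
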