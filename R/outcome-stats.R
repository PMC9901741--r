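#' Cox proportional-hazards fit
#'
#' Fits a Cox model by partial likelihood for the chosen endpoint with the
#' given covariate columns, complete-case on those columns. Ties are
#' handled by the Efron approximation. Non-convergence or separation does
#' not raise an error: the result carries a `converged` flag and the
#' offending warnings.
#'
#' @param data A tibble holding `<endpoint>_time`, `<endpoint>_event` and
#'   the covariate columns (e.g. the clinical table joined to an immune
#'   profile).
#' @param endpoint `"os"` (overall survival) or `"pfi"`
#'   (progression-free interval).
#' @param covariates Character vector of covariate column names. A
#'   covariate constant over the analysed samples is an error.
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @return An `ai_cox` object; see [tidy.ai_cox()] and [glance.ai_cox()].
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 150, seed = 7))
#' cohort <- join_cohort(sim$expr, sim$clinical)
#' profile <- immune_profile(score_cell_types(cohort))
#' dat <- dplyr::inner_join(cohort$clinical, profile, by = "sample_id")
#' fit <- fit_cox(dat, endpoint = "os", covariates = c("ai_ratio", "age"))
#' tidy(fit)
fit_cox <- function(data, endpoint = c("os", "pfi"), covariates,
                    ties = "efron") {
  endpoint <- match.arg(endpoint)
  time_col <- paste0(endpoint, "_time")
  event_col <- paste0(endpoint, "_event")
  needed <- c(time_col, event_col, covariates)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("fit_cox: missing column(s): ", paste(missing, collapse = ", ")))
  }
  dat <- data[, needed, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (sum(dat[[event_col]]) < 2) abort("fit_cox needs >= 2 events after complete-case filtering")
  constant <- covariates[vapply(covariates, function(v) {
    x <- dat[[v]]
    length(unique(x)) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    abort(paste0("constant covariate(s): ", paste(constant, collapse = ", ")))
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste0("`", covariates, "`", collapse = " + ")
  ))
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  converged <- length(notes) == 0 && all(is.finite(stats::coef(fit)))
  s <- summary(fit)
  result <- tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    se = s$coefficients[, "se(coef)"],
    conf_low = s$conf.int[, "lower .95"],
    conf_high = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  )
  structure(
    list(fit = fit, result = result, endpoint = endpoint,
         covariates = covariates, loglik = fit$loglik[2],
         loglik_null = fit$loglik[1], n = fit$n, events = fit$nevent,
         converged = converged, notes = notes),
    class = "ai_cox"
  )
}

#' @export
print.ai_cox <- function(x, ...) {
  cat("<ai_cox> endpoint ", x$endpoint, ", n = ", x$n, ", events = ",
      x$events, if (!x$converged) " [did not converge]", "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `ai_cox` object.
#' @param ... Unused.
#' @return A tibble with one row per covariate: `term`, `estimate`
#'   (log HR), `hr`, `se`, `conf_low`, `conf_high`, `p_value`.
#' @export
tidy.ai_cox <- function(x, ...) x$result

#' One-line summary of a Cox fit
#'
#' @param x An `ai_cox` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `events`, `loglik`, `loglik_null`,
#'   `converged`, `endpoint`.
#' @export
glance.ai_cox <- function(x, ...) {
  tibble::tibble(n = x$n, events = x$events, loglik = x$loglik,
                 loglik_null = x$loglik_null, converged = x$converged,
                 endpoint = x$endpoint)
}

#' Extract one covariate's estimate from Cox fits, for meta-analysis
#'
#' @param fits A named list of `ai_cox` objects (names become strata).
#' @param term Covariate term to extract.
#' @return A tibble `stratum`, `estimate` (log HR), `se`, `n`, `events`.
#' @export
cox_term <- function(fits, term) {
  purrr::imap_dfr(fits, function(f, nm) {
    row <- f$result[f$result$term == term, , drop = FALSE]
    if (nrow(row) == 0) abort(paste0("term '", term, "' not in fit '", nm, "'"))
    tibble::tibble(stratum = nm, estimate = row$estimate, se = row$se,
                   n = f$n, events = f$events)
  })
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survivor curves per stratum, optionally truncated at a
#' follow-up horizon, with the k-group log-rank test.
#'
#' @param data Tibble holding `<endpoint>_time` and `<endpoint>_event`.
#' @param strata Per-sample stratum labels (e.g. `"high"` / `"low"` from
#'   [median_split()]); `NA` rows are dropped.
#' @param endpoint `"os"` or `"pfi"`.
#' @param horizon_years Optional truncation horizon in years (365.25-day
#'   years); observations beyond it are censored at the horizon.
#' @return An `ai_km` object with `curves` (tibble: `stratum`, `time`,
#'   `n_risk`, `n_event`, `surv`), `p_value`, `chisq`, `df` and per-stratum
#'   counts. Plot with [autoplot.ai_km()].
#' @export
km_logrank <- function(data, strata, endpoint = c("os", "pfi"),
                       horizon_years = NULL) {
  endpoint <- match.arg(endpoint)
  time_col <- paste0(endpoint, "_time")
  event_col <- paste0(endpoint, "_event")
  stopifnot(length(strata) == nrow(data))
  keep <- !is.na(strata) & !is.na(data[[time_col]]) & !is.na(data[[event_col]])
  dat <- tibble::tibble(time = data[[time_col]][keep],
                        event = data[[event_col]][keep],
                        stratum = as.character(strata)[keep])
  if (length(unique(dat$stratum)) < 2) abort("km_logrank needs >= 2 strata")
  if (!is.null(horizon_years)) {
    horizon <- horizon_years * 365.25
    dat$event[dat$time > horizon] <- 0
    dat$time <- pmin(dat$time, horizon)
  }
  per_stratum <- dat |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event), .groups = "drop")
  if (any(per_stratum$events == 0)) {
    warn("stratum with zero events; log-rank may be uninformative")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = dat)
  df <- length(sd$n) - 1
  stratum_of <- rep(sub("^stratum=", "", names(sf$strata)), sf$strata)
  curves <- tibble::tibble(
    stratum = stratum_of, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, surv = sf$surv
  )
  structure(
    list(curves = curves, per_stratum = per_stratum, chisq = sd$chisq,
         df = df, p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
         endpoint = endpoint, horizon_years = horizon_years),
    class = "ai_km"
  )
}

#' @export
print.ai_km <- function(x, ...) {
  cat("<ai_km> endpoint ", x$endpoint, ", log-rank chisq = ",
      signif(x$chisq, 4), " (df ", x$df, "), p = ", signif(x$p_value, 3),
      "\n", sep = "")
  print(x$per_stratum)
  invisible(x)
}

#' Fixed-effect (inverse-variance) meta-analysis of hazard ratios
#'
#' Combines per-stratum log hazard ratios with weights proportional to
#' 1/SE^2; the combined log HR is the weighted mean and its SE is
#' `1/sqrt(sum(w))`, with a Wald p-value. Strata with non-finite estimates
#' or SE <= 0 are excluded with a warning. A DerSimonian-Laird
#' random-effects estimate is available behind `method = "random"` for
#' sensitivity analysis.
#'
#' @param per_stratum Tibble with columns `stratum`, `estimate` (log HR)
#'   and `se` — e.g. from [cox_term()].
#' @param method `"fixed"` (default) or `"random"`.
#' @return An `ai_meta` object; see [tidy.ai_meta()] / [glance.ai_meta()].
#' @export
meta_fixed_effect <- function(per_stratum, method = c("fixed", "random")) {
  method <- match.arg(method)
  tb <- tibble::as_tibble(per_stratum)
  stopifnot(all(c("stratum", "estimate", "se") %in% names(tb)))
  ok <- is.finite(tb$estimate) & is.finite(tb$se) & tb$se > 0
  if (any(!ok)) {
    warn(paste0("excluding stratum(s) with non-finite estimate or SE <= 0: ",
                paste(tb$stratum[!ok], collapse = ", ")))
    tb <- tb[ok, , drop = FALSE]
  }
  if (nrow(tb) < 2) abort("meta-analysis needs >= 2 usable strata")
  w <- 1 / tb$se^2
  est <- sum(w * tb$estimate) / sum(w)
  se <- sqrt(1 / sum(w))
  if (method == "random") {
    # DerSimonian-Laird between-stratum variance
    q <- sum(w * (tb$estimate - est)^2)
    df <- nrow(tb) - 1
    tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (tb$se^2 + tau2)
    est <- sum(w * tb$estimate) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  z <- est / se
  per <- dplyr::mutate(tb, weight = w / sum(w), hr = exp(.data$estimate))
  structure(
    list(per_stratum = per, estimate = est, se = se, hr = exp(est),
         conf_low = exp(est - 1.96 * se), conf_high = exp(est + 1.96 * se),
         p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         method = method, k = nrow(tb)),
    class = "ai_meta"
  )
}

#' @export
print.ai_meta <- function(x, ...) {
  cat("<ai_meta> ", x$method, "-effect over ", x$k, " strata: HR = ",
      signif(x$hr, 4), " [", signif(x$conf_low, 4), ", ",
      signif(x$conf_high, 4), "], p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy the per-stratum table of a meta-analysis
#'
#' @param x An `ai_meta` object.
#' @param ... Unused.
#' @return A tibble of per-stratum log HR, SE, HR and normalised weight.
#' @export
tidy.ai_meta <- function(x, ...) x$per_stratum

#' Combined-effect summary of a meta-analysis
#'
#' @param x An `ai_meta` object.
#' @param ... Unused.
#' @return A one-row tibble: combined `hr`, `estimate`, `se`, CI bounds,
#'   `p_value`, `k`, `method`.
#' @export
glance.ai_meta <- function(x, ...) {
  tibble::tibble(hr = x$hr, estimate = x$estimate, se = x$se,
                 conf_low = x$conf_low, conf_high = x$conf_high,
                 p_value = x$p_value, k = x$k, method = x$method)
}

#' Likelihood-ratio test between nested Cox models
#'
#' Chi-square test on twice the log-likelihood difference, with degrees of
#' freedom equal to the difference in covariate count. The smaller model's
#' covariates must be a subset of the larger model's and both fits must use
#' the same samples and endpoint.
#'
#' @param model_small,model_large `ai_cox` objects.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
nested_lrt <- function(model_small, model_large) {
  stopifnot(inherits(model_small, "ai_cox"), inherits(model_large, "ai_cox"))
  if (!all(model_small$covariates %in% model_large$covariates)) {
    abort("models are not nested: small model covariates must be a subset")
  }
  if (model_small$n != model_large$n || model_small$endpoint != model_large$endpoint) {
    abort("models must be fit on the same samples and endpoint")
  }
  df <- length(model_large$covariates) - length(model_small$covariates)
  stat <- max(0, 2 * (model_large$loglik - model_small$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

#' Two-group Wilcoxon (Mann-Whitney) rank-sum comparison
#'
#' Two-sided by default, with exact enumeration when both groups have at
#' most 8 observations and no ties, and the tie-corrected normal
#' approximation otherwise.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector aligned with `values`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   directions refer to the first group level in sorted order.
#' @return A one-row tibble: group labels and sizes, the rank-sum statistic
#'   `W`, `p_value`, and `effect` (difference of group means,
#'   first minus second).
#' @export
group_wilcoxon <- function(values, groups, alternative = "two.sided") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  lv <- sort(unique(groups))
  if (length(lv) != 2) abort("group_wilcoxon needs exactly 2 groups")
  x <- values[groups == lv[1]]
  y <- values[groups == lv[2]]
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(values)
  ht <- wilcox.test(x, y, alternative = alternative, exact = exact,
                    correct = !exact)
  tibble::tibble(
    group1 = lv[1], group2 = lv[2], n1 = length(x), n2 = length(y),
    statistic = unname(ht$statistic), p_value = ht$p.value,
    effect = mean(x) - mean(y), exact = exact
  )
}

#' Fisher's exact test on quadrant membership vs response
#'
#' Builds the 2x2 table of (sample in the high-A/I, high-TIL quadrant) by
#' (responder) and tests association by Fisher's exact test, two-sided by
#' the point-probability method, reporting the conditional odds ratio.
#'
#' @param quadrant Character quadrant labels (`"high/high"` etc.) from
#'   [add_strata()], or a logical vector of quadrant membership.
#' @param responder Logical per-sample responder indicator.
#' @param target Quadrant counted as "in" (default `"high/high"`).
#' @return A one-row tibble: the four cell counts, `odds_ratio`,
#'   `p_value`, and the in-quadrant responder fraction.
#' @export
fisher_quadrant <- function(quadrant, responder, target = "high/high") {
  stopifnot(length(quadrant) == length(responder))
  keep <- !is.na(quadrant) & !is.na(responder)
  inq <- if (is.logical(quadrant)) quadrant[keep] else quadrant[keep] == target
  resp <- as.logical(responder)[keep]
  if (length(inq) == 0) abort("empty table")
  tab <- table(factor(inq, levels = c(TRUE, FALSE)),
               factor(resp, levels = c(TRUE, FALSE)))
  ht <- fisher.test(tab)
  tibble::tibble(
    in_responder = tab[1, 1], in_nonresponder = tab[1, 2],
    out_responder = tab[2, 1], out_nonresponder = tab[2, 2],
    odds_ratio = unname(ht$estimate), p_value = ht$p.value,
    responder_fraction_in = if (sum(tab[1, ]) > 0) tab[1, 1] / sum(tab[1, ]) else NA_real_
  )
}

#' Fraction of samples with innate above adaptive score
#'
#' The "below the diagonal" fraction of an A-vs-I scatter: the proportion
#' of samples with I strictly greater than A (equivalently A/I ratio < 1).
#' Samples with a missing ratio are excluded and counted.
#'
#' @param profile Tibble with `A`, `I` and `ai_ratio` columns.
#' @param group Optional per-sample labels (e.g. response category).
#' @return A tibble per group: `n`, `n_missing`, `n_below`, `fraction`
#'   (NA with a warning when no usable samples remain).
#' @export
below_diagonal_fraction <- function(profile, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(profile))
  stopifnot(length(group) == nrow(profile))
  out <- tibble::tibble(group = as.character(group),
                        A = profile$A, I = profile$I,
                        missing = is.na(profile$ai_ratio)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = sum(!.data$missing),
      n_missing = sum(.data$missing),
      n_below = sum(.data$I > .data$A & !.data$missing),
      fraction = ifelse(.data$n > 0, .data$n_below / .data$n, NA_real_),
      .groups = "drop"
    )
  if (any(is.na(out$fraction))) {
    warn("group(s) with no usable samples: fraction undefined")
  }
  out
}
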