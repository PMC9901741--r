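#' Reverse log-transform of cell-type scores
#'
#' Cell-type scores live on the log2(TPM + 1) scale; the A/I scaling is
#' defined on the linear scale, so scores are first mapped back through
#' `2^x - 1`.
#'
#' @param x Numeric vector or matrix of log2(TPM + 1) values.
#' @return Values on the linear scale (non-negative for non-negative input).
#' @export
reverse_log <- function(x) 2^x - 1

#' Min-max scale cell-type values across a cohort
#'
#' Per cell type (column) and scope group, values are linearly scaled to
#' `[0, 1]`: `(x - min) / (max - min)`, with min and max the cohort-wide
#' (or group-wide) extremes. A degenerate cell type (max == min within a
#' group) maps to all zeros with a warning: a constant column carries no
#' discriminative signal and 0/0 must be avoided.
#'
#' The statistic is deliberately cohort-relative: adding a sample with a
#' new extreme changes every sample's scaled value for that cell type.
#'
#' @param linear Numeric samples-by-cell-types matrix on the linear scale.
#' @param scope Optional per-sample grouping vector (e.g. cancer type);
#'   `NULL` scales across the whole cohort. Every group needs >= 2 samples.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
minmax_scale <- function(linear, scope = NULL) {
  linear <- as.matrix(linear)
  if (is.null(scope)) scope <- rep("cohort", nrow(linear))
  if (length(scope) != nrow(linear)) abort("scope length must equal the number of samples")
  small <- names(which(table(scope) < 2))
  if (length(small) > 0) {
    abort(paste0("scope group(s) with < 2 samples: ", paste(small, collapse = ", ")))
  }
  out <- linear
  nm <- colnames(linear) %||% as.character(seq_len(ncol(linear)))
  degenerate <- character(0)
  for (g in unique(scope)) {
    idx <- which(scope == g)
    block <- linear[idx, , drop = FALSE]
    mins <- apply(block, 2, min)
    maxs <- apply(block, 2, max)
    flat <- maxs == mins
    rng <- ifelse(flat, 1, maxs - mins)
    out[idx, ] <- sweep(sweep(block, 2, mins, "-"), 2, rng, "/")
    out[idx, flat] <- 0
    if (any(flat)) degenerate <- c(degenerate, nm[flat])
  }
  if (length(degenerate) > 0) {
    warn(paste0("degenerate (constant) cell type(s) scaled to 0: ",
                paste(unique(degenerate), collapse = ", ")))
  }
  out
}

#' Adaptive and innate compartment scores
#'
#' Per sample, the adaptive score A is the mean of the scaled values over
#' adaptive cell types and the innate score I the mean over innate cell
#' types; `excluded` cell types contribute to neither.
#'
#' @param scaled Samples-by-cell-types matrix of scaled values in `[0, 1]`.
#' @param panel A marker panel tibble.
#' @return A tibble with columns `A` and `I`, one row per sample.
#' @export
compartment_scores <- function(scaled, panel) {
  panel <- validate_panel(panel)
  adaptive <- intersect(compartment_cell_types(panel, "adaptive"), colnames(scaled))
  innate <- intersect(compartment_cell_types(panel, "innate"), colnames(scaled))
  if (length(adaptive) == 0) abort("no adaptive cell types in the scaled matrix")
  if (length(innate) == 0) abort("no innate cell types in the scaled matrix")
  tibble::tibble(
    A = unname(rowMeans(scaled[, adaptive, drop = FALSE])),
    I = unname(rowMeans(scaled[, innate, drop = FALSE]))
  )
}

#' The adaptive-to-innate ratio
#'
#' `A / I` when the innate score is positive; `NA` when `I == 0`. No
#' epsilon is substituted by default — an epsilon-inflated near-infinite
#' ratio would silently fabricate an extreme value. Users who need a
#' complete column can supply a small positive `epsilon` added to the
#' denominator.
#'
#' @param A,I Numeric vectors of compartment scores in `[0, 1]`.
#' @param epsilon Optional denominator offset (default 0 = none).
#' @return Numeric vector; `NA` exactly where `I == 0` (and `epsilon` 0).
#' @export
ai_ratio <- function(A, I, epsilon = 0) {
  out <- A / (I + epsilon)
  if (epsilon == 0) {
    n_missing <- sum(I == 0, na.rm = TRUE)
    if (n_missing > 0) {
      inform(paste0("ai_ratio: ", n_missing, " sample(s) with innate score 0 set to NA"))
      out[I == 0] <- NA_real_
    }
  }
  out
}

#' Per-sample immune profile: scaled scores, A, I and the A/I ratio
#'
#' Runs the full scaling chain on a cell-type score table: reverse
#' log-transform, per-cell-type min-max scaling across the cohort (or
#' within `scope` groups), compartment means, and the A/I ratio. The
#' default scope is the whole analysis cohort — one dataset at a time —
#' with per-group scaling (e.g. per cancer type) available via `scope`.
#'
#' @param scores Tibble from [score_cell_types()].
#' @param panel Marker panel (default [default_panel()]).
#' @param scope Optional per-sample grouping vector for the min-max
#'   extremes; `NULL` uses cohort-wide extremes.
#' @param epsilon Passed to [ai_ratio()].
#' @return A tibble: `sample_id`, one `scaled <cell type>` column per cell
#'   type, `A`, `I`, `ai_ratio`, `til_score`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 30, seed = 1))
#' cohort <- join_cohort(sim$expr, sim$clinical)
#' profile <- immune_profile(score_cell_types(cohort))
#' head(profile[, c("sample_id", "A", "I", "ai_ratio")])
immune_profile <- function(scores, panel = default_panel(), scope = NULL,
                           epsilon = 0) {
  m <- scores_matrix(scores)
  scaled <- minmax_scale(reverse_log(m), scope = scope)
  comp <- compartment_scores(scaled, panel)
  scaled_tb <- tibble::as_tibble(scaled)
  names(scaled_tb) <- paste("scaled", names(scaled_tb))
  dplyr::bind_cols(
    tibble::tibble(sample_id = scores$sample_id),
    scaled_tb,
    comp,
    tibble::tibble(
      ai_ratio = ai_ratio(comp$A, comp$I, epsilon = epsilon),
      til_score = if ("til_score" %in% names(scores)) scores$til_score else til_score(scores)
    )
  )
}

#' Median-split labels
#'
#' Labels a value `"high"` when it is strictly greater than the median of
#' its scope group and `"low"` otherwise ("above median" read literally;
#' ties go to `"low"`, deterministically). Missing values are excluded
#' from the median and labelled `NA`.
#'
#' @param values Numeric vector.
#' @param scope Optional per-sample grouping vector defining the reference
#'   median (e.g. gender, cancer type); `NULL` uses one cohort median.
#' @return Character vector of `"high"` / `"low"` / `NA`, with the scope
#'   medians attached as attribute `"medians"` (a tibble `scope`,
#'   `median`, `n`).
#' @export
median_split <- function(values, scope = NULL) {
  if (is.null(scope)) scope <- rep("cohort", length(values))
  if (length(scope) != length(values)) abort("scope length must equal values length")
  meds <- tibble::tibble(scope = scope, value = values) |>
    dplyr::group_by(scope = .data$scope) |>
    dplyr::summarise(median = median(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  ref <- meds$median[match(scope, meds$scope)]
  labels <- ifelse(is.na(values), NA_character_,
                   ifelse(values > ref, "high", "low"))
  attr(labels, "medians") <- meds
  labels
}

#' Labels relative to the female median
#'
#' Compares every sample's value to the median over female samples within
#' the same stratum (typically cancer type): males are `"high"` when
#' strictly above the female median, and females are labelled against the
#' same reference. Strata with no female samples leave their samples
#' unlabelled with a warning.
#'
#' @param values Numeric vector.
#' @param gender Character vector (`"male"` / `"female"` / `"unknown"`).
#' @param scope Optional stratum vector (e.g. cancer type).
#' @return Character labels as in [median_split()], with attribute
#'   `"medians"` holding the per-stratum female medians.
#' @export
female_median_reference <- function(values, gender, scope = NULL) {
  if (is.null(scope)) scope <- rep("cohort", length(values))
  stopifnot(length(gender) == length(values), length(scope) == length(values))
  meds <- tibble::tibble(scope = scope, gender = gender, value = values) |>
    dplyr::group_by(scope = .data$scope) |>
    dplyr::summarise(
      median = if (any(.data$gender == "female" & !is.na(.data$value))) {
        median(.data$value[.data$gender == "female"], na.rm = TRUE)
      } else NA_real_,
      n = sum(.data$gender == "female" & !is.na(.data$value)),
      .groups = "drop"
    )
  no_female <- meds$scope[is.na(meds$median)]
  if (length(no_female) > 0) {
    warn(paste0("no female samples in stratum(s): ",
                paste(no_female, collapse = ", "), "; labels set to NA"))
  }
  ref <- meds$median[match(scope, meds$scope)]
  labels <- ifelse(is.na(values) | is.na(ref), NA_character_,
                   ifelse(values > ref, "high", "low"))
  attr(labels, "medians") <- meds
  labels
}

#' Add median-split strata and quadrants to an immune profile
#'
#' Adds `ai_group` and `til_group` (high/low by strict-above-median within
#' the given scopes) and their `quadrant` product (e.g. `"high/high"` =
#' A/I ratio and TIL score both above median).
#'
#' @param profile Tibble from [immune_profile()].
#' @param ai_scope,til_scope Optional per-sample grouping vectors defining
#'   the reference medians (whole cohort when `NULL`).
#' @return `profile` with `ai_group`, `til_group` and `quadrant` columns;
#'   the reference medians are attached as attribute `"strata_medians"`.
#' @export
add_strata <- function(profile, ai_scope = NULL, til_scope = NULL) {
  ai_group <- median_split(profile$ai_ratio, scope = ai_scope)
  til_group <- median_split(profile$til_score, scope = til_scope)
  out <- dplyr::mutate(
    profile,
    ai_group = as.character(ai_group),
    til_group = as.character(til_group),
    quadrant = ifelse(is.na(ai_group) | is.na(til_group), NA_character_,
                      paste(ai_group, til_group, sep = "/"))
  )
  attr(out, "strata_medians") <- list(ai = attr(ai_group, "medians"),
                                      til = attr(til_group, "medians"))
  out
}
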