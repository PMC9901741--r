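#' Assemble the per-sample outcome table
#'
#' Joins the clinical table of a cohort to an immune profile and adds
#' median-split strata, the ordinal stage encoding and a female indicator,
#' giving the single table the downstream statistics operate on.
#'
#' @param cohort An `ai_cohort`.
#' @param profile Tibble from [immune_profile()].
#' @param ai_scope,til_scope Median-split scopes passed to [add_strata()]:
#'   `NULL` (whole cohort) or one of `"gender"`, `"cancer_type"`,
#'   `"gender_cancer_type"`.
#' @return A tibble: clinical columns, `A`, `I`, `ai_ratio`, `til_score`,
#'   `ai_group`, `til_group`, `quadrant`, `stage_ord`, `female`.
#' @export
outcome_table <- function(cohort, profile, ai_scope = NULL, til_scope = NULL) {
  clin <- cohort$clinical
  scope_vec <- function(spec) {
    if (is.null(spec)) return(NULL)
    switch(spec,
      cohort = NULL,
      gender = clin$gender,
      cancer_type = clin$cancer_type,
      gender_cancer_type = paste(clin$gender, clin$cancer_type, sep = ":"),
      abort(paste0("unknown scope: ", spec))
    )
  }
  prof <- profile[match(clin$sample_id, profile$sample_id), , drop = FALSE]
  prof <- add_strata(prof, ai_scope = scope_vec(ai_scope),
                     til_scope = scope_vec(til_scope))
  out <- dplyr::inner_join(
    clin,
    dplyr::select(prof, "sample_id", "A", "I", "ai_ratio", "til_score",
                  "ai_group", "til_group", "quadrant"),
    by = "sample_id"
  )
  out$stage_ord <- stage_to_ordinal(out$stage)
  out$female <- as.numeric(out$gender == "female")
  attr(out, "strata_medians") <- attr(prof, "strata_medians")
  out
}

.known_analyses <- c("cox_forest", "km", "meta", "lrt_gender", "response",
                     "quadrant", "diagonal", "rank_check")

#' Run the full A/I analysis pipeline
#'
#' Orchestrates cohort loading, immune scoring, the A/I scaling chain and
#' the selected downstream analyses, writing every output table as plain
#' TSV/JSON plus a manifest (input checksums, package version, resolved
#' config). Re-running on identical inputs and config reproduces identical
#' output tables; only the manifest carries a timestamp.
#'
#' @param config A YAML file path or a list with elements:
#'   \describe{
#'     \item{expr, clin, panel}{input paths (`panel` optional: packaged
#'       default), or in-memory objects (`ai_expr`, data frame, panel).}
#'     \item{transform}{`"linear_tpm"` or `"log2p1"` (required for path
#'       input; never guessed).}
#'     \item{out_dir}{output directory (created).}
#'     \item{scale_scope}{min-max scope: `"cohort"` (default) or
#'       `"cancer_type"`.}
#'     \item{split_scope}{median-split scope for the A/I ratio:
#'       `"cohort"`, `"gender"` (default), `"cancer_type"` or
#'       `"gender_cancer_type"`.}
#'     \item{endpoint}{`"os"` (default) or `"pfi"`.}
#'     \item{horizon_years}{optional KM truncation horizon.}
#'     \item{analyses}{subset of `cox_forest`, `km`, `meta`, `lrt_gender`,
#'       `response`, `quadrant`, `diagonal`, `rank_check` (default: all
#'       except `rank_check`, which needs `cellline_expr`).}
#'     \item{cellline_expr}{optional cell-line expression path/object for
#'       `rank_check`.}
#'     \item{coverage_threshold}{marker coverage threshold (default 0.5).}
#'   }
#' @return An `ai_report`: list with the computed section results and the
#'   paths written. Stage errors are propagated with the stage name
#'   prefixed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  analyses <- cfg$analyses %||% setdiff(.known_analyses, "rank_check")
  unknown <- setdiff(analyses, .known_analyses)
  if (length(unknown) > 0) {
    abort(paste0("unknown analysis toggle(s): ", paste(unknown, collapse = ", ")))
  }
  out_dir <- cfg$out_dir %||% abort("config needs out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  endpoint <- cfg$endpoint %||% "os"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  checksums <- list()
  expr <- stage("cohort_io", {
    if (inherits(cfg$expr, "ai_expr")) cfg$expr
    else {
      checksums$expr <- unname(tools::md5sum(cfg$expr))
      read_expression(cfg$expr, transform = cfg$transform %||%
                        abort("config needs `transform` for path input"))
    }
  })
  clinical <- stage("cohort_io", {
    if (is.data.frame(cfg$clin)) validate_clinical(cfg$clin)
    else {
      checksums$clin <- unname(tools::md5sum(cfg$clin))
      read_clinical(cfg$clin)
    }
  })
  panel <- stage("cohort_io", {
    if (is.null(cfg$panel)) default_panel()
    else if (is.data.frame(cfg$panel)) validate_panel(cfg$panel)
    else {
      checksums$panel <- unname(tools::md5sum(cfg$panel))
      read_panel(cfg$panel)
    }
  })
  cohort <- stage("cohort_io", join_cohort(
    expr, clinical, panel,
    coverage_threshold = cfg$coverage_threshold %||% 0.5))

  scores <- stage("immune_scoring", score_cell_types(cohort))
  scale_scope <- cfg$scale_scope %||% "cohort"
  profile <- stage("ai_ratio", immune_profile(
    scores, panel = panel,
    scope = if (scale_scope == "cancer_type") cohort$clinical$cancer_type else NULL))
  outcome <- stage("ai_ratio", outcome_table(
    cohort, profile,
    ai_scope = cfg$split_scope %||% "gender",
    til_scope = cfg$split_scope %||% "gender"))

  paths <- list()
  write_tbl <- function(tb, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tb, p, progress = FALSE)
    paths[[name]] <<- p
    p
  }
  write_json <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null")
    paths[[name]] <<- p
    p
  }
  write_tbl(scores, "cell_type_scores")
  write_tbl(dplyr::select(outcome, -dplyr::starts_with("scaled ")), "outcome_table")
  med <- attr(outcome, "strata_medians")
  write_json(list(ai = med$ai, til = med$til,
                  scale_scope = scale_scope,
                  split_scope = cfg$split_scope %||% "gender"),
             "stratum_medians")

  report <- list(outcome = outcome, sections = list(), paths = paths)

  if ("cox_forest" %in% analyses) {
    report$sections$cox_forest <- stage("outcome_stats", {
      dat <- dplyr::inner_join(outcome[, c("sample_id", "age", "stage_ord", "female",
                                           paste0(endpoint, "_time"),
                                           paste0(endpoint, "_event"))],
                               scores, by = "sample_id")
      types <- setdiff(names(scores), c("sample_id", "til_score"))
      covs <- c(types, "age", "stage_ord", "female")
      covs <- covs[vapply(covs, function(v) length(unique(stats::na.omit(dat[[v]]))) > 1,
                          logical(1))]
      fit <- fit_cox(dat, endpoint = endpoint, covariates = covs)
      write_tbl(tidy(fit), "cox_forest")
      fit
    })
  }
  if ("km" %in% analyses) {
    report$sections$km <- stage("outcome_stats", {
      km <- km_logrank(outcome, outcome$ai_group, endpoint = endpoint,
                       horizon_years = cfg$horizon_years)
      write_tbl(km$curves, "km_curves")
      km
    })
  }
  if ("meta" %in% analyses) {
    report$sections$meta <- stage("outcome_stats", {
      res <- meta_by_gender(outcome, endpoint = endpoint)
      write_tbl(res$per_stratum, "meta_strata")
      write_json(res$combined, "meta_summary")
      res
    })
  }
  if ("lrt_gender" %in% analyses) {
    report$sections$lrt_gender <- stage("outcome_stats", {
      base_covs <- c("female", "age", "stage_ord")
      base_covs <- base_covs[vapply(base_covs, function(v)
        length(unique(stats::na.omit(outcome[[v]]))) > 1, logical(1))]
      dat <- outcome[!is.na(outcome$ai_ratio), , drop = FALSE]
      small <- fit_cox(dat, endpoint = endpoint, covariates = base_covs)
      large <- fit_cox(dat, endpoint = endpoint,
                       covariates = c(base_covs, "ai_ratio"))
      res <- nested_lrt(small, large)
      write_tbl(res, "lrt_gender")
      res
    })
  }
  response_tb <- NULL
  if (any(c("response", "quadrant", "diagonal") %in% analyses)) {
    response_tb <- stage("cohort_io", filter_response_evaluable(outcome))
  }
  if ("response" %in% analyses) {
    report$sections$response <- stage("outcome_stats", {
      cr_pd <- response_tb[response_tb$response %in% c("CR", "PD"), ]
      resp_pd <- dplyr::mutate(response_tb,
                               grp = ifelse(.data$response == "PD", "PD", "CR+PR"))
      res <- dplyr::bind_rows(
        dplyr::mutate(group_wilcoxon(cr_pd$ai_ratio, cr_pd$response),
                      comparison = "ai_ratio CR vs PD"),
        dplyr::mutate(group_wilcoxon(resp_pd$ai_ratio, resp_pd$grp),
                      comparison = "ai_ratio responders vs PD"),
        dplyr::mutate(group_wilcoxon(cr_pd$til_score, cr_pd$response),
                      comparison = "til_score CR vs PD")
      )
      write_tbl(res, "response_tests")
      res
    })
  }
  if ("quadrant" %in% analyses) {
    report$sections$quadrant <- stage("outcome_stats", {
      res <- fisher_quadrant(response_tb$quadrant,
                             response_tb$response %in% c("CR", "PR"))
      write_tbl(res, "quadrant_fisher")
      res
    })
  }
  if ("diagonal" %in% analyses) {
    report$sections$diagonal <- stage("outcome_stats", {
      res <- below_diagonal_fraction(response_tb, group = response_tb$response)
      write_tbl(res, "diagonal_fractions")
      res
    })
  }
  if ("rank_check" %in% analyses) {
    report$sections$rank_check <- stage("rank_validation", {
      if (is.null(cfg$cellline_expr)) abort("rank_check needs `cellline_expr`")
      cl <- if (inherits(cfg$cellline_expr, "ai_expr")) cfg$cellline_expr
        else {
          checksums$cellline_expr <- unname(tools::md5sum(cfg$cellline_expr))
          read_expression(cfg$cellline_expr,
                          transform = cfg$transform %||% "linear_tpm")
        }
      res <- compare_tumour_vs_cellline(cohort$expr, cl, panel = panel)
      write_tbl(res, "rank_check")
      res
    })
  }

  resolved <- cfg
  for (nm in c("expr", "clin", "panel", "cellline_expr")) {
    if (!is.null(resolved[[nm]]) && !is.character(resolved[[nm]])) {
      resolved[[nm]] <- paste0("<in-memory ", class(resolved[[nm]])[1], ">")
    }
  }
  resolved$analyses <- analyses
  manifest <- list(
    package_version = as.character(utils::packageVersion("airatio")),
    created = format(Sys.time(), tz = "UTC"),
    input_checksums = checksums,
    config = resolved,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  write_json(manifest, "manifest")
  report$paths <- paths
  class(report) <- "ai_report"
  report
}

#' @export
print.ai_report <- function(x, ...) {
  cat("<ai_report> sections: ", paste(names(x$sections), collapse = ", "),
      "\n  outputs: ", length(x$paths), " file(s)\n", sep = "")
  invisible(x)
}

#' Per-gender meta-analysis of the median-split hazard ratio
#'
#' For each gender, fits a univariate Cox model of the endpoint on the
#' high-vs-low A/I median-split group within each cancer type, then
#' combines the per-cancer-type log hazard ratios by fixed-effect
#' inverse-variance meta-analysis. Cancer types whose fit fails (too few
#' events, constant group, non-convergence) are skipped with a warning.
#'
#' @param outcome Tibble from [outcome_table()] (needs `ai_group`,
#'   `gender`, `cancer_type` and the endpoint columns).
#' @param endpoint `"os"` or `"pfi"`.
#' @param min_events Minimum events per cancer-type stratum (default 5).
#' @return A list: `per_stratum` (tibble gender, cancer_type, log HR, SE,
#'   n, events) and `combined` (one row per gender with the meta HR, CI
#'   and p).
#' @export
meta_by_gender <- function(outcome, endpoint = c("os", "pfi"), min_events = 5) {
  endpoint <- match.arg(endpoint)
  per <- list()
  for (g in intersect(c("female", "male"), unique(outcome$gender))) {
    for (ct in sort(unique(outcome$cancer_type))) {
      dat <- outcome[outcome$gender == g & outcome$cancer_type == ct &
                       !is.na(outcome$ai_group), , drop = FALSE]
      if (nrow(dat) < 4 || sum(dat[[paste0(endpoint, "_event")]], na.rm = TRUE) < min_events) next
      dat$ai_high <- as.numeric(dat$ai_group == "high")
      fit <- tryCatch(fit_cox(dat, endpoint = endpoint, covariates = "ai_high"),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      row <- fit$result[fit$result$term == "ai_high", ]
      per[[length(per) + 1]] <- tibble::tibble(
        gender = g, cancer_type = ct, estimate = row$estimate, se = row$se,
        hr = row$hr, n = fit$n, events = fit$events)
    }
  }
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0) abort("no usable cancer-type strata for meta-analysis")
  combined <- per |>
    dplyr::group_by(.data$gender) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) {
        return(tibble::tibble(hr = NA_real_, conf_low = NA_real_,
                              conf_high = NA_real_, p_value = NA_real_,
                              k = nrow(d)))
      }
      m <- meta_fixed_effect(dplyr::mutate(d, stratum = d$cancer_type))
      glance(m)[, c("hr", "conf_low", "conf_high", "p_value", "k")]
    }) |>
    dplyr::ungroup()
  list(per_stratum = per, combined = combined)
}
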