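#' Per-sample immune cell-type scores
#'
#' For each panel cell type, the score of a sample is the unweighted mean
#' of log2(TPM + 1) expression over that cell type's marker genes present
#' in the matrix (linear-TPM input is converted first; genes absent from
#' the matrix are skipped — coverage is validated at cohort join). No
#' per-gene standardisation is applied: the score is a plain mean of log
#' expression.
#'
#' The total TIL score of a sample is the mean of all panel cell-type
#' scores, including any `excluded`-compartment cell types.
#'
#' @param cohort An `ai_cohort` from [join_cohort()].
#' @return A tibble with columns `sample_id`, one column per cell type
#'   (log2 scale), and `til_score`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_samples = 20, seed = 1))
#' cohort <- join_cohort(sim$expr, sim$clinical)
#' score_cell_types(cohort)
score_cell_types <- function(cohort) {
  stopifnot(inherits(cohort, "ai_cohort"))
  values <- cohort$expr$values
  if (cohort$expr$transform == "linear_tpm") values <- log2(values + 1)

  markers <- cohort$panel |>
    dplyr::filter(.data$gene %in% rownames(values))
  by_type <- split(markers$gene, markers$cell_type)
  if (any(lengths(by_type) == 0)) {
    abort(paste0("no markers present for cell type(s): ",
                 paste(names(by_type)[lengths(by_type) == 0], collapse = ", ")))
  }
  scores <- vapply(by_type, function(g) {
    colMeans(values[g, , drop = FALSE])
  }, numeric(ncol(values)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1, dimnames = list(colnames(values), names(by_type)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(values)),
                          tibble::as_tibble(scores))
  out$til_score <- til_score(out)
  out
}

#' Total TIL score
#'
#' The per-sample mean over all cell-type score columns. Exposed separately
#' so a score table assembled by other means can be summarised the same
#' way.
#'
#' @param scores A tibble as returned by [score_cell_types()] (a
#'   `til_score` column, if present, is ignored).
#' @return Numeric vector, one value per row of `scores`.
#' @export
til_score <- function(scores) {
  cols <- setdiff(names(scores), c("sample_id", "til_score"))
  rowMeans(as.matrix(scores[, cols, drop = FALSE]))
}

# internal: score tibble -> samples x cell-types matrix
scores_matrix <- function(scores) {
  cols <- setdiff(names(scores), c("sample_id", "til_score"))
  m <- as.matrix(scores[, cols, drop = FALSE])
  rownames(m) <- scores$sample_id
  m
}
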