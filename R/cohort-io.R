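#' Construct an expression matrix object
#'
#' Wraps a non-negative genes-by-samples numeric matrix together with its
#' declared transform state. The transform is never guessed from the data:
#' the caller must state whether values are linear TPM (`"linear_tpm"`) or
#' log2(TPM + 1) (`"log2p1"`), because the reverse-log step of the A/I
#' scaling is only meaningful relative to that declaration.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param transform `"linear_tpm"` or `"log2p1"`.
#' @return An `ai_expr` object.
#' @export
expression_matrix <- function(values, transform = c("linear_tpm", "log2p1")) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  storage.mode(values) <- "double"
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(paste0("negative expression value for gene '",
                 rownames(values)[neg[1, 1]], "' in sample '",
                 colnames(values)[neg[1, 2]], "'"))
  }
  if (anyDuplicated(colnames(values))) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(colnames(values)[duplicated(colnames(values))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    warn(paste0("collapsing ", length(dup),
                " duplicated gene symbol(s) by mean: ",
                paste(head(dup, 5), collapse = ", "),
                if (length(dup) > 5) ", ..." else ""))
    values <- rowsum(values, group = rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }
  structure(list(values = values, transform = transform), class = "ai_expr")
}

#' @export
print.ai_expr <- function(x, ...) {
  cat("<ai_expr> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, transform = ", x$transform, "\n", sep = "")
  invisible(x)
}

#' @export
dim.ai_expr <- function(x) dim(x$values)

#' @export
as.matrix.ai_expr <- function(x, ...) x$values

#' Convert an expression object to a tibble
#'
#' @param x An `ai_expr` object.
#' @param ... Unused.
#' @return A tibble with a `gene` column followed by one column per sample.
#' @export
as_tibble.ai_expr <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(gene = rownames(x$values)),
                   tibble::as_tibble(x$values))
}

#' Read a gene-by-sample expression matrix
#'
#' Accepts either a tab-separated file (genes in rows, first column gene
#' symbols, header row of sample ids) or a MatrixMarket triplet file
#' (`.mtx`), in which case `rows` and `cols` name one-symbol-per-line text
#' files holding gene and sample names. All inputs may be
#' gzip-compressed. Duplicate gene symbols are collapsed by arithmetic mean
#' on the stored scale with a warning; duplicate sample ids and negative
#' values are hard errors.
#'
#' @param path Expression file.
#' @param transform Declared scale of the stored values: `"linear_tpm"` or
#'   `"log2p1"`. There is deliberately no auto-detection.
#' @param rows,cols For MatrixMarket input, paths to the row (gene) and
#'   column (sample) name files.
#' @return An `ai_expr` object.
#' @export
read_expression <- function(path, transform = c("linear_tpm", "log2p1"),
                            rows = NULL, cols = NULL) {
  transform <- match.arg(transform)
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    if (is.null(rows) || is.null(cols)) {
      abort("MatrixMarket input needs `rows` and `cols` name files")
    }
    m <- as.matrix(Matrix::readMM(path))
    rn <- trimws(readr::read_lines(rows, progress = FALSE))
    cn <- trimws(readr::read_lines(cols, progress = FALSE))
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      abort("row/column name files do not match matrix dimensions")
    }
    rownames(m) <- rn
    colnames(m) <- cn
    return(expression_matrix(m, transform))
  }
  # base parser: strtod is correctly rounded, so writing with shortest
  # round-trip digits and re-reading reproduces values bit-identically
  tb <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tb) < 2) abort("expression TSV needs a gene column plus >= 1 sample")
  genes <- trimws(as.character(tb[[1]]))
  vals <- as.matrix(tb[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort("non-numeric expression values (ragged or malformed rows?)")
  rownames(vals) <- genes
  colnames(vals) <- trimws(colnames(tb)[-1])
  expression_matrix(vals, transform)
}

#' Write an expression matrix as TSV
#'
#' Full-precision output: reading the file back reproduces the values
#' bit-identically.
#'
#' @param x An `ai_expr` object.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "ai_expr"))
  readr::write_tsv(as_tibble.ai_expr(x), path, progress = FALSE)
  invisible(path)
}

.gender_levels <- c("male", "female", "unknown")
.response_levels <- c("CR", "PR", "SD", "PD", "none")
.phenotype_levels <- c("inflamed", "excluded", "desert", "none")

# "IIIb" -> "III"; anything not matching a major stage -> "unknown"
collapse_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  s <- sub("^(IV|III|II|I).*$", "\\1", s)
  ifelse(s %in% c("I", "II", "III", "IV"), s, "unknown")
}

#' Ordinal encoding of tumour stage
#'
#' Major stages I-IV map to 1-4 for use as a numeric covariate in
#' regression; `"unknown"` maps to `NA`.
#'
#' @param stage Character vector of stage labels.
#' @return Integer vector.
#' @export
stage_to_ordinal <- function(stage) {
  unname(c(I = 1L, II = 2L, III = 3L, IV = 4L)[collapse_stage(stage)])
}

#' Read and validate a per-sample clinical table
#'
#' Tab-separated with required columns `sample_id`, `gender`,
#' `cancer_type`; optional columns `age`, `stage`, `os_time`, `os_event`,
#' `pfi_time`, `pfi_event`, `response` (CR/PR/SD/PD), `phenotype`
#' (inflamed/excluded/desert). Missing optional fields are filled with
#' their `"unknown"` / `"none"` sentinel; stage substages (e.g. "IIIb")
#' collapse to the major stage.
#'
#' @param path Path to the TSV (gzip accepted).
#' @return A validated clinical tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("clinical file not found: ", path))
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  validate_clinical(tb)
}

#' Validate a clinical table built in code
#'
#' Applies the same checks and sentinel fills as [read_clinical()].
#'
#' @param tb A data frame of per-sample clinical records.
#' @return A validated clinical tibble.
#' @export
validate_clinical <- function(tb) {
  tb <- tibble::as_tibble(tb)
  required <- c("sample_id", "gender", "cancer_type")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    abort(paste0("clinical table missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tb$sample_id <- trimws(as.character(tb$sample_id))
  if (anyDuplicated(tb$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(tb$sample_id[duplicated(tb$sample_id)]), collapse = ", ")))
  }
  tb$gender <- tolower(trimws(as.character(tb$gender)))
  tb$gender[!tb$gender %in% .gender_levels | is.na(tb$gender)] <- "unknown"
  tb$cancer_type <- trimws(as.character(tb$cancer_type))
  if (!"age" %in% names(tb)) tb$age <- NA_real_
  tb$age <- as.numeric(tb$age)
  tb$stage <- if ("stage" %in% names(tb)) collapse_stage(tb$stage) else "unknown"
  for (col in c("os_time", "pfi_time")) {
    if (!col %in% names(tb)) tb[[col]] <- NA_real_
    tb[[col]] <- as.numeric(tb[[col]])
    if (any(tb[[col]] < 0, na.rm = TRUE)) {
      abort(paste0("negative ", col, " for sample '",
                   tb$sample_id[which(tb[[col]] < 0)[1]], "'"))
    }
  }
  for (col in c("os_event", "pfi_event")) {
    if (!col %in% names(tb)) tb[[col]] <- NA_real_
    tb[[col]] <- as.numeric(tb[[col]])
    if (any(!tb[[col]] %in% c(0, 1) & !is.na(tb[[col]]))) {
      abort(paste0(col, " must be 0 or 1 (sample '",
                   tb$sample_id[which(!tb[[col]] %in% c(0, 1) & !is.na(tb[[col]]))[1]], "')"))
    }
  }
  tb$response <- if ("response" %in% names(tb)) {
    r <- toupper(trimws(as.character(tb$response)))
    ifelse(r %in% c("CR", "PR", "SD", "PD"), r, "none")
  } else "none"
  tb$phenotype <- if ("phenotype" %in% names(tb)) {
    p <- tolower(trimws(as.character(tb$phenotype)))
    ifelse(p %in% c("inflamed", "excluded", "desert"), p, "none")
  } else "none"
  tb
}

#' Restrict to response-evaluable patients
#'
#' Keeps only patients with a complete response (CR), partial response
#' (PR), or progressive disease (PD). Stable disease is excluded because it
#' is not interpretable as clearly good or poor outcome; records with no
#' response annotation are likewise dropped. Idempotent.
#'
#' @param clinical A clinical tibble.
#' @return The filtered tibble; counts of removed rows are messaged.
#' @export
filter_response_evaluable <- function(clinical) {
  keep <- clinical$response %in% c("CR", "PR", "PD")
  removed <- table(factor(clinical$response[!keep], levels = c("SD", "none")))
  if (any(!keep)) {
    inform(paste0("filter_response_evaluable: removed ", sum(!keep),
                  " sample(s) (SD: ", removed[["SD"]],
                  ", no response: ", removed[["none"]], ")"))
  }
  out <- clinical[keep, , drop = FALSE]
  if (nrow(out) == 0) warn("no response-evaluable samples remain")
  out
}

#' Join expression, clinical table and marker panel into a cohort
#'
#' Restricts to the intersection of expression and clinical sample ids
#' (order-stable: sorted by sample id), computes per-cell-type marker
#' coverage (fraction of a cell type's panel genes present in the
#' matrix), and refuses to proceed when any cell type falls below the
#' coverage threshold — a score over a near-empty marker set is
#' meaningless. Sample-id matching is exact string match after whitespace
#' strip; no cohort-specific barcode truncation is applied.
#'
#' @param expr An `ai_expr` object.
#' @param clinical A clinical tibble (see [read_clinical()]).
#' @param panel A marker panel (default [default_panel()]).
#' @param coverage_threshold Minimum per-cell-type marker coverage
#'   (default 0.5). Coverage below it is an error; between it and 1 a
#'   warning.
#' @return An `ai_cohort` object: the restricted expression matrix, the
#'   matching clinical rows, the panel, and a `coverage` tibble
#'   (cell_type, n_markers, n_present, coverage, missing_genes).
#' @export
join_cohort <- function(expr, clinical, panel = default_panel(),
                        coverage_threshold = 0.5) {
  stopifnot(inherits(expr, "ai_expr"))
  panel <- validate_panel(panel)
  clinical <- validate_clinical(clinical)
  shared <- sort(intersect(colnames(expr$values), clinical$sample_id))
  if (length(shared) == 0) abort("no sample ids shared between expression and clinical data")
  values <- expr$values[, shared, drop = FALSE]
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]

  coverage <- panel |>
    dplyr::group_by(.data$cell_type, .data$compartment) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_present = sum(.data$gene %in% rownames(values)),
      missing_genes = paste(setdiff(.data$gene, rownames(values)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(coverage = .data$n_present / .data$n_markers)

  low <- coverage |> dplyr::filter(.data$coverage < coverage_threshold)
  if (nrow(low) > 0) {
    abort(paste0("marker coverage below ", coverage_threshold, " for cell type(s): ",
                 paste0(low$cell_type, " (", low$n_present, "/", low$n_markers, ")",
                        collapse = ", ")))
  }
  partial <- coverage |> dplyr::filter(.data$coverage < 1)
  if (nrow(partial) > 0) {
    warn(paste0("incomplete marker coverage for: ",
                paste0(partial$cell_type, " (", partial$n_present, "/",
                       partial$n_markers, ")", collapse = ", ")))
  }
  structure(
    list(expr = expression_matrix(values, expr$transform),
         clinical = clinical, panel = panel, coverage = coverage),
    class = "ai_cohort"
  )
}

#' @export
print.ai_cohort <- function(x, ...) {
  cat("<ai_cohort> ", ncol(x$expr$values), " samples, ",
      nrow(x$expr$values), " genes, ",
      length(unique(x$panel$cell_type)), " panel cell types (",
      x$expr$transform, ")\n", sep = "")
  invisible(x)
}
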