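# Small in-code fixtures shared across test files.

# Minimal two-compartment panel: 2 adaptive + 2 innate cell types (one
# marker each unless genes are supplied) plus an optional excluded type.
tiny_panel <- function(excluded = FALSE) {
  tb <- tibble::tibble(
    cell_type = c("Ta", "Tb", "Na", "Nb"),
    gene = c("GA1", "GB1", "GN1", "GM1"),
    compartment = c("adaptive", "adaptive", "innate", "innate")
  )
  if (excluded) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(
      cell_type = "Ex", gene = "GX1", compartment = "excluded"))
  }
  tb
}

# Expression object from a named matrix-like spec: rows genes, cols samples.
tiny_expr <- function(values, transform = "log2p1") {
  expression_matrix(values, transform)
}

# Write an expression TSV and return its path.
write_expr_tsv <- function(values, path = tempfile(fileext = ".tsv")) {
  tb <- dplyr::bind_cols(tibble::tibble(gene = rownames(values)),
                         tibble::as_tibble(values))
  readr::write_tsv(tb, path, progress = FALSE)
  path
}

# Minimal clinical tibble for n samples.
tiny_clinical <- function(ids, gender = "female", cancer_type = "SYN1", ...) {
  tibble::tibble(sample_id = ids, gender = gender, cancer_type = cancer_type, ...)
}

# Score-matrix cohort used by the Eq-1 oracle checks: random 13-cell-type
# scores on the log2 scale.
random_score_matrix <- function(n_samples, panel, seed) {
  set.seed(seed)
  types <- unique(panel$cell_type)
  m <- matrix(runif(n_samples * length(types), 0, 8),
              nrow = n_samples,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)), types))
  m
}

# Scores matrix -> tibble accepted by immune_profile().
scores_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), tibble::as_tibble(m))
}

# The ratio cell types of the packaged panel (adaptive + innate only).
ratio_panel <- function() {
  dplyr::filter(default_panel(), compartment != "excluded")
}
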