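#' Within-sample expression ranks
#'
#' Ranks every gene within each sample by expression: the lowest expression
#' gets rank 1, the second lowest rank 2, and so on; tied values share the
#' average of the ranks they span. Because ranks depend only on order, the
#' result is identical for expression on the linear or any strictly
#' increasing transform of it.
#'
#' @param expr An `ai_expr` object with >= 2 genes.
#' @return A genes-by-samples matrix of (possibly fractional) ranks. Per
#'   sample the ranks sum to G(G+1)/2 for G genes.
#' @export
rank_genes <- function(expr) {
  stopifnot(inherits(expr, "ai_expr"))
  if (nrow(expr$values) < 2) abort("rank_genes needs >= 2 genes")
  apply(expr$values, 2, rank, ties.method = "average")
}

#' Per-group mean rank (and percentile) of immune marker genes
#'
#' Extracts the panel's marker genes from a rank matrix and averages each
#' gene's rank over the samples of each group (typically cancer type or
#' tissue). Ranks are also reported as percentiles (rank / number of
#' genes) so matrices with different gene counts are comparable.
#'
#' @param ranks Genes-by-samples rank matrix from [rank_genes()].
#' @param panel Marker panel (default [default_panel()]).
#' @param groups Optional per-sample grouping vector; `NULL` treats the
#'   whole matrix as one group.
#' @return A tibble: `group`, `cell_type`, `gene`, `mean_rank`,
#'   `mean_percentile`.
#' @export
mean_immune_rank <- function(ranks, panel = default_panel(), groups = NULL) {
  panel <- validate_panel(panel)
  if (is.null(groups)) groups <- rep("all", ncol(ranks))
  if (length(groups) != ncol(ranks)) abort("groups length must equal the number of samples")
  if (any(table(groups) == 0)) abort("empty group")
  genes <- intersect(panel$gene, rownames(ranks))
  if (length(genes) == 0) abort("no panel genes present in the rank matrix")
  G <- nrow(ranks)
  purrr::map_dfr(unique(groups), function(g) {
    idx <- which(groups == g)
    mr <- rowMeans(ranks[genes, idx, drop = FALSE])
    tibble::tibble(
      group = g,
      cell_type = panel$cell_type[match(genes, panel$gene)],
      gene = genes,
      mean_rank = unname(mr),
      mean_percentile = unname(mr) / G
    )
  })
}

# internal: per-sample mean percentile rank of marker genes
sample_marker_percentile <- function(expr, panel) {
  ranks <- rank_genes(expr)
  genes <- intersect(panel$gene, rownames(ranks))
  if (length(genes) == 0) abort("no panel genes present in the expression matrix")
  colMeans(ranks[genes, , drop = FALSE]) / nrow(ranks)
}

#' Tumour vs cell-line immune-rank comparison
#'
#' Tests whether immune marker genes rank higher in tumour samples (which
#' contain infiltrating immune cells) than in cancer cell lines (which do
#' not): a one-sided Wilcoxon rank-sum test, tumour greater, on the
#' per-sample mean marker percentile rank. A clearly higher tumour rank
#' supports that the immune signal originates from infiltrate rather than
#' from the cancer cells themselves.
#'
#' @param tumour_expr,cellline_expr `ai_expr` objects for the two arms
#'   (matched tissue is the caller's responsibility).
#' @param panel Marker panel (default [default_panel()]).
#' @return A one-row tibble: group sizes, mean percentile per arm, the
#'   difference of means (`effect`), the rank-sum statistic and one-sided
#'   p-value. With a single sample per arm the test is degenerate and a
#'   warning is emitted.
#' @export
compare_tumour_vs_cellline <- function(tumour_expr, cellline_expr,
                                       panel = default_panel()) {
  panel <- validate_panel(panel)
  pt <- sample_marker_percentile(tumour_expr, panel)
  pc <- sample_marker_percentile(cellline_expr, panel)
  if (length(pt) == 0 || length(pc) == 0) abort("both arms need >= 1 sample")
  if (length(pt) < 2 && length(pc) < 2) {
    warn("single sample per arm: rank-sum test is degenerate")
  }
  ht <- wilcox.test(pt, pc, alternative = "greater", exact = FALSE, correct = TRUE)
  tibble::tibble(
    n_tumour = length(pt),
    n_cellline = length(pc),
    mean_percentile_tumour = mean(pt),
    mean_percentile_cellline = mean(pc),
    effect = mean(pt) - mean(pc),
    statistic = unname(ht$statistic),
    p_value = ht$p.value
  )
}
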