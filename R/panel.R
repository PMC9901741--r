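#' Immune cell-type marker panels
#'
#' A marker panel maps immune cell types to marker genes and assigns each
#' cell type to an immune compartment: `adaptive`, `innate`, or `excluded`
#' (scored and included in the TIL mean but left out of the A/I ratio).
#'
#' @details
#' The packaged default ([default_panel()]) uses the Danaher et al. (2017)
#' marker-gene cell-type definitions across 14 cell types. The seven
#' adaptive cell types are CD8 T cells, B cells, CD45, cytotoxic cells,
#' T cells, Th1 cells and regulatory T cells; the six innate cell types are
#' dendritic cells, macrophages, mast cells, neutrophils, NK cells and
#' NK CD56dim cells. Exhausted CD8 cells carry compartment `excluded`: they
#' contribute to the total TIL score but not to either side of the ratio.
#'
#' @name marker-panel
NULL

.compartments <- c("adaptive", "innate", "excluded")

#' Validate a marker panel
#'
#' @param panel A data frame with columns `cell_type`, `gene`, `compartment`.
#' @return The panel as a tibble, invisibly checked: every cell type has at
#'   least one marker, compartments are one of adaptive/innate/excluded and
#'   constant within a cell type.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  required <- c("cell_type", "gene", "compartment")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  panel <- dplyr::mutate(panel, dplyr::across(dplyr::all_of(required), as.character))
  bad <- setdiff(unique(panel$compartment), .compartments)
  if (length(bad) > 0) {
    abort(paste0("unknown compartment(s): ", paste(bad, collapse = ", "),
                 " (expected adaptive, innate or excluded)"))
  }
  mixed <- panel |>
    dplyr::distinct(.data$cell_type, .data$compartment) |>
    dplyr::count(.data$cell_type) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    abort(paste0("compartment must be constant within a cell type; violated by: ",
                 paste(mixed$cell_type, collapse = ", ")))
  }
  if (any(is.na(panel$gene)) || any(panel$gene == "")) {
    abort("panel contains empty gene symbols")
  }
  panel
}

#' Read a marker panel from a three-column TSV
#'
#' Columns: `cell_type`, `gene`, `compartment` (adaptive / innate /
#' excluded). Gzip-compressed files are accepted.
#'
#' @param path Path to the TSV file.
#' @return A validated panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  panel <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  validate_panel(panel)
}

#' The packaged default immune marker panel
#'
#' Danaher-style cell-type marker definitions (14 cell types) with the
#' adaptive / innate compartment assignment used for the A/I ratio; see
#' [marker-panel] for the compartment membership.
#'
#' @return A panel tibble with columns `cell_type`, `gene`, `compartment`.
#' @export
#' @examples
#' default_panel() |> dplyr::count(cell_type, compartment)
default_panel <- function() {
  path <- system.file("extdata", "immune_marker_panel.tsv", package = "airatio",
                      mustWork = TRUE)
  read_panel(path)
}

#' Cell types of a compartment
#'
#' @param panel A marker panel tibble.
#' @param compartment One of `"adaptive"`, `"innate"`, `"excluded"`.
#' @return Character vector of cell-type names.
#' @export
compartment_cell_types <- function(panel, compartment) {
  compartment <- match.arg(compartment, .compartments)
  unique(panel$cell_type[panel$compartment == compartment])
}
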