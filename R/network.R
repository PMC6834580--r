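# Interaction-network export: edges between DE miRNAs and their DE predicted
# targets, annotated with both directions, for rendering in external tools.

#' Export a miRNA-target interaction edge list
#'
#' One edge per (differentially expressed miRNA, differentially expressed
#' predicted target gene). Each edge carries both direction labels and an
#' `opposite` flag, true when the gene moved in the opposite direction to its
#' targeting miRNA - the signature expected of genuine repression targets.
#'
#' @param targets Site-level tibble from [predict_targets()].
#' @param de_mirnas Tibble `mirna`, `direction` of DE miRNAs.
#' @param de_genes Tibble `gene_id`, `direction` of DE genes.
#' @param genes Optional character vector of known gene ids (the UTR
#'   universe); DE genes outside it raise an error.
#' @return A tibble `mirna`, `gene_id`, `mirna_direction`, `gene_direction`,
#'   `opposite`.
#' @export
export_network <- function(targets, de_mirnas, de_genes, genes = NULL) {
  stopifnot(all(c("mirna", "direction") %in% names(de_mirnas)),
            all(c("gene_id", "direction") %in% names(de_genes)))
  if (!is.null(genes) && !all(de_genes$gene_id %in% genes)) {
    abort("`de_genes` contains gene ids absent from the gene universe.")
  }
  if (nrow(de_mirnas) == 0) {
    return(tibble(mirna = character(0), gene_id = character(0),
                  mirna_direction = character(0),
                  gene_direction = character(0), opposite = logical(0)))
  }
  target_pairs(targets) |>
    inner_join(rename_dir(de_mirnas, "mirna_direction"), by = "mirna") |>
    inner_join(rename_dir(de_genes, "gene_direction"), by = "gene_id") |>
    mutate(opposite = .data$mirna_direction != .data$gene_direction) |>
    select("mirna", "gene_id", "mirna_direction", "gene_direction",
           "opposite") |>
    arrange(.data$mirna, .data$gene_id)
}

rename_dir <- function(d, new) {
  names(d)[names(d) == "direction"] <- new
  d
}

#' Write an edge list in SIF format
#'
#' Simple interaction format: `mirna interacts gene`, one edge per line.
#'
#' @param edges Edge tibble from [export_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  lines <- sprintf("%s\tinteracts\t%s", edges$mirna, edges$gene_id)
  writeLines(lines, path)
  invisible(path)
}
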