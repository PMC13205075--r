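triads_to_graph_tables <- function(triads) {
  if (!nrow(triads)) {
    return(list(
      nodes = tibble(id = character(), rna_class = character(),
                     status = character()),
      edges = tibble(source = character(), target = character(),
                     edge_type = character(), source_status = character(),
                     target_status = character())))
  }
  nodes <- bind_rows(
    tibble(id = triads$mrna_id, rna_class = "mRNA",
           status = triads$mrna_status),
    tibble(id = triads$mirna_id, rna_class = "miRNA",
           status = triads$mirna_status),
    tibble(id = triads$sponge_id, rna_class = triads$sponge_class,
           status = triads$sponge_status)) |>
    distinct() |>
    arrange(.data$id)
  edges <- bind_rows(
    tibble(source = triads$mirna_id, target = triads$mrna_id,
           edge_type = "mirna_represses_mrna",
           source_status = triads$mirna_status,
           target_status = triads$mrna_status),
    tibble(source = triads$sponge_id, target = triads$mirna_id,
           edge_type = "sponge_binds_mirna",
           source_status = triads$sponge_status,
           target_status = triads$mirna_status)) |>
    distinct() |>
    arrange(.data$edge_type, .data$source, .data$target)
  list(nodes = nodes, edges = edges)
}

#' Export a ceRNA network
#'
#' Writes the network induced by a triad table either as an edge-list TSV
#' (columns `source`, `target`, `edge_type`, `source_status`,
#' `target_status`) or as GraphML with `rna_class` and `status` node
#' attributes. Edges and nodes are de-duplicated across triads.
#'
#' @param triads Tibble from [assemble_triads()].
#' @param path Output file path.
#' @param format `"edge-tsv"` or `"graphml"`.
#' @param extra_edges Optional tibble of annotated edges outside the triad
#'   rules (columns `source`, `target`, `edge_type`, `source_status`,
#'   `target_status`), e.g. a direct lncRNA-mRNA regulation whose mechanism
#'   is uncertain; appended to the edge list, with missing nodes added
#'   with class/status `"unknown"`.
#' @return A list with the `nodes` and `edges` tibbles, invisibly.
#' @export
write_network <- function(triads, path, format = c("edge-tsv", "graphml"),
                          extra_edges = NULL) {
  if (is.character(format) && length(format) == 1 &&
      !format %in% c("edge-tsv", "graphml")) {
    stop_input(paste0("unknown network format: ", format))
  }
  format <- match.arg(format)
  gt <- triads_to_graph_tables(triads)
  if (!is.null(extra_edges) && nrow(extra_edges)) {
    gt$edges <- bind_rows(gt$edges, extra_edges) |> distinct()
    new_ids <- setdiff(c(extra_edges$source, extra_edges$target),
                       gt$nodes$id)
    if (length(new_ids)) {
      gt$nodes <- bind_rows(gt$nodes,
                            tibble(id = new_ids, rna_class = "unknown",
                                   status = "unknown")) |>
        arrange(.data$id)
    }
  }
  if (format == "edge-tsv") {
    readr::write_tsv(gt$edges, path)
  } else {
    g <- igraph::graph_from_data_frame(
      gt$edges |> select("source", "target", "edge_type",
                         "source_status", "target_status"),
      directed = TRUE,
      vertices = gt$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(gt)
}
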