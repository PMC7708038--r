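# Drug-target bipartite networks for enriched functional categories.

#' Build a drug-target bipartite network
#'
#' Connects a drug set with the members of an enriched functional category
#' via the drug-target annotation table. The target partition keeps the
#' category members targeted by at least one of the drugs; edges are all
#' annotated (drug, target) pairs restricted to both sets; drugs without an
#' edge are dropped. Each vertex carries a `type` attribute (`"drug"` or
#' `"target"`) and its `degree` (for targets: the number of connecting
#' drugs, the quantity the network visualizations color by).
#'
#' @param drugs Character vector of drugs (e.g. top hits of a search).
#' @param category_members Character vector of gene identifiers of the
#'   enriched category.
#' @param annotations A `DrugTargetTable`.
#' @return An `igraph` graph (possibly empty, with a warning, when no
#'   annotation pair links the two sets).
#' @examples
#' ann <- drug_target_table(list(A = c("T1", "T2"), B = "T1"))
#' g <- build_dtn(c("A", "B"), "T1", ann)
#' igraph::V(g)$degree
#' @export
build_dtn <- function(drugs, category_members, annotations) {
  if (length(drugs) == 0L || length(category_members) == 0L)
    vstop("drugs and category_members must be non-empty")
  if (!inherits(annotations, "DrugTargetTable"))
    annotations <- drug_target_table(annotations)
  drugs <- unique(as.character(drugs))
  category_members <- unique(as.character(category_members))
  annotated <- intersect(drugs, names(annotations))
  edges <- do.call(rbind, lapply(annotated, function(d) {
    tg <- intersect(annotations[[d]], category_members)
    if (length(tg) == 0L) return(NULL)
    data.frame(from = d, to = tg, stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    warning("no drug-target edge connects the drug set with the category",
            call. = FALSE)
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  verts <- data.frame(
    name = c(unique(edges$from), unique(edges$to)),
    type = c(rep("drug", length(unique(edges$from))),
             rep("target", length(unique(edges$to)))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Export / import a drug-target network
#'
#' Writes the graph with its `type` and `degree` vertex attributes to
#' GraphML or a JSON node-link file; `import_dtn()` reads either format
#' back into an identical graph.
#'
#' @param graph An `igraph` graph from [build_dtn()].
#' @param path Output file path.
#' @param format `"graphml"` or `"json"`.
#' @return `export_dtn()`: `path`, invisibly.
#' @export
export_dtn <- function(graph, path, format = c("graphml", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) vstop("unknown export format"))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    nodes <- if (igraph::vcount(graph) > 0) {
      data.frame(name = igraph::V(graph)$name,
                 type = igraph::V(graph)$type,
                 degree = igraph::V(graph)$degree,
                 stringsAsFactors = FALSE)
    } else data.frame(name = character(0), type = character(0),
                      degree = integer(0))
    edges <- if (igraph::ecount(graph) > 0) {
      el <- igraph::as_edgelist(graph)
      data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
    } else data.frame(from = character(0), to = character(0))
    jsonlite::write_json(list(nodes = nodes, links = edges), path,
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname export_dtn
#' @export
import_dtn <- function(path, format = c("graphml", "json")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) vstop("unknown export format"))
  if (!file.exists(path)) vstop("graph file not found: %s", path)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(x$nodes) == 0L || nrow(as.data.frame(x$nodes)) == 0L)
      return(igraph::make_empty_graph(directed = FALSE))
    g <- igraph::graph_from_data_frame(as.data.frame(x$links),
                                       directed = FALSE,
                                       vertices = as.data.frame(x$nodes))
    g
  }
}

#' Plot a drug-target network
#'
#' Static rendering with a bipartite-ish layout: drugs as squares, targets
#' as circles shaded by their connection count.
#'
#' @param graph An `igraph` graph from [build_dtn()].
#' @param ... Passed to `plot.igraph`.
#' @return Invisibly, the graph.
#' @export
plot_dtn <- function(graph, ...) {
  if (igraph::vcount(graph) == 0L) {
    warning("empty graph; nothing to plot", call. = FALSE)
    return(invisible(graph))
  }
  is_drug <- igraph::V(graph)$type == "drug"
  deg <- igraph::V(graph)$degree
  pal <- grDevices::colorRampPalette(c("#d0e7ff", "#08519c"))(max(deg))
  col <- ifelse(is_drug, "#ffd92f", pal[pmax(deg, 1)])
  igraph::plot.igraph(graph,
                      vertex.shape = ifelse(is_drug, "square", "circle"),
                      vertex.color = col, vertex.label.cex = 0.7, ...)
  invisible(graph)
}
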