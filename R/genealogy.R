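#' Ancestor-descendant graph of channel models
#'
#' Channel models are frequently reused and modified between publications;
#' linking each model to the models it was derived from yields a directed
#' genealogy. Nodes carry free-text metadata (subtype, neuron type, brain
#' area, animal); matching for crosstabs is exact-string after lowercasing
#' and trimming.
#'
#' @param nodes data frame with a character `id` column and optional
#'   metadata columns (`subtype`, `neuron_type`, `brain_area`, `animal`).
#' @param edges data frame with `ancestor` and `descendant` columns
#'   referencing node ids; self-loops are rejected.
#' @return An object of class `genealogy_graph`.
#' @export
genealogy_graph <- function(nodes, edges = NULL) {
  if (!is.data.frame(nodes) || !"id" %in% names(nodes)) {
    stop_invalid("nodes must be a data frame with an 'id' column")
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop_invalid("duplicate node ids")
  if (is.null(edges)) {
    edges <- data.frame(ancestor = character(0), descendant = character(0))
  }
  edges$ancestor <- as.character(edges$ancestor)
  edges$descendant <- as.character(edges$descendant)
  unknown <- setdiff(c(edges$ancestor, edges$descendant), nodes$id)
  if (length(unknown) > 0L) {
    stop_invalid("edges reference unknown node(s): %s",
                 paste(unknown, collapse = ", "))
  }
  if (any(edges$ancestor == edges$descendant)) {
    stop_invalid("self-loops are not allowed")
  }
  structure(list(nodes = nodes, edges = edges), class = "genealogy_graph")
}

#' Families: connected components of the genealogy
#'
#' Groups of models connected by ancestor-descendant relations (in either
#' direction) form a family. Family ids are assigned by decreasing family
#' size, ties broken by the lexicographically smallest member id.
#'
#' @param graph a [genealogy_graph()].
#' @return Named integer vector (channel id -> family id, `1..F`).
#' @export
channel_families <- function(graph) {
  stopifnot(inherits(graph, "genealogy_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes$id)
  comp <- igraph::components(g)
  membership <- comp$membership[graph$nodes$id]
  smallest <- vapply(seq_len(comp$no), function(i) {
    min(graph$nodes$id[membership == i])
  }, character(1))
  ord <- order(-comp$csize, smallest)
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  out <- remap[membership]
  names(out) <- graph$nodes$id
  out
}

#' Contingency table of two partitions
#'
#' Cross-tabulates two labelings of the same set of channels (e.g. cluster
#' vs family, or cluster vs subtype). Marginals equal the partition sizes.
#'
#' @param labels_a,labels_b label vectors named by channel id, covering the
#'   same ids.
#' @return A contingency table (`table`) of counts.
#' @export
crosstab_partitions <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)) ||
      !setequal(names(labels_a), names(labels_b))) {
    stop_invalid("partitions must be named and cover the same channel ids")
  }
  ids <- names(labels_a)
  norm <- function(x) trimws(tolower(as.character(x)))
  table(a = norm(labels_a[ids]), b = norm(labels_b[ids]))
}

#' @export
print.genealogy_graph <- function(x, ...) {
  cat(sprintf("<genealogy_graph: %d models, %d ancestor-descendant edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
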