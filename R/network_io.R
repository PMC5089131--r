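# GML keys must be alphanumeric; attribute names are lowercased and
# stripped of everything else on export.
gml_key <- function(x) {
  k <- gsub("[^A-Za-z0-9]", "", tolower(x))
  ifelse(grepl("^[0-9]", k), paste0("x", k), k)
}

gml_value <- function(v) {
  if (is.numeric(v)) {
    if (!is.finite(v)) return(NULL)
    if (is.integer(v) || v == round(v)) sprintf("%d", as.integer(v))
    else sprintf("%.17g", v)
  } else {
    if (is.na(v)) return(NULL)
    paste0("\"", gsub("\"", "'", as.character(v)), "\"")
  }
}

#' Export a network to GML, GraphViz dot, or an edge table
#'
#' GML carries every node and edge attribute (numerics at full precision so
#' a re-import reproduces them); dot carries node labels and edge colors
#' (green for positive, red for negative, grey for unsigned); `edge_tsv` is
#' one row per edge with source, target, sign, per-measure scores, p, q and
#' the supporting-measure list. Nodes and edges are written in
#' lexicographic order so repeated runs diff cleanly.
#'
#' @param network an [assoc_network].
#' @param path output file.
#' @param format `"gml"`, `"dot"` or `"edge_tsv"`.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path, format = c("gml", "dot", "edge_tsv")) {
  format <- match.arg(format)
  nodes <- network$nodes[order(network$nodes$id), , drop = FALSE]
  e <- network$edges
  e <- e[order(e$source, e$target), , drop = FALSE]
  con <- tryCatch(file(path, "w"),
                  error = function(err) stop("cannot write to ", path, ": ",
                                             conditionMessage(err)))
  on.exit(close(con))
  if (format == "gml") {
    lines <- c("graph [", "  directed 0")
    for (i in seq_len(nrow(nodes))) {
      ln <- sprintf("  node [ id %d label \"%s\"", i - 1L, nodes$id[i])
      for (col in setdiff(names(nodes), "id")) {
        val <- gml_value(nodes[[col]][i])
        if (!is.null(val)) ln <- paste(ln, gml_key(col), val)
      }
      lines <- c(lines, paste(ln, "]"))
    }
    for (i in seq_len(nrow(e))) {
      ln <- sprintf("  edge [ source %d target %d",
                    match(e$source[i], nodes$id) - 1L,
                    match(e$target[i], nodes$id) - 1L)
      for (col in setdiff(names(e), c("source", "target"))) {
        val <- gml_value(e[[col]][i])
        if (!is.null(val)) ln <- paste(ln, gml_key(col), val)
      }
      lines <- c(lines, paste(ln, "]"))
    }
    writeLines(c(lines, "]"), con)
  } else if (format == "dot") {
    lines <- "graph assocnet {"
    for (i in seq_len(nrow(nodes)))
      lines <- c(lines, sprintf("  \"%s\";", nodes$id[i]))
    col_of <- function(sign) switch(sign, positive = "green",
                                    negative = "red", "grey")
    for (i in seq_len(nrow(e))) {
      sg <- if ("sign" %in% names(e)) e$sign[i] else "unsigned"
      lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [color=%s];",
                                e$source[i], e$target[i], col_of(sg)))
    }
    writeLines(c(lines, "}"), con)
  } else {
    cols <- names(e)
    fmt <- function(v) {
      if (is.numeric(v)) ifelse(is.na(v), "NA", sprintf("%.17g", v))
      else ifelse(is.na(v), "NA", as.character(v))
    }
    body <- vapply(seq_len(nrow(e)), function(i)
      paste(vapply(cols, function(cn) fmt(e[[cn]])[i], character(1)),
            collapse = "\t"), character(1))
    writeLines(c(paste(cols, collapse = "\t"), body), con)
  }
  invisible(path)
}

#' Import a network from GML
#'
#' Reads a GML file (as written by [write_network()] or other tools) back
#' into an [assoc_network], restoring node and edge attributes.
#'
#' @param path GML file.
#' @return an [assoc_network].
#' @export
read_network_gml <- function(path) {
  g <- igraph::read_graph(path, format = "gml")
  ids <- igraph::vertex_attr(g, "label")
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (at in setdiff(igraph::vertex_attr_names(g), c("label", "id")))
    nodes[[at]] <- igraph::vertex_attr(g, at)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(source = ids[el[, 1L]], target = ids[el[, 2L]],
                      stringsAsFactors = FALSE)
  for (at in igraph::edge_attr_names(g))
    edges[[at]] <- igraph::edge_attr(g, at)
  swap <- edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  multigraph <- anyDuplicated(paste(edges$source, edges$target)) > 0
  assoc_network(nodes = nodes, edges = edges, multigraph = multigraph)
}

# igraph view of a network (plotting, graph statistics).
as_igraph <- function(network) {
  ids <- network$nodes$id
  if (nrow(network$edges) == 0)
    return(igraph::make_empty_graph(n = length(ids), directed = FALSE))
  g <- igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = network$nodes)
  g
}

#' Plot an association network
#'
#' Convenience plot: green edges for co-presence, red for mutual exclusion,
#' grey for unsigned; metadata nodes drawn as squares.
#'
#' @param x an [assoc_network].
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.assoc_network <- function(x, ...) {
  g <- as_igraph(x)
  # edge weights can be negative (oriented scores); not usable for layout
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")
  ecol <- "grey50"
  if (nrow(x$edges) > 0 && "sign" %in% names(x$edges))
    ecol <- c(positive = "forestgreen", negative = "firebrick",
              unsigned = "grey50")[x$edges$sign]
  shape <- rep("circle", nrow(x$nodes))
  if ("nodetype" %in% names(x$nodes))
    shape[x$nodes$nodetype %in% "metadata"] <- "square"
  igraph::plot.igraph(g, edge.color = ecol, vertex.shape = shape,
                      vertex.size = 8, vertex.label.cex = 0.7, ...)
  invisible(x)
}
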