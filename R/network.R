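#' Distinct architectures of a set
#'
#' Collapses an architecture set to its unique ordered domain tuples with
#' multiplicities. Two architectures are the same only if their ordered
#' domain tuples are identical, including repeat counts: `(OST-HTH, OST-HTH,
#' Tudor)` and `(OST-HTH, Tudor)` are different architectures, as are
#' `(A, B)` and `(B, A)`. With `collapse_repeats = TRUE`, runs of consecutive
#' identical tokens are collapsed to a single token before comparison, so
#' tandem-repeat count differences are ignored.
#'
#' @param archs an [arch_set()].
#' @param collapse_repeats collapse tandem repeats before deduplication?
#' @return A data frame with columns `signature` (semicolon-joined tuple),
#'   `multiplicity` (number of source records) and a list-column `domains`,
#'   sorted lexicographically by signature. Multiplicities sum to the record
#'   count.
#' @export
distinct_architectures <- function(archs, collapse_repeats = FALSE) {
  doms <- archs$domains
  if (isTRUE(collapse_repeats)) {
    doms <- lapply(doms, function(d) rle(d)$values)
  }
  sigs <- vapply(doms, arch_signature, "")
  if (length(sigs) == 0L) {
    out <- data.frame(signature = character(), multiplicity = integer())
    out$domains <- list()
    return(out)
  }
  tab <- table(sigs)
  sig_sorted <- sort(names(tab), method = "radix")
  out <- data.frame(signature = sig_sorted,
                    multiplicity = as.integer(tab[sig_sorted]),
                    stringsAsFactors = FALSE)
  out$domains <- strsplit(out$signature, ";", fixed = TRUE)
  out
}

#' Build the ordered domain co-occurrence network
#'
#' Represents a set of domain architectures as a directed network in which
#' each node is a domain and each edge X -> Y records that X occurs as the
#' immediate N-terminal neighbor of Y in at least one distinct architecture.
#' The edge weight is the number of *distinct* architectures containing that
#' adjacency: duplicate records never change the network, and an adjacency
#' repeated within one architecture (e.g. in `A;B;A;B`) still counts once
#' for that architecture.
#'
#' @param archs an [arch_set()].
#' @param collapse_repeats passed to [distinct_architectures()].
#' @return An object of class `arch_network`: a list with `graph` (a
#'   directed, weighted [igraph][igraph::make_graph] graph) and `n_distinct`
#'   (the number of distinct architectures used).
#' @examples
#' archs <- arch_set("p1", "Dmel", "Metazoa", list(c("A", "B", "A")))
#' net <- build_network(archs)
#' net
#' @export
build_network <- function(archs, collapse_repeats = FALSE) {
  dis <- distinct_architectures(archs, collapse_repeats = collapse_repeats)
  edges <- list()
  nodes <- character()
  for (d in dis$domains) {
    nodes <- union(nodes, d)
    if (length(d) >= 2L) {
      pairs <- unique(paste(d[-length(d)], d[-1], sep = "\t"))
      for (p in pairs) edges[[p]] <- (edges[[p]] %||% 0L) + 1L
    }
  }
  nodes <- sort(nodes, method = "radix")
  if (length(edges) > 0L) {
    keys <- sort(names(edges), method = "radix")
    ends <- strsplit(keys, "\t", fixed = TRUE)
    el <- data.frame(source = vapply(ends, `[`, "", 1L),
                     target = vapply(ends, `[`, "", 2L),
                     weight = as.integer(unlist(edges[keys])),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = data.frame(name = nodes))
  } else {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(nodes)
  }
  structure(list(graph = g, n_distinct = nrow(dis)),
            class = "arch_network")
}

#' @export
print.arch_network <- function(x, ...) {
  cat(sprintf(
    "Domain architecture network: %d domain(s), %d directed adjacency edge(s), %d distinct architecture(s)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_distinct))
  invisible(x)
}

# Deterministic edge-list data frame of an arch_network.
network_edges <- function(net, undirected = FALSE) {
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    return(data.frame(source = character(), target = character(),
                      weight = integer()))
  }
  if (isTRUE(undirected)) {
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  }
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  if (isTRUE(undirected)) {
    # canonical endpoint order for undirected edges
    flip <- el$source > el$target
    tmp <- el$source[flip]; el$source[flip] <- el$target[flip]
    el$target[flip] <- tmp
  }
  el <- el[order(el$source, el$target, method = "radix"), , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Export a domain network as edge-list TSV and/or DOT
#'
#' The edge list has columns `source`, `target`, `weight`, sorted by
#' endpoints for deterministic output. The DOT export is valid Graphviz; with
#' `undirected = TRUE` reciprocal edges X -> Y and Y -> X are merged into a
#' single edge whose weight is the sum, matching the undirected rendering in
#' which arrowheads are omitted.
#'
#' @param net an `arch_network` from [build_network()].
#' @param edges_path path for the edge-list TSV, or `NULL` to skip.
#' @param dot_path path for the DOT file, or `NULL` to skip.
#' @param undirected merge reciprocal edges (summing weights)?
#' @return Invisibly, the edge-list data frame that was written.
#' @export
write_network <- function(net, edges_path = NULL, dot_path = NULL,
                          undirected = FALSE) {
  el <- network_edges(net, undirected = undirected)
  if (!is.null(edges_path)) {
    lines <- c("source\ttarget\tweight",
               if (nrow(el) > 0L) paste(el$source, el$target, el$weight,
                                        sep = "\t"))
    writeLines(lines, edges_path, useBytes = TRUE)
  }
  if (!is.null(dot_path)) {
    nodes <- sort(igraph::V(net$graph)$name, method = "radix")
    quote_id <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
    arrow <- if (undirected) "--" else "->"
    header <- if (undirected) "graph archnet {" else "digraph archnet {"
    body <- c(paste0("  ", quote_id(nodes), ";"),
              if (nrow(el) > 0L) {
                sprintf("  %s %s %s [weight=%d, label=%d];",
                        quote_id(el$source), arrow, quote_id(el$target),
                        el$weight, el$weight)
              })
    writeLines(c(header, body, "}"), dot_path, useBytes = TRUE)
  }
  invisible(el)
}
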