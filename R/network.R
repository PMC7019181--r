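#' Build the phenotype co-occurrence network
#'
#' Undirected simple graph whose edges are the phenotype pairs enriched
#' (p <= `alpha`) in at least one gene; each edge carries its supporting
#' genes and the minimum p over them, each node its cohort-wide patient
#' frequency.
#'
#' @param pair_results Output of [enrich_pairs()] on the same cohort.
#' @param cohort The [id_cohort()] the results came from (for node
#'   frequencies).
#' @param alpha Edge-inclusion threshold on `p`.
#' @return Object of class `cooc_network`: list with `nodes`
#'   (`data.frame` of `id`, `freq`), `edges` (`data.frame` of `a`, `b`,
#'   `genes` pipe-joined, `min_p`) and `graph` (an `igraph` object with the
#'   same attributes).
#' @export
build_network <- function(pair_results, cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "id_cohort"))
  res <- pair_results[pair_results$p <= alpha, , drop = FALSE]
  if (!nrow(res)) {
    nodes <- data.frame(id = character(), freq = integer(),
                        stringsAsFactors = FALSE)
    edges <- data.frame(a = character(), b = character(), genes = character(),
                        min_p = numeric(), stringsAsFactors = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(nodes = nodes, edges = edges, graph = g),
                     class = "cooc_network"))
  }
  parts <- strsplit(res$unit, "|", fixed = TRUE)
  res$a <- vapply(parts, `[`, "", 1)
  res$b <- vapply(parts, `[`, "", 2)
  edges <- do.call(rbind, lapply(split(res, res$unit), function(d) {
    data.frame(a = d$a[1], b = d$b[1],
               genes = paste(sort(unique(d$gene)), collapse = "|"),
               min_p = min(d$p), stringsAsFactors = FALSE)
  }))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$a, edges$b)))
  freq <- vapply(ids, function(ph) {
    carriers <- cohort$pheno_index[[ph]]
    if (is.null(carriers)) 0L else length(carriers)
  }, 0L)
  nodes <- data.frame(id = ids, freq = as.integer(freq),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b", "genes", "min_p")], directed = FALSE,
    vertices = data.frame(name = nodes$id, freq = nodes$freq))
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat("<cooc_network>", nrow(x$nodes), "phenotype nodes,",
      nrow(x$edges), "enriched-pair edges\n")
  invisible(x)
}

#' Extract network modules
#'
#' @param net A [build_network()] result.
#' @param method `"components"` (connected components, default) or
#'   `"greedy-modularity"` (greedy modularity maximization).
#' @return List of character vectors (sorted node ids), one per module,
#'   ordered by decreasing size then first member; empty list for an empty
#'   network.
#' @export
extract_modules <- function(net,
                            method = c("components", "greedy-modularity")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "cooc_network"))
  if (!nrow(net$edges)) return(list())
  memb <- if (method == "components")
    igraph::components(net$graph)$membership
  else
    igraph::membership(igraph::cluster_fast_greedy(net$graph))
  mods <- lapply(split(names(memb), as.integer(memb)), sort)
  first <- vapply(mods, `[`, "", 1)
  mods <- mods[order(-lengths(mods), first)]
  names(mods) <- NULL
  mods
}

#' Gene-focused subnetwork
#'
#' The subgraph induced by the edges a given gene supports; its shape
#' summarizes how that gene's enriched phenotype pairs hang together.
#'
#' @param net A [build_network()] result.
#' @param gene Gene symbol.
#' @return A `cooc_network` restricted to the gene's edges, with a `gene`
#'   element set.
#' @export
gene_subnetwork <- function(net, gene) {
  stopifnot(inherits(net, "cooc_network"))
  hit <- vapply(strsplit(net$edges$genes, "|", fixed = TRUE),
                function(gs) gene %in% gs, TRUE)
  if (!any(hit))
    stop("gene '", gene, "' supports no edge in the network")
  edges <- net$edges[hit, , drop = FALSE]
  rownames(edges) <- NULL
  ids <- sort(unique(c(edges$a, edges$b)))
  nodes <- net$nodes[match(ids, net$nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b", "genes", "min_p")], directed = FALSE,
    vertices = data.frame(name = nodes$id, freq = nodes$freq))
  structure(list(nodes = nodes, edges = edges, graph = g, gene = gene),
            class = "cooc_network")
}

#' Classify the topology of a gene-focused subnetwork
#'
#' Three qualitative shapes recur among gene-focused co-occurrence
#' subnetworks: *radial* (one hub phenotype most pairs pass through),
#' *dense* (phenotypes co-occur with each other, clique-like) and *mixed*.
#' The classifier uses edge density `2E / (V (V - 1))` and Freeman degree
#' centralization; thresholds are configurable and chosen so that stars of
#' any size are radial and cliques of any size are dense.  Radial is checked
#' before dense, so a graph meeting both rules is radial; graphs below 3
#' nodes or 2 edges are radial by convention.
#'
#' @param sub A `cooc_network` (typically from [gene_subnetwork()]).
#' @param cent_min Minimum centralization for the radial label.
#' @param density_radial_max Maximum density for the radial label.
#' @param density_dense_min Minimum density for the dense label.
#' @return Object of class `subnetwork_class`: list with `gene`, `n_nodes`,
#'   `n_edges`, `density`, `centralization`, `label`.
#' @export
classify_topology <- function(sub, cent_min = 0.8, density_radial_max = 0.5,
                              density_dense_min = 0.6) {
  stopifnot(inherits(sub, "cooc_network"))
  v <- nrow(sub$nodes)
  e <- nrow(sub$edges)
  dens <- if (v >= 2) 2 * e / (v * (v - 1)) else 0
  cent <- if (v >= 3)
    igraph::centr_degree(sub$graph, mode = "all", loops = FALSE,
                         normalized = TRUE)$centralization
  else 0
  label <- if (v < 3 || e < 2) "radial"
  else if (cent >= cent_min && dens <= density_radial_max) "radial"
  else if (dens >= density_dense_min) "dense"
  else "mixed"
  structure(list(gene = if (is.null(sub$gene)) NA_character_ else sub$gene,
                 n_nodes = v, n_edges = e, density = dens,
                 centralization = cent, label = label),
            class = "subnetwork_class")
}

#' @export
print.subnetwork_class <- function(x, ...) {
  cat(sprintf("<subnetwork_class> %s: %d nodes, %d edges, density %.3f, centralization %.3f -> %s\n",
              x$gene, x$n_nodes, x$n_edges, x$density, x$centralization,
              x$label))
  invisible(x)
}

#' Classify every gene's subnetwork
#'
#' @param net A [build_network()] result.
#' @param ... Passed to [classify_topology()].
#' @return `data.frame` with one row per supporting gene: `gene`,
#'   `n_nodes`, `n_edges`, `density`, `centralization`, `label`.
#' @export
classify_gene_topologies <- function(net, ...) {
  genes <- sort(unique(unlist(strsplit(net$edges$genes, "|", fixed = TRUE))))
  rows <- lapply(genes, function(g) {
    cl <- classify_topology(gene_subnetwork(net, g), ...)
    data.frame(gene = g, n_nodes = cl$n_nodes, n_edges = cl$n_edges,
               density = cl$density, centralization = cl$centralization,
               label = cl$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), n_nodes = integer(),
                      n_edges = integer(), density = numeric(),
                      centralization = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Export a co-occurrence network
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"` (TSV with edge attributes).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
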