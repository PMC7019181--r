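# Exact hypergeometric tail by direct enumeration.  Every term
# choose(K, j) * choose(N - K, n - j) is a non-negative integer bounded by
# choose(N, n) <= choose(30, 15) ~ 1.6e8 for N <= 30, so the sum is exact in
# double arithmetic and the single division is correctly rounded.
hyper_tail_oracle <- function(N, K, n, k) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Build a small cohort from named vectors/lists keyed by patient id.
make_cohort <- function(genes, phenos, families = NULL, sites = NULL,
                        types = NULL, vocabulary = NULL) {
  ids <- names(genes)
  if (is.null(families))
    families <- stats::setNames(paste0("F_", ids), ids)
  patients <- data.frame(patient_id = ids, gene = unname(genes),
                         family_id = unname(families[ids]),
                         stringsAsFactors = FALSE)
  ph <- data.frame(patient_id = rep(ids, lengths(phenos[ids])),
                   phenotype_id = unlist(phenos[ids], use.names = FALSE),
                   stringsAsFactors = FALSE)
  muts <- NULL
  if (!is.null(sites))
    muts <- data.frame(patient_id = ids, site = unname(sites[ids]),
                       mtype = unname(types[ids]), stringsAsFactors = FALSE)
  id_cohort(patients, ph, muts, vocabulary)
}

# A deterministic cohort with fully penetrant, disjoint planted sets:
# every patient of a gene carries exactly the gene's planted phenotypes.
clean_planted_cohort <- function(n_genes = 6L, size = 8L) {
  generate_cohort(
    synthetic_spec(n_genes = n_genes,
                   gene_size_law = list(exponent = 1, min = size, max = size),
                   penetrance = 1, background_rate = 0,
                   family_extra_share = 0),
    seed = 1)
}

# Directly assemble a co-occurrence network from an edge list (for the
# topology classifier's closed-form cases).
make_net <- function(a, b, gene = "G") {
  edges <- data.frame(a = a, b = b, genes = gene, min_p = 0.01,
                      stringsAsFactors = FALSE)
  ids <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, freq = 1L))
  structure(list(nodes = data.frame(id = ids, freq = 1L,
                                    stringsAsFactors = FALSE),
                 edges = edges, graph = g, gene = gene),
            class = "cooc_network")
}

star_net <- function(m) make_net(rep("HUB", m), sprintf("L%02d", seq_len(m)))

clique_net <- function(m) {
  v <- sprintf("V%02d", seq_len(m))
  pr <- t(combn(v, 2))
  make_net(pr[, 1], pr[, 2])
}
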