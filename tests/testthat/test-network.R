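test_that("network construction aggregates supporting genes per edge", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "A", P3 = "B", P4 = "B"),
    phenos = list(P1 = c("X", "Y"), P2 = c("X", "Y"),
                  P3 = c("X", "Y"), P4 = c("X", "Y")))
  fake <- data.frame(gene = c("A", "B"), unit = "X|Y", k = 2L, n = 2L,
                     K = 4L, N = 4L, p = c(0.01, 0.02), p_adj = NA,
                     exclusive = FALSE, stringsAsFactors = FALSE)
  net <- build_network(fake, co)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$genes, "A|B")
  expect_equal(net$edges$min_p, 0.01)
  expect_equal(net$nodes$freq, c(4L, 4L))  # all four patients carry X and Y

  # nothing below threshold -> empty network, not an error
  empty <- build_network(fake, co, alpha = 0.001)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(extract_modules(empty), list())
})

test_that("planted pairs appear as edges of the co-occurrence network", {
  g <- generate_cohort(synthetic_spec(), seed = 1)
  pres <- enrich_pairs(g$cohort)
  net <- build_network(pres, g$cohort)
  recovered <- unlist(lapply(names(g$truth$planted_pairs), function(gn) {
    keys <- with(g$truth$planted_pairs[[gn]], paste(a, b, sep = "|"))
    keys[keys %in% pres$unit[pres$gene == gn]]
  }))
  edge_keys <- paste(net$edges$a, net$edges$b, sep = "|")
  expect_true(all(recovered %in% edge_keys))
  expect_gte(nrow(net$edges), length(unique(recovered)))
  # node frequencies are the cohort-wide carrier counts
  expect_equal(net$nodes$freq,
               unname(vapply(g$cohort$pheno_index[net$nodes$id], length, 0L)))
})

test_that("modules partition the non-isolated nodes", {
  two_cliques <- make_net(c("A", "A", "B", "D", "D", "E"),
                          c("B", "C", "C", "E", "F", "F"))
  mods <- extract_modules(two_cliques)
  expect_length(mods, 2)
  expect_setequal(unlist(mods), two_cliques$nodes$id)
  expect_length(extract_modules(two_cliques, "greedy-modularity"), 2)

  path4 <- make_net(c("A", "B", "C"), c("B", "C", "D"))
  expect_length(extract_modules(path4), 1)
})

test_that("gene subnetworks carry exactly the gene's edges", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "B"),
    phenos = list(P1 = c("X", "Y", "Z"), P2 = c("X", "W")))
  fake <- data.frame(gene = c("A", "A", "B"),
                     unit = c("X|Y", "X|Z", "W|X"),
                     k = 1L, n = 1L, K = 1L, N = 2L, p = 0.01, p_adj = NA,
                     exclusive = TRUE, stringsAsFactors = FALSE)
  net <- build_network(fake, co)
  subA <- gene_subnetwork(net, "A")
  expect_equal(nrow(subA$edges), 2)
  expect_setequal(subA$nodes$id, c("X", "Y", "Z"))
  expect_error(gene_subnetwork(net, "NOPE"), "NOPE")
  # union over genes of subnetwork edges = full edge set
  all_edges <- unlist(lapply(c("A", "B"), function(g) {
    s <- gene_subnetwork(net, g)
    paste(s$edges$a, s$edges$b, sep = "|")
  }))
  expect_setequal(unique(all_edges), paste(net$edges$a, net$edges$b, sep = "|"))
})

test_that("stars classify radial and cliques dense, with closed-form stats", {
  s5 <- classify_topology(star_net(5))
  expect_equal(s5$label, "radial")
  expect_equal(s5$density, 5 / 15)
  expect_equal(s5$centralization, 1.0)

  k5 <- classify_topology(clique_net(5))
  expect_equal(k5$label, "dense")
  expect_equal(k5$density, 1.0)
  expect_equal(k5$centralization, 0.0)

  # below 3 nodes / 2 edges the label is radial by convention
  expect_equal(classify_topology(make_net("A", "B"))$label, "radial")
})

test_that("a clique with a pendant chain is mixed, per a hand-enumerated oracle", {
  # K4 on V1..V4 plus the chain V4-C1-C2-C3-C4
  v <- sprintf("V%d", 1:4)
  k4 <- t(combn(v, 2))
  net <- make_net(c(k4[, 1], "V4", "C1", "C2", "C3"),
                  c(k4[, 2], "C1", "C2", "C3", "C4"))
  cl <- classify_topology(net)
  # degrees: V1-V3 = 3, V4 = 4, C1-C3 = 2, C4 = 1
  deg <- c(3, 3, 3, 4, 2, 2, 2, 1)
  expect_equal(cl$n_nodes, 8)
  expect_equal(cl$n_edges, 10)
  expect_equal(cl$density, 2 * 10 / (8 * 7))
  expect_equal(cl$centralization, sum(max(deg) - deg) / ((8 - 1) * (8 - 2)))
  expect_equal(cl$label, "mixed")
})

test_that("igraph centralization matches the Freeman formula on gene subnetworks", {
  g <- generate_cohort(synthetic_spec(), seed = 1)
  net <- build_network(enrich_pairs(g$cohort), g$cohort)
  tab <- classify_gene_topologies(net)
  expect_gt(nrow(tab), 0)
  for (i in seq_len(nrow(tab))) {
    sub <- gene_subnetwork(net, tab$gene[i])
    if (tab$n_nodes[i] < 3) next
    deg <- igraph::degree(sub$graph)
    expect_equal(tab$centralization[i],
                 sum(max(deg) - deg) /
                   ((tab$n_nodes[i] - 1) * (tab$n_nodes[i] - 2)))
  }
})

test_that("network export round-trips through GraphML and edge-list TSV", {
  net <- make_net(c("A", "A"), c("B", "C"))
  gpath <- tempfile(fileext = ".graphml")
  write_network(net, gpath, "graphml")
  back <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::gorder(back), 3)
  expect_equal(igraph::gsize(back), 2)
  epath <- tempfile(fileext = ".tsv")
  write_network(net, epath, "edgelist")
  expect_equal(nrow(read.delim(epath)), 2)
  unlink(c(gpath, epath))
})
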