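test_that("summary counts and the top-gene share are exact", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "A", P3 = "A", P4 = "B"),
    phenos = list(P1 = "X", P2 = c("X", "Y"), P3 = "Z", P4 = "W"))
  s <- summarize_cohort(co)
  expect_equal(s$n_patients, 4)
  expect_equal(s$n_genes, 2)
  expect_equal(unname(s$top_gene_share[1]), 0.75)
  expect_equal(names(s$top_gene_share), c("A", "B"))

  # degenerate single-gene cohort
  s1 <- summarize_cohort(make_cohort(genes = c(P1 = "A"),
                                     phenos = list(P1 = "X")))
  expect_equal(unname(s1$top_gene_share[1]), 1.0)

  # ties broken lexicographically
  co2 <- make_cohort(genes = c(P1 = "B", P2 = "B", P3 = "A", P4 = "A"),
                     phenos = list(P1 = "X", P2 = "X", P3 = "X", P4 = "X"))
  expect_equal(names(summarize_cohort(co2)$top_gene_share), c("A", "B"))
})

test_that("summary histograms conserve mass and the share curve is monotone", {
  s <- summarize_cohort(generate_cohort(synthetic_spec(), seed = 5)$cohort)
  expect_equal(sum(s$patients_per_gene), s$n_genes)
  expect_equal(sum(s$phenotypes_per_patient), s$n_patients)
  expect_true(all(diff(s$top_gene_share) >= 0))
  expect_equal(unname(s$top_gene_share[s$n_genes]), 1.0)
})

test_that("top-gene share matches the generator's assignment table", {
  g <- generate_cohort(synthetic_spec(), seed = 11)
  s <- summarize_cohort(g$cohort)
  sizes <- table(g$cohort$patients$gene)
  expected <- cumsum(sort(as.integer(sizes), decreasing = TRUE)) / sum(sizes)
  # gene-name tie-breaks cannot change the cumulative patient counts
  expect_equal(unname(s$top_gene_share), unname(expected))
})

test_that("mutation spectrum reports per-gene dominant types with a tie rule", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "A", P3 = "A", P4 = "A", P5 = "B", P6 = "B",
              P7 = "B", P8 = "B", P9 = "C"),
    phenos = as.list(setNames(rep("X", 9), paste0("P", 1:9))),
    sites = setNames(paste0("c.", 1:9), paste0("P", 1:9)),
    types = c(P1 = "missense", P2 = "missense", P3 = "missense",
              P4 = "splicing", P5 = "gross deletion", P6 = "gross deletion",
              P7 = "duplication", P8 = "duplication", P9 = "indel"))
  sp <- mutation_spectrum(co, top_n = 3)
  expect_equal(unname(sp$dominant["A"]), "missense/nonsense")
  expect_equal(unname(sp$dominant["B"]), "none")  # 2-2 tie
  # row sums equal per-gene mutation-record counts
  expect_equal(unname(rowSums(sp$counts)), c(4L, 4L, 1L))
  expect_error(mutation_spectrum(make_cohort(genes = c(P1 = "A"),
                                             phenos = list(P1 = "X"))),
               "no mutation records")
})

test_that("planted dominant mutation types are recovered from the spectrum", {
  hits <- unlist(lapply(1:100, function(s) {
    g <- generate_cohort(synthetic_spec(n_genes = 25), seed = s)
    sp <- mutation_spectrum(g$cohort, top_n = 25)
    nm <- rowSums(sp$counts)
    el <- names(nm)[nm >= 5]
    sp$dominant[el] == g$truth$dominant[el]
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("patients-phenotypes correlation matches a rank-then-Pearson oracle", {
  # perfect monotone and antitone toy cases
  co_up <- make_cohort(
    genes = c(P1 = "A", P2 = "B", P3 = "B", P4 = "C", P5 = "C", P6 = "C"),
    phenos = list(P1 = c("X1", "X2"), P2 = c("Y1", "Y2", "Y3"), P3 = "Y4",
                  P4 = c("Z1", "Z2"), P5 = c("Z3", "Z4"), P6 = c("Z5", "Z6")))
  expect_equal(phenotype_count_correlation(co_up)$rho, 1.0)
  co_down <- make_cohort(
    genes = c(P1 = "A", P2 = "B", P3 = "B", P4 = "C", P5 = "C", P6 = "C"),
    phenos = list(P1 = c("X1", "X2", "X3", "X4", "X5", "X6", "X7"),
                  P2 = c("Y1", "Y2"), P3 = c("Y3", "Y4"),
                  P4 = "Z1", P5 = "Z1", P6 = "Z1"))
  expect_equal(phenotype_count_correlation(co_down)$rho, -1.0)

  expect_error(
    phenotype_count_correlation(make_cohort(genes = c(P1 = "A", P2 = "B"),
                                            phenos = list(P1 = "X",
                                                          P2 = "Y"))),
    "at least 3 genes")

  # midrank-tied oracle equality on generated cohorts with <= 50 genes
  for (s in 1:3) {
    co <- generate_cohort(synthetic_spec(n_genes = 30), seed = s)$cohort
    ct <- phenotype_count_correlation(co)
    oracle <- cor(rank(ct$per_gene$n_patients), rank(ct$per_gene$n_phenotypes))
    expect_equal(ct$rho, oracle, tolerance = 1e-10)
  }
})

test_that("correlation is positive and significant on planted cohorts", {
  ok <- vapply(1:50, function(s) {
    ct <- phenotype_count_correlation(
      generate_cohort(synthetic_spec(n_genes = 200), seed = s)$cohort)
    ct$rho > 0 && ct$p_value < 0.001
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})
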