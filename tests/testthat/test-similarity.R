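test_that("patient similarity obeys its closed forms in both modes", {
  expect_equal(patient_similarity(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(patient_similarity(c("A", "B", "C"), c("B", "C", "D"),
                                  "shared-count"), 2)
  expect_equal(patient_similarity(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(patient_similarity(c("A", "B"), c("C", "D")), 0)
  expect_equal(patient_similarity(c("A", "B"), c("C", "D"), "shared-count"), 0)
  # symmetry
  expect_equal(patient_similarity(c("A", "B", "C"), c("B", "X")),
               patient_similarity(c("B", "X"), c("A", "B", "C")))
})

test_that("the similarity matrix agrees with pairwise set computation", {
  co <- generate_cohort(synthetic_spec(n_genes = 5), seed = 8)$cohort
  pp <- patient_phenotypes(co)
  for (mode in c("jaccard", "shared-count")) {
    s <- similarity_matrix(co, mode)
    ids <- rownames(s)
    for (i in c(1, 3)) for (j in c(2, 4)) {
      expect_equal(s[ids[i], ids[j]],
                   patient_similarity(pp[[ids[i]]], pp[[ids[j]]], mode))
    }
    expect_true(isSymmetric(unname(s)))
  }
})

test_that("intra-gene similarity exceeds inter-gene on planted cohorts", {
  ii <- suppressMessages(
    intra_inter_comparison(generate_cohort(synthetic_spec(), seed = 1)$cohort))
  expect_gt(ii$pooled$mean_intra, ii$pooled$mean_inter)
  expect_lt(ii$pooled$p_value, 0.01)
  eligible <- ii$per_gene[ii$per_gene$n_patients >= 5, ]
  expect_true(all(eligible$mean_intra > eligible$mean_inter))
})

test_that("identical planted sets across genes erase the intra/inter gap", {
  phen <- c("HP:0000001", "HP:0000002", "HP:0000003")
  genes <- setNames(rep(c("A", "B"), each = 4), sprintf("P%02d", 1:8))
  co <- make_cohort(genes = genes,
                    phenos = setNames(rep(list(phen), 8), names(genes)))
  ii <- intra_inter_comparison(co)
  expect_equal(ii$pooled$mean_intra, ii$pooled$mean_inter)
})

test_that("family comparison recovers planted within-family sharing", {
  fc1 <- family_comparison(
    generate_cohort(synthetic_spec(family_extra_share = 1), seed = 2)$cohort)
  expect_gt(fc1$pooled$mean_same, fc1$pooled$mean_other)
  expect_lt(fc1$pooled$p_value, 0.05)

  # a single two-patient family with identical phenotype sets
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "A", P3 = "A"),
    phenos = list(P1 = c("X", "Y"), P2 = c("X", "Y"), P3 = "Z"),
    families = c(P1 = "F1", P2 = "F1", P3 = "F2"),
    sites = c(P1 = "c.1A>G", P2 = "c.1A>G", P3 = "c.9del"),
    types = c(P1 = "missense", P2 = "missense", P3 = "missense"))
  fc <- family_comparison(co)
  expect_equal(fc$pooled$mean_same, 1.0)
  expect_error(family_comparison(make_cohort(genes = c(P1 = "A"),
                                             phenos = list(P1 = "X"))),
               "no mutation records")
})

test_that("gene-query similarity is Jaccard with deterministic ranking", {
  expect_equal(gene_query_similarity(c("A", "B", "C", "D"), c("A", "B", "E")),
               0.4)
  expect_equal(gene_query_similarity(c("A", "B"), c("A", "B")), 1.0)
  expect_equal(gene_query_similarity(c("A", "B"), c("C")), 0)
  expect_error(gene_query_similarity(c("A"), character(0)), "empty query")

  g <- clean_planted_cohort(n_genes = 4, size = 3)
  target <- names(g$truth$planted)[2]
  rk <- gene_query_ranking(g$cohort, g$truth$planted[[target]])
  expect_equal(rk$gene[1], target)
  expect_equal(rk$score[1], 1.0)
  expect_equal(rk$rank, 1:4)
})

test_that("fuzzy conversion scores exact and reordered phrases at the top", {
  vocab <- data.frame(
    id = c("HP:0000252", "HP:0000750", "HP:0001250"),
    name = c("Microcephaly", "Delayed or absent speech", "Seizure"),
    synonyms = c("Small head circumference|Decreased head size", "", ""),
    stringsAsFactors = FALSE)
  # exact name -> 100 and first
  m <- fuzzy_convert("Delayed or absent speech", vocab)
  expect_equal(m$score[1], 100L)
  expect_equal(m$phenotype_id[1], "HP:0000750")
  # case- and punctuation-insensitive
  expect_equal(fuzzy_convert("microcephaly!", vocab)$score[1], 100L)
  # token order does not matter
  s1 <- fuzzy_convert("delayed speech", vocab)
  s2 <- fuzzy_convert("speech delayed", vocab)
  expect_equal(s1$score, s2$score)
  # the semantically close target strictly outranks the unrelated one
  scores <- setNames(s1$score, s1$phenotype_id)
  expect_gt(scores["HP:0000750"], scores["HP:0001250"])
  # synonyms contribute to the maximum
  expect_equal(fuzzy_convert("small head circumference", vocab)$score[1], 100L)
  expect_error(fuzzy_convert("  ", vocab), "non-empty")
  expect_error(fuzzy_convert("x", vocab[0, ]), "empty vocabulary")
})
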