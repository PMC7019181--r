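test_that("cohort construction validates its invariants", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "A", P3 = "B"),
    phenos = list(P1 = c("HP:0000001", "HP:0000002"),
                  P2 = c("HP:0000002", "HP:0000003"),
                  P3 = "HP:0000004"))
  expect_s3_class(co, "id_cohort")
  expect_equal(nrow(co$patients), 3)
  expect_equal(length(co$gene_index), 2)
  expect_equal(length(co$pheno_index), 4)

  # duplicate patient ids are rejected
  expect_error(
    id_cohort(data.frame(patient_id = c("P1", "P1"), gene = "A",
                         family_id = "F"),
              data.frame(patient_id = "P1", phenotype_id = "X")),
    "duplicate patient")

  # an empty phenotype set is rejected, naming the patient
  expect_error(
    id_cohort(data.frame(patient_id = c("P1", "P2"), gene = "A",
                         family_id = "F"),
              data.frame(patient_id = "P1", phenotype_id = "X")),
    "P2")

  # phenotype ids missing from a supplied vocabulary are appended with a
  # warning, and duplicate (patient, phenotype) rows collapse silently
  expect_warning(
    co2 <- id_cohort(
      data.frame(patient_id = "P1", gene = "A", family_id = "F"),
      data.frame(patient_id = c("P1", "P1", "P1"),
                 phenotype_id = c("X", "X", "Y")),
      vocabulary = data.frame(id = "X", name = "Pheno X")),
    "absent from the vocabulary")
  expect_equal(nrow(co2$phenotypes), 2)
  expect_equal(co2$vocabulary$name[co2$vocabulary$id == "Y"], "Y")
})

test_that("mutation records are tied to the patient's causal gene", {
  co <- make_cohort(
    genes = c(P1 = "A", P2 = "B"),
    phenos = list(P1 = "X", P2 = "Y"),
    sites = c(P1 = "c.100A>G", P2 = "c.7del"),
    types = c(P1 = "missense", P2 = "gross deletion"))
  expect_equal(co$mutations$gene, c("A", "B"))
  expect_equal(co$mutations$mtype,
               c("missense/nonsense", "gross-deletion"))
})

test_that("free-text mutation descriptors map onto the six-way vocabulary", {
  expect_equal(
    map_mutation_type(c("Missense", "non-sense", "splice site", "frameshift",
                        "gross insertions (most duplications)",
                        "large deletion", "something odd")),
    c("missense/nonsense", "missense/nonsense", "splicing", "small-indel",
      "gross-insertion/duplication", "gross-deletion", "other"))
  expect_equal(map_mutation_type("gross-insertion/duplication"),
               "gross-insertion/duplication")
})

test_that("TSV and JSON round-trips preserve the cohort", {
  co <- generate_cohort(synthetic_spec(n_genes = 8), seed = 42)$cohort
  for (fmt in c("tsv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_cohort(co, path)
    back <- load_cohort(path)
    expect_equal(back$patients, co$patients)
    expect_equal(back$phenotypes, co$phenotypes)
    expect_equal(back$mutations[order(back$mutations$patient_id,
                                      back$mutations$site), ],
                 co$mutations[order(co$mutations$patient_id,
                                    co$mutations$site), ],
                 ignore_attr = TRUE)
    if (fmt == "json") {
      # JSON embeds the full vocabulary, synonyms included
      expect_equal(back$vocabulary, co$vocabulary)
    } else {
      # TSV carries names only for observed phenotypes
      obs <- unique(co$phenotypes$phenotype_id)
      expect_setequal(back$vocabulary$id, obs)
      expect_equal(back$vocabulary$name,
                   co$vocabulary$name[match(back$vocabulary$id,
                                            co$vocabulary$id)])
    }
    unlink(path)
  }
})

test_that("malformed cohort files fail with informative errors", {
  # empty gene field, named by row and field
  path <- tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tgene\tfamily_id\tphenotype_id",
               "P1\tA\tF1\tX",
               "P2\t\tF1\tY"), path)
  expect_error(load_cohort(path), "row 2.*gene")

  # one patient id under two genes violates the single-causal-gene model
  writeLines(c("patient_id\tgene\tfamily_id\tphenotype_id",
               "P1\tA\tF1\tX",
               "P1\tB\tF1\tY"), path)
  expect_error(load_cohort(path), "conflicting gene")

  # repeated (patient, phenotype) rows are deduplicated, not an error
  writeLines(c("patient_id\tgene\tfamily_id\tphenotype_id",
               "P1\tA\tF1\tX",
               "P1\tA\tF1\tX",
               "P1\tA\tF1\tY"), path)
  expect_equal(nrow(load_cohort(path)$phenotypes), 2)
  unlink(path)

  # JSON: a patient without phenotypes is named in the error
  jpath <- tempfile(fileext = ".json")
  writeLines('{"patients":[{"id":"P9","gene":"A","family":"F","phenotypes":[]}]}',
             jpath)
  expect_error(load_cohort(jpath), "P9")
  unlink(jpath)
})
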