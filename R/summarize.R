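#' Descriptive cohort summary
#'
#' Counts and the two concentration views used to describe cohort structure:
#' how patients distribute over genes (most ID genes are reported in very few
#' patients while a handful account for a large share) and how many
#' phenotypes each patient carries.
#'
#' @param cohort An [id_cohort()].
#' @return An object of class `cohort_summary`: list with `n_patients`,
#'   `n_genes`, `n_phenotypes` (distinct observed), `n_mutations`,
#'   `patients_per_gene` (named vector: patient count -> number of genes),
#'   `phenotypes_per_patient` (named vector: phenotype count -> number of
#'   patients), and `top_gene_share` (cumulative patient fraction covered by
#'   the r most patient-rich genes, named by gene; ties broken
#'   lexicographically).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "id_cohort"))
  gsz <- vapply(cohort$gene_index, length, 0L)
  psz <- vapply(patient_phenotypes(cohort), length, 0L)
  n_pat <- nrow(cohort$patients)
  ord <- order(-gsz, names(gsz))
  share <- cumsum(gsz[ord]) / n_pat
  structure(list(
    n_patients = n_pat,
    n_genes = length(gsz),
    n_phenotypes = length(cohort$pheno_index),
    n_mutations = nrow(cohort$mutations),
    patients_per_gene = table(gsz),
    phenotypes_per_patient = table(psz),
    top_gene_share = share
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat("  patients:  ", x$n_patients, "\n")
  cat("  genes:     ", x$n_genes, "\n")
  cat("  phenotypes:", x$n_phenotypes, "\n")
  cat("  mutations: ", x$n_mutations, "\n")
  one <- x$patients_per_gene["1"]
  if (!is.na(one))
    cat(sprintf("  singleton genes: %d (%.1f%%)\n", one, 100 * one / x$n_genes))
  k <- min(10L, length(x$top_gene_share))
  cat(sprintf("  top %d genes cover %.1f%% of patients\n",
              k, 100 * x$top_gene_share[k]))
  invisible(x)
}

#' @export
summary.id_cohort <- function(object, ...) summarize_cohort(object)

#' Per-gene mutation-type spectrum
#'
#' For the `top_n` genes ranked by patient count, counts mutation records in
#' each canonical type and reports the dominant type per gene; many ID genes
#' show a clear bias toward one variant class.
#'
#' @param cohort An [id_cohort()] with at least one mutation record.
#' @param top_n Number of top genes (by patient count, ties lexicographic).
#' @return List of class `mutation_spectrum` with `counts` (gene x type
#'   integer matrix, all-zero rows for genes without mutation records) and
#'   `dominant` (named character; `"none"` when the maximum is tied or the
#'   gene has no records).
#' @export
mutation_spectrum <- function(cohort, top_n = 57L) {
  stopifnot(inherits(cohort, "id_cohort"), top_n >= 1)
  if (!nrow(cohort$mutations))
    stop("cohort has no mutation records")
  gsz <- vapply(cohort$gene_index, length, 0L)
  genes <- names(gsz)[order(-gsz, names(gsz))]
  genes <- genes[seq_len(min(top_n, length(genes)))]
  types <- mutation_types()
  counts <- matrix(0L, length(genes), length(types),
                   dimnames = list(genes, types))
  mu <- cohort$mutations[cohort$mutations$gene %in% genes, , drop = FALSE]
  if (nrow(mu)) {
    tab <- table(factor(mu$gene, levels = genes),
                 factor(mu$mtype, levels = types))
    counts[] <- as.integer(tab)
  }
  dominant <- apply(counts, 1, function(r) {
    if (all(r == 0) || sum(r == max(r)) > 1) "none" else types[which.max(r)]
  })
  structure(list(counts = counts, dominant = dominant),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("<mutation_spectrum>", nrow(x$counts), "genes x",
      ncol(x$counts), "mutation types;",
      sum(x$dominant != "none"), "genes with a dominant type\n")
  invisible(x)
}

#' Correlation between patients per gene and phenotypes per gene
#'
#' Genes reported in more patients accumulate more distinct phenotypes; the
#' strength of that relation (one face of phenotype heterogeneity) is
#' measured by Spearman rank correlation with midranks for ties and the
#' large-sample approximation for the p-value.
#'
#' @param cohort An [id_cohort()] with at least 3 genes.
#' @return List with `rho`, `p_value`, `n_genes`, and `per_gene`
#'   (`data.frame` of gene, n_patients, n_phenotypes).
#' @export
phenotype_count_correlation <- function(cohort) {
  stopifnot(inherits(cohort, "id_cohort"))
  gsz <- vapply(cohort$gene_index, length, 0L)
  if (length(gsz) < 3)
    stop("need at least 3 genes, got ", length(gsz))
  prof <- gene_profiles(cohort, "union")
  nph <- vapply(prof, length, 0L)[names(gsz)]
  ct <- suppressWarnings(
    cor.test(gsz, nph, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_genes = length(gsz),
       per_gene = data.frame(gene = names(gsz),
                             n_patients = unname(gsz),
                             n_phenotypes = unname(nph),
                             stringsAsFactors = FALSE))
}
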