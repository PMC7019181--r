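#' Specification of a synthetic ID cohort
#'
#' Describes the planted structure a generated cohort should carry: a
#' heavy-tailed patients-per-gene distribution, disjoint gene-specific
#' ("planted") phenotypes expressed with a given penetrance, gene-specific
#' phenotype pairs, shared background phenotypes, small families whose
#' members share one extra phenotype, and a dominant mutation type per gene.
#'
#' @param n_genes Number of causal genes.
#' @param gene_size_law List with `exponent`, `min`, `max`: patients per gene
#'   are drawn from a truncated discrete power law P(s) proportional to
#'   s^-exponent on `min:max`.
#' @param vocab_size Total phenotype vocabulary size; defaults to
#'   `n_genes * planted_per_gene + 150` (planted ids first, the rest is the
#'   shared background pool).  With the default background rate this gives
#'   patients about 4-5 background phenotypes on top of their planted ones,
#'   so that a realistic minority of patients carries more than ten
#'   phenotypes.
#' @param planted_per_gene Gene-specific phenotypes per gene.
#' @param penetrance Probability that a planted phenotype manifests in a
#'   carrier patient.
#' @param planted_pairs_per_gene Number of gene-specific phenotype pairs
#'   (drawn among the gene's planted phenotypes) recorded as ground truth.
#' @param background_rate Per-phenotype Bernoulli probability of each
#'   background-pool phenotype in any patient.
#' @param families_per_gene Families per gene; `NULL` (default) gives
#'   families of about two affected patients (`ceiling(size / 2)` families),
#'   matching the small sibships typical of published pedigrees.
#' @param family_extra_share Probability that a family carries one shared
#'   background phenotype expressed by all of its members.
#' @param mutation_dominance Probability that a family's variant is of the
#'   gene's dominant mutation type (families share one variant).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 50L,
                           gene_size_law = list(exponent = 1.6, min = 1L,
                                                max = 60L),
                           vocab_size = NULL,
                           planted_per_gene = 3L,
                           penetrance = 0.8,
                           planted_pairs_per_gene = 2L,
                           background_rate = 0.03,
                           families_per_gene = NULL,
                           family_extra_share = 0.5,
                           mutation_dominance = 0.8) {
  if (is.null(vocab_size)) vocab_size <- n_genes * planted_per_gene + 150L
  spec <- list(n_genes = as.integer(n_genes),
               gene_size_law = gene_size_law,
               vocab_size = as.integer(vocab_size),
               planted_per_gene = as.integer(planted_per_gene),
               penetrance = penetrance,
               planted_pairs_per_gene = as.integer(planted_pairs_per_gene),
               background_rate = background_rate,
               families_per_gene = families_per_gene,
               family_extra_share = family_extra_share,
               mutation_dominance = mutation_dominance)
  probs <- c(spec$penetrance, spec$background_rate, spec$family_extra_share,
             spec$mutation_dominance)
  if (any(probs < 0 | probs > 1))
    stop("penetrance, background_rate, family_extra_share and ",
         "mutation_dominance must all lie in [0, 1]")
  if (spec$n_genes < 1 || spec$planted_per_gene < 1)
    stop("n_genes and planted_per_gene must be positive")
  if (spec$planted_pairs_per_gene > choose(spec$planted_per_gene, 2))
    stop("planted_pairs_per_gene exceeds the number of pairs available ",
         "among ", spec$planted_per_gene, " planted phenotypes")
  if (spec$vocab_size < spec$n_genes * spec$planted_per_gene + 20L)
    stop("vocab_size too small: need at least n_genes * planted_per_gene",
         " + 20 background phenotypes")
  with(gene_size_law, stopifnot(exponent > 0, min >= 1, max >= min))
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' A single RNG stream seeded once drives the whole draw, so identical
#' `(spec, seed)` yield byte-identical results.  Each patient's phenotype
#' set is: its gene's planted phenotypes each kept with probability
#' `penetrance`, plus independent background draws, plus the family's shared
#' phenotype (if any); an empty draw is rescued by forcing in one randomly
#' chosen planted phenotype.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer RNG seed.
#' @return List with `cohort` (an [id_cohort()]) and `truth`: per-gene
#'   planted phenotype ids, planted pairs (`data.frame` of canonical a < b),
#'   dominant mutation type, per-patient family and per-family shared
#'   phenotype.
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(seed))

  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  vocab_ids <- sprintf("HP:%07d", seq_len(spec$vocab_size))
  vocab <- data.frame(id = vocab_ids,
                      name = paste("Synthetic phenotype",
                                   sub("^HP:", "", vocab_ids)),
                      synonyms = "", stringsAsFactors = FALSE)
  n_planted <- spec$n_genes * spec$planted_per_gene
  planted <- split(vocab_ids[seq_len(n_planted)],
                   rep(genes, each = spec$planted_per_gene))[genes]
  background_pool <- vocab_ids[(n_planted + 1):spec$vocab_size]

  sizes_support <- spec$gene_size_law$min:spec$gene_size_law$max
  size_probs <- sizes_support^(-spec$gene_size_law$exponent)
  sizes <- sizes_support[sample.int(length(sizes_support), spec$n_genes,
                                    replace = TRUE, prob = size_probs)]

  planted_pairs <- lapply(genes, function(g) {
    all_pairs <- t(combn(sort(planted[[g]]), 2))
    pick <- sort(sample.int(nrow(all_pairs), spec$planted_pairs_per_gene))
    data.frame(a = all_pairs[pick, 1], b = all_pairs[pick, 2],
               stringsAsFactors = FALSE)
  })
  names(planted_pairs) <- genes
  types <- mutation_types()
  dominant <- setNames(sample(types, spec$n_genes, replace = TRUE), genes)

  pat_rows <- list(); phe_rows <- list(); mut_rows <- list()
  family_pheno <- character(0)
  pid_counter <- 0L
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    s <- sizes[gi]
    n_fam <- if (is.null(spec$families_per_gene)) ceiling(s / 2) else
      min(spec$families_per_gene, s)
    fam_of <- rep(seq_len(n_fam), length.out = s)
    fam_ids <- paste0(g, "_F", seq_len(n_fam))
    fam_site <- paste0("c.", sample.int(99999L, n_fam), "A>G")
    fam_type <- ifelse(runif(n_fam) < spec$mutation_dominance, dominant[g],
                       vapply(seq_len(n_fam), function(i)
                         sample(setdiff(types, dominant[g]), 1), ""))
    fam_shared <- ifelse(runif(n_fam) < spec$family_extra_share,
                         sample(background_pool, n_fam, replace = TRUE),
                         NA_character_)
    family_pheno[fam_ids] <- fam_shared

    for (j in seq_len(s)) {
      pid_counter <- pid_counter + 1L
      pid <- sprintf("P%05d", pid_counter)
      f <- fam_of[j]
      keep <- planted[[g]][runif(spec$planted_per_gene) < spec$penetrance]
      bg <- background_pool[runif(length(background_pool)) <
                              spec$background_rate]
      set <- c(keep, bg)
      if (!is.na(fam_shared[f])) set <- c(set, fam_shared[f])
      if (!length(set)) set <- sample(planted[[g]], 1)
      set <- sort(unique(set))
      pat_rows[[pid_counter]] <- data.frame(
        patient_id = pid, gene = g, family_id = fam_ids[f],
        stringsAsFactors = FALSE)
      phe_rows[[pid_counter]] <- data.frame(
        patient_id = pid, phenotype_id = set, stringsAsFactors = FALSE)
      mut_rows[[pid_counter]] <- data.frame(
        patient_id = pid, site = fam_site[f], mtype = fam_type[f],
        stringsAsFactors = FALSE)
    }
  }

  cohort <- id_cohort(do.call(rbind, pat_rows), do.call(rbind, phe_rows),
                      do.call(rbind, mut_rows), vocab)
  truth <- list(planted = planted,
                planted_pairs = planted_pairs,
                dominant = dominant,
                families = cohort$patients[, c("patient_id", "family_id")],
                family_pheno = family_pheno,
                seed = as.integer(seed),
                spec = spec)
  list(cohort = cohort, truth = truth)
}

#' Permute patient-to-gene assignments (null model)
#'
#' Randomly permutes which causal gene each patient carries while leaving
#' every phenotype set untouched; the number of patients per gene is
#' preserved, making the permuted cohort an exact null for per-gene
#' enrichment tests.
#'
#' @param cohort An [id_cohort()].
#' @param seed Integer RNG seed.
#' @return A new [id_cohort()] with shuffled gene labels (mutation records
#'   follow their patient's new gene).
#' @export
permute_labels <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "id_cohort"))
  set.seed(as.integer(seed))
  pat <- cohort$patients
  pat$gene <- pat$gene[sample.int(nrow(pat))]
  id_cohort(pat, cohort$phenotypes, cohort$mutations, cohort$vocabulary)
}
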