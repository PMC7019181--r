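#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more carriers among the `n` patients of a
#' focal gene when `K` of the `N` cohort patients carry the phenotype (or
#' phenotype pair): `P = sum_{j=k}^{min(K,n)} C(K,j) C(N-K,n-j) / C(N,n)`.
#' Vectorized over its arguments.
#'
#' @param N Cohort size.
#' @param K Cohort-wide carriers of the unit.
#' @param n Patients of the focal gene.
#' @param k Carriers of the unit among the focal gene's patients.
#' @return Numeric p-value(s) in (0, 1].
#' @examples
#' hypergeom_tail(20, 5, 4, 3)  # 155 / 4845
#' @export
hypergeom_tail <- function(N, K, n, k) {
  if (any(N < 0 | K < 0 | n < 0 | k < 0))
    stop("all counts must be non-negative")
  if (any(K > N) || any(n > N))
    stop("invalid 2x2 margins: need K <= N and n <= N")
  if (any(k > pmin(K, n)))
    stop("invalid overlap: need k <= min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

fisher_combine <- function(p1, p2) {
  pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  paste(a, b, sep = "|")
}

#' Enumerate the co-occurring phenotype pairs of one phenotype set
#'
#' Any two phenotypes present in the same patient form a co-occurrence pair;
#' pairs are canonical (`a < b` lexicographically).
#'
#' @param phenotypes Character vector of phenotype ids (one patient's set).
#' @return `data.frame` with columns `a`, `b`; zero rows when fewer than two
#'   phenotypes are given.
#' @export
enumerate_pairs <- function(phenotypes) {
  phenotypes <- sort(unique(as.character(phenotypes)))
  if (length(phenotypes) < 2)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  m <- combn(phenotypes, 2)
  data.frame(a = m[1, ], b = m[2, ], stringsAsFactors = FALSE)
}

# ---- internal count index ---------------------------------------------------
# All enrichment-derived quantities reduce to four count structures; keeping
# them explicit makes leave-one-patient-out recomputation an O(|patient|)
# decrement instead of a full cohort pass.

enrichment_index <- function(cohort) {
  stopifnot(inherits(cohort, "id_cohort"))
  genes <- sort(names(cohort$gene_index))
  phen <- cohort$vocabulary$id
  pp <- patient_phenotypes(cohort)
  patient_gene <- setNames(cohort$patients$gene, cohort$patients$patient_id)
  n_gene <- vapply(cohort$gene_index, length, 0L)[genes]
  gene_of_row <- patient_gene[cohort$phenotypes$patient_id]
  k_single <- unclass(table(factor(gene_of_row, levels = genes),
                            factor(cohort$phenotypes$phenotype_id,
                                   levels = phen)))
  storage.mode(k_single) <- "integer"
  patient_pairs <- lapply(pp, function(v) {
    if (length(v) < 2) return(character(0))
    m <- combn(v, 2)  # v is sorted, so pairs are canonical
    paste(m[1, ], m[2, ], sep = "|")
  })
  np <- lengths(patient_pairs)
  pair_long_gene <- rep(patient_gene[names(patient_pairs)], np)
  pair_long <- unlist(patient_pairs, use.names = FALSE)
  pair_K <- c(table(pair_long))
  storage.mode(pair_K) <- "integer"
  pair_gene <- lapply(split(pair_long, pair_long_gene), function(v) {
    tb <- c(table(v)); storage.mode(tb) <- "integer"; tb
  })
  empty <- setdiff(genes, names(pair_gene))
  pair_gene[empty] <- list(setNames(integer(0), character(0)))
  structure(list(
    genes = genes, phen = phen, N = nrow(cohort$patients),
    k_single = k_single, K_single = colSums(k_single),
    n_gene = n_gene,
    pair_gene = pair_gene[genes], pair_K = pair_K,
    patient_phenos = pp, patient_pairs = patient_pairs,
    patient_gene = patient_gene
  ), class = "enr_index")
}

# remove one patient's contribution from every count
holdout_index <- function(ix, patient_id) {
  g <- ix$patient_gene[[patient_id]]
  ph <- ix$patient_phenos[[patient_id]]
  pr <- ix$patient_pairs[[patient_id]]
  ix$k_single[g, ph] <- ix$k_single[g, ph] - 1L
  ix$K_single[ph] <- ix$K_single[ph] - 1L
  ix$n_gene[[g]] <- ix$n_gene[[g]] - 1L
  ix$N <- ix$N - 1L
  if (length(pr)) {
    pg <- ix$pair_gene[[g]]
    pg[pr] <- pg[pr] - 1L
    ix$pair_gene[[g]] <- pg[pg > 0L]
    ix$pair_K[pr] <- ix$pair_K[pr] - 1L
    ix$pair_K <- ix$pair_K[ix$pair_K > 0L]
  }
  ix$patient_phenos[[patient_id]] <- NULL
  ix$patient_pairs[[patient_id]] <- NULL
  ix$patient_gene <- ix$patient_gene[names(ix$patient_gene) != patient_id]
  ix
}

single_tests <- function(ix, min_support) {
  sel <- which(ix$k_single >= min_support, arr.ind = TRUE)
  if (!nrow(sel))
    return(data.frame(gene = character(), unit = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), stringsAsFactors = FALSE))
  k <- ix$k_single[sel]
  K <- ix$K_single[sel[, 2]]
  n <- ix$n_gene[sel[, 1]]
  data.frame(gene = ix$genes[sel[, 1]], unit = ix$phen[sel[, 2]],
             k = as.integer(k), n = as.integer(n), K = as.integer(K),
             N = ix$N,
             p = phyper(k - 1, K, ix$N - K, n, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

pair_tests <- function(ix, min_support) {
  rows <- lapply(ix$genes, function(g) {
    pg <- ix$pair_gene[[g]]
    pg <- pg[pg >= min_support]
    if (!length(pg)) return(NULL)
    K <- ix$pair_K[names(pg)]
    data.frame(gene = g, unit = names(pg), k = as.integer(pg),
               n = as.integer(ix$n_gene[[g]]), K = as.integer(K), N = ix$N,
               p = phyper(pg - 1, K, ix$N - K, ix$n_gene[[g]],
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), unit = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

finish_enrichment <- function(tab, alpha, adjust) {
  tab$p_adj <- if (adjust == "BH") p.adjust(tab$p, "BH") else NA_real_
  tab$exclusive <- tab$K == tab$k
  keep <- if (adjust == "BH") tab$p_adj <= alpha else tab$p <= alpha
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$gene, tab$p, tab$unit), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-gene enrichment of single phenotypes
#'
#' One upper-tail hypergeometric test per (gene, phenotype) whose gene-side
#' carrier count `k` reaches `min_support` (a phenotype must appear in at
#' least that many of the gene's patients to be testable); the background is
#' the whole cohort.  Units whose cohort-wide carriers all belong to the
#' focal gene (`K == k`) are flagged `exclusive` -- they identify the gene
#' outright.
#'
#' @param cohort An [id_cohort()].
#' @param min_support Minimum gene-side carrier count (default 5).  Use 0 to
#'   test every (gene, phenotype) combination -- the right universe when
#'   measuring the empirical type-I rate, since restricting to `k >= 1`
#'   conditions on partial evidence of enrichment.
#' @param alpha Significance threshold on `p` (or on `p_adj` when
#'   `adjust = "BH"`); pass `alpha = 1` to keep every performed test.
#' @param adjust `"none"` (default; mirrors raw-threshold practice) or
#'   `"BH"` for Benjamini-Hochberg across all performed tests.
#' @return `data.frame` with columns `gene`, `unit`, `k`, `n`, `K`, `N`,
#'   `p`, `p_adj`, `exclusive`, sorted by (gene, p, unit).
#' @export
enrich_phenotypes <- function(cohort, min_support = 5L, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ix <- if (inherits(cohort, "enr_index")) cohort else enrichment_index(cohort)
  finish_enrichment(single_tests(ix, min_support), alpha, adjust)
}

#' Per-gene enrichment of co-occurring phenotype pairs
#'
#' A patient carries a pair iff both phenotypes are in its set; otherwise
#' identical to [enrich_phenotypes()].  The `unit` column holds the
#' canonical pair as `"a|b"`.
#'
#' @inheritParams enrich_phenotypes
#' @return `data.frame` as in [enrich_phenotypes()].
#' @export
enrich_pairs <- function(cohort, min_support = 5L, alpha = 0.05,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ix <- if (inherits(cohort, "enr_index")) cohort else enrichment_index(cohort)
  finish_enrichment(pair_tests(ix, min_support), alpha, adjust)
}

#' Per-gene enriched phenotype and pair sets
#'
#' Convenience container consumed by [rank_genes()] and the SVM features:
#' for every gene, its enriched-phenotype ids and enriched-pair keys at the
#' given support and significance thresholds, together with the cohort-level
#' universes the prioritization tests draw from.
#'
#' @param x An [id_cohort()] (or an internal enrichment index).
#' @inheritParams enrich_phenotypes
#' @return Object of class `enriched_sets`: list with `single` and `pair`
#'   (named lists over all genes), `genes`, `V` (vocabulary size),
#'   `n_obs_pairs` / `obs_pairs` (count and keys of pairs observed in at
#'   least one patient) and `N`.
#' @export
enriched_sets <- function(x, min_support = 5L, alpha = 0.05) {
  ix <- if (inherits(x, "enr_index")) x else enrichment_index(x)
  st <- single_tests(ix, min_support)
  st <- st[st$p <= alpha, , drop = FALSE]
  pt <- pair_tests(ix, min_support)
  pt <- pt[pt$p <= alpha, , drop = FALSE]
  single <- lapply(setNames(ix$genes, ix$genes), function(g)
    sort(st$unit[st$gene == g]))
  pair <- lapply(setNames(ix$genes, ix$genes), function(g)
    sort(pt$unit[pt$gene == g]))
  structure(list(single = single, pair = pair, genes = ix$genes,
                 V = length(ix$phen), n_obs_pairs = length(ix$pair_K),
                 obs_pairs = names(ix$pair_K), N = ix$N),
            class = "enriched_sets")
}

#' @export
print.enriched_sets <- function(x, ...) {
  cat("<enriched_sets>", length(x$genes), "genes;",
      sum(lengths(x$single)), "enriched phenotypes;",
      sum(lengths(x$pair)), "enriched pairs\n")
  invisible(x)
}
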