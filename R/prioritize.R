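
# Per-gene query score: hypergeometric overlap between the query set and the
# gene's enriched-phenotype set (universe = vocabulary), likewise for query
# pairs over the observed-pair universe, Fisher-combined.  Falls back to the
# single-phenotype p alone when the gene has no enriched pairs or the query
# contributes no observed pair.
gene_query_score <- function(gene, query, query_pairs, sets) {
  enr_s <- sets$single[[gene]]
  enr_p <- sets$pair[[gene]]
  hits_single <- length(intersect(query, enr_s))
  p_single <- hypergeom_tail(sets$V, length(enr_s), length(query),
                             hits_single)
  hits_pair <- length(intersect(query_pairs, enr_p))
  if (length(enr_p) && length(query_pairs)) {
    p_pair <- hypergeom_tail(sets$n_obs_pairs, length(enr_p),
                             length(query_pairs), hits_pair)
    p <- fisher_combine(p_single, p_pair)
  } else {
    p_pair <- NA_real_
    p <- p_single
  }
  list(hits_single = hits_single, hits_pair = hits_pair,
       p_single = p_single, p_pair = p_pair, p = p)
}

#' Rank candidate genes for a query phenotype set
#'
#' For every gene, the overlap between the query and the gene's enriched
#' phenotypes is tested against the hypergeometric null (universe = the
#' phenotype vocabulary, draws = the query), the overlap between the query's
#' pairs and the gene's enriched pairs likewise (universe = pairs observed
#' in at least one patient), and the two p-values are Fisher-combined
#' (single-phenotype p alone when the gene has no enriched pairs).  Genes
#' are ordered by (combined p, total hits descending, gene symbol).
#'
#' @param query Non-empty character vector of phenotype ids; ids absent from
#'   the vocabulary are dropped with a warning.
#' @param sets An [enriched_sets()] object.
#' @param vocabulary Optional character vector of valid phenotype ids used
#'   to screen the query (defaults to no screening beyond emptiness).
#' @return Object of class `gene_ranking`: `data.frame` with columns `gene`,
#'   `hits_single`, `hits_pair`, `p_single`, `p_pair`, `p`, `rank`.
#' @export
rank_genes <- function(query, sets, vocabulary = NULL) {
  stopifnot(inherits(sets, "enriched_sets"))
  query <- unique(as.character(query))
  if (!is.null(vocabulary)) {
    bad <- setdiff(query, vocabulary)
    if (length(bad)) {
      warning(length(bad), " query phenotype(s) absent from the vocabulary ",
              "ignored: ", paste(bad, collapse = ", "))
      query <- setdiff(query, bad)
    }
  }
  if (!length(query)) stop("no query phenotypes left after screening")
  qp <- if (length(query) >= 2) {
    pr <- enumerate_pairs(query)
    keys <- paste(pr$a, pr$b, sep = "|")
    keys[keys %in% sets$obs_pairs]  # draws come from the observed universe
  } else character(0)
  rows <- lapply(sets$genes, function(g) {
    sc <- gene_query_score(g, query, qp, sets)
    data.frame(gene = g, hits_single = sc$hits_single,
               hits_pair = sc$hits_pair, p_single = sc$p_single,
               p_pair = sc$p_pair, p = sc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, -(out$hits_single + out$hits_pair), out$gene), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Prioritization accuracy as a function of query size
#'
#' Emulates clinical use on a cohort with known causal genes: repeatedly
#' sample a patient with at least `k` phenotypes, draw `k` of its phenotypes
#' as the query, recompute enrichment with that patient held out (so the
#' evaluated patient contributes nothing to the tables that rank it), rank
#' all genes, and record whether the true gene lands in the top 1/5/10 and
#' its combined p.  More phenotypes should mean more accurate, more
#' significant predictions.
#'
#' @param cohort An [id_cohort()].
#' @param k_values Integer vector of query sizes.
#' @param n_rep Replicates per query size.
#' @param seed RNG seed.
#' @param holdout Recompute enrichment without the sampled patient
#'   (default `TRUE`).
#' @param min_support,alpha Passed to [enriched_sets()].
#' @return `data.frame` with one row per usable `k`: `k`, `n_eval`, `top1`,
#'   `top5`, `top10`, `p_q1`, `p_median`, `p_q3` (quartiles of the true
#'   gene's combined p).  Query sizes no patient can support are skipped
#'   with a warning.
#' @export
evaluate_vs_k <- function(cohort, k_values = c(1L, 2L, 4L, 6L, 8L),
                          n_rep = 200L, seed = 1L, holdout = TRUE,
                          min_support = 5L, alpha = 0.05) {
  stopifnot(inherits(cohort, "id_cohort"), all(k_values >= 1))
  set.seed(as.integer(seed))
  ix <- enrichment_index(cohort)
  full_sets <- enriched_sets(ix, min_support, alpha)
  sizes <- lengths(ix$patient_phenos)
  rows <- list()
  for (k in sort(unique(as.integer(k_values)))) {
    eligible <- names(sizes)[sizes >= k]
    if (!length(eligible)) {
      warning("no patient has at least ", k, " phenotypes; k = ", k,
              " skipped")
      next
    }
    picks <- sample(eligible, n_rep, replace = TRUE)
    res <- vapply(picks, function(pid) {
      query <- sample(ix$patient_phenos[[pid]], k)
      sets <- if (holdout)
        enriched_sets(holdout_index(ix, pid), min_support, alpha)
      else full_sets
      rk <- rank_genes(query, sets)
      true_gene <- ix$patient_gene[[pid]]
      i <- match(true_gene, rk$gene)
      c(rank = rk$rank[i], p = rk$p[i])
    }, c(rank = 0, p = 0))
    rows[[length(rows) + 1L]] <- data.frame(
      k = k, n_eval = length(picks),
      top1 = mean(res["rank", ] <= 1),
      top5 = mean(res["rank", ] <= 5),
      top10 = mean(res["rank", ] <= 10),
      p_q1 = unname(quantile(res["p", ], 0.25)),
      p_median = median(res["p", ]),
      p_q3 = unname(quantile(res["p", ], 0.75)))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(k = integer(), n_eval = integer(), top1 = numeric(),
                      top5 = numeric(), top10 = numeric(), p_q1 = numeric(),
                      p_median = numeric(), p_q3 = numeric())
  out
}
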