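jaccard <- function(s1, s2) {
  u <- length(union(s1, s2))
  if (u == 0) return(0)
  length(intersect(s1, s2)) / u
}

#' Similarity between two patients' phenotype sets
#'
#' `"jaccard"` (default) normalizes the shared-phenotype count by the union
#' size, which compensates for the strong heterogeneity in phenotypes per
#' patient; `"shared-count"` is the raw number of common phenotypes.
#'
#' @param p1,p2 Character vectors of phenotype ids (one patient's set each).
#' @param mode `"jaccard"` or `"shared-count"`.
#' @return A single number: Jaccard in `[0, 1]` or a non-negative count.
#' @export
patient_similarity <- function(p1, p2, mode = c("jaccard", "shared-count")) {
  mode <- match.arg(mode)
  p1 <- unique(as.character(p1)); p2 <- unique(as.character(p2))
  if (mode == "jaccard") jaccard(p1, p2) else length(intersect(p1, p2))
}

#' All-pairs patient similarity matrix
#'
#' @param cohort An [id_cohort()].
#' @param mode As in [patient_similarity()].
#' @return Symmetric numeric matrix with patient ids as dimnames.
#' @export
similarity_matrix <- function(cohort, mode = c("jaccard", "shared-count")) {
  mode <- match.arg(mode)
  ph <- cohort$phenotypes
  pids <- cohort$patients$patient_id
  ids <- sort(unique(ph$phenotype_id))
  m <- matrix(0L, length(pids), length(ids), dimnames = list(pids, ids))
  m[cbind(ph$patient_id, ph$phenotype_id)] <- 1L
  inter <- tcrossprod(m)
  if (mode == "shared-count") return(inter)
  sz <- rowSums(m)
  un <- outer(sz, sz, `+`) - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

#' Intra- versus inter-gene patient similarity
#'
#' Phenotypic convergence per gene: within-gene patient pairs should be more
#' similar than pairs straddling two genes.  For each gene with at least two
#' patients, the mean similarity over its within-gene pairs is compared with
#' the mean over (gene patient, other-gene patient) pairs, with a one-sided
#' Mann-Whitney test (greater); a pooled comparison treats all within-gene
#' pairs against all between-gene pairs.  Pairs are treated as independent
#' observations, an approximation since pairs share patients.
#'
#' @param cohort An [id_cohort()] with at least two genes, at least one of
#'   which has two or more patients.
#' @param mode As in [patient_similarity()].
#' @return List with `per_gene` (`data.frame`: gene, n_patients, mean_intra,
#'   mean_inter, p_value) and `pooled` (list: mean_intra, mean_inter,
#'   n_intra, n_inter, p_value).
#' @export
intra_inter_comparison <- function(cohort,
                                   mode = c("jaccard", "shared-count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "id_cohort"))
  if (length(cohort$gene_index) < 2)
    stop("need at least two genes")
  s <- similarity_matrix(cohort, mode)
  gene_of <- setNames(cohort$patients$gene, cohort$patients$patient_id)
  gene_of <- gene_of[rownames(s)]
  eligible <- names(which(table(gene_of) >= 2))
  if (!length(eligible))
    stop("no gene has two or more patients")
  skipped <- setdiff(unique(gene_of), eligible)
  if (length(skipped))
    message(length(skipped), " gene(s) with a single patient skipped in the",
            " per-gene intra/inter comparison")
  ut <- upper.tri(s)
  same_gene <- outer(gene_of, gene_of, `==`)
  intra_all <- s[ut & same_gene]
  inter_all <- s[ut & !same_gene]
  per_gene <- do.call(rbind, lapply(eligible, function(g) {
    in_g <- gene_of == g
    intra <- s[upper.tri(s) & outer(in_g, in_g, `&`)]
    inter <- as.vector(s[in_g, !in_g])
    p <- if (length(inter))
      suppressWarnings(wilcox.test(intra, inter,
                                   alternative = "greater")$p.value)
    else NA_real_
    data.frame(gene = g, n_patients = sum(in_g),
               mean_intra = mean(intra), mean_inter = mean(inter),
               p_value = p, stringsAsFactors = FALSE)
  }))
  pooled_p <- suppressWarnings(
    wilcox.test(intra_all, inter_all, alternative = "greater")$p.value)
  list(per_gene = per_gene,
       pooled = list(mean_intra = mean(intra_all),
                     mean_inter = mean(inter_all),
                     n_intra = length(intra_all),
                     n_inter = length(inter_all),
                     p_value = pooled_p))
}

#' Same-family versus other-family patient similarity
#'
#' Within one gene, patients from the same family carry the identical
#' variant; their phenotype sets should be more alike than those of the
#' gene's patients from other families.  Units are (gene, mutation site)
#' groups with at least two patients in one family; other-family pairs share
#' the gene but not the family.
#'
#' @param cohort An [id_cohort()] with mutation records.
#' @param mode As in [patient_similarity()].
#' @return List with `per_unit` (`data.frame`: gene, site, n_same_pairs,
#'   n_other_pairs, same_mean, other_mean) and `pooled` (list: mean_same,
#'   mean_other, n_units, p_value from a one-sided paired Wilcoxon over
#'   units).
#' @export
family_comparison <- function(cohort, mode = c("jaccard", "shared-count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "id_cohort"))
  if (!nrow(cohort$mutations))
    stop("cohort has no mutation records")
  s <- similarity_matrix(cohort, mode)
  pat <- cohort$patients
  first_site <- vapply(split(cohort$mutations$site,
                             cohort$mutations$patient_id), `[`, "", 1)
  pat$site <- first_site[pat$patient_id]
  pat <- pat[!is.na(pat$site), , drop = FALSE]

  units <- unique(pat[, c("gene", "site")])
  rows <- lapply(seq_len(nrow(units)), function(i) {
    g <- units$gene[i]; st <- units$site[i]
    members <- pat[pat$gene == g & pat$site == st, , drop = FALSE]
    fams <- split(members$patient_id, members$family_id)
    fams <- fams[lengths(fams) >= 2]
    if (!length(fams)) return(NULL)
    same_vals <- unlist(lapply(fams, function(ids) {
      sub <- s[ids, ids, drop = FALSE]
      sub[upper.tri(sub)]
    }))
    others_by_member <- lapply(fams, function(ids) {
      other <- pat$patient_id[pat$gene == g &
                                !(pat$family_id %in%
                                    members$family_id[
                                      members$patient_id %in% ids])]
      if (!length(other)) return(numeric(0))
      as.vector(s[ids, other, drop = FALSE])
    })
    other_vals <- unlist(others_by_member)
    if (!length(other_vals)) return(NULL)
    data.frame(gene = g, site = st,
               n_same_pairs = length(same_vals),
               n_other_pairs = length(other_vals),
               same_mean = mean(same_vals), other_mean = mean(other_vals),
               stringsAsFactors = FALSE)
  })
  per_unit <- do.call(rbind, rows)
  if (is.null(per_unit))
    stop("no family with two or more patients sharing gene and mutation ",
         "site alongside patients from other families")
  rownames(per_unit) <- NULL
  p <- if (nrow(per_unit) >= 2)
    suppressWarnings(wilcox.test(per_unit$same_mean, per_unit$other_mean,
                                 paired = TRUE,
                                 alternative = "greater")$p.value)
  else NA_real_
  list(per_unit = per_unit,
       pooled = list(mean_same = mean(per_unit$same_mean),
                     mean_other = mean(per_unit$other_mean),
                     n_units = nrow(per_unit), p_value = p))
}

#' Similarity between a gene's phenotype profile and a query set
#'
#' @param gene_profile Character vector of phenotype ids (see
#'   [gene_profiles()]).
#' @param query Non-empty character vector of phenotype ids.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
gene_query_similarity <- function(gene_profile, query) {
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query phenotype set")
  jaccard(unique(as.character(gene_profile)), query)
}

#' Rank all genes by query similarity
#'
#' @param cohort An [id_cohort()].
#' @param query Non-empty character vector of phenotype ids.
#' @param type Profile type passed to [gene_profiles()].
#' @return `data.frame` with `gene`, `score`, `rank` (ties broken
#'   lexicographically by gene), sorted by rank.
#' @export
gene_query_ranking <- function(cohort, query, type = "union") {
  prof <- gene_profiles(cohort, type)
  score <- vapply(prof, gene_query_similarity, 0, query = query)
  ord <- order(-score, names(score))
  data.frame(gene = names(score)[ord], score = unname(score)[ord],
             rank = seq_along(score), stringsAsFactors = FALSE)
}

normalize_phrase <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

token_sort <- function(x) {
  vapply(strsplit(normalize_phrase(x), " ", fixed = TRUE),
         function(tok) paste(sort(tok), collapse = " "), "")
}

token_sort_ratio <- function(query, targets) {
  q <- token_sort(query)
  t <- token_sort(targets)
  d <- as.vector(adist(q, t))
  len <- pmax(nchar(q), nchar(t))
  score <- ifelse(len == 0, ifelse(nchar(t) == nchar(q), 100, 0),
                  100 * (1 - d / len))
  as.integer(round(pmax(0, score)))
}

#' Match a free-text phenotype description to the standard vocabulary
#'
#' Normalizes case and punctuation, sorts tokens (so "speech delayed" and
#' "delayed speech" score identically), and scores each vocabulary entry by
#' a normalized Levenshtein ratio in `[0, 100]` taken as the maximum over
#' the entry's name and synonyms; an exact (normalized) match scores 100.
#'
#' @param query Non-empty free-text string.
#' @param vocabulary `data.frame` with columns `id`, `name` and optionally
#'   `synonyms` (pipe-separated), e.g. an [id_cohort()]'s `vocabulary`.
#' @param top_k Number of matches to return.
#' @return `data.frame` with `phenotype_id`, `name`, `score`, sorted by
#'   (score desc, phenotype id asc).
#' @export
fuzzy_convert <- function(query, vocabulary, top_k = 10L) {
  if (length(query) != 1 || is.na(query) || !nzchar(trimws(query)))
    stop("query must be a single non-empty string")
  if (!nrow(vocabulary)) stop("empty vocabulary")
  syn <- if ("synonyms" %in% names(vocabulary)) vocabulary$synonyms else ""
  score <- vapply(seq_len(nrow(vocabulary)), function(i) {
    cands <- vocabulary$name[i]
    if (nzchar(syn[i]))
      cands <- c(cands, strsplit(syn[i], "|", fixed = TRUE)[[1]])
    max(token_sort_ratio(query, cands))
  }, 0L)
  out <- data.frame(phenotype_id = vocabulary$id, name = vocabulary$name,
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$phenotype_id), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_k)
}
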