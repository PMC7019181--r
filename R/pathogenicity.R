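predictor_features <- function() {
  c("f1_similarity", "f2_hit_single_frac", "f3_hit_pair_frac",
    "f4_neglog10_p", "f5_log_gene_patients", "f6_exclusive_frac",
    "f7_query_commonness")
}

# one (gene, query) feature vector; all inputs come from upstream modules
featurize_gene <- function(gene, query, ix, sets, query_pairs = NULL) {
  if (is.null(query_pairs)) {
    query_pairs <- if (length(query) >= 2) {
      pr <- enumerate_pairs(query)
      keys <- paste(pr$a, pr$b, sep = "|")
      keys[keys %in% sets$obs_pairs]
    } else character(0)
  }
  profile <- ix$phen[ix$k_single[gene, ] > 0L]
  sc <- gene_query_score(gene, query, query_pairs, sets)
  m <- length(query)
  excl <- ix$phen[ix$K_single == ix$k_single[gene, ] &
                    ix$k_single[gene, ] > 0L]
  setNames(c(
    jaccard(profile, query),
    sc$hits_single / m,
    if (m >= 2) sc$hits_pair / choose(m, 2) else 0,
    -log10(max(sc$p, 1e-300)),
    log1p(ix$n_gene[[gene]]),
    mean(query %in% excl),
    mean(ix$K_single[query] / ix$N)
  ), predictor_features())
}

#' Build a labeled training table for the pathogenicity SVM
#'
#' Positives are (true causal gene, patient phenotype set) for every patient,
#' featurized with that patient held out of all enrichment tables (no
#' leakage); negatives swap in randomly sampled non-causal genes at the same
#' phenotype set, so the learner must exploit gene-phenotype compatibility
#' rather than phenotype-count artifacts.
#'
#' @param cohort An [id_cohort()].
#' @param neg_ratio Negatives per positive; fractional ratios are realized
#'   stochastically per patient.
#' @param seed RNG seed (negative sampling).
#' @param min_support,alpha Passed to [enriched_sets()].
#' @return `data.frame` with `patient_id`, `gene`, `label` (1 = causal) and
#'   the seven feature columns.
#' @export
build_dataset <- function(cohort, neg_ratio = 1, seed = 1L,
                          min_support = 5L, alpha = 0.05) {
  stopifnot(inherits(cohort, "id_cohort"), neg_ratio >= 0)
  ix <- enrichment_index(cohort)
  if (neg_ratio > length(ix$genes) - 1)
    stop("neg_ratio = ", neg_ratio, " needs more non-causal genes than the ",
         "cohort has")
  set.seed(as.integer(seed))
  rows <- list()
  for (pid in names(ix$patient_gene)) {
    g <- ix$patient_gene[[pid]]
    query <- ix$patient_phenos[[pid]]
    hix <- holdout_index(ix, pid)
    hsets <- enriched_sets(hix, min_support, alpha)
    qp <- if (length(query) >= 2) {
      pr <- enumerate_pairs(query)
      keys <- paste(pr$a, pr$b, sep = "|")
      keys[keys %in% hsets$obs_pairs]
    } else character(0)
    n_neg <- floor(neg_ratio) + (runif(1) < neg_ratio - floor(neg_ratio))
    negs <- if (n_neg > 0)
      sample(setdiff(ix$genes, g), n_neg) else character(0)
    for (cand in c(g, negs)) {
      f <- featurize_gene(cand, query, hix, hsets, qp)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, gene = cand,
        label = as.integer(cand == g), t(f),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

binary_auc <- function(labels, scores) {
  r <- pROC::roc(labels, scores, levels = c("0", "1"), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  assign
}

scale_fit <- function(x) {
  ctr <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | is.na(s)] <- 1
  list(center = ctr, scale = s)
}

scale_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

#' Train the pathogenicity SVM with repeated stratified cross-validation
#'
#' Radial-basis-function SVM (other parameters at their defaults) with
#' repeated stratified 10-fold cross-validation.  Feature standardization is
#' fitted inside each training fold only, and probability-like scores come
#' from Platt-style logistic calibration fitted on the training folds, so
#' held-out scores never see their own fold.  Variable importance is
#' permutation importance: the AUC drop on a held-out third when one feature
#' column is shuffled, summarized as the median over `importance_reps`
#' independently seeded trainings.
#'
#' @param dataset Output of [build_dataset()] (or any `data.frame` with a
#'   0/1 `label` column and the seven feature columns).
#' @param folds Number of CV folds (default 10).
#' @param repeats Number of CV repetitions.
#' @param seed RNG seed.
#' @param importance_reps Trainings for permutation importance; 0 skips it.
#' @return List with `model` (class `pathogenicity_model`: fitted SVM plus the
#'   full-data standardization) and `report` (class `cv_report`: `folds`,
#'   `repeats`, `fold_auc`, `mean_auc`, `roc` data.frame of pooled held-out
#'   points, `importance` named per-feature medians or `NULL`).
#' @export
train_and_cv <- function(dataset, folds = 10L, repeats = 5L, seed = 1L,
                         importance_reps = 100L) {
  feats <- predictor_features()
  stopifnot(all(feats %in% names(dataset)))
  x <- as.matrix(dataset[, feats])
  y <- factor(dataset$label, levels = c(0, 1))
  if (any(table(y) == 0)) stop("dataset must contain both classes")
  if (nrow(x) < folds) stop("dataset smaller than the number of folds")
  set.seed(as.integer(seed))

  fold_auc <- numeric(0)
  pooled_scores <- numeric(0)
  pooled_labels <- character(0)
  for (r in seq_len(repeats)) {
    fa <- stratified_folds(y, folds)
    for (f in seq_len(folds)) {
      tr <- fa != f; te <- !tr
      sc <- scale_fit(x[tr, , drop = FALSE])
      fit <- e1071::svm(scale_apply(x[tr, , drop = FALSE], sc), y[tr],
                        kernel = "radial", probability = TRUE, scale = FALSE)
      pr <- attr(predict(fit, scale_apply(x[te, , drop = FALSE], sc),
                         probability = TRUE), "probabilities")[, "1"]
      if (length(unique(y[te])) == 2)
        fold_auc <- c(fold_auc, binary_auc(y[te], pr))
      pooled_scores <- c(pooled_scores, pr)
      pooled_labels <- c(pooled_labels, as.character(y[te]))
    }
  }
  roc_obj <- pROC::roc(pooled_labels, pooled_scores, levels = c("0", "1"),
                       direction = "<", quiet = TRUE)
  roc_df <- data.frame(fpr = 1 - roc_obj$specificities,
                       tpr = roc_obj$sensitivities)
  roc_df <- roc_df[order(roc_df$fpr, roc_df$tpr), ]
  rownames(roc_df) <- NULL

  importance <- NULL
  if (importance_reps > 0) {
    drops <- matrix(NA_real_, importance_reps, length(feats),
                    dimnames = list(NULL, feats))
    for (r in seq_len(importance_reps)) {
      set.seed(as.integer(seed) + r)
      third <- stratified_folds(y, 3L) == 1L
      sc <- scale_fit(x[!third, , drop = FALSE])
      fit <- e1071::svm(scale_apply(x[!third, , drop = FALSE], sc), y[!third],
                        kernel = "radial", probability = TRUE, scale = FALSE)
      xte <- scale_apply(x[third, , drop = FALSE], sc)
      base <- binary_auc(y[third],
                         attr(predict(fit, xte, probability = TRUE),
                              "probabilities")[, "1"])
      for (j in seq_along(feats)) {
        xp <- xte
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        drops[r, j] <- base - binary_auc(
          y[third], attr(predict(fit, xp, probability = TRUE),
                         "probabilities")[, "1"])
      }
    }
    importance <- apply(drops, 2, median)
  }

  sc_full <- scale_fit(x)
  fit_full <- e1071::svm(scale_apply(x, sc_full), y, kernel = "radial",
                         probability = TRUE, scale = FALSE)
  model <- structure(list(svm = fit_full, center = sc_full$center,
                          scale = sc_full$scale, features = feats),
                     class = "pathogenicity_model")
  report <- structure(list(folds = folds, repeats = repeats,
                           fold_auc = fold_auc, mean_auc = mean(fold_auc),
                           roc = roc_df, importance = importance),
                      class = "cv_report")
  list(model = model, report = report)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV x %d repeats: mean AUC = %.3f\n",
              x$folds, x$repeats, x$mean_auc))
  if (!is.null(x$importance)) {
    cat("  permutation importance (median AUC drop):\n")
    imp <- sort(x$importance, decreasing = TRUE)
    for (nm in names(imp)) cat(sprintf("    %-22s %+.4f\n", nm, imp[nm]))
  }
  invisible(x)
}

#' Dichotomize a pathogenic score
#'
#' The decision rule of the result table: `"Probably"` for scores strictly
#' above 0.5, `"Less likely"` otherwise (a score of exactly 0.5 is not
#' called pathogenic).
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @return Character vector of labels.
#' @export
pathogenicity_label <- function(score) {
  ifelse(score > 0.5, "Probably", "Less likely")
}

#' Score candidate genes for a patient's phenotype set
#'
#' Applies a trained model to each candidate gene, reporting the seven
#' columns of the standard result table: `GeneSymbol`,
#' `PathogenicGeneRank` (the candidate's rank among *all* cohort genes by
#' SVM score), `PathogenicScore` (calibrated probability), `Pathogenicity`
#' (`"Probably"` when the score exceeds 0.5, else `"Less likely"`),
#' `SimilarRank` / `SimilarScore` (Jaccard similarity between the gene's
#' phenotype profile and the query, ranked among all genes) and `Phenotypes`
#' (the gene's profile phenotypes matched by the query, semicolon-joined).
#' Candidate genes unknown to the cohort get score 0, `NA` ranks and a
#' warning.
#'
#' @param model An `pathogenicity_model` from [train_and_cv()].
#' @param candidate_genes Non-empty character vector of gene symbols.
#' @param query Non-empty character vector of phenotype ids.
#' @param cohort The [id_cohort()] backing the model.
#' @param min_support,alpha Passed to [enriched_sets()].
#' @return `data.frame` with exactly the seven columns above, candidates
#'   ordered by `PathogenicGeneRank` (unknown genes last).
#' @export
predict_pathogenicity <- function(model, candidate_genes, query, cohort,
                                  min_support = 5L, alpha = 0.05) {
  stopifnot(inherits(model, "pathogenicity_model"), inherits(cohort, "id_cohort"))
  candidate_genes <- unique(as.character(candidate_genes))
  query <- unique(as.character(query))
  if (!length(candidate_genes)) stop("empty candidate gene list")
  if (!length(query)) stop("empty query phenotype set")
  bad <- setdiff(query, cohort$vocabulary$id)
  if (length(bad)) {
    warning(length(bad), " query phenotype(s) absent from the vocabulary ",
            "ignored: ", paste(bad, collapse = ", "))
    query <- setdiff(query, bad)
    if (!length(query)) stop("no query phenotypes left after screening")
  }
  ix <- enrichment_index(cohort)
  sets <- enriched_sets(ix, min_support, alpha)
  fmat <- t(vapply(ix$genes, featurize_gene, numeric(7), query = query,
                   ix = ix, sets = sets))
  prob <- attr(predict(model$svm,
                       scale_apply(fmat, list(center = model$center,
                                              scale = model$scale)),
                       probability = TRUE), "probabilities")[, "1"]
  path_rank <- setNames(seq_along(ix$genes),
                        ix$genes[order(-prob, ix$genes)])
  sim <- gene_query_ranking(cohort, query)
  sim_rank <- setNames(sim$rank, sim$gene)
  sim_score <- setNames(sim$score, sim$gene)
  prof <- gene_profiles(cohort, "union")

  unknown <- setdiff(candidate_genes, ix$genes)
  if (length(unknown))
    warning("candidate gene(s) unknown to the cohort scored 0: ",
            paste(unknown, collapse = ", "))
  rows <- lapply(candidate_genes, function(g) {
    if (g %in% ix$genes) {
      data.frame(GeneSymbol = g,
                 PathogenicGeneRank = unname(path_rank[g]),
                 PathogenicScore = unname(prob[g]),
                 Pathogenicity = pathogenicity_label(prob[g]),
                 SimilarRank = unname(sim_rank[g]),
                 SimilarScore = unname(sim_score[g]),
                 Phenotypes = paste(sort(intersect(prof[[g]], query)),
                                    collapse = ";"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(GeneSymbol = g, PathogenicGeneRank = NA_integer_,
                 PathogenicScore = 0, Pathogenicity = "Less likely",
                 SimilarRank = NA_integer_, SimilarScore = 0,
                 Phenotypes = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$PathogenicGeneRank), out$PathogenicGeneRank), ]
  rownames(out) <- NULL
  out
}

#' Cumulative top-N recovery curve
#'
#' @param ranks Integer vector: rank of the true causal gene in each
#'   held-out evaluation (NA = not ranked).
#' @param n_max Largest N.
#' @return `data.frame` with `N` (1..n_max) and `rate`, the fraction of
#'   evaluations whose true gene ranked within the top N; non-decreasing.
#' @export
topn_curve <- function(ranks, n_max) {
  stopifnot(length(ranks) >= 1, n_max >= 1)
  r <- ifelse(is.na(ranks), Inf, ranks)
  data.frame(N = seq_len(n_max),
             rate = vapply(seq_len(n_max), function(N) mean(r <= N), 0))
}
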