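#' Mutation type vocabulary
#'
#' The closed six-way classification of pathogenic variants used throughout
#' the package: missense/nonsense, splicing, small indels, gross deletions,
#' gross insertions/duplications, and a residual class.
#'
#' @return Character vector of the six canonical mutation-type labels.
#' @export
mutation_types <- function() {
  c("missense/nonsense", "splicing", "small-indel",
    "gross-deletion", "gross-insertion/duplication", "other")
}

#' Map free-text mutation descriptions to the canonical six-way types
#'
#' Curated literature describes variant classes in many phrasings
#' ("non-sense", "gross insertions (most duplications)", "frameshift
#' indel" ...).  This maps them onto [mutation_types()]; anything
#' unrecognised becomes `"other"`.
#'
#' @param x Character vector of free-text mutation-type descriptors.
#' @return Character vector of the same length drawn from [mutation_types()].
#' @examples
#' map_mutation_type(c("Missense", "gross insertions (most duplications)"))
#' @export
map_mutation_type <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  lx <- tolower(x)
  canon <- mutation_types()
  exact <- match(lx, canon)
  out[!is.na(exact)] <- canon[exact[!is.na(exact)]]
  todo <- is.na(exact) & !is.na(lx) & nzchar(lx)
  hit <- function(pat) todo & grepl(pat, lx)
  # order matters: "gross deletion" must not fall through to plain indel
  out[hit("missense|nonsense|non-sense|stop[- ]?gain")] <- "missense/nonsense"
  out[hit("splic")] <- "splicing"
  out[hit("gross +del|large +del|^deletion|gross-deletion")] <- "gross-deletion"
  out[hit("gross +ins|large +ins|duplication|gross-insertion")] <-
    "gross-insertion/duplication"
  out[hit("indel|frameshift|small +del|small +ins")] <- "small-indel"
  out[is.na(x) | !nzchar(trimws(x))] <- NA_character_
  out
}

#' Construct a validated patient cohort
#'
#' The central container: one causal gene per patient, a non-empty set of
#' standard phenotype identifiers per patient, optional mutation records,
#' family groupings, and a phenotype vocabulary.
#'
#' @param patients `data.frame` with columns `patient_id`, `gene`,
#'   `family_id` (one row per patient).
#' @param phenotypes Long `data.frame` with columns `patient_id`,
#'   `phenotype_id` (one row per patient-phenotype; duplicates are removed).
#' @param mutations Optional `data.frame` with columns `patient_id`, `site`,
#'   `mtype`; `mtype` is passed through [map_mutation_type()].
#' @param vocabulary Optional `data.frame` with columns `id`, `name` and
#'   optionally `synonyms` (pipe-separated).  Phenotype ids observed in
#'   patients but absent from the vocabulary are appended with `name = id`
#'   and a warning.
#' @return An object of class `id_cohort`: a list with elements `patients`,
#'   `phenotypes`, `mutations`, `vocabulary` plus derived indexes
#'   `gene_index` (gene -> patient ids) and `pheno_index`
#'   (phenotype -> patient ids).
#' @export
id_cohort <- function(patients, phenotypes, mutations = NULL,
                      vocabulary = NULL) {
  stopifnot(is.data.frame(patients), is.data.frame(phenotypes))
  need <- c("patient_id", "gene", "family_id")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patients table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(c("patient_id", "phenotype_id") %in% names(phenotypes)))
    stop("phenotypes table needs columns patient_id, phenotype_id")

  patients <- data.frame(
    patient_id = as.character(patients$patient_id),
    gene = as.character(patients$gene),
    family_id = as.character(patients$family_id),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    stop("duplicate patient id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(patients$gene) | is.na(patients$gene)))
    stop("every patient needs a non-empty causal gene symbol")

  phenotypes <- unique(data.frame(
    patient_id = as.character(phenotypes$patient_id),
    phenotype_id = as.character(phenotypes$phenotype_id),
    stringsAsFactors = FALSE
  ))
  unknown_pat <- setdiff(phenotypes$patient_id, patients$patient_id)
  if (length(unknown_pat))
    stop("phenotype rows reference unknown patient(s): ",
         paste(unknown_pat, collapse = ", "))
  empty <- setdiff(patients$patient_id, phenotypes$patient_id)
  if (length(empty))
    stop("patient(s) with empty phenotype set: ",
         paste(empty, collapse = ", "))
  if (any(!nzchar(phenotypes$phenotype_id)))
    stop("empty phenotype id in phenotypes table")

  if (is.null(mutations)) {
    mutations <- data.frame(patient_id = character(), gene = character(),
                            site = character(), mtype = character(),
                            stringsAsFactors = FALSE)
  } else {
    mutations <- data.frame(
      patient_id = as.character(mutations$patient_id),
      site = as.character(mutations$site),
      mtype = map_mutation_type(mutations$mtype),
      stringsAsFactors = FALSE
    )
    bad <- setdiff(mutations$patient_id, patients$patient_id)
    if (length(bad))
      stop("mutation rows reference unknown patient(s): ",
           paste(bad, collapse = ", "))
    # a patient's mutations always carry its causal gene
    mutations$gene <-
      patients$gene[match(mutations$patient_id, patients$patient_id)]
    mutations <- mutations[, c("patient_id", "gene", "site", "mtype")]
  }

  observed <- sort(unique(phenotypes$phenotype_id))
  if (is.null(vocabulary)) {
    vocabulary <- data.frame(id = observed, name = observed,
                             synonyms = "", stringsAsFactors = FALSE)
  } else {
    vocabulary <- data.frame(
      id = as.character(vocabulary$id),
      name = as.character(vocabulary$name),
      synonyms = if ("synonyms" %in% names(vocabulary))
        as.character(vocabulary$synonyms) else "",
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(vocabulary$id))
      stop("duplicate phenotype id(s) in vocabulary")
    if (any(!nzchar(vocabulary$name)))
      stop("vocabulary names must be non-empty")
    new <- setdiff(observed, vocabulary$id)
    if (length(new)) {
      warning(length(new), " phenotype id(s) absent from the vocabulary ",
              "were added with name = id (e.g. ", new[1], ")")
      vocabulary <- rbind(vocabulary,
                          data.frame(id = new, name = new, synonyms = "",
                                     stringsAsFactors = FALSE))
    }
  }
  vocabulary <- vocabulary[order(vocabulary$id), , drop = FALSE]
  rownames(vocabulary) <- NULL

  ord <- order(phenotypes$patient_id, phenotypes$phenotype_id)
  phenotypes <- phenotypes[ord, , drop = FALSE]
  rownames(phenotypes) <- NULL
  rownames(patients) <- NULL

  structure(
    list(
      patients = patients,
      phenotypes = phenotypes,
      mutations = mutations,
      vocabulary = vocabulary,
      gene_index = split(patients$patient_id, patients$gene),
      pheno_index = split(phenotypes$patient_id, phenotypes$phenotype_id)
    ),
    class = "id_cohort"
  )
}

#' @export
print.id_cohort <- function(x, ...) {
  cat("<id_cohort>", nrow(x$patients), "patients |",
      length(x$gene_index), "genes |",
      length(x$pheno_index), "distinct phenotypes |",
      nrow(x$mutations), "mutation records\n")
  invisible(x)
}

#' Per-patient phenotype sets
#'
#' @param cohort An [id_cohort()].
#' @return Named list mapping patient id to its character vector of
#'   phenotype ids (sorted).
#' @export
patient_phenotypes <- function(cohort) {
  split(cohort$phenotypes$phenotype_id, cohort$phenotypes$patient_id)
}

#' Per-gene phenotype profiles
#'
#' A gene's profile is either the union of phenotypes seen in its patients
#' or its enriched-phenotype set (see [enriched_sets()]).
#'
#' @param cohort An [id_cohort()].
#' @param type `"union"` (default) or `"enriched"`.
#' @param ... Passed to [enriched_sets()] when `type = "enriched"`.
#' @return Named list gene -> character vector of phenotype ids.
#' @export
gene_profiles <- function(cohort, type = c("union", "enriched"), ...) {
  type <- match.arg(type)
  if (type == "union") {
    gene_of <- cohort$patients$gene[
      match(cohort$phenotypes$patient_id, cohort$patients$patient_id)]
    lapply(split(cohort$phenotypes$phenotype_id, gene_of),
           function(v) sort(unique(v)))
  } else {
    sets <- enriched_sets(cohort, ...)
    sets$single
  }
}
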