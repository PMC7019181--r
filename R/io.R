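#' Read a cohort file
#'
#' Two on-disk layouts are supported.  TSV: one row per (patient, phenotype)
#' with columns `patient_id`, `gene`, `family_id`, `phenotype_id` and
#' optionally `phenotype_name`, `mutation_site`, `mutation_type`; a patient's
#' mutation columns hold pipe-separated parallel lists repeated on each of
#' its rows.  JSON: an object with a `patients` array (fields `id`, `gene`,
#' `family`, `phenotypes`, `mutations`) and an optional `vocabulary` array.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @param vocabulary Optional vocabulary `data.frame` (or path to a
#'   vocabulary TSV, see [load_vocabulary()]) overriding any embedded one.
#' @return A validated [id_cohort()].
#' @export
load_cohort <- function(path, format = c("auto", "tsv", "json"),
                        vocabulary = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (is.character(vocabulary)) vocabulary <- load_vocabulary(vocabulary)
  if (format == "tsv") load_cohort_tsv(path, vocabulary)
  else load_cohort_json(path, vocabulary)
}

load_cohort_tsv <- function(path, vocabulary = NULL) {
  tab <- read.delim(path, colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  need <- c("patient_id", "gene", "family_id", "phenotype_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("cohort TSV is missing column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    bad <- which(!nzchar(trimws(tab[[col]])))
    if (length(bad))
      stop("malformed row ", bad[1], ": empty field '", col, "'")
  }
  first <- !duplicated(tab$patient_id)
  patients <- data.frame(patient_id = tab$patient_id[first],
                         gene = tab$gene[first],
                         family_id = tab$family_id[first],
                         stringsAsFactors = FALSE)
  # a patient id must not recur with a different gene or family
  for (col in c("gene", "family_id")) {
    ref <- patients[[col]][match(tab$patient_id, patients$patient_id)]
    bad <- which(ref != tab[[col]])
    if (length(bad))
      stop("duplicate patient id '", tab$patient_id[bad[1]],
           "' with conflicting ", col, " at row ", bad[1])
  }
  phenotypes <- tab[, c("patient_id", "phenotype_id")]

  mutations <- NULL
  if (all(c("mutation_site", "mutation_type") %in% names(tab))) {
    mut_rows <- tab[first & nzchar(tab$mutation_site), , drop = FALSE]
    if (nrow(mut_rows)) {
      parts <- lapply(seq_len(nrow(mut_rows)), function(i) {
        sites <- strsplit(mut_rows$mutation_site[i], "|", fixed = TRUE)[[1]]
        types <- strsplit(mut_rows$mutation_type[i], "|", fixed = TRUE)[[1]]
        if (length(sites) != length(types))
          stop("malformed row for patient ", mut_rows$patient_id[i],
               ": mutation_site and mutation_type lists differ in length")
        data.frame(patient_id = mut_rows$patient_id[i], site = sites,
                   mtype = types, stringsAsFactors = FALSE)
      })
      mutations <- do.call(rbind, parts)
    }
  }

  embedded <- NULL
  if (is.null(vocabulary) && "phenotype_name" %in% names(tab)) {
    keep <- !duplicated(tab$phenotype_id) & nzchar(tab$phenotype_name)
    if (any(keep))
      embedded <- data.frame(id = tab$phenotype_id[keep],
                             name = tab$phenotype_name[keep],
                             stringsAsFactors = FALSE)
  }
  id_cohort(patients, phenotypes, mutations,
            if (is.null(vocabulary)) embedded else vocabulary)
}

load_cohort_json <- function(path, vocabulary = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pats <- obj$patients
  if (is.null(pats)) stop("cohort JSON has no 'patients' array")
  get <- function(p, k) if (is.null(p[[k]])) "" else as.character(p[[k]])
  patients <- data.frame(
    patient_id = vapply(pats, get, "", k = "id"),
    gene = vapply(pats, get, "", k = "gene"),
    family_id = vapply(pats, get, "", k = "family"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(pats)) {
    if (!nzchar(patients$patient_id[i]))
      stop("malformed patient object ", i, ": empty field 'id'")
    if (!length(pats[[i]]$phenotypes))
      stop("patient(s) with empty phenotype set: ", patients$patient_id[i])
  }
  phenotypes <- do.call(rbind, lapply(seq_along(pats), function(i) {
    data.frame(patient_id = patients$patient_id[i],
               phenotype_id = unlist(pats[[i]]$phenotypes, use.names = FALSE),
               stringsAsFactors = FALSE)
  }))
  muts <- do.call(rbind, lapply(seq_along(pats), function(i) {
    m <- pats[[i]]$mutations
    if (!length(m)) return(NULL)
    data.frame(patient_id = patients$patient_id[i],
               site = vapply(m, get, "", k = "site"),
               mtype = vapply(m, get, "", k = "type"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(vocabulary) && !is.null(obj$vocabulary)) {
    vocabulary <- data.frame(
      id = vapply(obj$vocabulary, get, "", k = "id"),
      name = vapply(obj$vocabulary, get, "", k = "name"),
      synonyms = vapply(obj$vocabulary, function(v)
        paste(unlist(v$synonyms), collapse = "|"), ""),
      stringsAsFactors = FALSE
    )
  }
  id_cohort(patients, phenotypes, muts, vocabulary)
}

#' Write a cohort file
#'
#' Inverse of [load_cohort()]; round-trips patients, phenotype sets,
#' mutations and (for JSON) the vocabulary.
#'
#' @param cohort An [id_cohort()].
#' @param path Output file.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "tsv") {
    ph <- cohort$phenotypes
    pat <- cohort$patients[match(ph$patient_id, cohort$patients$patient_id), ]
    voc <- cohort$vocabulary
    msite <- vapply(split(cohort$mutations$site, cohort$mutations$patient_id),
                    paste, "", collapse = "|")
    mtype <- vapply(split(cohort$mutations$mtype, cohort$mutations$patient_id),
                    paste, "", collapse = "|")
    out <- data.frame(
      patient_id = ph$patient_id,
      gene = pat$gene,
      family_id = pat$family_id,
      phenotype_id = ph$phenotype_id,
      phenotype_name = voc$name[match(ph$phenotype_id, voc$id)],
      mutation_site = ifelse(is.na(msite[ph$patient_id]), "",
                             msite[ph$patient_id]),
      mutation_type = ifelse(is.na(mtype[ph$patient_id]), "",
                             mtype[ph$patient_id]),
      stringsAsFactors = FALSE
    )
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    phenos <- patient_phenotypes(cohort)
    muts <- split(cohort$mutations[, c("site", "mtype")],
                  cohort$mutations$patient_id)
    pats <- lapply(seq_len(nrow(cohort$patients)), function(i) {
      pid <- cohort$patients$patient_id[i]
      m <- muts[[pid]]
      list(id = pid, gene = cohort$patients$gene[i],
           family = cohort$patients$family_id[i],
           phenotypes = as.list(phenos[[pid]]),
           mutations = if (is.null(m)) list() else
             lapply(seq_len(nrow(m)), function(j)
               list(site = m$site[j], type = m$mtype[j])))
    })
    voc <- lapply(seq_len(nrow(cohort$vocabulary)), function(i) {
      syn <- cohort$vocabulary$synonyms[i]
      list(id = cohort$vocabulary$id[i], name = cohort$vocabulary$name[i],
           synonyms = if (nzchar(syn))
             as.list(strsplit(syn, "|", fixed = TRUE)[[1]]) else list())
    })
    jsonlite::write_json(list(patients = pats, vocabulary = voc), path,
                         auto_unbox = TRUE, pretty = FALSE)
  }
  invisible(path)
}

#' Read a phenotype vocabulary TSV
#'
#' Columns: `id`, `name`, optional `synonyms` (pipe-separated).
#'
#' @param path Vocabulary file.
#' @return `data.frame` with columns `id`, `name`, `synonyms`.
#' @export
load_vocabulary <- function(path) {
  v <- read.delim(path, colClasses = "character", na.strings = NULL)
  if (!all(c("id", "name") %in% names(v)))
    stop("vocabulary TSV needs columns id, name")
  if (!"synonyms" %in% names(v)) v$synonyms <- ""
  v[, c("id", "name", "synonyms")]
}
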