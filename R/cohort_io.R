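#' Construct a clinical cohort object
#'
#' A clinical cohort is a data frame with one row per patient and columns
#' `patient_id`, `time` (survival in days) and `event` (1 = death observed,
#' 0 = right-censored).  All survival statistics in the package consume this
#' single shared structure.
#'
#' @param patient_id character vector of unique patient identifiers.
#' @param time nonnegative survival times in days.
#' @param event event indicators, each 0 or 1.
#' @return A `clinical_cohort` data frame.
#' @export
clinical_cohort <- function(patient_id, time, event) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id))
    stop("duplicate patient id(s): ",
         paste(unique(patient_id[duplicated(patient_id)]), collapse = ", "))
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(patient_id) || length(event) != length(patient_id))
    stop("patient_id, time and event must have equal length")
  if (any(!is.finite(time)) || any(time < 0)) {
    bad <- which(!is.finite(time) | time < 0)
    stop("non-finite or negative survival time for patient(s): ",
         paste(patient_id[bad], collapse = ", "))
  }
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 or 1")
  out <- data.frame(patient_id = patient_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_cohort", "data.frame")
  out
}

#' Read a clinical survival table
#'
#' Expects a tab-delimited file with columns `patient_id`, `days_to_death`
#' and `days_to_last_followup` (blank/NA = missing) plus any number of free
#' annotation columns.  `days_to_death` yields an uncensored observation
#' (event = 1); patients without a death time but with a follow-up time are
#' right-censored at that time (event = 0); patients with neither are
#' dropped.  Patients whose annotation fields contain any of
#' `exclusion_terms` (fixed, case-insensitive substring match) are removed
#' before survival parsing, mirroring the removal of clinically confounded
#' patients (e.g. prior or synchronous malignancies) from an analysis
#' cohort.
#'
#' @param path path to the clinical TSV.
#' @param exclusion_terms character vector of annotation substrings that
#'   disqualify a patient.  Default: prior/synchronous malignancy phrases.
#'   Pass `character(0)` to disable annotation-based removal.
#' @return A [clinical_cohort()] with a `report` attribute counting each
#'   removal class (`n_input`, `n_excluded_annotation`, `n_missing_survival`,
#'   `n_retained`).
#' @export
read_clinical <- function(path,
                          exclusion_terms = c("Prior malignancy",
                                              "Synchronous malignancy")) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  req <- c("patient_id", "days_to_death", "days_to_last_followup")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient id(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  n_input <- nrow(df)

  ann_cols <- setdiff(names(df), req)
  excluded <- rep(FALSE, nrow(df))
  if (length(exclusion_terms) && length(ann_cols)) {
    ann <- df[, ann_cols, drop = FALSE]
    for (term in tolower(exclusion_terms)) {
      hit <- Reduce(`|`, lapply(ann, function(col)
        !is.na(col) & grepl(term, tolower(col), fixed = TRUE)))
      excluded <- excluded | hit
    }
  }
  df2 <- df[!excluded, , drop = FALSE]

  dtd <- suppressWarnings(as.numeric(df2$days_to_death))
  dtf <- suppressWarnings(as.numeric(df2$days_to_last_followup))
  has_death <- !is.na(dtd)
  has_fup <- !is.na(dtf)
  usable <- has_death | has_fup
  time <- ifelse(has_death, dtd, dtf)
  if (any(usable & (time < 0))) {
    bad <- df2$patient_id[usable & time < 0]
    stop("negative survival time for patient(s): ",
         paste(bad, collapse = ", "))
  }
  cohort <- clinical_cohort(df2$patient_id[usable], time[usable],
                            as.numeric(has_death[usable]))
  attr(cohort, "report") <- list(
    n_input = n_input,
    n_excluded_annotation = sum(excluded),
    n_missing_survival = sum(!usable),
    n_retained = nrow(cohort))
  cohort
}

#' Read a feature-by-patient abundance matrix
#'
#' First column: feature (transcript or gene) identifiers; header row:
#' patient identifiers; body: nonnegative TPM values.  Non-numeric or
#' negative cells and ragged or duplicated rows are hard errors, with
#' coordinates in the message.
#'
#' @param path path to the abundance TSV.
#' @return numeric matrix, features in rows, patients in columns.
#' @export
read_abundance <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1)
    stop("ragged abundance table: rows have ", paste(unique(nf),
         collapse = "/"), " fields")
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric abundance at feature '", ids[bad[1]],
           "', patient '", names(body)[j], "': '", body[[j]][bad[1]], "'")
    m[, j] <- v
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative abundance at feature '", rownames(m)[neg[1, 1]],
         "', patient '", colnames(m)[neg[1, 2]], "'")
  m
}

#' Read a transcript-to-gene map
#'
#' Tab-delimited columns `transcript_id`, `gene_id`, `biotype`.  Every
#' transcript must map to exactly one gene.
#'
#' @param path path to the map TSV.
#' @return data frame with the three columns and an `is_protein_coding`
#'   logical derived from the biotype.
#' @export
read_feature_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("transcript_id", "gene_id", "biotype")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("feature map lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("transcript(s) mapped more than once: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
               collapse = ", "))
  df$is_protein_coding <- df$biotype == "protein_coding"
  df
}

#' Sum transcript abundances to gene level
#'
#' Gene abundance is estimated as the sum of its transcripts' TPM values,
#' per patient.
#'
#' @param m transcript-level abundance matrix (from [read_abundance()]).
#' @param map feature map data frame with `transcript_id` and `gene_id`
#'   columns (see [read_feature_map()]).
#' @param skip_unmapped if `TRUE`, transcripts absent from the map are
#'   dropped (and counted in the `report` attribute) instead of raising an
#'   error.
#' @return gene-level abundance matrix with a `report` attribute.
#' @export
aggregate_to_genes <- function(m, map, skip_unmapped = FALSE) {
  idx <- match(rownames(m), map$transcript_id)
  unmapped <- rownames(m)[is.na(idx)]
  if (length(unmapped)) {
    if (!skip_unmapped)
      stop("unmapped transcript(s): ", paste(unmapped, collapse = ", "))
    m <- m[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  genes <- map$gene_id[idx]
  out <- rowsum(m, group = genes, reorder = TRUE)
  out <- as.matrix(out)
  attr(out, "report") <- list(n_transcripts = length(genes) +
                                length(unmapped),
                              n_unmapped_skipped = length(unmapped),
                              n_genes = nrow(out))
  out
}

#' Filter features eligible for the survival screen
#'
#' A feature is eligible when the fraction of patients expressing it
#' (TPM strictly greater than zero) is at least `1 - l`, where `l` is the
#' minimum percentile threshold of the scan; below that the low-expression
#' group of every allowed split would be dominated by ties at zero.
#' Features with an identical value in all patients are also dropped:
#' no informative split exists for them.
#'
#' @param m abundance matrix.
#' @param l minimum percentile threshold, `0 < l < 0.5` (default 0.15).
#' @return list with `matrix` (eligible features) and `report` (dropped
#'   feature ids by class).
#' @export
filter_eligible <- function(m, l = 0.15) {
  stopifnot(is.matrix(m), l > 0, l < 0.5)
  frac_expr <- rowMeans(m > 0)
  constant <- apply(m, 1, function(x) max(x) == min(x))
  low <- frac_expr < (1 - l) & !constant
  keep <- !low & !constant
  list(matrix = m[keep, , drop = FALSE],
       report = list(dropped_low_expression = rownames(m)[low],
                     dropped_constant = rownames(m)[constant],
                     n_kept = sum(keep)))
}
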