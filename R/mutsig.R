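## Mutational-signature validation: consensus SNV calls, 96-context
## substitution profiles, non-negative signature refitting, and the
## group-comparison statistics.

.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 substitution-in-context classes, in canonical order
#'
#' Six pyrimidine-reference substitution classes (C>A, C>G, C>T, T>A,
#' T>C, T>G), each stratified by the four 5' and four 3' flanking bases;
#' within a class the 5' base varies slowest.  Names follow the
#' `A[C>T]G` convention.
#'
#' @return character vector of length 96.
#' @export
mut_classes_96 <- function() {
  out <- character(0)
  for (s in .SUBS)
    for (b5 in .BASES)
      for (b3 in .BASES)
        out <- c(out, paste0(b5, "[", s, "]", b3))
  out
}

.revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(.COMP[ch])), collapse = ""), character(1))
}

#' Construct a mutation catalog
#'
#' @param patient_id,caller,chrom,pos,ref,alt,context record vectors
#'   (`context` optional: trinucleotide string centred on the mutated
#'   base, or `NA`).
#' @return A `mutation_catalog` data frame.
#' @export
mutation_catalog <- function(patient_id, caller, chrom, pos, ref, alt,
                             context = NA_character_) {
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  out <- data.frame(patient_id = as.character(patient_id),
                    caller = as.character(caller),
                    chrom = as.character(chrom),
                    pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    context = as.character(context),
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Read somatic variant calls from a MAF-style table
#'
#' Tab-delimited, 1-based coordinates.  Column names are matched against
#' both plain (`patient_id`, `chrom`, `pos`, `ref`, `alt`, `caller`,
#' `context`) and MAF-standard spellings (`Tumor_Sample_Barcode`,
#' `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`).
#'
#' @param path path to the file.
#' @param caller caller name to assign when the file has no caller
#'   column.
#' @return A [mutation_catalog()].
#' @export
read_maf <- function(path, caller = NULL) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, comment.char = "#")
  pick <- function(candidates, required = TRUE) {
    i <- which(tolower(names(df)) %in% tolower(candidates))
    if (!length(i)) {
      if (required)
        stop("MAF lacks a column among: ",
             paste(candidates, collapse = ", "))
      return(NULL)
    }
    df[[i[1]]]
  }
  pat <- pick(c("patient_id", "Tumor_Sample_Barcode"))
  chrom <- pick(c("chrom", "Chromosome"))
  pos <- pick(c("pos", "Start_Position", "Start_position"))
  ref <- pick(c("ref", "Reference_Allele"))
  alt <- pick(c("alt", "Tumor_Seq_Allele2"))
  cl <- pick(c("caller", "Center"), required = FALSE)
  if (is.null(cl)) {
    if (is.null(caller))
      stop("file has no caller column; supply `caller =`")
    cl <- caller
  }
  ctx <- pick(c("context", "Trinucleotide_Context"), required = FALSE)
  if (is.null(ctx)) ctx <- NA_character_
  mutation_catalog(pat, cl, chrom, pos, ref, alt, ctx)
}

#' Consensus mutations found by every required caller
#'
#' A (patient, chrom, pos, ref, alt) record is retained iff it is present
#' for each caller in `required_callers`; the output is the untagged
#' consensus catalog.
#'
#' @param catalog a [mutation_catalog()] with caller tags.
#' @param required_callers caller names that must all report a record.
#' @return consensus [mutation_catalog()] (caller column set to
#'   `"consensus"`).
#' @export
intersect_callers <- function(catalog, required_callers) {
  required_callers <- unique(required_callers)
  absent <- setdiff(required_callers, unique(catalog$caller))
  if (length(absent))
    stop("required caller(s) absent from catalog: ",
         paste(absent, collapse = ", "))
  sub <- catalog[catalog$caller %in% required_callers, , drop = FALSE]
  key <- paste(sub$patient_id, sub$chrom, sub$pos, sub$ref, sub$alt,
               sep = "\r")
  ## count distinct callers per record key
  kc <- unique(data.frame(key = key, caller = sub$caller,
                          stringsAsFactors = FALSE))
  tab <- table(kc$key)
  keep_keys <- names(tab)[tab == length(required_callers)]
  out <- sub[key %in% keep_keys & !duplicated(key), , drop = FALSE]
  out$caller <- "consensus"
  rownames(out) <- NULL
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Build 96-context mutation profiles per patient
#'
#' Only single-nucleotide variants (single-base ACGT ref and alt) are
#' profiled.  The trinucleotide context comes from the catalog's
#' `context` column or is extracted from `ref_seqs` (positions
#' pos-1..pos+1, 1-based).  Purine-reference SNVs are reverse-complemented
#' to the pyrimidine convention before binning.  Records with non-ACGT
#' context, or whose context middle base contradicts the ref allele, are
#' skipped and counted.
#'
#' @param consensus a consensus [mutation_catalog()].
#' @param ref_seqs optional named character vector/list of chromosome
#'   sequences used when a record has no inline context.
#' @param patients optional patient ids to include even with zero SNVs
#'   (all-zero profile rows).
#' @return integer matrix, patients x 96, columns [mut_classes_96()];
#'   skip counts in attribute `report`.
#' @export
build_profiles <- function(consensus, ref_seqs = NULL, patients = NULL) {
  cls <- mut_classes_96()
  snv <- consensus[nchar(consensus$ref) == 1 & nchar(consensus$alt) == 1 &
                     consensus$ref %in% .BASES &
                     consensus$alt %in% .BASES, , drop = FALSE]
  ctx <- snv$context
  need <- is.na(ctx) | !nzchar(ctx)
  if (any(need)) {
    if (is.null(ref_seqs))
      stop("records without inline context and no ref_seqs supplied")
    ctx[need] <- vapply(which(need), function(i) {
      seq <- ref_seqs[[snv$chrom[i]]]
      if (is.null(seq)) return(NA_character_)
      substr(seq, snv$pos[i] - 1, snv$pos[i] + 1)
    }, character(1))
  }
  badlen <- !is.na(ctx) & nchar(ctx) != 3
  if (any(badlen)) {
    i <- which(badlen)[1]
    stop("context of length != 3 for record ", snv$patient_id[i], ":",
         snv$chrom[i], ":", snv$pos[i])
  }
  valid <- !is.na(ctx) & grepl("^[ACGT]{3}$", ctx) &
    substr(ctx, 2, 2) == snv$ref
  n_skipped <- sum(!valid)
  snv <- snv[valid, , drop = FALSE]
  ctx <- ctx[valid]
  ref <- snv$ref
  alt <- snv$alt
  ## pyrimidine convention: reverse-complement purine-reference records
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ctx[pur] <- .revcomp(ctx[pur])
    ref[pur] <- unname(.COMP[ref[pur]])
    alt[pur] <- unname(.COMP[alt[pur]])
  }
  bin <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                substr(ctx, 3, 3))
  pats <- unique(c(if (!is.null(patients)) as.character(patients),
                   consensus$patient_id))
  prof <- matrix(0L, length(pats), 96, dimnames = list(pats, cls))
  if (nrow(snv)) {
    tab <- table(factor(snv$patient_id, levels = pats),
                 factor(bin, levels = cls))
    prof <- prof + unclass(tab)
  }
  attr(prof, "report") <- list(n_snv = nrow(snv), n_skipped = n_skipped)
  prof
}

#' Read a signature definition matrix
#'
#' Tab-delimited, 96 rows (context classes, first column) by K signature
#' columns; each column is a probability distribution over the 96
#' classes.
#'
#' @param path path to the TSV.
#' @return numeric 96 x K matrix, rows ordered as [mut_classes_96()].
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  cls <- mut_classes_96()
  if (!setequal(rn, cls))
    stop("signature matrix rows are not the 96 context classes")
  m <- m[cls, , drop = FALSE]
  if (any(m < 0)) stop("negative signature entries")
  csum <- colSums(m)
  if (any(abs(csum - 1) > 1e-6))
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[abs(csum - 1) > 1e-6], collapse = ", "))
  m
}

#' Non-negative least-squares signature contributions
#'
#' Solves `min || S w - profile ||_2` subject to `w >= 0` for each
#' patient profile: the linear contribution of each reference signature
#' to the patient's 96-context profile.
#'
#' @param profiles patients x 96 matrix (or a single length-96 vector).
#' @param sigs 96 x K signature matrix.
#' @return patients x K contribution matrix (or a length-K vector for a
#'   single profile).
#' @export
fit_contributions <- function(profiles, sigs) {
  single <- is.null(dim(profiles))
  if (single) profiles <- matrix(profiles, nrow = 1)
  if (ncol(profiles) != nrow(sigs))
    stop("profile length and signature rows disagree")
  K <- ncol(sigs)
  out <- matrix(0, nrow(profiles), K,
                dimnames = list(rownames(profiles), colnames(sigs)))
  for (i in seq_len(nrow(profiles))) {
    y <- as.numeric(profiles[i, ])
    if (all(y == 0)) next
    out[i, ] <- pracma::lsqnonneg(sigs, y)$x
  }
  if (single) out[1, ] else out
}

#' Mood's median test for two groups
#'
#' The pooled median is computed; a 2x2 table counts values strictly
#' above versus not above it per group (ties with the median count as
#' "not above").  The table is tested by chi-square without continuity
#' correction, falling back to the exact hypergeometric (Fisher) test
#' when any expected cell is below 5.  All values are retained, including
#' zeros.
#'
#' @param a,b numeric samples.
#' @return list with `statistic` (chi-square, NA for the exact
#'   fallback), `p_value`, `table`, `method` and `degenerate` (TRUE when
#'   all values are identical, in which case p = 1).
#' @export
moods_median_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  pooled <- c(a, b)
  if (max(pooled) == min(pooled))
    return(list(statistic = 0, p_value = 1,
                table = matrix(c(0, length(a), 0, length(b)), 2,
                               dimnames = list(c("above", "not_above"),
                                               c("a", "b"))),
                method = "degenerate", degenerate = TRUE))
  med <- stats::median(pooled)
  tab <- matrix(c(sum(a > med), sum(a <= med),
                  sum(b > med), sum(b <= med)), 2,
                dimnames = list(c("above", "not_above"), c("a", "b")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    list(statistic = NA_real_, p_value = min(p, 1), table = tab,
         method = "exact", degenerate = FALSE)
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         table = tab, method = "chi-square", degenerate = FALSE)
  }
}

#' Compare signature contributions between patient groups
#'
#' Per signature: Mood's median test between the low and high group and
#' the difference of mean contributions (high minus low).
#'
#' @param contributions patients x signatures matrix (e.g. from
#'   [fit_contributions()]).
#' @param groups character/factor of `"low"`/`"high"` labels, named by
#'   patient id or aligned with the contribution rows.
#' @param alpha significance level for flagging rows (default 0.05).
#' @return data frame with `signature`, `p_value`, `mean_diff`
#'   (mean high - mean low) and `significant`.
#' @export
compare_groups <- function(contributions, groups, alpha = 0.05) {
  if (!is.null(names(groups))) {
    if (!all(rownames(contributions) %in% names(groups)))
      stop("unlabeled patient(s) in the contribution table")
    groups <- groups[rownames(contributions)]
  }
  groups <- as.character(groups)
  if (!all(groups %in% c("low", "high")))
    stop("group labels must be 'low' or 'high'")
  if (!any(groups == "low") || !any(groups == "high"))
    stop("both groups must be nonempty")
  res <- lapply(colnames(contributions), function(sg) {
    lo <- contributions[groups == "low", sg]
    hi <- contributions[groups == "high", sg]
    mt <- moods_median_test(lo, hi)
    data.frame(signature = sg, p_value = mt$p_value,
               mean_diff = mean(hi) - mean(lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p_value < alpha
  out
}

#' Group labels from a screen result's optimal split
#'
#' Uses a feature's optimal threshold (`k_star`) from the screen to label
#' each patient `"low"` (the `k_star` lowest-expressing patients) or
#' `"high"`.
#'
#' @param feature_id feature whose split defines the groups.
#' @param neep_results a [run_neep()] data frame.
#' @param x the feature's abundance values, named by patient id.
#' @param cohort the [clinical_cohort()] the screen used.
#' @return named character vector of `"low"`/`"high"` per patient.
#' @export
split_groups <- function(feature_id, neep_results, x, cohort) {
  row <- neep_results[neep_results$feature_id == feature_id, , drop = FALSE]
  if (nrow(row) != 1) stop("feature '", feature_id, "' not in results")
  ord <- .abundance_order(x, cohort)
  lab <- rep("high", nrow(cohort))
  lab[ord[seq_len(row$k_star)]] <- "low"
  stats::setNames(lab, cohort$patient_id)
}

#' Confounder tests between two patient groups
#'
#' Dispatch by declared variable kind: `metric` uses the Welch two-sample
#' t-test, `integer` the Wilcoxon rank-sum test (normal approximation
#' with tie correction), `binary` the two-sample test of equal
#' proportions (with continuity correction).  Missing values are dropped
#' per variable and counted; a variable with no usable values is skipped
#' with a warning.
#'
#' @param covariates data frame of patient covariates (rows aligned with
#'   `groups`).
#' @param groups `"low"`/`"high"` labels per patient.
#' @param kinds named character vector: for each tested column of
#'   `covariates`, one of `"metric"`, `"integer"`, `"binary"`.
#' @return data frame with `variable`, `kind`, `p_value`, `n_used`.
#' @export
confounder_tests <- function(covariates, groups, kinds) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(covariates),
            all(groups %in% c("low", "high")))
  res <- list()
  for (v in names(kinds)) {
    kind <- kinds[[v]]
    if (!kind %in% c("metric", "integer", "binary"))
      stop("unknown variable kind '", kind, "' for ", v)
    x <- covariates[[v]]
    use <- !is.na(x)
    if (!any(use)) {
      warning("variable '", v, "' has no usable values; skipped")
      next
    }
    xl <- x[use & groups == "low"]
    xh <- x[use & groups == "high"]
    p <- switch(kind,
      metric = stats::t.test(xl, xh, var.equal = FALSE)$p.value,
      integer = suppressWarnings(
        stats::wilcox.test(xl, xh, exact = FALSE,
                           correct = TRUE)$p.value),
      binary = {
        suc <- c(sum(xl == 1), sum(xh == 1))
        tot <- c(length(xl), length(xh))
        suppressWarnings(stats::prop.test(suc, tot)$p.value)
      })
    res[[length(res) + 1]] <- data.frame(variable = v, kind = kind,
                                         p_value = p, n_used = sum(use),
                                         stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(variable = character(0), kind = character(0),
                      p_value = numeric(0), n_used = integer(0)))
  do.call(rbind, res)
}

#' One-sided exact binomial enrichment test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`: is the
#' number of features significant for a signature larger than expected by
#' chance?
#'
#' @param n_significant observed count.
#' @param n_total number of trials.
#' @param background_p background success probability (0 < p < 1).
#' @return the exact one-sided p-value.
#' @export
signature_enrichment_test <- function(n_significant, n_total,
                                      background_p) {
  stopifnot(n_significant >= 0, n_significant <= n_total,
            background_p > 0, background_p < 1)
  stats::binom.test(n_significant, n_total, background_p,
                    alternative = "greater")$p.value
}
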