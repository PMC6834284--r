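## Synthetic-data generators with recorded ground truth.  Every generator
## is a pure function of its parameters and seed, and the truth object is
## sufficient to score the downstream stage without re-reading generator
## internals.

#' Simulate a survival cohort
#'
#' Survival times are exponential with the given baseline hazard;
#' censoring times are uniform on (0, censor_horizon]; the observed time
#' is the minimum of the two and the event indicator marks an observed
#' death.  When `event_rate_target` is supplied, the censoring horizon is
#' solved from the closed-form event probability
#' `P(event) = 1 - (1 - exp(-lambda c)) / (lambda c)` so the realized
#' event fraction approximates the target.
#'
#' @param n number of patients (>= 2).
#' @param event_rate_target optional target event fraction in (0, 1).
#' @param baseline_hazard exponential hazard per day (default
#'   `log(2)/730`: two-year median survival).
#' @param censor_horizon upper bound of the uniform censoring time, days;
#'   ignored when `event_rate_target` is given, `Inf` disables censoring.
#' @param seed RNG seed.
#' @return A [clinical_cohort()] with attribute `sim_params`.
#' @export
simulate_cohort <- function(n, event_rate_target = NULL,
                            baseline_hazard = log(2) / 730,
                            censor_horizon = 3000, seed = 1) {
  stopifnot(n >= 2, baseline_hazard > 0)
  if (!is.null(event_rate_target)) {
    stopifnot(event_rate_target > 0, event_rate_target < 1)
    pe <- function(c) 1 - (1 - exp(-baseline_hazard * c)) /
      (baseline_hazard * c)
    censor_horizon <- stats::uniroot(function(c) pe(c) - event_rate_target,
                                     lower = 1e-6, upper = 1e9,
                                     tol = 1e-9)$root
  }
  set.seed(seed)
  t_death <- stats::rexp(n, rate = baseline_hazard)
  t_cens <- if (is.finite(censor_horizon))
    stats::runif(n, 0, censor_horizon) else rep(Inf, n)
  time <- pmin(t_death, t_cens)
  event <- as.numeric(t_death <= t_cens)
  cohort <- clinical_cohort(sprintf("P%05d", seq_len(n)), time, event)
  attr(cohort, "sim_params") <- list(baseline_hazard = baseline_hazard,
                                     censor_horizon = censor_horizon,
                                     seed = seed)
  cohort
}

#' Simulate expression features with planted survival effects
#'
#' Null features are log-normal TPM draws independent of survival.  Each
#' planted feature designates a fraction `1 - split_fraction` of patients
#' as the high-expression group; the high group's survival times are
#' regenerated with the baseline hazard multiplied by `hr`, and the
#' feature's abundance gives the high set a shifted log-normal
#' distribution so the rank split recovers the designation.  In
#' `"shared"` mode (default) all planted features share one designation
#' driving a single modified cohort; `"per-feature"` mode gives each
#' planted feature a private perturbed cohort copy, stored in the truth
#' object.
#'
#' @param cohort a [simulate_cohort()] result (its `sim_params` provide
#'   the hazard and censoring mechanism).
#' @param n_null number of null features.
#' @param planted data frame (or list coercible to one) with columns
#'   `hr` and `split_fraction`, one row per planted feature; may be
#'   empty.
#' @param seed RNG seed.
#' @param mode `"shared"` or `"per-feature"`.
#' @param meanlog_shift lognormal mean-log separation between the
#'   designated high and low groups (default 2).
#' @param sdlog lognormal sd-log of the abundance noise (default 0.6).
#' @return list with `matrix` (features x patients), `cohort` (the
#'   cohort to screen against; modified in shared mode) and `truth`
#'   (planted feature table, designation, per-feature cohorts in
#'   per-feature mode).
#' @export
simulate_expression <- function(cohort, n_null, planted = NULL, seed = 1,
                                mode = c("shared", "per-feature"),
                                meanlog_shift = 2, sdlog = 0.6) {
  mode <- match.arg(mode)
  params <- attr(cohort, "sim_params")
  if (is.null(params))
    stop("cohort lacks sim_params; use simulate_cohort()")
  planted <- if (is.null(planted))
    data.frame(hr = numeric(0), split_fraction = numeric(0))
  else as.data.frame(planted)
  n_pl <- nrow(planted)
  n <- nrow(cohort)
  set.seed(seed)

  regen_high <- function(chrt, high_idx, hr) {
    lam <- params$baseline_hazard * hr
    t_death <- stats::rexp(length(high_idx), rate = lam)
    t_cens <- if (is.finite(params$censor_horizon))
      stats::runif(length(high_idx), 0, params$censor_horizon)
    else rep(Inf, length(high_idx))
    chrt$time[high_idx] <- pmin(t_death, t_cens)
    chrt$event[high_idx] <- as.numeric(t_death <= t_cens)
    chrt
  }

  ids <- sprintf("F%05d", seq_len(n_pl + n_null))
  mat <- matrix(NA_real_, n_pl + n_null, n,
                dimnames = list(ids, cohort$patient_id))
  truth <- list(planted = data.frame(feature_id = ids[seq_len(n_pl)],
                                     hr = planted$hr,
                                     split_fraction = planted$split_fraction,
                                     stringsAsFactors = FALSE))
  out_cohort <- cohort

  if (n_pl > 0) {
    if (mode == "shared") {
      if (length(unique(planted$split_fraction)) > 1)
        stop("shared-cohort mode requires a single split_fraction ",
             "(one designation drives survival)")
      sf <- planted$split_fraction[1]
      if (length(unique(planted$hr)) > 1)
        stop("shared-cohort mode requires a single hr")
      n_low <- round(sf * n)
      high <- sort(sample.int(n, n - n_low))
      designation <- seq_len(n) %in% high
      out_cohort <- regen_high(cohort, high, planted$hr[1])
      attr(out_cohort, "sim_params") <- params
      for (i in seq_len(n_pl))
        mat[i, ] <- stats::rlnorm(n, meanlog = meanlog_shift * designation,
                                  sdlog = sdlog)
      truth$designation <- stats::setNames(designation, cohort$patient_id)
    } else {
      truth$cohorts <- list()
      for (i in seq_len(n_pl)) {
        sf <- planted$split_fraction[i]
        n_low <- round(sf * n)
        high <- sort(sample.int(n, n - n_low))
        designation <- seq_len(n) %in% high
        chrt <- regen_high(cohort, high, planted$hr[i])
        attr(chrt, "sim_params") <- params
        truth$cohorts[[ids[i]]] <- chrt
        mat[i, ] <- stats::rlnorm(n, meanlog = meanlog_shift * designation,
                                  sdlog = sdlog)
      }
    }
  }
  for (i in seq_len(n_null))
    mat[n_pl + i, ] <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  list(matrix = mat, cohort = out_cohort, truth = truth)
}

#' Simulate a toy interactome with planted gained/ghost domain paths
#'
#' Generates a gene model (every gene with `isoforms_per_gene` isoforms),
#' random per-isoform background domain sets, random background PPI edges
#' and a decoy DDI catalog over a reserved domain vocabulary never
#' assigned to any isoform (so background interactions have no structural
#' support).  For each planted path a dedicated gene pair is connected;
#' the designated significant isoform of the left gene receives a gained
#' domain (or a sibling receives a ghost domain), the partner gene's
#' first isoform carries the matching interacting domain, the pair is
#' added to the DDI catalog, and the expected path is recorded in the
#' truth object.  Domain accessions use disjoint numeric ranges per role
#' so planted paths cannot collide with the background.
#'
#' @param n_genes number of genes (>= 2 * n_planted_paths).
#' @param isoforms_per_gene isoforms per gene (>= 2).
#' @param domain_vocab_size size of the background domain vocabulary.
#' @param n_planted_paths number of planted paths.
#' @param seed RNG seed.
#' @return list with `gene_model`, `domains`, `interactome`, `ddi`,
#'   `significant` (data frame of feature_id/significant usable as
#'   [build_mgg()] input) and `truth` (expected path table,
#'   `sig_variants`).
#' @export
simulate_interactome <- function(n_genes = 20, isoforms_per_gene = 3,
                                 domain_vocab_size = 40,
                                 n_planted_paths = 5, seed = 1) {
  stopifnot(isoforms_per_gene >= 2, n_genes >= 2 * max(1, n_planted_paths))
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  gm <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g,
               transcript_id = paste0(g, ".T", seq_len(isoforms_per_gene)),
               is_protein_coding = TRUE, stringsAsFactors = FALSE)))
  gm <- gene_model(gm)

  bg_vocab <- sprintf("PF1%04d", seq_len(domain_vocab_size))
  res_vocab <- sprintf("PF2%04d", seq_len(10))

  ## background domain sets: 1-3 background domains per isoform
  dom <- do.call(rbind, lapply(gm$transcript_id, function(tx) {
    k <- sample(1:3, 1)
    data.frame(transcript_id = tx,
               accession = sample(bg_vocab, k),
               stringsAsFactors = FALSE)
  }))

  ## background PPI edges and decoy DDIs (reserved vocabulary only)
  ea <- sample(genes, n_genes, replace = TRUE)
  eb <- sample(genes, n_genes, replace = TRUE)
  edges <- data.frame(gene_a = pmin(ea, eb), gene_b = pmax(ea, eb),
                      stringsAsFactors = FALSE)
  ddi_a <- sample(res_vocab, 10, replace = TRUE)
  ddi_b <- sample(res_vocab, 10, replace = TRUE)

  sig_variants <- character(0)
  truth_paths <- list()
  for (p in seq_len(n_planted_paths)) {
    gA <- genes[2 * p - 1]
    gB <- genes[2 * p]
    sig <- paste0(gA, ".T1")
    partner <- paste0(gB, ".T1")
    status <- if (p %% 2 == 1) "gained" else "ghost"
    dA <- sprintf("PF3%04d", p)
    dB <- sprintf("PF4%04d", p)
    carrier <- if (status == "gained") sig else paste0(gA, ".T2")
    dom <- rbind(dom, data.frame(transcript_id = c(carrier, partner),
                                 accession = c(dA, dB),
                                 stringsAsFactors = FALSE))
    edges <- rbind(edges, data.frame(gene_a = min(gA, gB),
                                     gene_b = max(gA, gB),
                                     stringsAsFactors = FALSE))
    ddi_a <- c(ddi_a, dA)
    ddi_b <- c(ddi_b, dB)
    sig_variants <- c(sig_variants, sig)
    truth_paths[[p]] <- data.frame(
      sig_variant = sig, sig_gene = gA, sig_domain = dA,
      sig_domain_status = status, partner_domain = dB,
      partner_variant = partner, partner_gene = gB,
      interpretation = if (status == "ghost") "lost-interaction"
                       else "gained-interaction",
      stringsAsFactors = FALSE)
  }
  dom <- unique(dom)
  rownames(dom) <- NULL
  class(dom) <- c("domain_assignment", "data.frame")
  edges <- edges[!duplicated(paste(edges$gene_a, edges$gene_b)), ]
  rownames(edges) <- NULL
  class(edges) <- c("interactome", "data.frame")
  significant <- data.frame(feature_id = gm$transcript_id,
                            significant = gm$transcript_id %in% sig_variants,
                            stringsAsFactors = FALSE)
  truth <- list(
    paths = if (length(truth_paths)) {
      tp <- do.call(rbind, truth_paths)
      tp <- tp[order(tp$sig_variant, tp$partner_variant, tp$sig_domain,
                     tp$partner_domain), , drop = FALSE]
      rownames(tp) <- NULL
      tp
    } else NULL,
    sig_variants = sig_variants)
  list(gene_model = gm, domains = dom, interactome = edges,
       ddi = ddi_catalog(ddi_a, ddi_b), significant = significant,
       truth = truth)
}

#' Synthetic signature definitions
#'
#' `K` probability distributions over the 96 substitution classes; each
#' signature concentrates 80% of its mass on a private block of classes
#' and spreads 20% uniformly, giving well-separated but overlapping
#' profiles.  These are synthetic stand-ins shaped like reference
#' signature matrices; real signature definitions in the same 96 x K TSV
#' layout can be dropped in.
#'
#' @param K number of signatures (<= 8).
#' @param seed RNG seed.
#' @return 96 x K matrix, columns summing to 1.
#' @export
synthetic_signatures <- function(K = 5, seed = 1) {
  stopifnot(K >= 1, K <= 8)
  set.seed(seed)
  cls <- mut_classes_96()
  block <- floor(96 / K)
  m <- matrix(0, 96, K, dimnames = list(cls, paste0("SynthSig", seq_len(K))))
  for (k in seq_len(K)) {
    idx <- ((k - 1) * block + 1):(k * block)
    w <- stats::runif(length(idx))
    m[idx, k] <- 0.8 * w / sum(w)
    m[, k] <- m[, k] + 0.2 / 96
  }
  sweep(m, 2, colSums(m), "/")
}

#' Simulate per-caller mutation catalogs from signature mixtures
#'
#' Each patient's 96-class profile is a multinomial draw of
#' `n_mutations` from the mixture `sigs %*% weights[patient, ]`;
#' mutations are materialized as SNV records with consistent inline
#' trinucleotide contexts and unique positions.  Each of the `callers`
#' receives an independent copy in which every record is dropped with
#' probability `caller_dropout`, emulating caller discordance.
#'
#' @param n_patients number of patients.
#' @param sigs 96 x K signature matrix (e.g. [synthetic_signatures()]).
#' @param weights n_patients x K mixture weights, rows summing to 1.
#' @param n_mutations mutations per patient.
#' @param caller_dropout per-caller record dropout probability.
#' @param callers caller names (default four).
#' @param seed RNG seed.
#' @return list with `catalog` (a tagged [mutation_catalog()] over all
#'   callers) and `truth` (`weights`, per-patient `profiles` of true
#'   counts).
#' @export
simulate_mutations <- function(n_patients, sigs, weights,
                               n_mutations = 5000, caller_dropout = 0.05,
                               callers = c("muse", "mutect",
                                           "somaticsniper", "varscan"),
                               seed = 1) {
  stopifnot(nrow(weights) == n_patients, ncol(weights) == ncol(sigs))
  if (any(abs(rowSums(weights) - 1) > 1e-8))
    stop("weight rows must sum to 1")
  set.seed(seed)
  cls <- mut_classes_96()
  pats <- sprintf("M%04d", seq_len(n_patients))
  rownames(weights) <- pats
  profiles <- matrix(0L, n_patients, 96, dimnames = list(pats, cls))
  recs <- list()
  for (i in seq_len(n_patients)) {
    probs <- as.numeric(sigs %*% weights[i, ])
    cnt <- if (n_mutations > 0)
      as.integer(stats::rmultinom(1, n_mutations, probs)) else
      integer(96)
    profiles[i, ] <- cnt
    if (sum(cnt) == 0) next
    bins <- rep(cls, cnt)
    b5 <- substr(bins, 1, 1)
    ref <- substr(bins, 3, 3)
    alt <- substr(bins, 5, 5)
    b3 <- substr(bins, 7, 7)
    recs[[i]] <- data.frame(patient_id = pats[i], chrom = "1",
                            pos = 10L * seq_along(bins) + 1L,
                            ref = ref, alt = alt,
                            context = paste0(b5, ref, b3),
                            stringsAsFactors = FALSE)
  }
  base <- if (length(recs)) do.call(rbind, recs) else
    data.frame(patient_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               context = character(0), stringsAsFactors = FALSE)
  per_caller <- lapply(callers, function(cl) {
    keep <- stats::runif(nrow(base)) >= caller_dropout
    cbind(base[keep, , drop = FALSE],
          caller = rep(cl, sum(keep)), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_caller)
  catalog <- mutation_catalog(all$patient_id, all$caller, all$chrom,
                              all$pos, all$ref, all$alt, all$context)
  list(catalog = catalog,
       truth = list(weights = weights, profiles = profiles,
                    patients = pats))
}

## ---- fixture writers: the same dialects the readers consume ----------

#' Write synthetic fixtures in the formats the readers consume
#'
#' `write_clinical_tsv` writes a clinical table (`days_to_death` /
#' `days_to_last_followup`); `write_abundance_tsv` a feature x patient
#' TPM table; `write_interactome_fixtures` the gene model TSV, a minimal
#' BioGRID-dialect TSV, a 3did-style flat file and an hmmscan-style
#' domtblout for a [simulate_interactome()] result; `write_maf_tsv` a
#' caller-tagged mutation table.
#'
#' @param cohort,m,sim,catalog objects to serialize.
#' @param path,dir output file or directory.
#' @name synthetic_writers
NULL

#' @rdname synthetic_writers
#' @export
write_clinical_tsv <- function(cohort, path) {
  df <- data.frame(patient_id = cohort$patient_id,
                   days_to_death = ifelse(cohort$event == 1,
                                          cohort$time, NA),
                   days_to_last_followup = ifelse(cohort$event == 0,
                                                  cohort$time, NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_abundance_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_interactome_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$gene_model, file.path(dir, "gene_model.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bg <- data.frame(
    `Official Symbol Interactor A` = sim$interactome$gene_a,
    `Official Symbol Interactor B` = sim$interactome$gene_b,
    `Experimental System Type` = "physical",
    `Organism ID Interactor A` = "9606",
    `Organism ID Interactor B` = "9606",
    check.names = FALSE)
  utils::write.table(bg, file.path(dir, "biogrid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ddi_lines <- sprintf("#=ID\t%s\t%s\t(%s.1@Pfam\t%s.1@Pfam)",
                       sim$ddi$domain_a, sim$ddi$domain_b,
                       sim$ddi$domain_a, sim$ddi$domain_b)
  writeLines(ddi_lines, file.path(dir, "ddi_3did.txt"))
  d <- sim$domains
  dt_lines <- sprintf(
    "%s %s.1 100 %s - 350 1e-20 80.0 0.1 1 1 1e-22 1e-20 75.0 0.1 5 95 10 100 8 102 0.9 -",
    tolower(d$accession), d$accession, d$transcript_id)
  writeLines(c("# hmmscan per-domain output", dt_lines),
             file.path(dir, "domains.domtblout"))
  utils::write.table(sim$significant, file.path(dir, "significant.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname synthetic_writers
#' @export
write_maf_tsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic_writers
#' @export
write_signatures_tsv <- function(sigs, path) {
  df <- data.frame(class = rownames(sigs), sigs, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
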