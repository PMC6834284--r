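## Multi-granularity graphs: integrate gene-level PPIs, domain-domain
## interactions and per-isoform domain assignments to predict protein
## interactions gained or lost by survival-significant isoforms, as
## variant-domain-domain-variant paths.

#' Read a gene model table
#'
#' Tab-delimited columns `gene_id`, `transcript_id`, `is_protein_coding`
#' (logical or 0/1).  Transcripts must be unique across genes.
#'
#' @param path path to the TSV.
#' @return A `gene_model` data frame.
#' @export
read_gene_model <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  req <- c("gene_id", "transcript_id", "is_protein_coding")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("gene model lacks column(s): ", paste(miss, collapse = ", "))
  df$is_protein_coding <- df$is_protein_coding %in% c("TRUE", "True", "1")
  gene_model(df)
}

#' @rdname read_gene_model
#' @param df data frame with the three gene model columns.
#' @export
gene_model <- function(df) {
  if (anyDuplicated(df$transcript_id))
    stop("transcript(s) assigned to more than one gene: ",
         paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
               collapse = ", "))
  df <- df[, c("gene_id", "transcript_id", "is_protein_coding")]
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read a gene-level interactome from a BioGRID tab-delimited file
#'
#' Auto-detects the TAB2/TAB3 dialect from the header, keeps rows whose
#' experimental system type is `physical` and whose both interactors are
#' human (taxon 9606), and deduplicates unordered gene pairs.  Interactors
#' are identified by their official symbols.
#'
#' @param path path to the BioGRID file.
#' @param taxon organism identifier both interactors must carry
#'   (default `"9606"`).
#' @return An `interactome` data frame with columns `gene_a`, `gene_b`
#'   (unordered pairs, `gene_a <= gene_b`), plus a `report` attribute with
#'   per-filter counts.
#' @export
read_biogrid <- function(path, taxon = "9606") {
  header <- readLines(path, n = 1)
  header <- sub("^#", "", header)
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  find_col <- function(patterns) {
    for (p in patterns) {
      i <- grep(p, cols, ignore.case = TRUE)
      if (length(i)) return(i[1])
    }
    NA_integer_
  }
  i_sys <- find_col("^Experimental System Type$")
  i_a <- find_col("^Official Symbol Interactor A$")
  i_b <- find_col("^Official Symbol Interactor B$")
  i_oa <- find_col(c("^Organism ID Interactor A$", "^Organism Interactor A$"))
  i_ob <- find_col(c("^Organism ID Interactor B$", "^Organism Interactor B$"))
  if (any(is.na(c(i_sys, i_a, i_b, i_oa, i_ob))))
    stop("not a TAB2/TAB3 BioGRID file: need 'Experimental System Type', ",
         "'Official Symbol Interactor A/B' and ",
         "'Organism (ID) Interactor A/B' columns")
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, comment.char = "",
                          quote = "")
  names(df) <- cols[seq_len(ncol(df))]
  n_rows <- nrow(df)
  phys <- tolower(df[[i_sys]]) == "physical"
  df <- df[phys, , drop = FALSE]
  n_physical <- nrow(df)
  human <- df[[i_oa]] == taxon & df[[i_ob]] == taxon
  df <- df[human, , drop = FALSE]
  n_human <- nrow(df)
  a <- pmin(df[[i_a]], df[[i_b]])
  b <- pmax(df[[i_a]], df[[i_b]])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("interactome", "data.frame")
  attr(out, "report") <- list(n_rows = n_rows, n_physical = n_physical,
                              n_human = n_human, n_edges = nrow(out))
  out
}

#' Read a domain-domain interaction catalog
#'
#' Accepts either the 3did flat-file format (pairs parsed from `#=ID`
#' lines, Pfam accessions with version suffixes stripped) or a two-column
#' TSV of accession pairs.  The catalog is symmetric and allows
#' self-pairs.
#'
#' @param path path to the catalog file.
#' @return A `ddi_catalog` data frame of canonical unordered pairs
#'   (`domain_a <= domain_b`).
#' @export
read_3did <- function(path) {
  lines <- readLines(path)
  idl <- grep("^#=ID", lines, value = TRUE)
  if (length(idl)) {
    pairs <- lapply(idl, function(l) {
      acc <- regmatches(l, gregexpr("PF\\d+", l))[[1]]
      if (length(acc) < 2) return(NULL)
      ## last two PF accessions on the line are the interacting pair
      utils::tail(acc, 2)
    })
    pairs <- do.call(rbind, pairs)
  } else {
    df <- tryCatch(
      utils::read.delim(path, header = FALSE, colClasses = "character",
                        comment.char = "#"),
      error = function(e) stop("no parsable domain pairs in ", path))
    if (ncol(df) < 2) stop("no parsable domain pairs in ", path)
    ## tolerate a header row
    if (grepl("domain", df[1, 1], ignore.case = TRUE))
      df <- df[-1, , drop = FALSE]
    pairs <- as.matrix(df[, 1:2])
  }
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no parsable domain pairs in ", path)
  pairs <- sub("\\.\\d+$", "", pairs)
  ddi_catalog(pairs[, 1], pairs[, 2])
}

#' @rdname read_3did
#' @param domain_a,domain_b accession vectors forming the pairs.
#' @export
ddi_catalog <- function(domain_a, domain_b) {
  a <- pmin(domain_a, domain_b)
  b <- pmax(domain_a, domain_b)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(domain_a = a[keep], domain_b = b[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("ddi_catalog", "data.frame")
  out
}

#' Test membership of domain pairs in a DDI catalog (symmetric)
#'
#' @param ddi a [ddi_catalog()].
#' @param a,b accession vectors (recycled).
#' @return logical vector.
#' @export
ddi_contains <- function(ddi, a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  key %in% paste(ddi$domain_a, ddi$domain_b, sep = "\r")
}

#' Read per-isoform domain assignments
#'
#' Accepts HMMER3 per-domain tabular output (`--domtblout`, from either
#' hmmscan or hmmsearch; the orientation is detected from which column
#' carries the Pfam accession) or a two-column TSV
#' (`transcript_id`, `accession`).  domtblout rows are kept when the
#' independent per-domain E-value is at or below `e_value_cutoff`;
#' accession version suffixes (`.N`) are stripped; malformed rows are
#' skipped with a warning and counted.
#'
#' @param path path to the assignments file.
#' @param e_value_cutoff independent per-domain E-value cutoff
#'   (default 0.01).
#' @return A `domain_assignment` data frame with columns `transcript_id`,
#'   `accession` (unique rows), plus a `report` attribute.
#' @export
read_domains <- function(path, e_value_cutoff = 0.01) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) {
    out <- data.frame(transcript_id = character(0),
                      accession = character(0), stringsAsFactors = FALSE)
    class(out) <- c("domain_assignment", "data.frame")
    return(out)
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (max(nf) >= 13) {
    ## domtblout: col 2 = target accession (hmmscan: the Pfam model),
    ## col 5 = query accession (hmmsearch: the Pfam model), col 13 =
    ## independent per-domain E-value ("i-Evalue")
    skipped <- 0L
    recs <- lapply(fields, function(f) {
      if (length(f) < 13) return("skip")
      if (grepl("^PF\\d+", f[2])) {
        tx <- f[4]; acc <- f[2]
      } else if (grepl("^PF\\d+", f[5])) {
        tx <- f[1]; acc <- f[5]
      } else return("skip")
      ev <- suppressWarnings(as.numeric(f[13]))
      if (is.na(ev)) return("skip")
      if (ev > e_value_cutoff) return(NULL)
      c(tx, acc)
    })
    bad <- vapply(recs, identical, logical(1), "skip")
    skipped <- sum(bad)
    if (skipped)
      warning(skipped, " malformed domtblout row(s) skipped")
    recs <- recs[!bad]
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (length(recs)) {
      mat <- do.call(rbind, recs)
      df <- data.frame(transcript_id = mat[, 1], accession = mat[, 2],
                       stringsAsFactors = FALSE)
    } else {
      df <- data.frame(transcript_id = character(0),
                       accession = character(0), stringsAsFactors = FALSE)
    }
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            colClasses = "character", comment.char = "#")
    if (grepl("transcript", df[1, 1], ignore.case = TRUE))
      df <- df[-1, , drop = FALSE]
    names(df)[1:2] <- c("transcript_id", "accession")
    df <- df[, 1:2]
    skipped <- 0L
  }
  df$accession <- sub("\\.\\d+$", "", df$accession)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("domain_assignment", "data.frame")
  attr(df, "report") <- list(n_assignments = nrow(df),
                             n_skipped = skipped)
  df
}

# domain set of one transcript (character(0) when none assigned)
.domains_of <- function(domains, tx) {
  domains$accession[domains$transcript_id == tx]
}

#' Classify gained and ghost domains of a significant isoform
#'
#' Within one gene, *ghost* domains are present in at least one
#' survival-insignificant isoform but absent from the significant isoform
#' (a potential lost interaction); *gained* domains are present in the
#' significant isoform but absent from every insignificant isoform (a
#' potential gained interaction).  Isoforms of the gene that themselves
#' passed the significance cutoff are excluded from the insignificant
#' reference set.
#'
#' @param transcripts all transcript ids of the gene (>= 2 required).
#' @param domains a [read_domains()] assignment.
#' @param sig_variant the significant isoform to classify.
#' @param significant all significant transcript ids of the gene
#'   (defaults to just `sig_variant`).
#' @return list with character vectors `gained` and `ghost`.
#' @export
classify_domains <- function(transcripts, domains, sig_variant,
                             significant = sig_variant) {
  if (!(sig_variant %in% transcripts))
    stop("sig_variant '", sig_variant, "' is not an isoform of this gene")
  if (length(transcripts) < 2)
    stop("gene has a single isoform: gained/ghost domains are undefined")
  insig <- setdiff(transcripts, significant)
  sig_dom <- unique(.domains_of(domains, sig_variant))
  insig_dom <- unique(domains$accession[domains$transcript_id %in% insig])
  list(gained = sort(setdiff(sig_dom, insig_dom)),
       ghost = sort(setdiff(insig_dom, sig_dom)))
}

#' Build multi-granularity graphs
#'
#' Filter cascade over all variant-variant expansions of the gene-level
#' interactome, with per-stage candidate-pair counts logged in order:
#' (1) expand gene pairs to all ordered variant pairs; (2) keep pairs
#' whose left variant is survival-significant and protein-coding;
#' (3) keep pairs where some domain of the left variant's
#' present-or-ghost set and some domain present on the right variant form
#' a catalogued domain-domain interaction; (4) keep pairs where such a
#' supporting left domain is gained or ghost; (5) drop pairs whose left
#' gene lacks multiple isoforms.  One path is emitted per
#' (significant variant, left domain, right domain, partner variant)
#' combination surviving the cascade; ghost domains are interpreted as
#' lost interactions and gained domains as gained interactions.  Partner
#' variants are not required to be significant.
#'
#' @param neep_results a [run_neep()] data frame (or any data frame with
#'   `feature_id` and `significant` columns), or a character vector of
#'   significant transcript ids.
#' @param gene_model a [gene_model()].
#' @param interactome an [read_biogrid()] interactome.
#' @param domains a [read_domains()] assignment.
#' @param ddi a [ddi_catalog()].
#' @return A `mgg_paths` data frame with columns `sig_variant`,
#'   `sig_gene`, `sig_domain`, `sig_domain_status` (gained/ghost),
#'   `partner_domain`, `partner_variant`, `partner_gene`,
#'   `interpretation`; per-stage counts in attribute `cascade`.
#' @export
build_mgg <- function(neep_results, gene_model, interactome, domains,
                      ddi) {
  sig <- if (is.character(neep_results)) neep_results
         else neep_results$feature_id[neep_results$significant]
  sig <- intersect(sig, gene_model$transcript_id)
  tx_by_gene <- split(gene_model$transcript_id, gene_model$gene_id)
  coding <- gene_model$transcript_id[gene_model$is_protein_coding]
  gene_of <- stats::setNames(gene_model$gene_id, gene_model$transcript_id)
  dom_by_tx <- split(domains$accession, domains$transcript_id)

  if (nrow(interactome) == 0) {
    warning("empty interactome: no paths can be built")
    return(.empty_mgg(c(n_variant_pairs = 0, n_left_significant_coding = 0,
                        n_ddi_supported = 0, n_gained_or_ghost = 0,
                        n_multi_isoform = 0)))
  }

  ## ordered (left gene, right gene) pairs from the undirected interactome
  la <- interactome$gene_a; lb <- interactome$gene_b
  self <- la == lb
  left_genes <- c(la, lb[!self])
  right_genes <- c(lb, la[!self])
  ntx_l <- lengths(tx_by_gene)[left_genes]
  ntx_r <- lengths(tx_by_gene)[right_genes]
  ntx_l[is.na(ntx_l)] <- 0
  ntx_r[is.na(ntx_r)] <- 0
  stage1 <- sum(as.numeric(ntx_l) * as.numeric(ntx_r))

  ## materialize only pairs whose left variant is significant and coding
  sig_coding <- intersect(sig, coding)
  stage2 <- 0
  cand <- list()
  for (i in seq_along(left_genes)) {
    ltx <- tx_by_gene[[left_genes[i]]]
    rtx <- tx_by_gene[[right_genes[i]]]
    if (is.null(ltx) || is.null(rtx)) next
    lsig <- intersect(ltx, sig_coding)
    if (!length(lsig)) next
    stage2 <- stage2 + length(lsig) * length(rtx)
    cand[[length(cand) + 1]] <-
      expand.grid(sig_variant = lsig, partner_variant = rtx,
                  stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(.empty_mgg(c(n_variant_pairs = stage1,
                        n_left_significant_coding = 0, n_ddi_supported = 0,
                        n_gained_or_ghost = 0, n_multi_isoform = 0)))
  cand <- unique(do.call(rbind, cand))

  ## per significant variant: present domains and gained/ghost status
  status_of <- list()
  for (v in unique(cand$sig_variant)) {
    g <- gene_of[[v]]
    txs <- tx_by_gene[[g]]
    present <- unique(dom_by_tx[[v]])
    if (length(txs) >= 2) {
      cls <- classify_domains(txs, domains, v,
                              significant = intersect(txs, sig))
    } else {
      cls <- list(gained = character(0), ghost = character(0))
    }
    st <- c(stats::setNames(rep("present", length(present)), present),
            stats::setNames(rep("ghost", length(cls$ghost)), cls$ghost))
    st[cls$gained] <- "gained"
    status_of[[v]] <- st
  }

  ddi_key <- paste(ddi$domain_a, ddi$domain_b, sep = "\r")
  paths <- list()
  supported <- logical(nrow(cand))
  altered <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- cand$sig_variant[i]
    w <- cand$partner_variant[i]
    st <- status_of[[v]]
    dA <- names(st)
    dB <- unique(dom_by_tx[[w]])
    if (!length(dA) || !length(dB)) next
    combos <- expand.grid(dA = dA, dB = dB, stringsAsFactors = FALSE)
    hit <- paste(pmin(combos$dA, combos$dB),
                 pmax(combos$dA, combos$dB), sep = "\r") %in% ddi_key
    if (!any(hit)) next
    supported[i] <- TRUE
    combos <- combos[hit, , drop = FALSE]
    stt <- st[combos$dA]
    alt <- stt %in% c("gained", "ghost")
    if (!any(alt)) next
    altered[i] <- TRUE
    combos <- combos[alt, , drop = FALSE]
    stt <- stt[alt]
    paths[[length(paths) + 1]] <- data.frame(
      sig_variant = v, sig_gene = gene_of[[v]],
      sig_domain = combos$dA, sig_domain_status = unname(stt),
      partner_domain = combos$dB, partner_variant = w,
      partner_gene = gene_of[[w]],
      interpretation = ifelse(stt == "ghost", "lost-interaction",
                              "gained-interaction"),
      stringsAsFactors = FALSE)
  }
  stage3 <- sum(supported)
  stage4 <- sum(altered)
  multi <- lengths(tx_by_gene) >= 2
  multi_ok <- altered & multi[gene_of[cand$sig_variant]]
  stage5 <- sum(multi_ok)

  if (length(paths)) {
    out <- unique(do.call(rbind, paths))
    keep <- multi[out$sig_gene]
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$sig_variant, out$partner_variant,
                     out$sig_domain, out$partner_domain), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- .empty_mgg(NULL)
  }
  class(out) <- c("mgg_paths", "data.frame")
  attr(out, "cascade") <- c(n_variant_pairs = stage1,
                            n_left_significant_coding = stage2,
                            n_ddi_supported = stage3,
                            n_gained_or_ghost = stage4,
                            n_multi_isoform = stage5)
  out
}

.empty_mgg <- function(cascade) {
  out <- data.frame(sig_variant = character(0), sig_gene = character(0),
                    sig_domain = character(0),
                    sig_domain_status = character(0),
                    partner_domain = character(0),
                    partner_variant = character(0),
                    partner_gene = character(0),
                    interpretation = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("mgg_paths", "data.frame")
  if (!is.null(cascade)) attr(out, "cascade") <- cascade
  out
}

#' Write (and read back) multi-granularity graph paths
#'
#' TSV with one row per path, deduplicated and sorted by significant
#' variant then partner.
#'
#' @param paths a [build_mgg()] result.
#' @param path output file.
#' @export
write_mgg <- function(paths, path) {
  df <- unique(as.data.frame(paths))
  if (nrow(df))
    df <- df[order(df$sig_variant, df$partner_variant, df$sig_domain,
                   df$partner_domain), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mgg
#' @export
read_mgg <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  class(df) <- c("mgg_paths", "data.frame")
  df
}

#' Export the quadripartite path graph as GraphML
#'
#' Nodes are variants and domains (typed); edges connect significant
#' variant to its altered domain, the two interacting domains, and the
#' partner domain to the partner variant.  Requires the igraph package.
#'
#' @param paths a [build_mgg()] result.
#' @param path output `.graphml` file.
#' @export
write_mgg_graphml <- function(paths, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("the igraph package is required for GraphML export")
  if (!nrow(paths)) stop("no paths to export")
  edges <- rbind(
    data.frame(from = paths$sig_variant,
               to = paste0("dom:", paths$sig_domain)),
    data.frame(from = paste0("dom:", paths$sig_domain),
               to = paste0("dom:", paths$partner_domain)),
    data.frame(from = paste0("dom:", paths$partner_domain),
               to = paths$partner_variant))
  g <- igraph::graph_from_data_frame(unique(edges), directed = FALSE)
  ntype <- ifelse(grepl("^dom:", igraph::V(g)$name), "domain", "variant")
  igraph::V(g)$type <- ntype
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
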