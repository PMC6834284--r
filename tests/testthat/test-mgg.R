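test_that("BioGRID reader filters physical human interactions and deduplicates", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("BioGRID Interaction ID", "Official Symbol Interactor A",
          "Official Symbol Interactor B", "Experimental System Type",
          "Organism ID Interactor A", "Organism ID Interactor B",
          sep = "\t"),
    "1\tTP53\tMDM2\tphysical\t9606\t9606",
    "2\tMDM2\tTP53\tphysical\t9606\t9606",   # same unordered pair
    "3\tTP53\tBRCA1\tgenetic\t9606\t9606",   # wrong system type
    "4\tTP53\tTrp53\tphysical\t9606\t10090", # wrong organism
    "5\tBRCA1\tBARD1\tphysical\t9606\t9606"), f)
  ia <- read_biogrid(f)
  expect_equal(nrow(ia), 2)
  expect_true(all(ia$gene_a <= ia$gene_b))
  rep <- attr(ia, "report")
  expect_equal(rep$n_rows, 5)
  expect_equal(rep$n_physical, 4)
  expect_equal(rep$n_human, 3)
  expect_equal(rep$n_edges, 2)

  writeLines("foo\tbar", f)
  expect_error(read_biogrid(f), "TAB2/TAB3")
})

test_that("3did flat and TSV dialects yield the same symmetric catalog", {
  f <- tempfile()
  writeLines(c(
    "#=ID\t1-cysPrx_C\t1-cysPrx_C\t(PF10417.4@Pfam\tPF10417.4@Pfam)",
    "#=ID\tKinase\tCyclin\t(PF00069.26@Pfam\tPF00134.24@Pfam)",
    "#=3D\tsome structure line"), f)
  ddi <- read_3did(f)
  expect_true(ddi_contains(ddi, "PF00069", "PF00134"))
  expect_true(ddi_contains(ddi, "PF00134", "PF00069"))  # symmetric
  expect_true(ddi_contains(ddi, "PF10417", "PF10417"))  # self-pair
  expect_false(ddi_contains(ddi, "PF00069", "PF10417"))

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("PF00069\tPF00134", "PF00134\tPF00069",
               "PF10417\tPF10417"), f2)
  ddi2 <- read_3did(f2)
  expect_equal(nrow(ddi2), 2)  # deduplicated unordered pairs
  srt <- function(d) {
    d <- as.data.frame(d)
    d <- d[order(d$domain_a, d$domain_b), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(srt(ddi2), srt(ddi))

  writeLines("# nothing here", f2)
  expect_error(read_3did(f2), "parsable")
})

test_that("domain assignments honour the E-value cutoff and strip versions", {
  f <- tempfile()
  writeLines(c(
    "# hmmscan domtblout",
    "Pkinase PF00069.26 264 T1 - 500 1e-40 130.1 0.1 1 1 1e-42 1e-40 120.0 0.1 5 260 10 270 8 275 0.95 -",
    "Cyclin PF00134.24 130 T1 - 500 2e-03 11.0 0.0 1 1 5e-02 2e-01 9.0 0.0 5 120 10 130 8 135 0.80 -",
    "Pkinase PF00069.26 264 T1 - 500 1e-40 130.1 0.1 2 2 1e-42 1e-40 120.0 0.1 5 260 10 270 8 275 0.95 -"),
    f)
  da <- read_domains(f, e_value_cutoff = 0.01)
  expect_equal(nrow(da), 1)  # above-cutoff row dropped, duplicate hit deduplicated
  expect_equal(da$accession, "PF00069")
  expect_equal(da$transcript_id, "T1")

  # TSV fallback
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("T1\tPF00069.26", "T2\tPF00134"), f2)
  da2 <- read_domains(f2)
  expect_equal(da2$accession, c("PF00069", "PF00134"))
})

test_that("gained/ghost classification implements the set algebra", {
  dom <- data.frame(
    transcript_id = c("V1", "V1", "V2", "V2", "V3", "V3", "V3"),
    accession = c("A", "B", "A", "C", "A", "C", "D"),
    stringsAsFactors = FALSE)
  class(dom) <- c("domain_assignment", "data.frame")

  cl <- classify_domains(c("V1", "V2", "V3"), dom, "V1")
  expect_equal(cl$gained, "B")
  expect_equal(cl$ghost, c("C", "D"))
  expect_length(intersect(cl$gained, cl$ghost), 0)

  # identical domain sets: nothing gained, nothing ghost
  dom2 <- dom[dom$transcript_id != "V3", ]
  dom2$accession <- rep(c("A", "B"), 2)
  class(dom2) <- c("domain_assignment", "data.frame")
  cl2 <- classify_domains(c("V1", "V2"), dom2, "V1")
  expect_length(cl2$gained, 0)
  expect_length(cl2$ghost, 0)

  expect_error(classify_domains(c("V1", "V2"), dom, "V9"), "isoform")
  expect_error(classify_domains("V1", dom, "V1"), "single isoform")
})

test_that("gained/ghost are always disjoint on random assignments", {
  set.seed(21)
  for (i in 1:50) {
    txs <- paste0("T", 1:4)
    dom <- data.frame(
      transcript_id = sample(txs, 12, replace = TRUE),
      accession = sample(LETTERS[1:6], 12, replace = TRUE),
      stringsAsFactors = FALSE)
    class(dom) <- c("domain_assignment", "data.frame")
    cl <- classify_domains(txs, dom, "T1")
    expect_length(intersect(cl$gained, cl$ghost), 0)
    # re-check definitions independently
    sig_dom <- unique(dom$accession[dom$transcript_id == "T1"])
    insig_dom <- unique(dom$accession[dom$transcript_id != "T1"])
    expect_setequal(cl$gained, setdiff(sig_dom, insig_dom))
    expect_setequal(cl$ghost, setdiff(insig_dom, sig_dom))
  }
})

test_that("hand-traced toy cascade emits exactly the expected path", {
  gm <- gene_model(data.frame(
    gene_id = c("X", "X", "Y"),
    transcript_id = c("V1", "V2", "W1"),
    is_protein_coding = TRUE))
  dom <- data.frame(transcript_id = c("V2", "W1"),
                    accession = c("C", "E"), stringsAsFactors = FALSE)
  class(dom) <- c("domain_assignment", "data.frame")
  ia <- data.frame(gene_a = "X", gene_b = "Y", stringsAsFactors = FALSE)
  class(ia) <- c("interactome", "data.frame")

  paths <- build_mgg("V1", gm, ia, dom, ddi_catalog("C", "E"))
  expect_equal(nrow(paths), 1)
  expect_equal(paths$sig_variant, "V1")
  expect_equal(paths$sig_domain, "C")
  expect_equal(paths$sig_domain_status, "ghost")
  expect_equal(paths$partner_domain, "E")
  expect_equal(paths$partner_variant, "W1")
  expect_equal(paths$interpretation, "lost-interaction")

  # without DDI support: no path
  p0 <- build_mgg("V1", gm, ia, dom, ddi_catalog("C", "Z"))
  expect_equal(nrow(p0), 0)

  # gained self-interacting domain on both sides
  dom2 <- data.frame(transcript_id = c("V1", "W1"), accession = "B",
                     stringsAsFactors = FALSE)
  class(dom2) <- c("domain_assignment", "data.frame")
  p2 <- build_mgg("V1", gm, ia, dom2, ddi_catalog("B", "B"))
  expect_equal(nrow(p2), 1)
  expect_equal(p2$sig_domain_status, "gained")
  expect_equal(p2$interpretation, "gained-interaction")

  # empty interactome: warning, empty output
  ia0 <- ia[0, ]
  class(ia0) <- c("interactome", "data.frame")
  expect_warning(pe <- build_mgg("V1", gm, ia0, dom,
                                 ddi_catalog("C", "E")), "empty")
  expect_equal(nrow(pe), 0)
})

test_that("planted interactome paths are recovered exactly with a monotone cascade", {
  sim <- simulate_interactome(n_genes = 24, isoforms_per_gene = 3,
                              n_planted_paths = 6, seed = 31)
  paths <- build_mgg(sim$significant, sim$gene_model, sim$interactome,
                     sim$domains, sim$ddi)
  expect_equal(strip_paths(paths), strip_paths(sim$truth$paths))
  casc <- attr(paths, "cascade")
  expect_true(all(diff(unname(casc)) <= 0))

  # every emitted path independently satisfies all filters
  sig <- sim$significant$feature_id[sim$significant$significant]
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    expect_true(p$sig_variant %in% sig)
    expect_true(ddi_contains(sim$ddi, p$sig_domain, p$partner_domain))
    expect_true(any(sim$interactome$gene_a == min(p$sig_gene, p$partner_gene) &
                      sim$interactome$gene_b == max(p$sig_gene, p$partner_gene)))
    gene_tx <- sim$gene_model$transcript_id[sim$gene_model$gene_id ==
                                              p$sig_gene]
    expect_gte(length(gene_tx), 2)
    cl <- classify_domains(gene_tx, sim$domains, p$sig_variant)
    expect_true(p$sig_domain %in% c(cl$gained, cl$ghost))
  }

  # no planted paths + decoy DDIs only: empty output
  sim0 <- simulate_interactome(n_genes = 10, n_planted_paths = 0, seed = 32)
  p0 <- build_mgg(sim0$significant, sim0$gene_model, sim0$interactome,
                  sim0$domains, sim0$ddi)
  expect_equal(nrow(p0), 0)
})

test_that("path TSV round-trips and deduplicates", {
  sim <- simulate_interactome(n_planted_paths = 3, seed = 33)
  paths <- build_mgg(sim$significant, sim$gene_model, sim$interactome,
                     sim$domains, sim$ddi)
  f <- tempfile(fileext = ".tsv")
  write_mgg(rbind(paths, paths), f)  # duplicated input
  back <- read_mgg(f)
  expect_equal(strip_paths(back), strip_paths(paths))

  write_mgg(paths[0, ], f)
  expect_equal(nrow(read_mgg(f)), 0)
})

test_that("fixture writers round-trip through the readers", {
  sim <- simulate_interactome(n_planted_paths = 4, seed = 34)
  d <- tempfile()
  write_interactome_fixtures(sim, d)
  sig <- utils::read.delim(file.path(d, "significant.tsv"))
  sig$significant <- as.logical(sig$significant)
  paths <- build_mgg(sig,
                     read_gene_model(file.path(d, "gene_model.tsv")),
                     read_biogrid(file.path(d, "biogrid.tsv")),
                     read_domains(file.path(d, "domains.domtblout")),
                     read_3did(file.path(d, "ddi_3did.txt")))
  expect_equal(strip_paths(paths), strip_paths(sim$truth$paths))

  # same seed: byte-identical fixture files
  d2 <- tempfile()
  write_interactome_fixtures(simulate_interactome(n_planted_paths = 4,
                                                  seed = 34), d2)
  for (fn in list.files(d)) {
    expect_identical(readLines(file.path(d, fn)),
                     readLines(file.path(d2, fn)))
  }
})
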