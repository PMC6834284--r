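test_that("caller intersection keeps only records seen by every caller", {
  cat <- mutation_catalog(
    patient_id = rep("p1", 9),
    caller = c("a", "b", "c", "d",   # mutation 1 in 4/4
               "a", "b", "c",        # mutation 2 in 3/4
               "a", "a"),            # mutations 3,4 in one caller
    chrom = "1",
    pos = c(10, 10, 10, 10, 20, 20, 20, 30, 40),
    ref = "C", alt = "T", context = "ACA")
  cons <- intersect_callers(cat, c("a", "b", "c", "d"))
  expect_equal(nrow(cons), 1)
  expect_equal(cons$pos, 10L)

  # single required caller: identity on that caller's records
  one <- intersect_callers(cat, "a")
  expect_equal(sort(one$pos), c(10L, 20L, 30L, 40L))

  expect_error(intersect_callers(cat, c("a", "zz")), "zz")
})

test_that("96-class binning follows the pyrimidine-reference convention", {
  cls <- mut_classes_96()
  expect_length(cls, 96)
  expect_length(unique(cls), 96)

  # C>T in ACA context: direct bin
  p1 <- build_profiles(mutation_catalog("p", "c", "1", 5, "C", "T", "ACA"))
  expect_equal(unname(p1["p", "A[C>T]A"]), 1)
  expect_equal(sum(p1), 1)

  # G>T with context AGC: reverse complement to G[C>A]T
  p2 <- build_profiles(mutation_catalog("p", "c", "1", 5, "G", "T", "AGC"))
  expect_equal(unname(p2["p", "G[C>A]T"]), 1)

  # zero-SNV patient listed explicitly: all-zero profile
  p3 <- build_profiles(mutation_catalog("p", "c", "1", 5, "C", "T", "ACA"),
                       patients = c("p", "q"))
  expect_equal(sum(p3["q", ]), 0)

  # non-ACGT context skipped and counted; indels not profiled
  cat4 <- mutation_catalog(c("p", "p", "p"), "c", "1", c(5, 9, 15),
                           c("C", "C", "CT"), c("T", "A", "C"),
                           c("ACA", "ANA", "ACT"))
  p4 <- build_profiles(cat4)
  expect_equal(sum(p4), 1)
  expect_equal(attr(p4, "report")$n_skipped, 1)

  # context resolvable from a reference sequence
  cat5 <- mutation_catalog("p", "c", "chrZ", 3, "C", "G")
  p5 <- build_profiles(cat5, ref_seqs = c(chrZ = "TACGT"))
  expect_equal(unname(p5["p", "A[C>G]G"]), 1)
})

test_that("binning conserves counts and the reverse-complement map is consistent", {
  set.seed(41)
  sigs <- synthetic_signatures(3, seed = 5)
  W <- matrix(1 / 3, 4, 3)
  sm <- simulate_mutations(4, sigs, W, n_mutations = 500,
                           caller_dropout = 0, seed = 6)
  cons <- intersect_callers(sm$catalog,
                            c("muse", "mutect", "somaticsniper", "varscan"))
  expect_equal(nrow(cons), 4 * 500)  # no dropout: everything consensus
  prof <- build_profiles(cons)
  expect_equal(rowSums(prof)[sm$truth$patients],
               stats::setNames(rep(500, 4), sm$truth$patients))
  # binning reproduces the generator's true per-bin counts exactly
  expect_equal(unclass(prof[sm$truth$patients, ]),
               unclass(sm$truth$profiles), ignore_attr = TRUE)

  # re-encoding each bin's representative mutation returns the same bin
  cls <- mut_classes_96()
  for (bin in cls[c(1, 17, 42, 96)]) {
    ref <- substr(bin, 3, 3)
    alt <- substr(bin, 5, 5)
    ctx <- paste0(substr(bin, 1, 1), ref, substr(bin, 7, 7))
    # purine version of the same physical mutation
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
    pr <- build_profiles(mutation_catalog(
      c("u", "v"), "c", "1", c(1, 2) * 10 + 1,
      c(ref, comp[[ref]]), c(alt, comp[[alt]]), c(ctx, rc(ctx))))
    expect_equal(unname(pr["u", bin]), 1)
    expect_equal(unname(pr["v", bin]), 1)
  }
})

test_that("non-negative refitting recovers exact and sampled mixtures", {
  sigs <- synthetic_signatures(5, seed = 7)
  # exact nonnegative combination: zero residual, exact weights
  w_true <- c(100, 0, 50, 0, 0)
  prof <- as.numeric(sigs %*% w_true)
  w <- fit_contributions(prof, sigs)
  expect_equal(unname(w), w_true, tolerance = 1e-6)
  expect_lt(sqrt(sum((sigs %*% w - prof)^2)), 1e-8)

  # zero profile: zero vector
  expect_equal(unname(fit_contributions(rep(0, 96), sigs)), rep(0, 5))

  # multinomial sample from a 2-signature mixture: proportions recovered
  set.seed(8)
  two <- sigs[, 1:2]
  counts <- as.numeric(stats::rmultinom(1, 10000, two %*% c(0.6, 0.4)))
  w2 <- fit_contributions(counts, two)
  expect_equal(unname(w2 / sum(w2)), c(0.6, 0.4), tolerance = 0.05)
})

test_that("Mood's median test builds the correct table with exact fallback", {
  mt <- moods_median_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mt$table), matrix(c(0, 3, 3, 0), 2))
  expect_equal(mt$method, "exact")  # expected cells < 5
  # oracle: two-sided hypergeometric on the same table
  expect_equal(mt$p_value, stats::fisher.test(mt$table)$p.value)

  # symmetry
  expect_equal(moods_median_test(c(4, 5, 6), c(1, 2, 3))$p_value,
               mt$p_value)

  # identical samples: p = 1
  expect_equal(moods_median_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-12)

  # all values identical: degenerate flag
  d <- moods_median_test(rep(2, 5), rep(2, 7))
  expect_true(d$degenerate)
  expect_equal(d$p_value, 1)

  # large groups use chi-square without continuity correction
  set.seed(9)
  a <- rnorm(40); b <- rnorm(40, 2)
  mt2 <- moods_median_test(a, b)
  expect_equal(mt2$method, "chi-square")
  expect_equal(mt2$p_value,
               stats::pchisq(mt2$statistic, 1, lower.tail = FALSE))
})

test_that("group comparison reports mean differences and flags planted shifts", {
  set.seed(10)
  contrib <- cbind(SigA = c(rnorm(30, 10), rnorm(30, 10)),
                   SigB = c(rnorm(30, 5), rnorm(30, 11)))
  rownames(contrib) <- sprintf("p%02d", 1:60)
  groups <- stats::setNames(rep(c("low", "high"), each = 30),
                            rownames(contrib))
  cmp <- compare_groups(contrib, groups)
  expect_false(cmp$significant[cmp$signature == "SigA"])
  expect_true(cmp$significant[cmp$signature == "SigB"])
  expect_equal(cmp$mean_diff[cmp$signature == "SigB"], 6, tolerance = 0.5)

  # single patient per group: difference is the plain subtraction
  c1 <- matrix(c(3, 8), 2, 1, dimnames = list(c("x", "y"), "S"))
  g1 <- stats::setNames(c("low", "high"), c("x", "y"))
  expect_equal(compare_groups(c1, g1)$mean_diff, 5)

  expect_error(compare_groups(contrib, rep("low", 60)), "nonempty")
})

test_that("confounder tests dispatch by declared variable kind", {
  set.seed(11)
  cov <- data.frame(cigs = c(rnorm(50, 20), rnorm(50, 20)),
                    years = c(rpois(50, 20), rpois(50, 20)),
                    smoker = c(rbinom(50, 1, 0.1), rbinom(50, 1, 0.5)),
                    allmiss = NA_real_)
  groups <- rep(c("low", "high"), each = 50)
  expect_warning(
    res <- confounder_tests(cov, groups,
                            kinds = c(cigs = "metric", years = "integer",
                                      smoker = "binary",
                                      allmiss = "metric")),
    "allmiss")
  expect_equal(res$variable, c("cigs", "years", "smoker"))
  expect_gt(res$p_value[res$variable == "cigs"], 0.05)  # identical dists
  expect_lt(res$p_value[res$variable == "smoker"], 0.01)
  # binary route equals prop.test directly
  direct <- stats::prop.test(c(sum(cov$smoker[1:50]),
                               sum(cov$smoker[51:100])), c(50, 50))$p.value
  expect_equal(res$p_value[res$variable == "smoker"], direct)

  expect_error(confounder_tests(cov, groups, kinds = c(cigs = "weird")),
               "unknown")
})

test_that("enrichment test is the exact upper binomial tail", {
  expect_equal(signature_enrichment_test(0, 10, 0.3), 1)
  expect_equal(signature_enrichment_test(10, 10, 0.5), 2^-10)
  # direct summation oracle
  expect_equal(signature_enrichment_test(5, 100, 0.05),
               sum(stats::dbinom(5:100, 100, 0.05)), tolerance = 1e-12)
})

test_that("MAF reading accepts plain and MAF-standard column names", {
  f <- tempfile(fileext = ".maf")
  writeLines(c(
    paste("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", sep = "\t"),
    "TCGA-01\t1\t12345\tC\tT"), f)
  cat <- read_maf(f, caller = "mutect")
  expect_equal(cat$patient_id, "TCGA-01")
  expect_equal(cat$caller, "mutect")
  expect_equal(cat$pos, 12345L)

  f2 <- tempfile(fileext = ".tsv")
  sm <- simulate_mutations(2, synthetic_signatures(2, seed = 1),
                           matrix(0.5, 2, 2), n_mutations = 50,
                           caller_dropout = 0, seed = 2)
  write_maf_tsv(sm$catalog, f2)
  back <- read_maf(f2)
  expect_equal(nrow(back), nrow(sm$catalog))
  expect_equal(back$context, sm$catalog$context)
})
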