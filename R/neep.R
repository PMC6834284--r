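## Core screen: percentile-range minimum-p-value scan, shared Monte-Carlo
## null, empirical p-values, BH adjustment, effect sizes, robustness.

# Per-cohort quantities reused by every sweep (see src/scan.cpp):
# distinct death times, at-risk counts, d_j/n_j prefix sums and the
# variance coefficients; plus each patient's count of death times it is
# at risk for.
.logrank_precompute <- function(cohort) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  times <- cohort$time
  events <- cohort$event
  if (sum(events) == 0) stop("cohort has no death events")
  dt <- sort(unique(times[events == 1]))
  J <- length(dt)
  nrisk <- vapply(dt, function(t) sum(times >= t), numeric(1))
  d <- vapply(dt, function(t) sum(times == t & events == 1), numeric(1))
  a <- d / nrisk
  b <- ifelse(nrisk > 1, d * (nrisk - d) / (nrisk^2 * (nrisk - 1)), 0)
  cumA <- c(0, cumsum(a))
  mi <- findInterval(times, dt)     # death times <= time_i
  list(mi = as.integer(mi), ev = as.integer(events), cumA = cumA, b = b,
       nrisk = nrisk, J = J, s = length(times))
}

.k_range <- function(s, l, h) {
  stopifnot(l > 0, h < 1, l < h)
  kmin <- floor(l * s)
  kmax <- floor(h * s)
  if (kmin < 1)
    stop("floor(l*s) < 1: threshold range is empty for this cohort size")
  if (kmin > kmax) stop("empty threshold range: floor(l*s) > floor(h*s)")
  if (kmax > s - 1) kmax <- s - 1   # high group must be nonempty
  c(kmin = kmin, kmax = kmax)
}

# Ascending abundance order with ties broken by patient id (stable and
# deterministic; under the null any tie-break is exchangeable with the
# permutations used to build the null).
.abundance_order <- function(x, cohort) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), cohort$patient_id))
      stop("abundance names do not match the cohort's patients")
    x <- x[cohort$patient_id]
  } else if (length(x) != nrow(cohort)) {
    stop("abundance vector length does not match the cohort")
  }
  order(x, cohort$patient_id)
}

#' Minimum-p-value threshold scan of one feature
#'
#' Patients are sorted by ascending abundance (ties broken by patient id);
#' for each low-group size k from `floor(l*s)` to `floor(h*s)` the logrank
#' test compares the k lowest-expressing patients against the rest.  The
#' smallest p over the sweep is returned, with the achieving k (smallest k
#' on ties) and the full per-k p-value vector.
#'
#' @param x abundance values, one per patient (named by patient id, or
#'   aligned with the cohort's row order).
#' @param cohort a [clinical_cohort()].
#' @param l,h lower and upper percentile thresholds (defaults 0.15, 0.85).
#' @return list with `min_p`, `k_star`, `p_values` (named by k),
#'   `chi_square` (per k) and `order` (patient index permutation used).
#' @export
threshold_scan <- function(x, cohort, l = 0.15, h = 0.85) {
  ord <- .abundance_order(x, cohort)
  xs <- if (!is.null(names(x))) x[cohort$patient_id] else x
  if (max(xs) == min(xs)) stop("constant feature: no informative split")
  pre <- .logrank_precompute(cohort)
  kr <- .k_range(pre$s, l, h)
  res <- scan_pvalues_cpp(pre$mi[ord], pre$ev[ord], pre$cumA, pre$b,
                          pre$nrisk, kr[["kmin"]], kr[["kmax"]])
  ks <- seq.int(kr[["kmin"]], kr[["kmax"]])
  p <- res$p
  names(p) <- ks
  chi <- res$chi
  names(chi) <- ks
  list(min_p = res$min_p, k_star = res$k_star, p_values = p,
       chi_square = chi, order = ord)
}

#' Exact size of the minimum-p null support
#'
#' The number of distinct low/high partitions reachable by the threshold
#' scan of a cohort of `s` patients:
#' `sum over i = floor(l*s) .. floor(h*s) of choose(s, i)`.
#' Computed exactly with an addition-only big-integer Pascal row, since the
#' value exceeds double precision for realistic cohorts (s in the hundreds).
#'
#' @param s number of patients.
#' @param l,h percentile thresholds.
#' @return the exact count: a numeric when representable below 2^53,
#'   otherwise a character string of decimal digits.
#' @export
null_size <- function(s, l, h) {
  kr <- c(kmin = floor(l * s), kmax = floor(h * s))
  stopifnot(kr[["kmin"]] >= 1, kr[["kmin"]] <= kr[["kmax"]],
            kr[["kmax"]] <= s)
  ## big integers as little-endian base-1e15 limb vectors (addition only:
  ## limb sums stay below 2^53)
  base <- 1e15
  add <- function(u, v) {
    n <- max(length(u), length(v))
    u <- c(u, numeric(n - length(u)))
    v <- c(v, numeric(n - length(v)))
    w <- u + v
    carry <- 0
    for (i in seq_len(n)) {
      w[i] <- w[i] + carry
      carry <- if (w[i] >= base) 1 else 0
      if (carry) w[i] <- w[i] - base
    }
    if (carry) w <- c(w, 1)
    w
  }
  ## Pascal row s: row[[i+1]] = choose(s, i)
  row <- list(1)
  for (n in seq_len(s)) {
    new <- vector("list", n + 1)
    new[[1]] <- 1
    for (i in seq_len(n - 1))
      new[[i + 1]] <- add(row[[i]], row[[i + 1]])
    new[[n + 1]] <- 1
    row <- new
  }
  tot <- 0
  for (i in seq.int(kr[["kmin"]], kr[["kmax"]]))
    tot <- add(tot, row[[i + 1]])
  ## render
  if (length(tot) == 1) return(tot[1])
  val <- sum(tot * base^(seq_along(tot) - 1))
  if (val < 2^53) return(val)
  paste0(sprintf("%.0f", tot[length(tot)]),
         paste0(sprintf("%015.0f", rev(tot[-length(tot)])), collapse = ""))
}

#' Build the shared Monte-Carlo null of minimum p-values
#'
#' For each of `N` simulations one uniform random permutation of the
#' cohort is drawn and the threshold sweep of [threshold_scan()] is run on
#' it (all allowed low-group sizes within one permutation); the minimum
#' logrank p is recorded.  The sorted values calibrate every feature
#' screened against the same cohort: only patient ranks enter the scan, so
#' a single null serves all features.
#'
#' @param cohort a [clinical_cohort()].
#' @param l,h percentile thresholds.
#' @param N number of simulations.
#' @param seed RNG seed; identical seed and spec give bit-identical output.
#' @return A `neep_null` list: `values` (ascending minimum p-values,
#'   length N) and `spec` (s, l, h, N, seed).
#' @export
build_null <- function(cohort, l = 0.15, h = 0.85, N = 10000, seed = 1) {
  stopifnot(N >= 1)
  pre <- .logrank_precompute(cohort)
  kr <- .k_range(pre$s, l, h)
  set.seed(seed)
  vals <- null_minp_cpp(pre$mi, pre$ev, pre$cumA, pre$b, pre$nrisk,
                        kr[["kmin"]], kr[["kmax"]], as.integer(N))
  structure(list(values = sort(vals),
                 spec = list(s = pre$s, l = l, h = h, N = N, seed = seed)),
            class = "neep_null")
}

#' @export
print.neep_null <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo minimum-p null: N = %d draws, s = %d patients, l = %g, h = %g, seed = %s\n",
    x$spec$N, x$spec$s, x$spec$l, x$spec$h, format(x$spec$seed)))
  invisible(x)
}

#' Exact null distribution by full enumeration of orderings
#'
#' For small cohorts the distribution of the minimum p-value under a
#' uniform random permutation can be computed exactly: the low groups of
#' the sweep are nested prefixes of one ordering, so enumerating all `s!`
#' orderings (each equally likely) and recording each ordering's minimum
#' p gives the exact CDF that [build_null()] samples from.  Intended for
#' `s <= 9` (9! = 362,880 orderings).
#'
#' @param cohort a [clinical_cohort()].
#' @param l,h percentile thresholds.
#' @return A `neep_null` whose `values` hold one minimum p per ordering
#'   (sorted); `spec$N` is `s!`.
#' @export
enumerate_null <- function(cohort, l = 0.15, h = 0.85) {
  pre <- .logrank_precompute(cohort)
  s <- pre$s
  if (s > 9) stop("full enumeration is limited to s <= 9")
  kr <- .k_range(s, l, h)
  perms <- .all_permutations(s)
  res <- minp_orderings_cpp(perms, pre$mi, pre$ev, pre$cumA, pre$b,
                            pre$nrisk, kr[["kmin"]], kr[["kmax"]])
  structure(list(values = sort(res$min_p),
                 spec = list(s = s, l = l, h = h, N = ncol(perms),
                             seed = NA)),
            class = "neep_null")
}

# all permutations of 1..n as an n x n! integer matrix (columns)
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1)
  cols <- lapply(seq_len(n), function(pos) {
    rbind(sub[seq_len(pos - 1), , drop = FALSE],
          matrix(as.integer(n), 1, ncol(sub)),
          sub[seq.int(pos, n - 1)[seq_len(n - pos)], , drop = FALSE])
  })
  do.call(cbind, cols)
}

#' Empirical p-value of an observed minimum p against the null
#'
#' With `r` = number of null values at or below `min_p`: mode
#' `"plus-one"` (default) returns `(r + 1) / (N + 1)` — the standard
#' permutation-test estimator, never zero, so downstream BH adjustment is
#' well defined; mode `"fraction"` returns the plain fraction r/N of
#' simulated values at or below the observed one, reported as `1/N` with a
#' `zero_replaced` attribute when r = 0.
#'
#' @param min_p observed minimum p-value(s), in (0, 1].
#' @param null a [build_null()] result.
#' @param mode `"plus-one"` or `"fraction"`.
#' @return empirical p-value(s), same length as `min_p`.
#' @export
empirical_p <- function(min_p, null, mode = c("plus-one", "fraction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(null, "neep_null"), length(null$values) >= 1)
  if (any(min_p <= 0 | min_p > 1))
    stop("min_p must lie in (0, 1]")
  N <- length(null$values)
  r <- findInterval(min_p, null$values)  # count of null values <= min_p
  if (mode == "plus-one") {
    (r + 1) / (N + 1)
  } else {
    out <- r / N
    zero <- out == 0
    out[zero] <- 1 / N
    if (any(zero)) attr(out, "zero_replaced") <- which(zero)
    out
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up q-values: `q_(i) = min over j >= i of (m p_(j) / j)`,
#' capped at 1 and mapped back to input order.  Thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Plan the null size for distinct adjacent p-values
#'
#' Since calibrated p-values are uniform under the null, the probability
#' that two adjacent sorted p-values differ is approximately
#' `1 - m / N` for `m` tested features and `N` simulations; with
#' `N = multiplier * m` this is `1 - 1/multiplier`.
#'
#' @param m_features number of features that will be tested.
#' @param multiplier null size as a multiple of `m_features` (default 10).
#' @return list with `N` (exact product) and `distinct_probability`.
#' @export
plan_null <- function(m_features, multiplier = 10) {
  stopifnot(m_features >= 1, multiplier >= 1)
  N <- multiplier * m_features
  list(N = N, distinct_probability = 1 - m_features / N)
}

# Batch scan of every row of an abundance matrix against one cohort.
# Returns min_p and k_star per feature via a single compiled call.
.scan_matrix <- function(m, cohort, l, h) {
  pre <- .logrank_precompute(cohort)
  kr <- .k_range(pre$s, l, h)
  ords <- vapply(seq_len(nrow(m)),
                 function(i) .abundance_order(stats::setNames(m[i, ],
                                                              colnames(m)),
                                              cohort),
                 integer(pre$s))
  res <- minp_orderings_cpp(ords, pre$mi, pre$ev, pre$cumA, pre$b,
                            pre$nrisk, kr[["kmin"]], kr[["kmax"]])
  list(min_p = res$min_p, k_star = res$k_star, kmin = kr[["kmin"]],
       kmax = kr[["kmax"]])
}

#' Run the full calibrated survival screen
#'
#' One shared Monte-Carlo null serves all features.  Per feature: the
#' minimum-p threshold scan, the empirical p against the null, and effect
#' sizes (O/E hazard ratio, mortality at the horizons) at the optimal
#' split; then BH adjustment across all tested features.
#'
#' @param m abundance matrix (features x patients), already filtered with
#'   [filter_eligible()] at the same `l`.
#' @param cohort a [clinical_cohort()]; its patients must equal the
#'   matrix's columns.
#' @param l,h percentile thresholds (defaults 0.15, 0.85).
#' @param null optional pre-built [build_null()]; built here otherwise.
#' @param N null size when `null` is not supplied.
#' @param seed RNG seed for the null.
#' @param fdr significance cutoff on q-values (default 0.1).
#' @param mode empirical p-value mode, see [empirical_p()].
#' @param horizons mortality horizons in days.
#' @return data frame (one row per feature, sorted by `neep_p` then
#'   feature id) with columns `feature_id`, `k_star`, `low_n`, `high_n`,
#'   `min_p`, `neep_p`, `q_value`, `significant`, `hazard_ratio`,
#'   `mort_low_1y/2y/5y`, `mort_high_1y/2y/5y`; the null spec is attached
#'   as attribute `null_spec`.
#' @export
run_neep <- function(m, cohort, l = 0.15, h = 0.85, null = NULL,
                     N = 10000, seed = 1, fdr = 0.1,
                     mode = c("plus-one", "fraction"),
                     horizons = c(365, 730, 1825)) {
  mode <- match.arg(mode)
  if (!setequal(colnames(m), cohort$patient_id))
    stop("matrix patients and cohort patients differ")
  m <- m[, cohort$patient_id, drop = FALSE]
  if (is.null(null)) null <- build_null(cohort, l, h, N, seed)
  if (null$spec$s != nrow(cohort) || null$spec$l != l || null$spec$h != h)
    stop("null distribution was built for a different cohort or range")
  sc <- .scan_matrix(m, cohort, l, h)
  neep_p <- empirical_p(sc$min_p, null, mode)
  q <- bh_adjust(as.numeric(neep_p))
  s <- nrow(cohort)
  eff <- lapply(seq_len(nrow(m)), function(i) {
    ord <- .abundance_order(stats::setNames(m[i, ], colnames(m)), cohort)
    k <- sc$k_star[i]
    lowi <- ord[seq_len(k)]
    highi <- ord[-seq_len(k)]
    group_effect(cohort$time[lowi], cohort$event[lowi],
                 cohort$time[highi], cohort$event[highi], horizons)
  })
  out <- data.frame(
    feature_id = rownames(m),
    k_star = sc$k_star,
    low_n = sc$k_star,
    high_n = s - sc$k_star,
    min_p = sc$min_p,
    neep_p = as.numeric(neep_p),
    q_value = q,
    significant = q < fdr,
    hazard_ratio = vapply(eff, function(e) e$hazard_ratio, numeric(1)),
    mort_low_1y = vapply(eff, function(e) e$mortality_low[1], numeric(1)),
    mort_low_2y = vapply(eff, function(e) e$mortality_low[2], numeric(1)),
    mort_low_5y = vapply(eff, function(e) e$mortality_low[3], numeric(1)),
    mort_high_1y = vapply(eff, function(e) e$mortality_high[1], numeric(1)),
    mort_high_2y = vapply(eff, function(e) e$mortality_high[2], numeric(1)),
    mort_high_5y = vapply(eff, function(e) e$mortality_high[3], numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$neep_p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "null_spec") <- null$spec
  out
}

#' Write screen results to TSV
#'
#' @param results a [run_neep()] data frame.
#' @param path output file.
#' @export
write_neep <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rank-stability of the screen under patient removal
#'
#' Each simulation removes `floor(fraction * s)` patients uniformly at
#' random, reruns the minimum-p scan on the reduced cohort, and ranks the
#' features by minimum p.  Because p-values shrink with sample size, ranks
#' rather than p-values are compared: the Spearman rank correlation of
#' each simulation's ranks against the full-data ranks measures stability.
#'
#' @param m abundance matrix (features x patients).
#' @param cohort a [clinical_cohort()].
#' @param l,h percentile thresholds.
#' @param fraction fraction of patients removed per simulation
#'   (`0 <= fraction < 1`).
#' @param n_sims number of simulations.
#' @param seed RNG seed.
#' @return list with `observed_rank` (full-data ranks, named by feature),
#'   `ranks` (features x n_sims matrix), `rho` (per-simulation Spearman
#'   correlation) and `mean_rho`.
#' @export
robustness_simulation <- function(m, cohort, l = 0.15, h = 0.85,
                                  fraction = 0.05, n_sims = 100,
                                  seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (!setequal(colnames(m), cohort$patient_id))
    stop("matrix patients and cohort patients differ")
  m <- m[, cohort$patient_id, drop = FALSE]
  s <- nrow(cohort)
  full <- .scan_matrix(m, cohort, l, h)
  obs_rank <- rank(full$min_p, ties.method = "average")
  names(obs_rank) <- rownames(m)
  if (n_sims == 0)
    return(list(observed_rank = obs_rank,
                ranks = matrix(numeric(0), nrow(m), 0,
                               dimnames = list(rownames(m), NULL)),
                rho = numeric(0), mean_rho = NA_real_))
  n_remove <- floor(fraction * s)
  s2 <- s - n_remove
  if (floor(l * s2) < 1 || s2 < 2)
    stop("reduced cohort too small for the threshold range")
  set.seed(seed)
  ranks <- matrix(NA_real_, nrow(m), n_sims,
                  dimnames = list(rownames(m), NULL))
  rho <- numeric(n_sims)
  for (b in seq_len(n_sims)) {
    keep <- sort(sample.int(s, s2))
    sub_cohort <- clinical_cohort(cohort$patient_id[keep],
                                  cohort$time[keep], cohort$event[keep])
    sub <- m[, keep, drop = FALSE]
    sc <- .scan_matrix(sub, sub_cohort, l, h)
    ranks[, b] <- rank(sc$min_p, ties.method = "average")
    rho[b] <- stats::cor(obs_rank, ranks[, b], method = "spearman")
  }
  list(observed_rank = obs_rank, ranks = ranks, rho = rho,
       mean_rho = mean(rho))
}

#' Approximate smallest informative group size (Schoenfeld)
#'
#' Schoenfeld's approximation for the logrank test requires roughly
#' `d = (z_{1-alpha} + z_{power})^2 / (pi1 pi2 log(hr)^2)` events; with the
#' cohort's event fraction this bounds the size of the smaller patient
#' group, which in turn suggests the minimum percentile threshold `l` of
#' the scan.  This is a planning heuristic only — the screen itself makes
#' no use of it.
#'
#' @param n cohort size.
#' @param n_events observed death events.
#' @param hr target hazard ratio.
#' @param alpha one-sided type-I level (default 0.1).
#' @param power target power (default 0.75).
#' @return list with `events_needed`, `min_group_size` and the implied
#'   `min_percentile`.
#' @export
logrank_power_group_size <- function(n, n_events, hr, alpha = 0.1,
                                     power = 0.75) {
  stopifnot(n > 0, n_events > 0, hr > 0, hr != 1)
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  event_frac <- n_events / n
  ## events needed at allocation fraction f: d(f) = (za+zb)^2/(f(1-f)log^2 hr)
  ## smallest group size g such that with f = g/n the available events
  ## d_avail = n * event_frac satisfy d(f) <= d_avail
  f <- seq(0.01, 0.5, by = 0.001)
  d_needed <- (za + zb)^2 / (f * (1 - f) * log(hr)^2)
  ok <- d_needed <= n * event_frac
  if (!any(ok)) return(list(events_needed = min(d_needed),
                            min_group_size = NA_integer_,
                            min_percentile = NA_real_))
  fmin <- min(f[ok])
  list(events_needed = (za + zb)^2 / (fmin * (1 - fmin) * log(hr)^2),
       min_group_size = ceiling(fmin * n),
       min_percentile = fmin)
}
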