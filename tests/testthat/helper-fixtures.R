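# Shared fixtures, built in code at test time.

# tiny clinical TSV: 3 usable patterns + annotation-based exclusions
write_tiny_clinical <- function(path) {
  writeLines(c(
    "patient_id\tdays_to_death\tdays_to_last_followup\thistory",
    "P1\t200\t\tnone",
    "P2\t\t400\tnone",
    "P3\t\t\tnone",
    "P4\t150\t\tPrior malignancy",
    "P5\t\t300\tSynchronous malignancy noted"),
    path)
  path
}

# drop attributes that legitimately differ between a computed and an
# expected path table (cascade counts, row names)
strip_paths <- function(d) {
  d <- as.data.frame(d)
  attr(d, "cascade") <- NULL
  rownames(d) <- NULL
  d
}

# pure-R minimum-p sweep, independent of the compiled kernel: evaluates
# logrank() from scratch at every k
r_min_p_sweep <- function(ord, cohort, l = 0.15, h = 0.85) {
  s <- nrow(cohort)
  kmin <- floor(l * s)
  kmax <- min(floor(h * s), s - 1)
  ps <- vapply(kmin:kmax, function(k) {
    lo <- ord[seq_len(k)]
    hi <- ord[-seq_len(k)]
    logrank(cohort$time[lo], cohort$event[lo],
            cohort$time[hi], cohort$event[hi])$p_value
  }, numeric(1))
  min(ps)
}
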