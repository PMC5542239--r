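library(data.table)

# three-gene toy panel, written as a real BED and read back through the
# package's own reader
tiny_panel <- local({
  memo <- NULL
  function() {
    if (!is.null(memo)) return(memo)
    bed <- c("chr1\t100\t300\tGENEA_ex1",
             "chr1\t1000\t1200\tGENEA_ex2",
             "chr1\t2000\t2300\tGENEA_ex3",
             "chr2\t500\t700\tGENEB_ex1",
             "chr2\t1500\t1800\tGENEB_ex2",
             "chr3\t100\t400\tGENEC_ex1")
    f <- tempfile(fileext = ".bed")
    writeLines(bed, f)
    memo <<- read_panel(f)
    memo
  }
})

flat_reference <- function(panel) {
  data.table(exon_id = panel$exon_id, ref_value = 1, masked = FALSE)
}

# one variant-call row with sensible defaults
mkcall <- function(chrom = "chr1", pos = 150L, ref = "A", alt = "G",
                   af = 0.2, fwd = 10L, rev = 10L, caller = "MuTect",
                   sample_id = "S1") {
  data.table(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, allele_fraction = af,
             alt_forward = as.integer(fwd), alt_reverse = as.integer(rev),
             caller = caller)
}

as_merged <- function(...) {
  calls <- rbindlist(list(...))
  calls[, `:=`(callers = caller, n_callers = 1L,
               filter_status = "pass", filter_reason = NA_character_)]
  calls
}

# the perfect-observer cohort world: noise-free assays, fully sensitive
# callers, no false positives, no germline leakage
perfect_cohort_config <- function(n_patients = 72L, ...) {
  cohort_config(n_patients = n_patients, noise = FALSE,
                germline_per_sample = 0,
                caller_models = data.table(
                  caller = c("MuTect", "LoFreq", "SNVer"),
                  sensitivity = 1, fp_rate = 0), ...)
}

# independently coded product-limit + Greenwood oracle (plain loops; no
# shared code with km_estimate)
km_oracle <- function(times, events, t_eval) {
  s <- 1; gw <- 0
  for (tt in sort(unique(times[events == 1]))) {
    if (tt > t_eval) break
    n_at_risk <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    s <- s * (1 - d / n_at_risk)
    if (n_at_risk > d) gw <- gw + d / (n_at_risk * (n_at_risk - d))
  }
  list(surv = s, se = s * sqrt(gw))
}

# brute-force two-group log-rank tally (observed/expected/variance)
logrank_oracle_2g <- function(groups, times, events) {
  g1 <- sort(unique(groups))[1L]
  U <- 0; V <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at <- times >= tt
    n <- sum(at); n1 <- sum(at & groups == g1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & groups == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) U^2 / V else 0
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# two-sided Fisher exact p by full hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)), 0)
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
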