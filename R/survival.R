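#' Per-gene alteration prevalence
#'
#' Fraction of cohort patients with at least one alteration per gene
#' (patients counted once per gene regardless of how many variants they
#' carry).
#'
#' @param matrix an `nb_matrix` from [build_alteration_matrix()].
#' @return `data.table(gene, n_altered, fraction)` sorted by decreasing
#'   fraction.
#' @export
prevalence_table <- function(matrix) {
  patients <- attr(matrix, "patients")
  if (is.null(patients) || length(patients) == 0L)
    stopf("prevalence_table: empty cohort")
  tab <- as.data.table(matrix)[, .(n_altered = uniqueN(patient_id)), by = gene]
  tab[, fraction := n_altered / length(patients)]
  setorder(tab, -fraction, gene)
  tab[]
}

#' Kaplan-Meier product-limit estimate with Greenwood standard errors
#'
#' At tied times events precede censorings (the standard convention: a
#' subject censored at `t` is still at risk for the event at `t`).
#' Greenwood's formula gives the variance:
#' `Var S(t) = S(t)^2 * sum_{t_j <= t} d_j / (n_j (n_j - d_j))`.
#'
#' @param times follow-up times (months), non-negative.
#' @param events 1 = event, 0 = censored.
#' @return object of class `nb_km`: `data.table(time, n_risk, n_event,
#'   n_censor, surv, se)` over distinct observed times, with `n`
#'   subjects as attribute.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stopf("km_estimate: no subjects")
  if (any(times < 0)) stopf("km_estimate: negative time")
  if (!all(events %in% c(0, 1))) stopf("km_estimate: events must be 0/1")
  dt <- data.table(time = as.numeric(times), event = as.integer(events))
  tab <- dt[, .(d = sum(event), c = sum(1L - event)), keyby = time]
  n <- nrow(dt)
  tab[, n_risk := n - cumsum(shift(d + c, fill = 0L))]
  tab[, haz := fifelse(n_risk > 0L, d / n_risk, 0)]
  tab[, surv := cumprod(1 - haz)]
  tab[, gw := cumsum(fifelse(n_risk > d & d > 0L,
                             d / (n_risk * (n_risk - d)), 0))]
  tab[, se := surv * sqrt(gw)]
  out <- tab[, .(time, n_risk, n_event = d, n_censor = c, surv, se)]
  setattr(out, "n", n)
  setattr(out, "class", unique(c("nb_km", class(out))))
  out[]
}

#' Survival and Greenwood SE at a time point
#'
#' Returns the step value of the product-limit curve at `t` (the value
#' after all events at times `<= t`).
#'
#' @param km an `nb_km`.
#' @param t time point.
#' @return list `surv`, `se` (both 1 and 0 before the first event).
#' @export
km_survival_at <- function(km, t) {
  idx <- max(which(km$time <= t), 0L)
  if (idx == 0L) return(list(surv = 1, se = 0))
  list(surv = km$surv[idx], se = km$se[idx])
}

#' G-sample log-rank test
#'
#' Classic log-rank: at each distinct event time the observed events per
#' group are compared with their hypergeometric expectation given the
#' risk sets; the chi-square statistic uses the full covariance of the
#' first G-1 groups, with df = G - 1.
#'
#' @param groups group labels (>= 2 non-empty groups).
#' @param times,events as in [km_estimate()].
#' @return list `chisq`, `df`, `p`.
#' @export
logrank_test <- function(groups, times, events) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2L) stopf("logrank_test: need >= 2 non-empty groups")
  if (length(groups) != length(times) || length(times) != length(events))
    stopf("logrank_test: input length mismatch")
  G <- length(lev)
  gidx <- match(groups, lev)
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in ev_times) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    d_t <- sum(events == 1 & times == t)
    if (n_t == 0L || d_t == 0L) next
    n_g <- tabulate(gidx[at_risk], nbins = G)
    d_g <- tabulate(gidx[events == 1 & times == t], nbins = G)
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1L) {
      f <- d_t * (n_t - d_t) / (n_t - 1)
      p_g <- n_g / n_t
      V <- V + f * (diag(p_g, G) - tcrossprod(p_g))
    }
  }
  u <- (O - E)[-G]
  Vm <- V[-G, -G, drop = FALSE]
  # Moore-Penrose inverse: the covariance can be singular in tiny or
  # degenerate strata (all events in one risk pattern)
  chisq <- if (all(abs(u) < 1e-12)) 0 else {
    sv <- svd(Vm)
    pos <- sv$d > max(sv$d) * 1e-12
    vinv_u <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% u) / sv$d[pos])
    as.numeric(t(u) %*% vinv_u)
  }
  df <- G - 1L
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Mutual-exclusivity check between a gene set and a binary status
#'
#' Counts patients altered in any gene of `gene_set` who are also
#' positive for the status (e.g. MYCN amplification), and reports a
#' two-sided Fisher exact p for the 2x2 table as a descriptive summary.
#'
#' @param matrix an `nb_matrix`.
#' @param gene_set character vector of genes (e.g. `c("ARID1A","ARID1B")`).
#' @param status named logical vector (names = patient ids) or logical
#'   vector aligned with the matrix roster.
#' @return list `overlap`, `table` (2x2), `p`.
#' @export
mutual_exclusivity <- function(matrix, gene_set, status) {
  patients <- attr(matrix, "patients")
  if (is.null(names(status))) {
    if (length(status) != length(patients))
      stopf("mutual_exclusivity: status must be named or match the roster")
    names(status) <- patients
  }
  if (!all(patients %in% names(status)))
    stopf("mutual_exclusivity: status missing for some patients")
  altered <- patients %in% as.data.table(matrix)[gene %chin% gene_set, patient_id]
  pos <- as.logical(status[patients])
  tab <- table(factor(altered, c(TRUE, FALSE)), factor(pos, c(TRUE, FALSE)))
  list(overlap = sum(altered & pos), table = tab,
       p = fisher.test(tab)$p.value)
}

#' Stratified survival summary
#'
#' Splits the cohort into the study's strata - ARID1B-altered,
#' MYCN-amplified (and not ARID1B-altered), and neither - plus the
#' two-group ARID1B split, and reports per stratum the Kaplan-Meier
#' estimate with Greenwood SE at the horizon, together with global and
#' pairwise log-rank p-values. Empty strata are reported with `n = 0`
#' and missing estimates rather than raising.
#'
#' @param clinical `data.table` with `patient_id, risk_group,
#'   mycn_amplified` and `<endpoint>_time`, `<endpoint>_event` columns.
#' @param matrix an `nb_matrix` (supplies ARID1B status).
#' @param horizon months at which survival is read (default 36).
#' @param endpoint `"rfs"` or `"os"`.
#' @param high_risk_only restrict to the high-risk group first.
#' @return list of class `nb_strata`: `strata`
#'   (`data.table(stratum, n, surv, se)`), `logrank_global`,
#'   `logrank_pairwise`, `two_group` (ARID1B vs wild-type analogue).
#' @export
stratify_and_summarize <- function(clinical, matrix, horizon = 36,
                                   endpoint = "rfs", high_risk_only = FALSE) {
  cl <- as.data.table(clinical)
  if (high_risk_only) cl <- cl[risk_group == "high"]
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(cl)))
    stopf("stratify_and_summarize: missing %s/%s columns", tcol, ecol)
  arid1b <- unique(as.data.table(matrix)[gene == "ARID1B", patient_id])
  cl[, stratum := fifelse(patient_id %chin% arid1b, "ARID1B",
                          fifelse(mycn_amplified, "MYCN", "neither"))]
  strata_def <- c("ARID1B", "MYCN", "neither")
  strata <- rbindlist(lapply(strata_def, function(s) {
    sub <- cl[stratum == s]
    if (nrow(sub) == 0L)
      return(data.table(stratum = s, n = 0L, surv = NA_real_, se = NA_real_))
    km <- km_estimate(sub[[tcol]], sub[[ecol]])
    at <- km_survival_at(km, horizon)
    data.table(stratum = s, n = nrow(sub), surv = at$surv, se = at$se)
  }))
  present <- strata[n > 0L, stratum]
  logrank_global <- if (length(present) >= 2L)
    logrank_test(cl[stratum %chin% present, stratum],
                 cl[stratum %chin% present][[tcol]],
                 cl[stratum %chin% present][[ecol]]) else NULL
  pairs <- if (length(present) >= 2L) utils::combn(present, 2L, simplify = FALSE) else list()
  logrank_pairwise <- rbindlist(lapply(pairs, function(pr) {
    sub <- cl[stratum %chin% pr]
    lr <- logrank_test(sub$stratum, sub[[tcol]], sub[[ecol]])
    data.table(stratum_a = pr[1L], stratum_b = pr[2L], chisq = lr$chisq, p = lr$p)
  }))
  cl[, arid1b_group := fifelse(patient_id %chin% arid1b, "ARID1B", "wild-type")]
  two_group <- rbindlist(lapply(c("ARID1B", "wild-type"), function(g) {
    sub <- cl[arid1b_group == g]
    if (nrow(sub) == 0L)
      return(data.table(group = g, n = 0L, surv = NA_real_, se = NA_real_))
    km <- km_estimate(sub[[tcol]], sub[[ecol]])
    at <- km_survival_at(km, horizon)
    data.table(group = g, n = nrow(sub), surv = at$surv, se = at$se)
  }))
  two_group_p <- if (cl[, uniqueN(arid1b_group)] == 2L)
    logrank_test(cl$arid1b_group, cl[[tcol]], cl[[ecol]])$p else NA_real_
  out <- list(strata = strata, logrank_global = logrank_global,
              logrank_pairwise = logrank_pairwise, two_group = two_group,
              two_group_p = two_group_p, endpoint = endpoint,
              horizon = horizon, high_risk_only = high_risk_only)
  class(out) <- "nb_strata"
  out
}
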