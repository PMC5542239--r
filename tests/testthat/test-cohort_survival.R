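test_that("prevalence counts patients once per gene", {
  som <- data.table(sample_id = c("P1", "P1", "P2"), gene = "ALK",
                    effect = "missense")
  cnv <- data.table(sample_id = character(), gene = character(),
                    class = character())
  m <- build_alteration_matrix(som, cnv, sprintf("P%d", 1:72))
  # fabricate 12 ALK-altered of 72 via direct matrix rows
  m12 <- data.table(patient_id = sprintf("P%d", 1:12), gene = "ALK",
                    cell = "snv_indel")
  setattr(m12, "patients", sprintf("P%d", 1:72))
  tab <- prevalence_table(m12)
  expect_identical(tab$n_altered, 12L)
  expect_equal(round(100 * tab$fraction, 1), 16.7)
  # the duplicated-variant patient still counts once
  tab2 <- prevalence_table(m)
  expect_identical(tab2$n_altered, 2L)
  empty <- data.table(patient_id = character(), gene = character(),
                      cell = character())
  setattr(empty, "patients", character())
  expect_error(prevalence_table(empty), "empty cohort")
})

test_that("KM worked examples reproduce the published stratum estimates", {
  # 5 subjects: censored 6, event 12, censored 18, event 24, censored 36+
  km <- km_estimate(c(6, 12, 18, 24, 40), c(0, 1, 0, 1, 0))
  expect_equal(km_survival_at(km, 36)$surv, (3 / 4) * (1 / 2))
  # 4 high-risk subjects: censored 6, event 12, event 24, censored 36+
  km2 <- km_estimate(c(6, 12, 24, 40), c(0, 1, 1, 0))
  expect_equal(km_survival_at(km2, 36)$surv, (2 / 3) * (1 / 2))
  # no events: S = 1, SE = 0 throughout
  km3 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_true(all(km3$se == 0))
  # n distinct events, no censoring: empirical survival
  km4 <- km_estimate(1:5, rep(1, 5))
  expect_equal(km4$surv, (5:1 - 1) / 5)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_estimate(numeric(), integer()), "no subjects")
})

test_that("KM and Greenwood match an independent oracle and survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    times <- sample(1:5, n, replace = TRUE)      # forces ties
    events <- rbinom(n, 1, 0.6)
    km <- km_estimate(times, events)
    for (t_eval in c(1.5, 3, 5)) {
      o <- km_oracle(times, events, t_eval)
      at <- km_survival_at(km, t_eval)
      expect_equal(at$surv, o$surv, tolerance = 1e-10)
      expect_equal(at$se, o$se, tolerance = 1e-10)
    }
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    sm <- summary(sf, times = sort(unique(times)), extend = TRUE)
    ours <- vapply(sort(unique(times)),
                   function(tt) km_survival_at(km, tt)$surv, 0)
    expect_equal(ours, sm$surv, tolerance = 1e-10)
  }
})

test_that("log-rank: degenerate and symmetry properties", {
  times <- c(3, 5, 8, 8, 12, 20)
  events <- c(1, 0, 1, 1, 0, 1)
  # two identical groups duplicated: statistic 0, p 1
  lr <- logrank_test(rep(c("a", "b"), each = 6), rep(times, 2), rep(events, 2))
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)
  # label swap leaves the statistic unchanged
  g <- c("a", "a", "b", "a", "b", "b")
  l1 <- logrank_test(g, times, events)
  l2 <- logrank_test(ifelse(g == "a", "b", "a"), times, events)
  expect_equal(l1$chisq, l2$chisq)
  # permutation of subject order leaves it unchanged
  set.seed(2); o <- sample(6)
  l3 <- logrank_test(g[o], times[o], events[o])
  expect_equal(l1$chisq, l3$chisq)
  expect_error(logrank_test(rep("a", 6), times, events), "2 non-empty")
})

test_that("log-rank matches brute force and survival::survdiff", {
  skip_if_not_installed("survival")
  # the fixed 6-subject example against the hand tally
  g <- c("a", "a", "a", "b", "b", "b")
  times <- c(2, 4, 6, 3, 8, 9)
  events <- c(1, 1, 0, 1, 1, 0)
  lr <- logrank_test(g, times, events)
  o <- logrank_oracle_2g(g, times, events)
  expect_equal(lr$chisq, o$chisq, tolerance = 1e-10)
  expect_equal(lr$p, o$p, tolerance = 1e-10)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(6:14, 1)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (uniqueN(g) < 2) next
    times <- sample(1:6, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) next
    lr <- logrank_test(g, times, events)
    o <- logrank_oracle_2g(g, times, events)
    expect_equal(lr$chisq, o$chisq, tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(times, events) ~ g)
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
  }
  # three groups against survdiff
  g3 <- rep(c("a", "b", "c"), each = 5)
  t3 <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10, 1, 2, 8, 9, 11)
  e3 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1)
  lr3 <- logrank_test(g3, t3, e3)
  sd3 <- survival::survdiff(survival::Surv(t3, e3) ~ g3)
  expect_identical(lr3$df, 2L)
  expect_equal(lr3$chisq, sd3$chisq, tolerance = 1e-8)
})

test_that("mutual exclusivity: overlap counting and Fisher oracle", {
  roster <- sprintf("P%02d", 1:72)
  m <- data.table(patient_id = roster[1:8], gene = rep(c("ARID1B", "ARID1A"), 4),
                  cell = "snv_indel")
  setattr(m, "patients", roster)
  status <- setNames(rep(FALSE, 72), roster)
  status[roster[c(1, 2, 20, 21, 22)]] <- TRUE   # two double positives
  me <- mutual_exclusivity(m, c("ARID1A", "ARID1B"), status)
  expect_identical(me$overlap, 2L)
  # Fisher p equals exhaustive hypergeometric enumeration on (3,0;5,64)
  m2 <- data.table(patient_id = roster[1:3], gene = "ARID1B", cell = "snv_indel")
  setattr(m2, "patients", roster)
  status2 <- setNames(rep(FALSE, 72), roster)
  status2[roster[4:8]] <- TRUE
  me2 <- mutual_exclusivity(m2, "ARID1B", status2)
  expect_identical(me2$overlap, 0L)
  expect_equal(me2$p, fisher_oracle(0, 3, 5, 64), tolerance = 1e-10)
})

test_that("stratified summary reports the three strata and empty ones gracefully", {
  clinical <- data.table(
    patient_id = sprintf("P%d", 1:8),
    risk_group = c(rep("high", 6), "non-high", "non-high"),
    mycn_amplified = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    os_time = c(6, 12, 24, 40, 10, 30, 50, 50),
    os_event = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 0L),
    rfs_time = c(6, 12, 24, 40, 10, 30, 50, 50),
    rfs_event = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 0L))
  m <- data.table(patient_id = sprintf("P%d", 1:4), gene = "ARID1B",
                  cell = "snv_indel")
  setattr(m, "patients", clinical$patient_id)
  s <- stratify_and_summarize(clinical, m, horizon = 36, endpoint = "os",
                              high_risk_only = TRUE)
  # ARID1B stratum is exactly the 4-subject worked example: S(36) = 1/3
  expect_equal(s$strata[stratum == "ARID1B", surv], 1 / 3)
  expect_identical(s$strata[stratum == "neither", n], 0L)
  expect_true(is.na(s$strata[stratum == "neither", surv]))
  expect_identical(s$strata[stratum == "MYCN", n], 2L)
  expect_identical(s$two_group[group == "ARID1B", n], 4L)
})

test_that("KM at the horizon recovers a configured survival fraction", {
  est <- vapply(1:40, function(i) {
    d <- simulate_survival(300, 0.905, horizon = 36, censoring_rate = 0.2,
                           seed = 2000 + i)
    km_survival_at(km_estimate(d$time, d$event), 36)$surv
  }, 0)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.905), 3 * mc_se + 1e-4)
})
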