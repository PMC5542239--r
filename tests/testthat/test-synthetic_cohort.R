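test_that("alteration prevalence endpoints behave: 0 means never, 1 means always", {
  gt <- default_gene_table(unique(default_panel()$gene))
  gt[, prevalence := 0]
  gt[gene == "ALK", prevalence := 1]
  cc <- cohort_config(gene_table = gt, n_patients = 10L)
  co <- generate_cohort(cc, seed = 3)
  expect_identical(sort(unique(co$truth$gene)), "ALK")
  expect_identical(uniqueN(co$truth$patient_id), 10L)
})

test_that("simulated ALK prevalence concentrates on the configured 12/72", {
  cc <- cohort_config()
  n_rep <- 150L
  frac <- vapply(seq_len(n_rep), function(i) {
    co <- generate_cohort(cc, seed = 10000 + i)
    uniqueN(co$truth[gene == "ALK", patient_id]) / cc$n_patients
  }, 0)
  q <- 12 / 72
  tol <- 3 * sqrt(q * (1 - q) / (cc$n_patients * n_rep))
  expect_lt(abs(mean(frac) - q), tol)
})

test_that("generators are pure functions of (config, seed)", {
  cc <- cohort_config(n_patients = 12L)
  s1 <- simulate_cohort(cc, seed = 77)
  s2 <- simulate_cohort(cc, seed = 77)
  expect_equal(s1$cohort$truth, s2$cohort$truth)
  expect_equal(s1$caller_calls, s2$caller_calls)
  expect_equal(s1$coverage, s2$coverage)
  expect_equal(s1$fish, s2$fish)
  s3 <- simulate_cohort(cc, seed = 78)
  expect_false(identical(s1$cohort$patients, s3$cohort$patients))
})

test_that("coverage/BAF expectations follow the purity mixture model", {
  p <- tiny_panel()
  # CN = 2 anywhere: expected ratio 1 regardless of purity
  for (pur in c(0.3, 0.7, 1)) {
    prof <- simulate_coverage(NULL, pur, p, depth_mean = 100, noise = FALSE)
    expect_equal(prof$coverage$mean_coverage, rep(100, nrow(p)))
    expect_equal(prof$baf$baf, rep(0.5, nrow(prof$baf)))
  }
  # CN = 4 at purity 1: ratio 2
  prof <- simulate_coverage(data.table(gene = "GENEA", cn = 4, n_minor = 2),
                            1, p, depth_mean = 100, noise = FALSE)
  expect_equal(prof$coverage[grepl("GENEA", exon_id), mean_coverage],
               rep(200, 3))
  # CN = 1 (nB = 0) at purity 0.5: BAF (0 + 0.5)/(0.5 + 1) = 1/3,
  # ratio (0.5 + 1)/2 = 0.75
  prof <- simulate_coverage(data.table(gene = "GENEB", cn = 1, n_minor = 0),
                            0.5, p, depth_mean = 100, noise = FALSE)
  expect_equal(prof$baf[gene == "GENEB", baf], rep(1 / 3, 3))
  expect_equal(prof$coverage[grepl("GENEB", exon_id), mean_coverage],
               rep(75, 2))
  expect_error(simulate_coverage(NULL, 1.5, p), "purity")
  expect_error(simulate_coverage(NULL, 0.5, p, depth_mean = -1), "positive")
})

test_that("perfect callers reproduce the truth set; FPs carry signatures", {
  truth <- data.table(sample_id = c("S1", "S1", "S2"), chrom = "chr1",
                      pos = c(100L, 500L, 100L), ref = "A", alt = "G",
                      vaf = c(0.1, 0.3, 0.25))
  perfect <- data.table(caller = c("a", "b"), sensitivity = 1, fp_rate = 0)
  out <- simulate_caller_outputs(truth, perfect, tiny_panel(), noise = FALSE,
                                 seed = 1)
  for (cl in c("a", "b")) {
    expect_identical(nrow(out$calls[[cl]]), 3L)
    expect_equal(out$calls[[cl]]$allele_fraction, truth$vaf)
  }
  expect_identical(nrow(out$fp_log), 0L)

  noisy <- data.table(caller = "a", sensitivity = 1, fp_rate = 0.5)
  out2 <- simulate_caller_outputs(truth, noisy, tiny_panel(), noise = TRUE,
                                  fp_slots = 10L, seed = 4)
  expect_gt(nrow(out2$fp_log), 0L)
  expect_true(all(out2$fp_log$signature %in% c("strand_bias", "cluster")))
})

test_that("survival generator matches its closed form and endpoints", {
  # s = 1: no events, ever
  d <- simulate_survival(50, 1, seed = 1)
  expect_identical(sum(d$event), 0L)
  expect_error(simulate_survival(5, 0), "\\(0, 1\\]")
  # lambda = -log(0.905)/36: verify via the large-sample event fraction
  d <- simulate_survival(10000, 0.375, horizon = 36, censoring_rate = 0,
                         admin_horizon = 1e9, seed = 42)
  emp_s36 <- mean(d$time > 36)
  expect_lt(abs(emp_s36 - 0.375), 3 * sqrt(0.375 * 0.625 / 10000))
})

test_that("FISH counts always cover 50 nuclei; amplified/normal separate cleanly", {
  amp_calls <- vapply(1:400, function(i)
    score_mycn(simulate_fish_counts(TRUE, seed = i))$amplified, NA)
  wt_calls <- vapply(1:400, function(i)
    score_mycn(simulate_fish_counts(FALSE, seed = i))$amplified, NA)
  expect_gt(mean(amp_calls), 0.99)
  expect_lt(mean(wt_calls), 0.01)
  expect_identical(nrow(simulate_fish_counts(TRUE, seed = 9)), 50L)
})

test_that("ARID1 / MYCN exclusivity flag is honored exactly", {
  cc <- cohort_config(mycn_prevalence = 0.4)  # stress the overlap chance
  for (s in 1:25) {
    co <- generate_cohort(cc, seed = s)
    arid1 <- unique(co$truth[gene %in% c("ARID1A", "ARID1B"), patient_id])
    amp <- co$patients[mycn_amplified == TRUE, patient_id]
    expect_identical(length(intersect(arid1, amp)), 0L)
  }
  cc2 <- cohort_config(mycn_prevalence = 0.9, exclusivity = FALSE)
  overlaps <- vapply(1:20, function(s) {
    co <- generate_cohort(cc2, seed = s)
    arid1 <- unique(co$truth[gene %in% c("ARID1A", "ARID1B"), patient_id])
    length(intersect(arid1, co$patients[mycn_amplified == TRUE, patient_id]))
  }, 0L)
  expect_gt(sum(overlaps), 0L)
})

test_that("cohort files round-trip through the readers", {
  cc <- perfect_cohort_config(n_patients = 6L)
  sim <- simulate_cohort(cc, seed = 21)
  d <- file.path(tempdir(), "cohort_rt")
  write_cohort_files(sim, d)
  back <- read_cohort_dir(d)
  expect_identical(uniqueN(back$cohort$patients$patient_id), 6L)
  expect_equal(nrow(back$coverage), nrow(sim$coverage))
  res <- run_cohort_pipeline(back, pipeline_config())
  truthpg <- unique(sim$cohort$truth[, .(patient_id, gene)])
  called <- unique(as.data.table(res$matrix)[, .(patient_id, gene)])
  expect_equal(nrow(truthpg[!called, on = c("patient_id", "gene")]), 0L)
})
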