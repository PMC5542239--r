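test_that("normalization divides by sample median then reference, then log2", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tG1_ex1", "chr1\t200\t300\tG2_ex1",
               "chr1\t400\t500\tG3_ex1"), f)
  p3 <- read_panel(f)
  cov <- data.table(exon_id = p3$exon_id, mean_coverage = c(100, 200, 400))
  norm <- normalize_coverage(cov, flat_reference(p3), p3)
  expect_equal(norm$log2_ratio, c(-1, 0, 1))
  # scale invariance: doubling every exon changes nothing
  cov2 <- copy(cov)[, mean_coverage := mean_coverage * 2]
  expect_equal(normalize_coverage(cov2, flat_reference(p3), p3)$log2_ratio,
               norm$log2_ratio)
  # sample identical to reference: all zero
  covr <- data.table(exon_id = p3$exon_id, mean_coverage = c(50, 100, 150))
  ref <- data.table(exon_id = p3$exon_id, ref_value = c(0.5, 1, 1.5),
                    masked = FALSE)
  expect_equal(normalize_coverage(covr, ref, p3)$log2_ratio, c(0, 0, 0))
  # zero median is a sample-level failure
  cov0 <- data.table(exon_id = p3$exon_id, mean_coverage = c(0, 0, 0))
  expect_error(normalize_coverage(cov0, flat_reference(p3), p3), "median")
})

test_that("masked reference exons propagate and fully-masked genes are omitted", {
  p <- tiny_panel()
  ref <- flat_reference(p)
  ref[grepl("GENEC", exon_id), ref_value := 0]
  cov <- data.table(exon_id = p$exon_id, mean_coverage = rep(100, nrow(p)))
  norm <- normalize_coverage(cov, ref, p)
  expect_true(all(norm[gene == "GENEC", masked]))
  expect_warning(cn <- call_copy_number(norm, 1, pipeline_config()), "GENEC")
  expect_false("GENEC" %in% cn$gene)
})

test_that("noise-free round trip inverts the mixture exactly (1e-9)", {
  p <- tiny_panel()
  ref <- flat_reference(p)
  cfg <- pipeline_config()
  for (pur in seq(0.3, 1, by = 0.1)) {
    for (cn_true in 0:8) {
      prof <- simulate_coverage(
        data.table(gene = "GENEB", cn = cn_true, n_minor = 0),
        pur, p, depth_mean = 400, noise = FALSE)
      norm <- normalize_coverage(prof$coverage, ref, p)
      cn <- call_copy_number(norm, pur, cfg)
      expect_lt(abs(cn[gene == "GENEB", cn] - cn_true), 1e-9)
      expect_lt(abs(cn[gene == "GENEA", cn] - 2), 1e-9)
    }
  }
})

test_that("copy number is strictly increasing in the coverage ratio", {
  cfg <- pipeline_config()
  for (pur in c(0.4, 1)) {
    cns <- vapply(seq(0.2, 3, by = 0.1), function(r) {
      norm <- data.table(exon_id = "e", gene = "G", log2_ratio = log2(r),
                         masked = FALSE)
      call_copy_number(norm, pur, cfg)$cn
    }, 0)
    expect_true(all(diff(cns) > 0))
  }
})

test_that("class thresholds are strict: CN 4 is neutral, CN < 1 is loss", {
  cfg <- pipeline_config()
  # p = 1, gene log2 ratio 1 -> r = 2 -> CN = 4 -> neutral, not gain
  norm <- data.table(exon_id = "e", gene = "G", log2_ratio = 1, masked = FALSE)
  cn <- call_copy_number(norm, 1, cfg)
  expect_equal(cn$cn, 4)
  expect_identical(cn$class, "neutral")
  # p = 0.5, r = 0.6 -> CN = 0.4 -> loss
  norm2 <- data.table(exon_id = "e", gene = "G", log2_ratio = log2(0.6),
                      masked = FALSE)
  cn2 <- call_copy_number(norm2, 0.5, cfg)
  expect_equal(cn2$cn, 0.4)
  expect_identical(cn2$class, "loss")
  # dense CN sweep: exactly the values < 1 are loss, > 4 gain
  for (pur in c(0.5, 1)) {
    sweep <- seq(0, 8, by = 0.25)
    classes <- vapply(sweep, function(k) {
      r <- (pur * k + 2 * (1 - pur)) / 2
      n <- data.table(exon_id = "e", gene = "G", log2_ratio = log2(max(r, 1e-12)),
                      masked = FALSE)
      call_copy_number(n, pur, cfg)$class
    }, "")
    expect_identical(classes == "loss", sweep < 1)
    expect_identical(classes == "gain", sweep > 4)
  }
})

test_that("purity estimation: exact on the grid noise-free, flagged when flat", {
  p <- default_panel()
  cfg <- pipeline_config()
  ref <- flat_reference(p)
  prof <- simulate_coverage(
    data.table(gene = c("ATM", "ALK"), cn = c(0, 8), n_minor = c(0, 0)),
    0.7, p, depth_mean = 500, noise = FALSE)
  norm <- normalize_coverage(prof$coverage, ref, p)
  est <- estimate_purity(norm, prof$baf, cfg, p)
  expect_true(est$identifiable)
  expect_equal(est$purity, 0.70)
  # flat profile, BAF 0.5 everywhere: unidentifiable, p set to 1
  prof2 <- simulate_coverage(NULL, 0.6, p, depth_mean = 500, noise = FALSE)
  est2 <- estimate_purity(normalize_coverage(prof2$coverage, ref, p),
                          prof2$baf, cfg, p)
  expect_false(est2$identifiable)
  expect_equal(est2$purity, 1)
  expect_error(estimate_purity(norm, prof$baf,
                               pipeline_config(purity_grid = numeric())),
               "grid")
})

test_that("single-copy loss at p = 0.5 ties BAF 1/3 to log2 -0.415", {
  p <- tiny_panel()
  prof <- simulate_coverage(data.table(gene = "GENEB", cn = 1, n_minor = 0),
                            0.5, p, depth_mean = 1000, noise = FALSE)
  norm <- normalize_coverage(prof$coverage, flat_reference(p), p)
  expect_equal(unique(norm[gene == "GENEB", log2_ratio]), log2(0.75),
               tolerance = 1e-12)
  expect_equal(prof$baf[gene == "GENEB", baf], rep(1 / 3, 3))
})

test_that("purity recovery under realistic noise: median error within 0.05", {
  p <- default_panel()
  cfg <- pipeline_config()
  ref <- build_reference_profile(p, n_normals = 20, depth_mean = 500,
                                 nb_dispersion = 0.1, noise = TRUE, seed = 99)
  set.seed(7)
  n_rep <- 40L
  errs <- vapply(seq_len(n_rep), function(i) {
    pt <- runif(1, 0.3, 1)
    prof <- simulate_coverage(
      data.table(gene = c("ATM", "ALK"), cn = c(1, 8), n_minor = c(0, 0)),
      pt, p, depth_mean = 500, nb_dispersion = 0.1, noise = TRUE,
      het_sites_per_gene = 3, seed = 5000 + i)
    norm <- normalize_coverage(prof$coverage, ref, p)
    abs(estimate_purity(norm, prof$baf, cfg, p)$purity - pt)
  }, 0)
  expect_lte(median(errs), 0.05)
})
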