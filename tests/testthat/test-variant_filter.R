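test_that("merge collapses identical calls, unions callers, takes median AF", {
  a <- mkcall(pos = 100L, af = 0.10, fwd = 5L, rev = 5L, caller = "MuTect")
  b <- mkcall(pos = 100L, af = 0.12, fwd = 20L, rev = 22L, caller = "LoFreq")
  c <- mkcall(pos = 100L, af = 0.20, fwd = 8L, rev = 9L, caller = "SNVer")
  m <- merge_callers(list(a, b, c))
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_callers, 3L)
  expect_identical(m$callers, "LoFreq,MuTect,SNVer")
  expect_equal(m$allele_fraction, 0.12)          # median of 0.10/0.12/0.20
  expect_identical(m$alt_forward, 20L)           # deepest caller's strands
  # three disjoint variants, one caller each
  m2 <- merge_callers(list(mkcall(pos = 1L), mkcall(pos = 2L, caller = "LoFreq"),
                           mkcall(pos = 3L, caller = "SNVer")))
  expect_identical(nrow(m2), 3L)
  expect_true(all(m2$n_callers == 1L))
  # conflicting ref alleles at one position
  expect_error(merge_callers(list(mkcall(pos = 9L, ref = "A"),
                                  mkcall(pos = 9L, ref = "C", caller = "LoFreq"))),
               "conflicting ref")
})

test_that("strand-bias filter applies the exact binomial rule", {
  cfg <- pipeline_config()
  m <- as_merged(mkcall(pos = 100L, fwd = 50L, rev = 48L),
                 mkcall(pos = 200L, fwd = 60L, rev = 0L),
                 mkcall(pos = 300L, fwd = 12L, rev = 0L))  # biased but p too big
  f <- filter_artifacts(m, cfg)
  expect_identical(f[pos == 100L, filter_status], "pass")
  expect_identical(f[pos == 200L, filter_reason], "strand_bias")
  # 2 * 0.5^12 = 4.9e-4 < 1e-3: removed; 2 * 0.5^9 = 3.9e-3: retained
  expect_identical(f[pos == 300L, filter_status], "removed")
  m9 <- as_merged(mkcall(pos = 400L, fwd = 9L, rev = 0L))
  expect_identical(filter_artifacts(m9, cfg)$filter_status, "pass")
  # closed-form p equals binom.test
  expect_equal(2 * pbinom(0, 60, 0.5), binom.test(0, 60)$p.value)
})

test_that("cluster filter removes >= 3 distinct calls in a 10-bp window", {
  cfg <- pipeline_config()
  m <- as_merged(mkcall(pos = 100L), mkcall(pos = 104L), mkcall(pos = 108L),
                 mkcall(pos = 500L), mkcall(pos = 509L),
                 mkcall(pos = 800L, sample_id = "S2"),
                 mkcall(pos = 804L, sample_id = "S2"))
  f <- filter_artifacts(m, cfg)
  expect_identical(f[pos %in% c(100L, 104L, 108L), unique(filter_reason)],
                   "cluster")
  expect_identical(f[pos %in% c(500L, 509L), unique(filter_status)], "pass")
  expect_identical(f[sample_id == "S2", unique(filter_status)], "pass")
})

test_that("missing strand counts pass with a warning", {
  m <- as_merged(mkcall(pos = 100L, fwd = NA, rev = NA))
  expect_warning(f <- filter_artifacts(m, pipeline_config()), "strand counts")
  expect_identical(f$filter_status, "pass")
})

test_that("the two-rule germline filter truth table holds", {
  cfg <- pipeline_config()
  panel <- default_panel()
  ann <- default_annotation_table(panel)
  res <- default_population_resources(panel)
  hot <- ann[protein_change == "R1275Q"]
  popdb_site <- res$popdb[pop_af >= 0.02][1]
  pon_site <- res$pon[pon_count >= 20][1]
  clean_pos <- panel[gene == "TP53", start[1] + 5L]

  m <- as_merged(
    mkcall(chrom = ann[gene == "TP53" & effect == "missense"][1, chrom],
           pos = ann[gene == "TP53" & effect == "missense"][1, pos],
           ref = ann[gene == "TP53" & effect == "missense"][1, ref],
           alt = ann[gene == "TP53" & effect == "missense"][1, alt], af = 0.98),
    mkcall(chrom = hot$chrom, pos = hot$pos, ref = hot$ref, alt = hot$alt,
           af = 0.98),
    mkcall(chrom = popdb_site$chrom, pos = popdb_site$pos,
           ref = popdb_site$ref, alt = popdb_site$alt, af = 0.30),
    mkcall(chrom = pon_site$chrom, pos = pon_site$pos,
           ref = pon_site$ref, alt = pon_site$alt, af = 0.30),
    mkcall(chrom = panel[gene == "TP53", chrom[1]], pos = clean_pos, af = 0.30))
  m <- suppressWarnings(annotate_effects(m, ann, panel))
  f <- filter_germline(m, res, cfg)
  expect_identical(f$filter_reason[1], "germline_vaf")  # >= 97% VAF, not hotspot
  expect_identical(f$filter_status[2], "pass")          # hotspot exemption
  expect_identical(f$filter_reason[3], "popdb")         # popDB >= 1%
  expect_identical(f$filter_reason[4], "pon")           # PoN >= 3% of 480
  expect_identical(f$filter_status[5], "pass")          # below every threshold
})

test_that("filters are idempotent and account for every record", {
  cfg <- pipeline_config()
  panel <- default_panel()
  res <- default_population_resources(panel)
  set.seed(1)
  m <- as_merged(
    rbindlist(lapply(1:30, function(i)
      mkcall(pos = sample.int(5000L, 1), af = runif(1),
             fwd = sample.int(40L, 1) - 1L, rev = sample.int(40L, 1) - 1L))))
  m <- unique(m, by = c("sample_id", "chrom", "pos"))
  f1 <- filter_artifacts(m, cfg)
  f2 <- filter_artifacts(f1, cfg)
  expect_equal(f1$filter_status, f2$filter_status)
  g1 <- filter_germline(f1, res, cfg)
  g2 <- filter_germline(g1, res, cfg)
  expect_equal(g1$filter_reason, g2$filter_reason)
  expect_identical(nrow(g1), nrow(m))
  expect_identical(sum(g1$filter_status == "pass") +
                     sum(g1$filter_status == "removed"), nrow(m))
})

test_that("lowering the VAF cut never enlarges the retained set", {
  panel <- default_panel()
  res <- default_population_resources(panel)
  set.seed(2)
  m <- as_merged(rbindlist(lapply(1:40, function(i)
    mkcall(pos = 10000L + i * 7L, af = runif(1)))))
  prev <- Inf
  for (cut in c(0.99, 0.97, 0.8, 0.5, 0.2)) {
    cfg <- pipeline_config(vaf_germline_cut = cut)
    kept <- sum(filter_germline(m, res, cfg)$filter_status == "pass")
    expect_lte(kept, prev)
    prev <- kept
  }
})

test_that("perfect callers + clean genome: retained calls equal the truth set", {
  cc <- perfect_cohort_config(n_patients = 24L)
  sim <- simulate_cohort(cc, seed = 13)
  cfg <- pipeline_config()
  merged <- merge_callers(sim$caller_calls, cfg$min_callers)
  merged <- filter_artifacts(merged, cfg)
  merged <- annotate_effects(merged, default_annotation_table(cc$panel), cc$panel)
  merged <- filter_germline(merged, sim$resources, cfg)
  kept <- somatic_calls(merged)[, .(sample_id, chrom, pos, ref, alt)]
  truth <- sim$cohort$truth[!is.na(pos),
                            .(sample_id = patient_id, chrom, pos, ref, alt)]
  setkeyv(kept, names(kept)); setkeyv(truth, names(truth))
  expect_equal(as.data.frame(unique(kept)), as.data.frame(unique(truth)))
})

test_that("annotation assigns effects, hotspots, and positional fallback", {
  panel <- default_panel()
  ann <- default_annotation_table(panel)
  hot <- ann[protein_change == "F1174I"]
  stopg <- ann[gene == "BRCA1" & effect == "nonsense"]
  m <- as_merged(
    mkcall(chrom = hot$chrom, pos = hot$pos, ref = hot$ref, alt = hot$alt),
    mkcall(chrom = stopg$chrom, pos = stopg$pos, ref = stopg$ref,
           alt = stopg$alt),
    mkcall(chrom = panel[gene == "KRAS", chrom[1]],
           pos = panel[gene == "KRAS", start[1] + 60L]),  # on-panel, unannotated
    mkcall(chrom = "chr21", pos = 1L))                    # intergenic
  expect_warning(a <- annotate_effects(m, ann, panel), "outside panel")
  expect_true(a$hotspot[1])
  expect_identical(a$gene[1], "ALK")
  expect_identical(a$effect[2], "nonsense")
  expect_true(a$truncating[2])
  expect_identical(a$gene[3], "KRAS")
  expect_identical(a$effect[3], "other")
  expect_identical(a$effect[4], "other")
  expect_true(is.na(a$gene[4]))
})
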