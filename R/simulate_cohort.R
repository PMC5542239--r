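#' Simulate a complete cohort data bundle
#'
#' Runs [generate_cohort()] and then emits everything the downstream
#' pipeline consumes: per-caller variant calls (with injected artifact
#' false positives and residual germline variants), per-sample exon
#' coverage and B-allele-frequency tables, a normal reference profile,
#' FISH signal counts, and the clinical table. In the noise-free world
#' all patients without a copy-number truth alteration share one flat
#' coverage profile, which keeps large replicate simulations cheap.
#'
#' @param config an `nb_cohort_config`.
#' @param seed integer seed.
#' @param reference optional precomputed [build_reference_profile()]
#'   table, reused across replicate cohorts in simulation studies.
#' @return list of class `nb_cohort_sim`: `cohort` (see
#'   [generate_cohort()]), `caller_calls`, `fp_log`, `germline_log`,
#'   `coverage` (long `data.table`: `sample_id, exon_id, mean_coverage`),
#'   `baf` (long), `reference`, `fish` (long), `resources`.
#' @export
simulate_cohort <- function(config, seed, reference = NULL) {
  cohort <- generate_cohort(config, seed)
  panel <- config$panel
  patients <- cohort$patients
  truth <- cohort$truth
  resources <- default_population_resources(panel)

  tv <- truth[!is.na(pos),
              .(sample_id = patient_id, chrom, pos, ref, alt, vaf)]
  co <- simulate_caller_outputs(tv, config$caller_models, panel = panel,
                                sample_ids = patients$patient_id,
                                depth_mean = config$depth_mean,
                                noise = config$noise,
                                fp_slots = config$fp_slots,
                                seed = child_seed(seed, "callers"))
  germ <- inject_germline(patients$patient_id, panel, resources,
                          rate = config$germline_per_sample,
                          depth_mean = config$depth_mean,
                          seed = child_seed(seed, "germline"))
  if (nrow(germ)) {
    keep <- c("sample_id", "chrom", "pos", "ref", "alt", "allele_fraction",
              "alt_forward", "alt_reverse")
    for (cl in names(co$calls)) {
      g <- germ[, ..keep][, caller := cl]
      co$calls[[cl]] <- rbind(co$calls[[cl]], g)
    }
  }

  cn_by_patient <- split(
    truth[alteration_kind %chin% c("cn_gain", "cn_loss"),
          .(patient_id, gene, cn = true_cn, n_minor)],
    by = "patient_id", keep.by = FALSE)
  flat_profile <- NULL
  cov_list <- vector("list", nrow(patients))
  baf_list <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    cnt <- cn_by_patient[[pid]]
    if (is.null(cnt) || nrow(cnt) == 0L) {
      if (!config$noise) {
        if (is.null(flat_profile))
          flat_profile <- simulate_coverage(NULL, purity = 1, panel = panel,
                                            depth_mean = config$depth_mean,
                                            nb_dispersion = config$nb_dispersion,
                                            noise = FALSE,
                                            het_sites_per_gene = config$het_sites_per_gene,
                                            seed = child_seed(seed, "flat"))
        prof <- flat_profile
      } else {
        prof <- simulate_coverage(NULL, purity = patients$purity[i], panel = panel,
                                  depth_mean = config$depth_mean,
                                  nb_dispersion = config$nb_dispersion,
                                  noise = TRUE,
                                  het_sites_per_gene = config$het_sites_per_gene,
                                  seed = child_seed(seed, "cov", i))
      }
    } else {
      prof <- simulate_coverage(cnt, purity = patients$purity[i], panel = panel,
                                depth_mean = config$depth_mean,
                                nb_dispersion = config$nb_dispersion,
                                noise = config$noise,
                                het_sites_per_gene = config$het_sites_per_gene,
                                seed = child_seed(seed, "cov", i))
    }
    cov_list[[i]] <- prof$coverage$mean_coverage
    baf_list[[i]] <- prof$baf
  }
  coverage_long <- data.table(
    sample_id = rep(patients$patient_id, each = nrow(panel)),
    exon_id = rep(panel$exon_id, nrow(patients)),
    mean_coverage = unlist(cov_list, use.names = FALSE))
  nbaf <- nrow(baf_list[[1L]])
  baf_long <- rbindlist(baf_list)[
    , sample_id := rep(patients$patient_id, each = nbaf)]
  setcolorder(baf_long, "sample_id")

  if (is.null(reference))
    reference <- build_reference_profile(panel, depth_mean = config$depth_mean,
                                         nb_dispersion = config$nb_dispersion,
                                         noise = config$noise,
                                         seed = child_seed(seed, "reference"))

  set.seed(child_seed(seed, "fish"))
  nn <- config$n_nuclei
  np <- nrow(patients)
  fish <- data.table(
    sample_id = rep(patients$patient_id, each = nn),
    nucleus = rep(seq_len(nn), np),
    mycn_signals = rpois(np * nn, rep(fifelse(patients$mycn_amplified,
                                              config$fish_mycn_mean,
                                              config$fish_ref_mean), each = nn)),
    cep2_signals = rpois(np * nn, config$fish_ref_mean))

  out <- list(cohort = cohort, caller_calls = co$calls, fp_log = co$fp_log,
              germline_log = germ, coverage = coverage_long,
              baf = baf_long, reference = reference, fish = fish,
              resources = resources)
  class(out) <- "nb_cohort_sim"
  out
}

#' Inject residual germline variants
#'
#' Tumor-only sequencing sees germline variation alongside somatic
#' calls; the two-rule germline filter exists to remove it. Per unit
#' `rate`, each sample receives (independently, Bernoulli) one
#' near-homozygous variant (allele fraction 0.97-1.0) at a site absent
#' from all resources, one heterozygous variant at a population-database
#' site with frequency above the filter cut, and one at a
#' panel-of-normals site above the occurrence cut.
#'
#' @param sample_ids character vector of samples.
#' @param panel an `nb_panel`.
#' @param resources an `nb_resources`.
#' @param rate per-type injection probability per sample.
#' @param depth_mean depth scale for read counts.
#' @param seed integer seed.
#' @return `data.table` of injected records with a `germline_type` column.
#' @export
inject_germline <- function(sample_ids, panel, resources, rate = 1,
                            depth_mean = 500, seed = 1L) {
  empty <- data.table(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      allele_fraction = numeric(), alt_forward = integer(),
                      alt_reverse = integer(), germline_type = character())
  if (rate <= 0 || !length(sample_ids)) return(empty)
  set.seed(seed)
  ex1 <- panel[, .SD[1L], by = gene]
  popdb_hi <- resources$popdb[pop_af >= 0.01]
  pon_hi <- resources$pon[pon_count / resources$pon_n >= 0.03]
  rows <- list()
  for (s in sample_ids) {
    if (runif(1) < rate) {
      e <- ex1[sample.int(nrow(ex1), 1L)]
      af <- runif(1, 0.97, 1.0)
      rows[[length(rows) + 1L]] <- data.table(
        sample_id = s, chrom = e$chrom, pos = e$start + 92L, ref = "T",
        alt = "C", allele_fraction = af, germline_type = "high_vaf")
    }
    if (runif(1) < rate && nrow(popdb_hi)) {
      g <- popdb_hi[sample.int(nrow(popdb_hi), 1L)]
      rows[[length(rows) + 1L]] <- data.table(
        sample_id = s, chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
        allele_fraction = runif(1, 0.4, 0.6), germline_type = "popdb")
    }
    if (runif(1) < rate && nrow(pon_hi)) {
      g <- pon_hi[sample.int(nrow(pon_hi), 1L)]
      rows[[length(rows) + 1L]] <- data.table(
        sample_id = s, chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
        allele_fraction = runif(1, 0.3, 0.7), germline_type = "pon")
    }
  }
  if (!length(rows)) return(empty)
  out <- rbindlist(rows)
  n_alt <- round(out$allele_fraction * depth_mean)
  fwd <- rbinom(nrow(out), n_alt, 0.5)
  out[, `:=`(alt_forward = as.integer(fwd), alt_reverse = as.integer(n_alt - fwd))]
  out[]
}

#' Write a simulated cohort to the on-disk formats the pipeline reads
#'
#' Emits per-caller variant TSVs, the coverage, BAF and reference tables,
#' FISH counts, the clinical table, the panel BED, a config echo, and a
#' `truth/` directory with the generator's truth tables for oracle
#' comparison. Re-running with the same config and seed reproduces every
#' file byte for byte.
#'
#' @param sim an `nb_cohort_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  stopifnot(inherits(sim, "nb_cohort_sim"))
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  for (cl in names(sim$caller_calls))
    write_variant_tsv(sim$caller_calls[[cl]],
                      file.path(dir, "calls", paste0(cl, ".tsv")))
  fwrite(sim$coverage, file.path(dir, "coverage.tsv"), sep = "\t")
  fwrite(sim$baf, file.path(dir, "baf.tsv"), sep = "\t")
  fwrite(sim$reference, file.path(dir, "reference.tsv"), sep = "\t")
  fwrite(sim$fish, file.path(dir, "fish_counts.csv"))
  fwrite(sim$cohort$patients, file.path(dir, "clinical.csv"))
  write_panel_bed(sim$cohort$config$panel, file.path(dir, "panel.bed"))
  fwrite(sim$cohort$truth, file.path(dir, "truth", "alterations.tsv"),
         sep = "\t", na = ".")
  fwrite(sim$fp_log, file.path(dir, "truth", "fp_log.tsv"), sep = "\t")
  fwrite(sim$germline_log, file.path(dir, "truth", "germline_log.tsv"),
         sep = "\t")
  cfg <- sim$cohort$config
  cfg_echo <- cfg[setdiff(names(cfg), c("panel", "gene_table", "caller_models"))]
  cfg_echo$seed <- sim$cohort$seed
  yaml::write_yaml(cfg_echo, file.path(dir, "cohort_config.yaml"))
  fwrite(cfg$gene_table, file.path(dir, "truth", "gene_table.tsv"), sep = "\t")
  invisible(dir)
}
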