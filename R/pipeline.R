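#' Run the full downstream pipeline on a simulated (or loaded) cohort
#'
#' Variant side: per-caller calls are merged (union), artifact-filtered
#' (strand bias, clusters), annotated, and germline-filtered. CNV side:
#' per sample, coverage is reference-normalized, purity estimated from
#' ratios and BAFs, and gene-level purity-adjusted copy numbers called.
#' The two sides feed the alteration matrix, prevalence table,
#' actionability classification, FISH scoring and survival
#' stratification.
#'
#' Identical flat coverage profiles (shared by all copy-neutral samples
#' of a noise-free simulation) are analyzed once and the result reused.
#'
#' @param sim an `nb_cohort_sim` from [simulate_cohort()], or a
#'   compatible list with elements `caller_calls`, `coverage`, `baf`,
#'   `reference`, `fish`, `resources`, and `cohort$patients`.
#' @param config an `nb_config`.
#' @param survival_summaries also compute the stratified survival
#'   summaries (default TRUE; skipped in large replicate studies that
#'   only need prevalences).
#' @return list of class `nb_results`: `somatic`, `all_calls`, `cnv`,
#'   `purity`, `matrix`, `prevalence`, `actionable`, `fish_scores`,
#'   `clinical`, `survival` (rfs cohort split and os high-risk strata).
#' @export
run_cohort_pipeline <- function(sim, config = pipeline_config(),
                                survival_summaries = TRUE) {
  panel <- sim$cohort$config$panel
  resources <- sim$resources %||% default_population_resources(panel)
  ann <- default_annotation_table(panel)
  patients <- sim$cohort$patients

  merged <- merge_callers(sim$caller_calls, min_callers = config$min_callers)
  merged <- filter_artifacts(merged, config)
  merged <- annotate_effects(merged, ann, panel)
  merged <- filter_germline(merged, resources, config)
  somatic <- somatic_calls(merged)

  ids <- patients$patient_id
  ne <- nrow(panel)
  canonical <- nrow(sim$coverage) == ne * length(ids) &&
    identical(sim$coverage$sample_id, rep(ids, each = ne)) &&
    identical(sim$coverage$exon_id, rep(panel$exon_id, length(ids)))
  if (canonical) {
    covmat <- matrix(sim$coverage$mean_coverage, nrow = ne,
                     dimnames = list(NULL, ids))
    exon_ids <- panel$exon_id
  } else {
    cw <- dcast(sim$coverage, exon_id ~ sample_id, value.var = "mean_coverage")
    exon_ids <- cw$exon_id
    covmat <- as.matrix(cw[, !"exon_id"])
  }
  baf_by_sample <- split(sim$baf, by = "sample_id", keep.by = FALSE)
  cnv_list <- vector("list", nrow(patients))
  purity_list <- vector("list", nrow(patients))
  cache_cov <- NULL; cache_res <- NULL
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    covvec <- covmat[, pid]
    if (!is.null(cache_cov) && identical(covvec, cache_cov)) {
      res <- cache_res
    } else {
      covdt <- data.table(exon_id = exon_ids, mean_coverage = covvec)
      norm <- normalize_coverage(covdt, sim$reference, panel)
      pur <- estimate_purity(norm, baf_by_sample[[pid]], config, panel)
      cn <- call_copy_number(norm, pur, config)
      res <- list(pur = pur, cn = cn)
      if (is.null(cache_cov) || !pur$identifiable) {
        # cache the (single) flat profile seen in noise-free cohorts
        if (!pur$identifiable) { cache_cov <- covvec; cache_res <- res }
      }
    }
    cnv_list[[i]] <- data.table(sample_id = pid, res$cn)
    purity_list[[i]] <- data.table(sample_id = pid, purity = res$pur$purity,
                                   neutral_log2 = res$pur$neutral_log2,
                                   residual = res$pur$residual,
                                   identifiable = res$pur$identifiable)
  }
  cnv <- rbindlist(cnv_list)
  purity <- rbindlist(purity_list)

  mat <- build_alteration_matrix(somatic, cnv, patients$patient_id)
  prev <- prevalence_table(mat)
  act <- classify_actionable(somatic, cnv)

  fish_scores <- score_mycn_all(sim$fish, config$fish_fold_threshold)
  clinical <- copy(patients)
  clinical[fish_scores, on = c(patient_id = "sample_id"),
           `:=`(mycn_ratio = i.mycn_ratio, mycn_fish = i.mycn_amplified)]
  clinical[, mycn_amplified := mycn_fish][, mycn_fish := NULL]

  survival <- NULL
  if (survival_summaries) {
    survival <- list(
      rfs_all = stratify_and_summarize(clinical, mat,
                                       horizon = config$survival_horizon_months,
                                       endpoint = "rfs"),
      os_high_risk = stratify_and_summarize(clinical, mat,
                                            horizon = config$survival_horizon_months,
                                            endpoint = "os",
                                            high_risk_only = TRUE))
  }
  out <- list(somatic = somatic, all_calls = merged, cnv = cnv,
              purity = purity, matrix = mat, prevalence = prev,
              actionable = act, fish_scores = fish_scores,
              clinical = clinical, survival = survival, config = config)
  class(out) <- "nb_results"
  out
}

#' Write the cohort report files
#'
#' Emits (a) the patient-by-gene alteration matrix as TSV (cells `none`,
#' `snv_indel`, `cn_gain`, `cn_loss`, `both`), (b) the prevalence table,
#' (c) the actionability table, (d) a survival summary JSON with
#' Kaplan-Meier estimates, Greenwood SEs and log-rank p-values per
#' stratum, and (e) a run log echoing the configuration and seed.
#' Re-running on the same results is byte-identical.
#'
#' @param results an `nb_results` from [run_cohort_pipeline()].
#' @param out_dir output directory (created if needed).
#' @param seed seed echoed into the run log.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("write_report: cannot create directory %s", out_dir)
  patients <- attr(results$matrix, "patients")
  genes <- sort(unique(c(results$prevalence$gene, results$matrix$gene)))
  wide <- dcast(as.data.table(results$matrix), patient_id ~ gene,
                value.var = "cell", fill = "none")
  roster <- data.table(patient_id = patients)
  wide <- wide[roster, on = "patient_id"]
  for (cc in setdiff(names(wide), "patient_id")) set(wide, which(is.na(wide[[cc]])), cc, "none")
  fwrite(wide, file.path(out_dir, "alteration_matrix.tsv"), sep = "\t")
  fwrite(results$prevalence, file.path(out_dir, "prevalence.tsv"), sep = "\t")
  fwrite(results$actionable, file.path(out_dir, "actionability.tsv"), sep = "\t")
  fwrite(results$somatic, file.path(out_dir, "somatic_calls.tsv"), sep = "\t",
         na = ".")
  fwrite(results$cnv, file.path(out_dir, "cnv_calls.tsv"), sep = "\t")

  surv_json <- list()
  if (!is.null(results$survival)) {
    for (nm in names(results$survival)) {
      s <- results$survival[[nm]]
      surv_json[[nm]] <- list(
        endpoint = s$endpoint, horizon_months = s$horizon,
        high_risk_only = s$high_risk_only,
        strata = s$strata,
        two_group = s$two_group, two_group_logrank_p = s$two_group_p,
        logrank_global = if (!is.null(s$logrank_global))
          s$logrank_global[c("chisq", "df", "p")] else NULL,
        logrank_pairwise = s$logrank_pairwise)
    }
  }
  jsonlite::write_json(surv_json, file.path(out_dir, "survival_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  log_lines <- c(
    sprintf("nbpanel run, seed = %s", seed),
    "config:",
    vapply(setdiff(names(results$config), "purity_grid"), function(k)
      sprintf("  %s: %s", k, paste(format(results$config[[k]]), collapse = " ")),
      character(1L)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
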