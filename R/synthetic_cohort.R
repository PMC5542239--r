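#' Cohort simulation configuration
#'
#' Describes the statistical world the analysis assumes, parameterized
#' from the published cohort: 72 patients; per-gene alteration
#' prevalences as printed for the recurrently altered genes (ALK 12/72,
#' BRCA1 10/72, ATM 9/72, PTCH1 8/72, ARID1B 5/72, ARID1A 3/72, ATRX
#' 3/72, and single patients for HRAS, MET, ERBB2, STK11); a shared
#' background prevalence for the remaining panel genes solved so that the
#' configured probability of carrying at least one alteration equals the
#' printed cohort rate (63/72); alteration-kind mixtures per gene taken
#' from the printed breakdowns (e.g. 6 ALK hotspot SNVs, 5 other
#' missense, 1 copy-number gain among 12 ALK-altered patients); tumor
#' purity uniform on 0.3-1.0 (only specimens above 30% tumor content
#' were sequenced); negative-binomial exon depths; and
#' exponential survival per stratum matching the printed 3-year survival
#' fractions.
#'
#' @param panel an `nb_panel`; background genes are taken from it.
#' @param n_patients cohort size (default 72).
#' @param overall_alteration_rate configured probability that a patient
#'   carries at least one panel alteration (default 63/72).
#' @param gene_table optional replacement `data.table` of per-gene
#'   prevalences and kind weights (see [default_gene_table()]).
#' @param high_risk_fraction baseline probability of high-risk group
#'   membership (default 31/72, the size of the high-risk stratum).
#' @param arid1b_high_risk_fraction probability that an ARID1B-altered
#'   patient is high-risk (default 0.8: four of five).
#' @param mycn_prevalence MYCN FISH amplification prevalence
#'   (default 5/72; amplified patients are assigned high-risk).
#' @param exclusivity if `TRUE` (default), no patient carries both an
#'   ARID1A/ARID1B alteration and MYCN amplification.
#' @param purity_range truth tumor purity range (default `c(0.3, 1)`).
#' @param depth_mean mean exon sequencing depth (default 500 reads).
#' @param nb_dispersion negative-binomial dispersion of exon depth
#'   (default 0.1; 0 gives Poisson noise).
#' @param noise if `FALSE`, coverage and B-allele fractions are emitted
#'   at their expected values (the noise-free world used for exact
#'   round-trip checks) and caller read counts are deterministic.
#' @param het_sites_per_gene heterozygous SNP sites per gene contributing
#'   B-allele-frequency observations (default 3).
#' @param cn_gain_value,cn_loss_value true total copy number assigned to
#'   gain / loss truth alterations (defaults 8 and 0: high-level
#'   single-allele amplification and biallelic deletion, the patterns the
#'   strict `CN > 4` / `CN < 1` call thresholds imply).
#' @param vaf_range truth variant allele fraction range for somatic
#'   sequence alterations (default `c(0.05, 0.5)`).
#' @param caller_models `data.table(caller, sensitivity, fp_rate)`;
#'   defaults emulate three SNV callers with high sensitivity and small
#'   per-site false-positive rates.
#' @param fp_slots number of decoy sites per caller at which false
#'   positives may be injected (default 20).
#' @param germline_per_sample expected number of residual germline
#'   variants per sample presented to the filter: one near-homozygous
#'   high-VAF variant, one at a population-database site and one at a
#'   panel-of-normals site per unit rate (default 1; set 0 for the
#'   perfect-caller world).
#' @param survival named lists of 3-year survival fractions: `rfs`
#'   (`arid1b`, `wt`) for the whole cohort split and `os` (`arid1b`,
#'   `mycn`, `neither`) for the high-risk strata, from the printed
#'   Kaplan-Meier estimates.
#' @param survival_horizon_months horizon the fractions refer to (36).
#' @param censoring_rate probability a subject is censored before
#'   administrative follow-up end (default 0.2).
#' @param admin_horizon_months administrative follow-up end (default 60).
#' @param fish_mycn_mean,fish_ref_mean,n_nuclei Poisson means of per-
#'   nucleus MYCN signals in amplified tumors and CEP2 reference signals,
#'   and nuclei counted per sample (defaults 40, 2, 50).
#' @return object of class `nb_cohort_config`.
#' @export
cohort_config <- function(panel = default_panel(),
                          n_patients = 72L,
                          overall_alteration_rate = 63 / 72,
                          gene_table = NULL,
                          high_risk_fraction = 31 / 72,
                          arid1b_high_risk_fraction = 0.8,
                          mycn_prevalence = 5 / 72,
                          exclusivity = TRUE,
                          purity_range = c(0.3, 1),
                          depth_mean = 500,
                          nb_dispersion = 0.1,
                          noise = TRUE,
                          het_sites_per_gene = 3L,
                          cn_gain_value = 8,
                          cn_loss_value = 0,
                          vaf_range = c(0.05, 0.5),
                          caller_models = default_caller_models(),
                          fp_slots = 20L,
                          germline_per_sample = 1,
                          survival = list(
                            rfs = list(arid1b = 0.375, wt = 0.905),
                            os = list(arid1b = 0.333, mycn = 0.300,
                                      neither = 0.905)),
                          survival_horizon_months = 36,
                          censoring_rate = 0.2,
                          admin_horizon_months = 60,
                          fish_mycn_mean = 40,
                          fish_ref_mean = 2,
                          n_nuclei = 50L) {
  if (depth_mean <= 0) stopf("depth_mean must be positive")
  check_fraction(high_risk_fraction, "high_risk_fraction")
  check_fraction(mycn_prevalence, "mycn_prevalence")
  check_fraction(censoring_rate, "censoring_rate")
  check_fraction(purity_range, "purity_range")
  if (purity_range[1] <= 0) stopf("purity_range lower bound must be > 0")
  for (s in unlist(survival)) if (s <= 0 || s > 1)
    stopf("stratum survival fractions must lie in (0, 1]")
  if (is.null(gene_table))
    gene_table <- default_gene_table(unique(panel$gene), overall_alteration_rate)
  check_fraction(gene_table$prevalence, "gene prevalence")
  check_fraction(caller_models$sensitivity, "caller sensitivity")
  check_fraction(caller_models$fp_rate, "caller fp_rate")
  cfg <- list(
    panel = panel, n_patients = as.integer(n_patients),
    overall_alteration_rate = overall_alteration_rate,
    gene_table = gene_table,
    high_risk_fraction = high_risk_fraction,
    arid1b_high_risk_fraction = arid1b_high_risk_fraction,
    mycn_prevalence = mycn_prevalence, exclusivity = exclusivity,
    purity_range = purity_range, depth_mean = depth_mean,
    nb_dispersion = nb_dispersion, noise = noise,
    het_sites_per_gene = as.integer(het_sites_per_gene),
    cn_gain_value = cn_gain_value, cn_loss_value = cn_loss_value,
    vaf_range = vaf_range, caller_models = caller_models,
    fp_slots = as.integer(fp_slots),
    germline_per_sample = germline_per_sample,
    survival = survival,
    survival_horizon_months = survival_horizon_months,
    censoring_rate = censoring_rate,
    admin_horizon_months = admin_horizon_months,
    fish_mycn_mean = fish_mycn_mean, fish_ref_mean = fish_ref_mean,
    n_nuclei = as.integer(n_nuclei))
  class(cfg) <- "nb_cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_caller_models <- function() {
  data.table(caller = c("MuTect", "LoFreq", "SNVer"),
             sensitivity = c(0.97, 0.95, 0.92),
             fp_rate = c(0.02, 0.03, 0.03))
}

#' Per-gene alteration prevalences and kind mixtures
#'
#' Builds the gene table of the packaged cohort configuration. The
#' recurrently altered genes carry the printed prevalences and kind
#' breakdowns; every other panel gene shares a background prevalence
#' `q_bg` solved from
#' `(1 - q_bg)^n_bg = (1 - overall_rate) / prod(1 - q_named)`,
#' so that the configured probability of at least one alteration equals
#' `overall_rate` under independent per-gene draws.
#'
#' Kind weight columns: `w_missense`, `w_truncating` (nonsense),
#' `w_indel` (frameshift), `w_hotspot` (named activating change),
#' `w_exon_skip`, `w_cn_gain`, `w_cn_loss`.
#'
#' @param genes character vector of panel gene names.
#' @param overall_alteration_rate see [cohort_config()].
#' @return `data.table` keyed by `gene`.
#' @export
default_gene_table <- function(genes, overall_alteration_rate = 63 / 72) {
  named <- rbind(
    data.table(gene = "ALK",    prevalence = 12 / 72, w_missense = 5, w_truncating = 0, w_indel = 0, w_hotspot = 6, w_exon_skip = 0, w_cn_gain = 1, w_cn_loss = 0),
    data.table(gene = "BRCA1",  prevalence = 10 / 72, w_missense = 3, w_truncating = 3, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 4, w_cn_loss = 0),
    data.table(gene = "ATM",    prevalence = 9 / 72,  w_missense = 6, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 3),
    data.table(gene = "PTCH1",  prevalence = 8 / 72,  w_missense = 6, w_truncating = 2, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "ARID1B", prevalence = 5 / 72,  w_missense = 4, w_truncating = 0, w_indel = 1, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "ARID1A", prevalence = 3 / 72,  w_missense = 1, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "ATRX",   prevalence = 3 / 72,  w_missense = 1, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "HRAS",   prevalence = 1 / 72,  w_missense = 0, w_truncating = 0, w_indel = 0, w_hotspot = 1, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "MET",    prevalence = 1 / 72,  w_missense = 0, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 1, w_cn_gain = 0, w_cn_loss = 0),
    data.table(gene = "ERBB2",  prevalence = 1 / 72,  w_missense = 0, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 1, w_cn_loss = 0),
    data.table(gene = "STK11",  prevalence = 1 / 72,  w_missense = 0, w_truncating = 0, w_indel = 0, w_hotspot = 0, w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 1))
  named <- named[gene %in% genes]
  bg_genes <- setdiff(genes, named$gene)
  p_none_named <- prod(1 - named$prevalence)
  target_none <- 1 - overall_alteration_rate
  if (target_none > p_none_named)
    stopf("overall_alteration_rate %.3f is below the named-gene floor", overall_alteration_rate)
  q_bg <- if (length(bg_genes)) 1 - (target_none / p_none_named)^(1 / length(bg_genes)) else 0
  bg <- data.table(gene = bg_genes, prevalence = q_bg, w_missense = 1,
                   w_truncating = 0, w_indel = 0, w_hotspot = 0,
                   w_exon_skip = 0, w_cn_gain = 0, w_cn_loss = 0)
  out <- rbind(named, bg)
  setkey(out, gene)
  out[]
}

#' Analytic cohort rates implied by a configuration
#'
#' Closed-form consequences of the independent per-gene Bernoulli model:
#' the probability that a patient carries at least one alteration, the
#' per-gene prevalences, and the probability that at least one
#' actionability rule fires (per gene, the actionable share of its kind
#' weights: ALK hotspot SNVs and copy-number gain, BRCA1 truncating,
#' ATM and STK11 copy-number loss, HRAS hotspot, MET exon skip, ERBB2
#' copy-number gain). These are the values parameter-recovery
#' simulations are checked against.
#'
#' @param config an `nb_cohort_config`.
#' @return list: `any_alteration`, `gene_prevalence` (named vector),
#'   `actionable_fraction`.
#' @export
configured_rates <- function(config) {
  gt <- config$gene_table
  wcols <- c("w_missense", "w_truncating", "w_indel", "w_hotspot",
             "w_exon_skip", "w_cn_gain", "w_cn_loss")
  wsum <- rowSums(as.matrix(gt[, ..wcols]))
  act_share <- setNames(numeric(nrow(gt)), gt$gene)
  if ("ALK" %in% gt$gene)
    act_share["ALK"] <- gt[gene == "ALK", w_hotspot + w_cn_gain] / wsum[gt$gene == "ALK"]
  for (g in c("BRCA1", "ATM", "HRAS", "MET", "ERBB2", "STK11")) {
    if (!g %in% gt$gene) next
    w <- switch(g, BRCA1 = gt[gene == g, w_truncating],
                ATM = gt[gene == g, w_cn_loss],
                HRAS = gt[gene == g, w_hotspot],
                MET = gt[gene == g, w_exon_skip],
                ERBB2 = gt[gene == g, w_cn_gain],
                STK11 = gt[gene == g, w_cn_loss])
    act_share[g] <- w / wsum[gt$gene == g]
  }
  act_share[is.na(act_share)] <- 0
  a <- gt$prevalence * act_share[gt$gene]
  list(any_alteration = 1 - prod(1 - gt$prevalence),
       gene_prevalence = setNames(gt$prevalence, gt$gene),
       actionable_fraction = 1 - prod(1 - a))
}

kind_names <- c("w_missense" = "snv_missense", "w_truncating" = "snv_truncating",
                "w_indel" = "indel", "w_hotspot" = "snv_missense",
                "w_exon_skip" = "snv_truncating", "w_cn_gain" = "cn_gain",
                "w_cn_loss" = "cn_loss")

#' Generate the truth state of a synthetic cohort
#'
#' Draws, fully reproducibly from `seed`: per-gene alteration indicators
#' (independent Bernoulli at the configured prevalences), an alteration
#' kind per altered patient-gene pair from the gene's kind weights with a
#' concrete coding change taken from the packaged annotation table, truth
#' allele fractions and copy numbers, tumor purity, MYCN amplification
#' (never co-occurring with ARID1A/ARID1B alterations when the
#' exclusivity flag is set), risk group, and relapse-free / overall
#' survival outcomes per stratum.
#'
#' @param config an `nb_cohort_config`.
#' @param seed integer seed.
#' @return list of class `nb_cohort`: `patients` (one row per patient:
#'   id, risk group, MYCN status, purity, survival columns) and `truth`
#'   (one row per truth alteration with genomic and kind detail), plus
#'   `config` and `seed`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "nb_cohort_config"))
  gt <- config$gene_table
  n <- config$n_patients
  ann <- default_annotation_table(config$panel)
  set.seed(child_seed(seed, "cohort"))

  ids <- sprintf("P%03d", seq_len(n))
  # gene x patient alteration indicators
  G <- nrow(gt)
  hit <- matrix(runif(n * G) < rep(gt$prevalence, each = n), nrow = n)
  idx <- which(hit, arr.ind = TRUE)
  truth <- data.table(patient_id = ids[idx[, 1L]], gene = gt$gene[idx[, 2L]])

  # alteration kind per altered pair
  wcols <- names(kind_names)
  W <- as.matrix(gt[truth$gene, ..wcols, on = "gene"])
  pick <- integer(nrow(truth))
  if (nrow(truth)) {
    u <- runif(nrow(truth))
    cw <- t(apply(W, 1L, function(w) cumsum(w) / sum(w)))
    pick <- max.col(cw >= u, ties.method = "first")
  }
  truth[, kind_col := wcols[pick]]
  truth[, alteration_kind := unname(kind_names[kind_col])]
  truth[, `:=`(hotspot = kind_col == "w_hotspot", exon_skip = kind_col == "w_exon_skip")]

  # attach a concrete coding change for sequence alterations
  eff_for <- c(w_missense = "missense", w_truncating = "nonsense",
               w_indel = "frameshift")
  truth[, `:=`(chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
               alt = NA_character_, protein_change = NA_character_,
               effect = NA_character_)]
  truth[!kind_col %chin% c("w_cn_gain", "w_cn_loss"),
        c("chrom", "pos", "ref", "alt", "protein_change", "effect") := {
          kc <- kind_col[1L]; n_grp <- .N
          cand <- if (kc == "w_hotspot") ann[gene == .BY$gene & hotspot == TRUE]
          else if (kc == "w_exon_skip") ann[gene == .BY$gene & exon_skip == TRUE]
          else ann[gene == .BY$gene & effect == eff_for[[kc]] & hotspot == FALSE]
          if (nrow(cand) == 0L) stopf("no annotation entry for %s / %s", .BY$gene, kc)
          cand[sample.int(nrow(cand), n_grp, replace = TRUE),
               .(chrom, pos, ref, alt, protein_change, effect)]
        }, by = .(gene, kind_col)]
  truth[, vaf := NA_real_]
  truth[!is.na(pos), vaf := runif(sum(!is.na(pos)), config$vaf_range[1], config$vaf_range[2])]
  truth[, true_cn := 2]
  truth[alteration_kind == "cn_gain", true_cn := config$cn_gain_value]
  truth[alteration_kind == "cn_loss", true_cn := config$cn_loss_value]
  truth[, n_minor := ifelse(alteration_kind %chin% c("cn_gain", "cn_loss"), 0L, 1L)]
  truth[, kind_col := NULL]

  arid1 <- unique(truth[gene %chin% c("ARID1A", "ARID1B"), patient_id])
  arid1b <- unique(truth[gene == "ARID1B", patient_id])

  patients <- data.table(patient_id = ids)
  patients[, purity := runif(n, config$purity_range[1], config$purity_range[2])]
  eligible <- if (config$exclusivity) !(ids %chin% arid1) else rep(TRUE, n)
  patients[, mycn_amplified := eligible & runif(n) < config$mycn_prevalence]
  hr <- runif(n) < config$high_risk_fraction
  hr[ids %chin% arid1b] <- runif(sum(ids %chin% arid1b)) < config$arid1b_high_risk_fraction
  hr[patients$mycn_amplified] <- TRUE
  patients[, risk_group := ifelse(hr, "high", "non-high")]

  # survival: RFS split on ARID1B over the whole cohort; OS per the
  # high-risk three-way strata (non-high-risk patients follow "neither")
  sv <- config$survival
  rfs_frac <- ifelse(ids %chin% arid1b, sv$rfs$arid1b, sv$rfs$wt)
  os_frac <- ifelse(ids %chin% arid1b, sv$os$arid1b,
                    ifelse(patients$mycn_amplified, sv$os$mycn, sv$os$neither))
  draw <- function(frac, tag) {
    out <- data.table(time = numeric(n), event = integer(n))
    for (f in unique(frac)) {
      sel <- which(frac == f)
      d <- simulate_survival(length(sel), f,
                             horizon = config$survival_horizon_months,
                             censoring_rate = config$censoring_rate,
                             admin_horizon = config$admin_horizon_months,
                             seed = child_seed(seed, tag, round(f * 1e6)))
      out[sel, `:=`(time = d$time, event = d$event)]
    }
    out
  }
  rfs <- draw(rfs_frac, "rfs")
  os <- draw(os_frac, "os")
  patients[, `:=`(rfs_time = rfs$time, rfs_event = rfs$event,
                  os_time = os$time, os_event = os$event)]

  out <- list(patients = patients, truth = truth, config = config, seed = seed)
  class(out) <- "nb_cohort"
  out
}

#' Simulate right-censored survival times for one stratum
#'
#' Event times are exponential with rate `lambda = -log(s) / H`, the
#' unique constant hazard putting survival `s` at horizon `H`. Subjects
#' are censored uniformly on `(0, admin_horizon)` with probability
#' `censoring_rate`, and administratively at `admin_horizon` otherwise.
#' With `s = 1` no events ever occur and all records are censored.
#'
#' @param n number of subjects.
#' @param survival_fraction stratum survival `s` at the horizon, in (0,1].
#' @param horizon horizon `H` in months.
#' @param censoring_rate probability of early uniform censoring.
#' @param admin_horizon administrative follow-up end (months).
#' @param seed integer seed.
#' @return `data.table(time, event)` with `event` 1 = event, 0 = censored.
#' @export
simulate_survival <- function(n, survival_fraction, horizon = 36,
                              censoring_rate = 0.2, admin_horizon = 60,
                              seed = 1L) {
  if (survival_fraction <= 0 || survival_fraction > 1)
    stopf("survival_fraction must lie in (0, 1]")
  set.seed(seed)
  if (survival_fraction == 1) {
    t_event <- rep(Inf, n)
  } else {
    lambda <- -log(survival_fraction) / horizon
    t_event <- rexp(n, rate = lambda)
  }
  cens <- runif(n) < censoring_rate
  t_cens <- ifelse(cens, runif(n, 0, admin_horizon), admin_horizon)
  data.table(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate FISH signal counts for one sample
#'
#' Fifty (by default) non-overlapping nuclei are scored; per nucleus the
#' CEP2 reference signals are Poisson with mean 2, and the MYCN signals
#' Poisson with mean 2 (non-amplified) or `mycn_mean` (amplified,
#' default 40).
#'
#' @param amplified logical truth status.
#' @param seed integer seed.
#' @param n_nuclei nuclei scored (default 50).
#' @param mycn_mean amplified MYCN Poisson mean (default 40).
#' @param ref_mean CEP2 (and non-amplified MYCN) Poisson mean (default 2).
#' @return `data.table(nucleus, mycn_signals, cep2_signals)`.
#' @export
simulate_fish_counts <- function(amplified, seed = 1L, n_nuclei = 50L,
                                 mycn_mean = 40, ref_mean = 2) {
  set.seed(seed)
  data.table(nucleus = seq_len(n_nuclei),
             mycn_signals = rpois(n_nuclei, if (amplified) mycn_mean else ref_mean),
             cep2_signals = rpois(n_nuclei, ref_mean))
}
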