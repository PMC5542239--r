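#' Per-exon capture efficiencies of a panel
#'
#' Capture efficiency varies by exon (GC content, probe design) but is a
#' property of the assay, shared between tumors and the normal reference.
#' Efficiencies are derived deterministically from the exon index (a
#' golden-ratio low-discrepancy sequence pushed through a lognormal), so
#' every simulated sample and the reference see the same pattern.
#'
#' @param panel an `nb_panel`.
#' @param sd lognormal sigma of the efficiency spread (default 0.25);
#'   `sd = 0` gives uniform efficiency 1 (the noise-free world).
#' @return numeric vector aligned with `panel` rows.
#' @export
exon_efficiency <- function(panel, sd = 0.25) {
  if (sd == 0) return(rep(1, nrow(panel)))
  i <- seq_len(nrow(panel))
  h <- (i * 0.61803398874989) %% 1
  exp(sd * stats::qnorm(pmin(pmax(h, 1e-9), 1 - 1e-9)))
}

#' Simulate per-exon coverage and B-allele frequencies for one sample
#'
#' The generative model the copy-number caller inverts: with tumor purity
#' `p` and true total copy number `CN` for a gene, the expected coverage
#' ratio of its exons is `r = (p*CN + 2*(1-p)) / 2`, and the expected
#' B-allele fraction at a heterozygous site with `nB` minor-allele copies
#' is `(p*nB + (1-p)) / (p*CN + 2*(1-p))`. Exon depths are
#' negative-binomial around `depth_mean * efficiency * r` (Poisson when
#' `nb_dispersion = 0`); site alt counts are binomial. With
#' `noise = FALSE` both are emitted at their expected values (counts may
#' then be non-integer) and efficiencies are uniform, which makes the
#' normalize/call round trip exact.
#'
#' @param cn_table `data.table(gene, cn, n_minor)` for aberrant genes;
#'   genes absent from it are diploid (`cn = 2`, `n_minor = 1`).
#' @param purity tumor purity in (0, 1].
#' @param panel an `nb_panel`.
#' @param depth_mean mean depth of a diploid exon of average efficiency.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param noise draw noise (`TRUE`) or emit expectations (`FALSE`).
#' @param het_sites_per_gene heterozygous sites per gene.
#' @param seed integer seed.
#' @return list with `coverage` (`exon_id, mean_coverage`) and `baf`
#'   (`chrom, pos, gene, ref_count, alt_count, baf`).
#' @export
simulate_coverage <- function(cn_table = NULL, purity, panel,
                              depth_mean = 500, nb_dispersion = 0.1,
                              noise = TRUE, het_sites_per_gene = 3L,
                              seed = 1L) {
  if (purity <= 0 || purity > 1) stopf("purity must lie in (0, 1]")
  if (depth_mean <= 0) stopf("depth_mean must be positive")
  cn <- rep(2, nrow(panel)); nb <- rep(1, nrow(panel))
  if (!is.null(cn_table) && nrow(cn_table)) {
    if (any(cn_table$cn < 0)) stopf("copy numbers must be >= 0")
    m <- match(panel$gene, cn_table$gene)
    cn[!is.na(m)] <- cn_table$cn[m[!is.na(m)]]
    nb[!is.na(m)] <- cn_table$n_minor[m[!is.na(m)]]
  }
  p <- purity
  r <- (p * cn + 2 * (1 - p)) / 2
  eff <- exon_efficiency(panel, sd = if (noise) 0.25 else 0)
  mu <- depth_mean * eff * r
  set.seed(seed)
  cov_val <- if (!noise) mu
  else if (nb_dispersion > 0) rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  else rpois(length(mu), mu)
  coverage <- data.table(exon_id = panel$exon_id, mean_coverage = as.numeric(cov_val))

  ex1 <- panel[, .SD[1L], by = gene]
  k <- het_sites_per_gene
  genes_rep <- rep(ex1$gene, each = k)
  gi <- match(genes_rep, panel$gene)  # first exon row per gene
  site_pos <- rep(ex1$start, each = k) + 96L + 5L * (seq_len(k) - 1L)
  cn_g <- cn[gi]; nb_g <- nb[gi]; r_g <- r[gi]
  b <- (p * nb_g + (1 - p)) / (p * cn_g + 2 * (1 - p))
  d <- depth_mean * r_g
  if (noise) {
    tot <- rpois(length(d), d)
    alt <- rbinom(length(d), tot, b)
  } else {
    tot <- d
    alt <- b * d
  }
  baf <- data.table(chrom = rep(ex1$chrom, each = k), pos = site_pos,
                    gene = genes_rep, ref_count = tot - alt, alt_count = alt)
  baf[, baf := ifelse(tot > 0, alt_count / (ref_count + alt_count), NA_real_)]
  list(coverage = coverage, baf = baf)
}

#' Reference coverage profile from simulated normal samples
#'
#' Per-exon median of self-normalized coverage across diploid normal
#' samples, emulating the pattern-matched normal reference datasets of
#' the original pipeline. Exons with non-positive reference values are
#' masked.
#'
#' @param panel an `nb_panel`.
#' @param n_normals normal samples to simulate (default 20).
#' @param depth_mean,nb_dispersion,noise as in [simulate_coverage()].
#' @param seed integer seed.
#' @return `data.table(exon_id, ref_value, masked)`.
#' @export
build_reference_profile <- function(panel, n_normals = 20L, depth_mean = 500,
                                    nb_dispersion = 0.1, noise = TRUE,
                                    seed = 1L) {
  mat <- vapply(seq_len(n_normals), function(j) {
    cv <- simulate_coverage(NULL, purity = 1, panel = panel,
                            depth_mean = depth_mean,
                            nb_dispersion = nb_dispersion, noise = noise,
                            het_sites_per_gene = 1L,
                            seed = child_seed(seed, "normal", j))$coverage
    cv$mean_coverage / median(cv$mean_coverage)
  }, numeric(nrow(panel)))
  ref <- apply(mat, 1L, median)
  data.table(exon_id = panel$exon_id, ref_value = ref, masked = !(ref > 0))
}

#' Simulate the outputs of the three SNV/indel callers
#'
#' Each truth variant is detected independently per caller at the
#' caller's sensitivity; detected calls carry the truth allele fraction
#' and strand-balanced alt read counts. False positives are injected at
#' decoy panel positions with one of two artifact signatures the artifact
#' filter is designed to remove: fully strand-skewed alt reads, or a
#' trio of calls clustered within 8 bp. Injected records are listed in
#' the returned `fp_log`.
#'
#' @param truth_variants `data.table` with `sample_id, chrom, pos, ref,
#'   alt, vaf` (sequence alterations only).
#' @param caller_models `data.table(caller, sensitivity, fp_rate)`.
#' @param panel an `nb_panel` (decoy positions are drawn from it).
#' @param sample_ids samples in which false positives may appear
#'   (defaults to those present in `truth_variants`).
#' @param depth_mean read depth scale for alt counts.
#' @param noise deterministic strand split and guaranteed detection when
#'   `FALSE`.
#' @param fp_slots decoy site budget per caller and sample.
#' @param seed integer seed.
#' @return list: `calls` (named list of per-caller `data.table`s with
#'   `sample_id, chrom, pos, ref, alt, allele_fraction, alt_forward,
#'   alt_reverse, caller`) and `fp_log`.
#' @export
simulate_caller_outputs <- function(truth_variants, caller_models,
                                    panel = default_panel(),
                                    sample_ids = NULL,
                                    depth_mean = 500, noise = TRUE,
                                    fp_slots = 20L, seed = 1L) {
  check_fraction(caller_models$sensitivity, "sensitivity")
  check_fraction(caller_models$fp_rate, "fp_rate")
  tv <- as.data.table(truth_variants)
  if (is.null(sample_ids)) sample_ids <- unique(tv$sample_id)
  ex2 <- panel[, .SD[min(2L, .N)], by = gene]
  calls <- list(); fp_log <- list()
  for (ci in seq_len(nrow(caller_models))) {
    cm <- caller_models[ci]
    set.seed(child_seed(seed, "caller", ci))
    det <- if (noise) tv[runif(.N) < cm$sensitivity] else copy(tv)
    n_alt <- round(det$vaf * depth_mean)
    fwd <- if (noise) rbinom(nrow(det), n_alt, 0.5) else floor(n_alt / 2)
    out <- det[, .(sample_id, chrom, pos, ref, alt, allele_fraction = vaf)]
    out[, `:=`(alt_forward = as.integer(fwd),
               alt_reverse = as.integer(n_alt - fwd), caller = cm$caller)]
    if (cm$fp_rate > 0 && noise && length(sample_ids)) {
      n_fp <- rbinom(length(sample_ids), fp_slots, cm$fp_rate)
      fp_rows <- list()
      for (si in which(n_fp > 0L)) {
        for (j in seq_len(n_fp[si])) {
          e <- ex2[sample.int(nrow(ex2), 1L)]
          base_pos <- e$start + 40L + 2L * sample.int(30L, 1L)
          sig <- if (j %% 2L == 1L) "strand_bias" else "cluster"
          af <- runif(1L, 0.02, 0.1)
          if (sig == "strand_bias") {
            fp <- data.table(sample_id = sample_ids[si], chrom = e$chrom,
                             pos = base_pos, ref = "C", alt = "A",
                             allele_fraction = af, alt_forward = 60L,
                             alt_reverse = 0L, caller = cm$caller)
          } else {
            nr <- 15L
            fp <- data.table(sample_id = sample_ids[si], chrom = e$chrom,
                             pos = base_pos + c(0L, 4L, 8L), ref = "C",
                             alt = "A", allele_fraction = af,
                             alt_forward = nr, alt_reverse = nr,
                             caller = cm$caller)
          }
          fp_rows[[length(fp_rows) + 1L]] <- fp
          fp_log[[length(fp_log) + 1L]] <-
            fp[, .(sample_id, caller, chrom, pos, signature = sig)]
        }
      }
      if (length(fp_rows)) out <- rbind(out, rbindlist(fp_rows))
    }
    calls[[cm$caller]] <- out[]
  }
  list(calls = calls,
       fp_log = if (length(fp_log)) rbindlist(fp_log)
       else data.table(sample_id = character(), caller = character(),
                       chrom = character(), pos = integer(),
                       signature = character()))
}
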