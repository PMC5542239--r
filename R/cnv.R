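#' Reference-normalized per-exon log2 coverage ratios
#'
#' Each exon's mean coverage is divided by the sample's median exon
#' coverage (self-normalization, removing library size), then by the
#' reference profile's value for that exon (removing capture
#' efficiency), and transformed to the binary logarithm. Exons masked in
#' the reference (non-positive values) are propagated as masked.
#'
#' @param coverage `data.table(exon_id, mean_coverage)` for one sample.
#' @param reference `data.table(exon_id, ref_value, masked)` from
#'   [build_reference_profile()].
#' @param panel an `nb_panel` (supplies the gene of each exon).
#' @return `data.table(exon_id, gene, log2_ratio, masked)` in panel order.
#' @export
normalize_coverage <- function(coverage, reference, panel = default_panel()) {
  coverage <- as.data.table(coverage)
  cov <- coverage$mean_coverage[match(panel$exon_id, coverage$exon_id)]
  if (anyNA(cov))
    stopf("normalize_coverage: coverage missing for %d panel exon(s)",
          sum(is.na(cov)))
  ri <- match(panel$exon_id, reference$exon_id)
  refv <- reference$ref_value[ri]
  masked <- reference$masked[ri] | !(refv > 0)
  masked[is.na(masked)] <- TRUE
  med <- median(cov[!masked])
  if (!is.finite(med) || med <= 0)
    stopf("normalize_coverage: sample median coverage is zero; sample unusable")
  l <- rep(NA_real_, nrow(panel))
  l[!masked] <- log2((cov[!masked] / med) / refv[!masked])
  data.table(exon_id = panel$exon_id, gene = panel$gene, log2_ratio = l,
             masked = masked)
}

#' Estimate tumor purity from coverage ratios and B-allele frequencies
#'
#' Grid search over candidate purities under the two-component mixture
#' model: at purity `p` a gene with integer copy number `CN` has coverage
#' ratio `r = (p*CN + 2*(1-p))/2` and het-site folded B-allele fraction
#' `(p*nB + (1-p)) / (p*CN + 2*(1-p))` for the best integer minor-allele
#' count `nB <= CN/2`. The copy-neutral log2 level is first located as
#' the median of per-gene mean log2 ratios (exact when most genes are
#' diploid, and far less noisy than any per-exon statistic). For each
#' candidate `p`, every gene is assigned the integer copy number (0 to
#' `cn_max`) minimizing its summed squared coverage-ratio and folded-BAF
#' deviations plus a complexity penalty `c` charged to every non-diploid
#' assignment; `c = pen_factor * median((r - 1)^2)` is calibrated from
#' the data's own diploid scatter, so that noise cannot buy aberrant
#' copy numbers (the small-`p` overfitting degeneracy: as `p` shrinks,
#' the lattice of attainable ratios becomes dense and would otherwise
#' absorb diploid noise). In the noise-free world `c` collapses to 0 and
#' the fit is exact. The purity with the smallest total objective wins;
#' exact ties resolve to the largest purity (the least aberrant genome
#' explaining the data). A flat profile with all BAFs near 0.5 carries
#' no purity information: the solution is then flagged unidentifiable
#' and `p` set to 1.
#'
#' @param norm output of [normalize_coverage()].
#' @param baf `data.table` with `gene` (or `chrom, pos` resolvable
#'   through `panel`), `ref_count`, `alt_count`.
#' @param config an `nb_config` (supplies `purity_grid` and `cn_max`).
#' @param panel optional `nb_panel` for positional gene assignment.
#' @param w_baf weight of each squared BAF deviation relative to a
#'   squared coverage-ratio deviation (default 20: at panel depths a
#'   het-site allele fraction is far more precise than a gene's mean
#'   coverage ratio).
#' @param pen_factor multiplier on the median diploid scatter defining
#'   the non-diploid complexity penalty (default 3).
#' @return object of class `nb_purity`: `purity`, `neutral_log2`,
#'   `residual`, `identifiable`.
#' @export
estimate_purity <- function(norm, baf, config = pipeline_config(),
                            panel = NULL, w_baf = 20, pen_factor = 3) {
  grid <- config$purity_grid
  if (!length(grid)) stopf("estimate_purity: empty purity grid")
  usable <- norm[masked == FALSE]
  if (nrow(usable) == 0L) stopf("estimate_purity: no unmasked exons")
  baf <- as.data.table(baf)
  if (!"gene" %in% names(baf)) {
    if (is.null(panel)) stopf("estimate_purity: baf lacks 'gene'; supply panel")
    baf[, gene := panel_gene_at(panel, chrom, pos)]
  }
  baf <- baf[!is.na(gene) & (ref_count + alt_count) > 0]
  baf[, b := pmin(alt_count, ref_count) / (alt_count + ref_count)]

  gene_l <- usable[, .(l = mean(log2_ratio)), by = gene]
  neutral <- median(gene_l[is.finite(l), l])
  gene_r <- gene_l[, .(gene, r = 2^(l - neutral))]
  # -Inf log ratios (zero coverage) mean ratio 0
  gene_r[is.na(r), r := 0]

  flat <- (nrow(gene_r) == 0L ||
             max(abs(log2(pmax(gene_r$r, 2^-10)))) < 0.05) &&
    (nrow(baf) == 0L || max(abs(baf$b - 0.5)) < 0.05)
  if (flat) {
    out <- list(purity = 1, neutral_log2 = neutral, residual = 0,
                identifiable = FALSE)
    class(out) <- "nb_purity"
    return(out)
  }

  bmap <- match(baf$gene, gene_r$gene)
  ok_b <- !is.na(bmap)
  b_obs <- baf$b[ok_b]; b_gene <- bmap[ok_b]
  cn_max <- config$cn_max
  G <- nrow(gene_r)
  cpen <- pen_factor * median((gene_r$r - 1)^2)

  # all candidate purities evaluated at once; BAF deviations are computed
  # on unique observed values and aggregated per gene with one matrix
  # product (in the noise-free world only a handful of values occur)
  pv <- sort(grid)
  P <- length(pv)
  S <- length(b_obs)
  if (S) {
    ub <- sort(unique(b_obs))
    U <- length(ub)
    cnt <- matrix(0, G, U)
    tab <- table(b_gene, match(b_obs, ub))
    cnt[as.integer(rownames(tab)), as.integer(colnames(tab))] <- tab
  }
  best_gene <- matrix(Inf, G, P)
  for (k in 0:cn_max) {
    r_pred <- (pv * k + 2 * (1 - pv)) / 2
    col <- outer(gene_r$r, r_pred, "-")^2 + if (k == 2L) 0 else cpen
    if (S) {
      denom <- pv * k + 2 * (1 - pv)
      dev_ub <- matrix(Inf, U, P)
      for (nb in 0:max(floor(k / 2), 0L)) {
        pred <- (pv * nb + (1 - pv)) / denom
        d <- outer(ub, pred, "-")^2
        # denom 0 (CN 0 in a pure tumor): no reads expected, the site
        # carries no BAF information
        d[, denom <= 1e-12] <- 0
        dev_ub <- pmin(dev_ub, d)
      }
      col <- col + w_baf * (cnt %*% dev_ub)
    }
    best_gene <- pmin(best_gene, col)
  }
  obj_p <- colSums(best_gene)
  i_best <- max(which(obj_p <= min(obj_p) + 1e-15))  # ties: largest purity
  out <- list(purity = pv[i_best], neutral_log2 = neutral,
              residual = obj_p[i_best], identifiable = TRUE)
  class(out) <- "nb_purity"
  out
}

#' @export
print.nb_purity <- function(x, ...) {
  cat(sprintf("<nb_purity> p = %.2f%s, neutral log2 = %.4f, residual = %.3g\n",
              x$purity, if (x$identifiable) "" else " (unidentifiable)",
              x$neutral_log2, x$residual))
  invisible(x)
}

#' Purity-adjusted gene-level copy-number calls
#'
#' Per gene, the mean log2 ratio over its unmasked exons is inverted
#' through the purity mixture: `r = 2^(mean log2 - neutral)` and
#' `CN = (2*r - 2*(1-p)) / p`. Classes use the strict thresholds of the
#' original pipeline: loss when `CN < 1`, gain when `CN > 4` (a CN of
#' exactly 4 is neutral). In addition, a gene only leaves the neutral
#' class when its mean log2 ratio departs from the neutral level by more
#' than `cn_min_z` standard errors of the within-gene exon scatter -
#' without this evidence gate, the strict thresholds convert gene-level
#' coverage noise into copy-number calls at low purity. The gate
#' vanishes for noise-free data (the scatter is zero). Genes whose exons
#' are all masked are omitted with a warning.
#'
#' @param norm output of [normalize_coverage()].
#' @param purity an `nb_purity` (or a bare numeric purity, in which case
#'   the neutral level defaults to 0).
#' @param config an `nb_config`.
#' @param cn_min_z evidence gate in SE units (default 3.5).
#' @return `data.table(gene, log2_ratio, cn, class)`.
#' @export
call_copy_number <- function(norm, purity, config = pipeline_config(),
                             cn_min_z = 3.5) {
  if (is.numeric(purity)) purity <- structure(
    list(purity = purity, neutral_log2 = 0, residual = NA_real_,
         identifiable = TRUE), class = "nb_purity")
  p <- purity$purity
  if (p <= 0 || p > 1) stopf("call_copy_number: purity must lie in (0, 1]")
  norm <- as.data.table(norm)
  genes_all <- unique(norm$gene)
  live <- norm[masked == FALSE]
  dead <- setdiff(genes_all, unique(live$gene))
  if (length(dead))
    warnf("call_copy_number: omitting gene(s) with all exons masked: %s",
          paste(dead, collapse = ", "))
  gf <- factor(live$gene, levels = unique(live$gene))
  n_ex <- tabulate(gf)
  l_mean <- as.vector(rowsum(live$log2_ratio, gf)) / n_ex
  # within-gene exon scatter -> SE of the gene mean (0 for exact data);
  # floored by the pooled (median) per-gene scatter so that a lucky
  # low-variance gene cannot slip through the gate on a few exons
  ss <- as.vector(rowsum((live$log2_ratio - l_mean[as.integer(gf)])^2, gf))
  sd_g <- sqrt(ifelse(n_ex > 1L, ss / (n_ex - 1L), 0))
  sd_pool <- median(sd_g[is.finite(sd_g)])
  se <- pmax(sd_g, sd_pool) / sqrt(n_ex)
  calls <- data.table(gene = levels(gf),
                      log2_ratio = l_mean - purity$neutral_log2)
  r <- 2^calls$log2_ratio
  calls[, cn := (2 * r - 2 * (1 - p)) / p]
  calls[, class := fifelse(cn < config$loss_below, "loss",
                           fifelse(cn > config$gain_above, "gain", "neutral"))]
  calls[abs(log2_ratio) <= cn_min_z * se, class := "neutral"]
  calls[]
}
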