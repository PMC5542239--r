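#!/usr/bin/env Rscript
# Regenerates inst/extdata (the packaged default panel BED and default
# config). Deterministic: no RNG. Run from the repository root.

suppressPackageStartupMessages(library(data.table))

named <- c(ALK = "chr2", ARID1A = "chr1", ARID1B = "chr6", ATM = "chr11",
           ATRX = "chrX", BRCA1 = "chr17", ERBB2 = "chr17", HRAS = "chr11",
           MET = "chr7", PTCH1 = "chr9", STK11 = "chr19")

others <- c("ABL1", "AKT1", "AKT2", "APC", "AR", "AURKA", "BRAF", "BRCA2",
            "CCND1", "CCNE1", "CDH1", "CDK4", "CDK6", "CDKN2A", "CREBBP",
            "CSF1R", "CTNNB1", "DDR2", "EGFR", "EP300", "ESR1", "EZH2",
            "FBXW7", "FGFR1", "FGFR2", "FGFR3", "FGFR4", "FLT3", "GNA11",
            "GNAQ", "GNAS", "IDH1", "IDH2", "JAK1", "JAK2", "JAK3", "KDR",
            "KEAP1", "KIT", "KRAS", "MAP2K1", "MAP2K2", "MDM2", "MLH1",
            "MPL", "MSH2", "MSH6", "MTOR", "NF1", "NF2", "NOTCH1", "NPM1",
            "NRAS", "NTRK1", "PALB2", "PDGFRA", "PDGFRB", "PIK3CA",
            "PIK3R1", "PMS2", "PTEN", "PTPN11", "RB1", "RET", "ROS1",
            "SMAD4", "SMARCA4", "SMARCB1", "SMO", "SRC", "TP53", "TSC1")
stopifnot(length(named) + length(others) == 83L)

genes <- c(names(named), others)
chroms <- c(unname(named), paste0("chr", 1L + (seq_along(others) - 1L) %% 22L))

rows <- list()
per_chrom_slot <- integer()
for (i in seq_along(genes)) {
  g <- genes[i]; ch <- chroms[i]
  slot <- per_chrom_slot[ch] <- (if (is.na(per_chrom_slot[ch])) 0L else per_chrom_slot[ch]) + 1L
  base <- 1000000L + 300000L * (slot - 1L)
  n_ex <- 3L + (i %% 6L)
  for (k in seq_len(n_ex)) {
    s <- base + (k - 1L) * 2000L
    len <- 120L + ((i * 7L + k * 13L) %% 140L)
    rows[[length(rows) + 1L]] <- data.table(
      chrom = ch, start = s, end = s + len, name = sprintf("%s_ex%d", g, k))
  }
}
bed <- rbindlist(rows)
setorder(bed, chrom, start)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
fwrite(bed, "inst/extdata/panel_default.bed", sep = "\t", col.names = FALSE)
cat(sprintf("panel: %d genes, %d exons, %d bp covered\n",
            uniqueN(bed[, sub('_ex.*$', '', name)]), nrow(bed),
            sum(bed$end - bed$start)))

# default pipeline configuration, as YAML
if (requireNamespace("nbpanel", quietly = TRUE)) {
  nbpanel::write_config(nbpanel::pipeline_config(),
                        "inst/extdata/config_default.yaml")
  cat("wrote inst/extdata/config_default.yaml\n")
} else cat("nbpanel not installed; skipped config_default.yaml\n")
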