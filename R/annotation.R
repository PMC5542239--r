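#' Packaged variant annotation table
#'
#' A minimal stand-in for full transcript annotation: a deterministic
#' lookup keyed on `(chrom, pos, ref, alt)` giving gene, protein change
#' and effect class for a repertoire of synthetic coding changes in every
#' panel gene (two missense, one nonsense, one frameshift indel, one
#' synonymous each), plus the clinically pivotal real changes the study
#' names: the activating ALK hotspots R1275Q, F1174I and R1192G, HRAS
#' Q61R, a MET exon-14 skipping splice variant, and the ATRX missense
#' changes A1988S, V2189A and R498G. Protein positions outside the named
#' changes are placeholders, not transcript-accurate.
#'
#' @param panel an `nb_panel`; positions are placed inside its exons.
#' @return `data.table` with columns `chrom, pos, ref, alt, gene,
#'   protein_change, effect, hotspot, exon_skip`. `pos` is 1-based.
#' @export
default_annotation_table <- function(panel = default_panel()) {
  key <- panel_cache_key(panel)
  hit <- .nb_cache$annotation[[key]]
  if (!is.null(hit)) return(hit)
  ann <- build_annotation_table(panel)
  .nb_cache$annotation[[key]] <- ann
  ann
}

build_annotation_table <- function(panel) {
  ex1 <- panel[, .SD[1L], by = gene]
  ex2 <- panel[, .SD[min(2L, .N)], by = gene]
  gi <- seq_len(nrow(ex1))
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  a1 <- aa[1L + (gi %% 20L)]
  a2 <- aa[1L + ((gi + 7L) %% 20L)]
  base <- function(k) c("A", "C", "G", "T")[1L + (k %% 4L)]

  mk <- function(ex, off, ref, alt, pchange, effect) {
    data.table(chrom = ex$chrom, pos = ex$start + off + 1L, ref = ref,
               alt = alt, gene = ex$gene, protein_change = pchange,
               effect = effect, hotspot = FALSE, exon_skip = FALSE)
  }
  ann <- rbind(
    mk(ex1, 11L, base(gi), base(gi + 1L), sprintf("%s%d%s", a1, 100L + gi, a2), "missense"),
    mk(ex2, 21L, base(gi + 1L), base(gi + 2L), sprintf("%s%d%s", a2, 200L + gi, a1), "missense"),
    mk(ex1, 31L, base(gi + 2L), base(gi + 3L), sprintf("R%d*", 70L + gi), "nonsense"),
    mk(ex1, 41L, paste0(base(gi), "AG"), base(gi), sprintf("K%dfs", 150L + gi), "frameshift"),
    mk(ex1, 51L, base(gi + 3L), base(gi), sprintf("L%dL", 60L + gi), "synonymous"))

  special <- function(gene, off, ref, alt, pchange, effect, hotspot = FALSE,
                      exon_skip = FALSE) {
    e <- ex1[gene, on = "gene"]
    data.table(chrom = e$chrom, pos = e$start + off + 1L, ref = ref, alt = alt,
               gene = gene, protein_change = pchange, effect = effect,
               hotspot = hotspot, exon_skip = exon_skip)
  }
  ann <- rbind(
    ann,
    special("ALK", 61L, "G", "A", "R1275Q", "missense", hotspot = TRUE),
    special("ALK", 63L, "T", "A", "F1174I", "missense", hotspot = TRUE),
    special("ALK", 65L, "G", "A", "R1192G", "missense", hotspot = TRUE),
    special("HRAS", 61L, "A", "G", "Q61R", "missense", hotspot = TRUE),
    special("MET", 61L, "G", "T", "e14_skip", "splice", exon_skip = TRUE),
    special("ATRX", 61L, "G", "T", "A1988S", "missense"),
    special("ATRX", 63L, "T", "C", "V2189A", "missense"),
    special("ATRX", 65L, "C", "G", "R498G", "missense"))
  setkey(ann, chrom, pos, ref, alt)
  ann[]
}

#' Packaged population-frequency resources
#'
#' Stand-in for the external germline resources of a tumor-only pipeline:
#' a population allele-frequency table (the union of public SNP
#' databases), occurrence counts in a panel of `pon_n` normal samples
#' (default 480), and the hotspot whitelist exempted from the high-VAF
#' germline rule. All sites are synthetic and placed at panel positions
#' distinct from the annotation table's coding changes.
#'
#' @param panel an `nb_panel`.
#' @param pon_n panel-of-normals size.
#' @return list of class `nb_resources`: `popdb` (`chrom, pos, ref, alt,
#'   pop_af`), `pon` (`chrom, pos, ref, alt, pon_count`), `pon_n`,
#'   `hotspots` (`gene, protein_change`).
#' @export
default_population_resources <- function(panel = default_panel(), pon_n = 480L) {
  key <- paste0(panel_cache_key(panel), "_", pon_n)
  hit <- .nb_cache$resources[[key]]
  if (!is.null(hit)) return(hit)
  ex1 <- panel[, .SD[1L], by = gene]
  n <- nrow(ex1)
  # alternate sites above/below the filtering thresholds so both branches
  # of each rule are exercised
  popdb <- data.table(chrom = ex1$chrom, pos = ex1$start + 72L,
                      ref = "C", alt = "T",
                      pop_af = ifelse(seq_len(n) %% 2L == 0L, 0.02 + 0.01 * (seq_len(n) %% 5L), 0.002))
  pon <- data.table(chrom = ex1$chrom, pos = ex1$start + 82L,
                    ref = "G", alt = "A",
                    pon_count = ifelse(seq_len(n) %% 2L == 0L, 20L + (seq_len(n) %% 40L), 3L))
  ann <- default_annotation_table(panel)
  res <- list(popdb = popdb, pon = pon, pon_n = as.integer(pon_n),
              hotspots = ann[hotspot == TRUE, .(gene, protein_change)])
  class(res) <- "nb_resources"
  .nb_cache$resources[[key]] <- res
  res
}

#' Annotate merged variant calls with gene, protein change and effect
#'
#' Joins calls against the packaged annotation table by
#' `(chrom, pos, ref, alt)`. Calls without an annotation entry fall back
#' to the panel gene overlapping their position with effect `"other"`;
#' off-panel calls get gene `NA` and effect `"other"` with a warning.
#' Truncating status (nonsense, frameshift, canonical splice) is derived
#' from the effect class.
#'
#' @param calls variant `data.table` (see [merge_callers()]).
#' @param annotation annotation table from [default_annotation_table()].
#' @param panel an `nb_panel` for the positional fallback.
#' @return calls with `gene`, `protein_change`, `effect`, `hotspot`,
#'   `exon_skip` and `truncating` columns filled.
#' @export
annotate_effects <- function(calls, annotation = default_annotation_table(panel),
                             panel = default_panel()) {
  calls <- copy(as.data.table(calls))
  hit <- annotation[calls[, .(chrom, pos, ref, alt)], on = .(chrom, pos, ref, alt)]
  calls[, `:=`(gene = hit$gene, protein_change = hit$protein_change,
               effect = hit$effect,
               hotspot = !is.na(hit$hotspot) & hit$hotspot,
               exon_skip = !is.na(hit$exon_skip) & hit$exon_skip)]
  miss <- is.na(calls$effect)
  if (any(miss)) {
    g <- panel_gene_at(panel, calls$chrom[miss], calls$pos[miss])
    calls[miss, `:=`(gene = g, effect = "other")]
    if (anyNA(g))
      warnf("annotate_effects: %d call(s) outside panel genes annotated as 'other'",
            sum(is.na(g)))
  }
  calls[, truncating := effect %chin% c("nonsense", "frameshift", "splice")]
  calls[]
}
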