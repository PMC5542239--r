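#' Read a targeted-panel definition from BED
#'
#' The panel is the coordinate frame of the whole pipeline: an interval
#' set of captured exons, one row per exon, carrying a name column of the
#' form `GENE_exN`. BED semantics (0-based, half-open) are preserved in
#' the returned table; variant positions elsewhere in the package are
#' 1-based, so a 1-bp BED interval `[s, s+1)` corresponds to VCF position
#' `s + 1`.
#'
#' @param path BED3+ file; column 4 must carry `GENE` or `GENE_exN` names.
#' @return a `data.table` of class `nb_panel` with columns `gene`,
#'   `exon_id`, `chrom`, `start`, `end` (0-based half-open), sorted by
#'   `(chrom, start)`. The total covered length is stored in attribute
#'   `covered_bp`.
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  keep <- nzchar(trimws(lines))
  if (!any(keep)) {
    warnf("read_panel: %s contains no intervals; returning an empty panel", path)
    return(empty_panel())
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nline <- which(keep)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 4L || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      stopf("read_panel: malformed BED line %d in %s", nline[i], path)
    if (as.numeric(f[3]) <= as.numeric(f[2]))
      stopf("read_panel: end <= start on line %d in %s", nline[i], path)
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "bed"))
  panel <- data.table(
    gene = sub("_ex.*$", "", gr$name),
    exon_id = gr$name,
    chrom = as.character(gr$seqnames),
    start = as.integer(gr$start) - 1L,  # back to 0-based half-open
    end = as.integer(gr$end))
  validate_panel(panel)
}

empty_panel <- function() {
  panel <- data.table(gene = character(), exon_id = character(),
                      chrom = character(), start = integer(), end = integer())
  setattr(panel, "class", c("nb_panel", class(panel)))
  setattr(panel, "covered_bp", 0L)
  panel
}

validate_panel <- function(panel) {
  panel <- as.data.table(panel)
  setorder(panel, chrom, start)
  ov <- panel[, {
    n <- .N
    if (n > 1L) any(start[-1L] < end[-n]) else FALSE
  }, by = .(gene, chrom)]
  if (any(ov$V1))
    stopf("panel has overlapping exons within gene(s): %s",
          paste(unique(ov$gene[ov$V1]), collapse = ", "))
  setattr(panel, "class", unique(c("nb_panel", class(panel))))
  setattr(panel, "covered_bp", sum(panel$end - panel$start))
  panel[]
}

#' Write a panel back to BED
#' @param panel an `nb_panel`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "nb_panel"))
  out <- panel[, .(chrom, start, end, exon_id)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' The packaged default 83-gene panel
#'
#' An illustrative reconstruction of an 83-gene pediatric solid-tumor
#' panel: the clinically pivotal genes of the study (ALK, BRCA1, ATM,
#' PTCH1, ARID1A/B, ATRX, HRAS, MET, ERBB2, STK11) on their true
#' chromosomes plus 72 further cancer genes. Exon structures are
#' representative, not transcript-accurate; the original panel's exon
#' composition is not public.
#'
#' @return an `nb_panel` with 83 distinct genes.
#' @export
default_panel <- function() {
  if (is.null(.nb_cache$default_panel))
    .nb_cache$default_panel <- read_panel(
      system.file("extdata", "panel_default.bed", package = "nbpanel",
                  mustWork = TRUE))
  .nb_cache$default_panel
}

#' Map 1-based positions onto panel genes
#'
#' @param panel an `nb_panel`.
#' @param chrom,pos vectors of 1-based variant coordinates.
#' @return character vector of gene names (NA where off-panel).
#' @export
panel_gene_at <- function(panel, chrom, pos) {
  q <- data.table(chrom = chrom, p0 = pos - 1L, idx = seq_along(pos))
  hit <- panel[q, on = .(chrom, start <= p0, end > p0), .(idx = i.idx, gene = x.gene)]
  hit <- hit[!is.na(gene)][!duplicated(idx)]
  out <- rep(NA_character_, length(pos))
  out[hit$idx] <- hit$gene
  out
}
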