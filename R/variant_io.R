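#' Read one caller's variant calls (VCF 4.2 or TSV)
#'
#' Accepts either a VCF 4.2 file carrying `AF` (alt allele fraction),
#' `ADF` and `ADR` (alt-supporting forward/reverse read counts) in INFO,
#' or a TSV with columns `chrom, pos, ref, alt, allele_fraction,
#' alt_forward, alt_reverse` (missing values `'.'`; an optional
#' `sample_id` column for cohort-wide tables is preserved). Positions
#' are 1-based in both encodings and kept 1-based. Records without an allele
#' fraction are skipped, counted, and reported via a warning; the count
#' is attached as attribute `skipped`.
#'
#' @param path input file; `.vcf` triggers VCF parsing, anything else TSV.
#' @param caller_name label attached to every record.
#' @return `data.table` with columns `chrom, pos, ref, alt,
#'   allele_fraction, alt_forward, alt_reverse, caller`.
#' @export
read_variant_table <- function(path, caller_name) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    info <- VariantAnnotation::info(v)
    first_num <- function(x) {
      if (is.list(x) || methods::is(x, "List"))
        vapply(x, function(e) if (length(e)) as.numeric(e[[1L]]) else NA_real_, 0)
      else as.numeric(x)
    }
    alt <- as.character(unlist(lapply(as.list(rr$ALT), function(a) as.character(a)[1L])))
    dt <- data.table(
      chrom = as.character(as.data.frame(rr)$seqnames),
      pos = as.integer(as.data.frame(rr)$start),
      ref = as.character(rr$REF),
      alt = alt,
      allele_fraction = if ("AF" %in% names(info)) first_num(info$AF) else NA_real_,
      alt_forward = if ("ADF" %in% names(info)) as.integer(first_num(info$ADF)) else NA_integer_,
      alt_reverse = if ("ADR" %in% names(info)) as.integer(first_num(info$ADR)) else NA_integer_)
  } else {
    dt <- fread(path, sep = "\t", na.strings = c(".", "NA", ""),
                colClasses = list(character = c("chrom", "ref", "alt")))
    need <- c("chrom", "pos", "ref", "alt", "allele_fraction",
              "alt_forward", "alt_reverse")
    missing_cols <- setdiff(need, names(dt))
    if (length(missing_cols))
      stopf("read_variant_table: %s lacks column(s) %s", path,
            paste(missing_cols, collapse = ", "))
    keep <- c(intersect("sample_id", names(dt)), need)
    dt <- dt[, ..keep]
    dt[, `:=`(pos = as.integer(pos), allele_fraction = as.numeric(allele_fraction),
              alt_forward = as.integer(alt_forward), alt_reverse = as.integer(alt_reverse))]
  }
  bad <- is.na(dt$allele_fraction)
  if (any(bad)) {
    warnf("read_variant_table: skipped %d record(s) without allele fraction in %s",
          sum(bad), path)
    dt <- dt[!bad]
  }
  dt[, caller := caller_name]
  setattr(dt, "skipped", sum(bad))
  dt[]
}

#' Write variant calls as TSV or VCF 4.2
#'
#' `write_variant_tsv()` writes the package's canonical snake-case TSV
#' (missing values as `'.'`). `write_variant_vcf()` writes a minimal VCF
#' 4.2 with `AF/ADF/ADR` INFO fields; when a `filter_status` column is
#' present its removal reason is mirrored into FILTER.
#'
#' @param calls variant `data.table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(calls, path) {
  fwrite(as.data.table(calls), path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

#' @rdname write_variant_tsv
#' @export
write_variant_vcf <- function(calls, path) {
  calls <- as.data.table(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=nbpanel",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alt allele fraction">',
    '##INFO=<ID=ADF,Number=A,Type=Integer,Description="Alt-supporting reads, forward strand">',
    '##INFO=<ID=ADR,Number=A,Type=Integer,Description="Alt-supporting reads, reverse strand">',
    '##FILTER=<ID=germline_vaf,Description="Allele fraction >= germline cut, not a hotspot">',
    '##FILTER=<ID=popdb,Description="Population database allele frequency >= cut">',
    '##FILTER=<ID=pon,Description="Panel-of-normals occurrence >= cut">',
    '##FILTER=<ID=strand_bias,Description="Alt reads abnormally strand biased">',
    '##FILTER=<ID=cluster,Description="Clustered calls within window">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  filt <- if ("filter_status" %in% names(calls)) {
    ifelse(calls$filter_status == "pass" | is.na(calls$filter_status),
           "PASS", calls$filter_reason)
  } else rep("PASS", nrow(calls))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%s;ADF=%d;ADR=%d",
                  calls$chrom, calls$pos, calls$ref, calls$alt, filt,
                  format(calls$allele_fraction, trim = TRUE, digits = 10),
                  calls$alt_forward, calls$alt_reverse)
  writeLines(c(hdr, body), path)
  invisible(path)
}
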