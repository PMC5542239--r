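#' Merge per-caller variant calls
#'
#' Calls identical in `(sample_id, chrom, pos, ref, alt)` collapse to a
#' single record whose caller set is the union, whose allele fraction is
#' the median across reporting callers, and whose strand counts come from
#' the caller with the greatest alt read depth. The merge is a union by
#' default (single-caller support suffices); `min_callers` turns on a
#' consensus requirement.
#'
#' @param call_lists list of per-caller `data.table`s as returned by
#'   [read_variant_table()] or [simulate_caller_outputs()]; a
#'   `sample_id` column is optional and preserved.
#' @param min_callers minimum supporting callers to keep a record.
#' @return merged `data.table` with `callers` (comma-separated),
#'   `n_callers`, `filter_status = "pass"` and `filter_reason = NA`.
#' @export
merge_callers <- function(call_lists, min_callers = 1L) {
  all <- rbindlist(call_lists, use.names = TRUE, fill = TRUE)
  if (!"sample_id" %in% names(all)) all[, sample_id := "sample"]
  if (nrow(all) == 0L) {
    all[, `:=`(callers = character(), n_callers = integer(),
               filter_status = character(), filter_reason = character())]
    return(all[])
  }
  conflicts <- all[, uniqueN(ref), by = .(sample_id, chrom, pos)][V1 > 1L]
  if (nrow(conflicts))
    stopf("merge_callers: conflicting ref alleles at %d position(s), e.g. %s:%d",
          nrow(conflicts), conflicts$chrom[1L], conflicts$pos[1L])
  merged <- all[, {
    depth <- alt_forward + alt_reverse
    best <- if (all(is.na(depth))) 1L else which.max(ifelse(is.na(depth), -1L, depth))
    .(allele_fraction = median(allele_fraction),
      alt_forward = alt_forward[best], alt_reverse = alt_reverse[best],
      callers = paste(sort(unique(caller)), collapse = ","),
      n_callers = uniqueN(caller))
  }, by = .(sample_id, chrom, pos, ref, alt)]
  merged <- merged[n_callers >= min_callers]
  merged[, `:=`(filter_status = "pass", filter_reason = NA_character_)]
  setorder(merged, sample_id, chrom, pos, ref, alt)
  merged[]
}

#' Remove strand-biased and clustered artifact calls
#'
#' Operationalizes the removal of calls from abnormally aligned,
#' strand-biased and clustered reads. A call is strand-biased when the
#' exact two-sided binomial test of its alt forward/reverse counts
#' against 0.5 gives `p < strand_bias_p` (default 1e-3) and at least
#' `strand_bias_fraction` (default 95%) of alt reads sit on one strand.
#' Calls are clustered when at least `cluster_min_calls` (default 3)
#' distinct positions fall within any `cluster_window_bp` (default
#' 10 bp) window in the same sample; all members of such a window are
#' removed. Calls lacking strand counts pass with a warning (the test
#' cannot run). Rows already removed by an earlier filter are left
#' untouched, which makes the filter idempotent.
#'
#' @param calls merged call table (see [merge_callers()]).
#' @param config an `nb_config`.
#' @return the call table with `filter_status` / `filter_reason` updated.
#' @export
filter_artifacts <- function(calls, config = pipeline_config()) {
  calls <- copy(as.data.table(calls))
  live <- calls$filter_status == "pass"
  f <- calls$alt_forward; r <- calls$alt_reverse
  n <- f + r
  no_counts <- live & (is.na(f) | is.na(r))
  if (any(no_counts))
    warnf("filter_artifacts: %d call(s) lack strand counts; retained untested",
          sum(no_counts))
  testable <- live & !is.na(n) & n > 0L
  pval <- rep(NA_real_, nrow(calls))
  pval[testable] <- pmin(1, 2 * pbinom(pmin(f[testable], r[testable]),
                                       n[testable], 0.5))
  one_sided_frac <- pmax(f, r) / n
  sb <- testable & pval < config$strand_bias_p &
    one_sided_frac >= config$strand_bias_fraction
  calls[sb, `:=`(filter_status = "removed", filter_reason = "strand_bias")]

  if (any(calls$filter_status == "pass")) {
    calls[, .row := .I]
    cl_rows <- calls[filter_status == "pass",
                     .row[cluster_members(pos, config$cluster_window_bp,
                                          config$cluster_min_calls)],
                     by = .(sample_id, chrom)]$V1
    if (length(cl_rows))
      calls[cl_rows, `:=`(filter_status = "removed", filter_reason = "cluster")]
    calls[, .row := NULL]
  }
  calls[]
}

# TRUE for every call belonging to a window of width `win` containing at
# least `k` distinct positions
cluster_members <- function(pos, win, k) {
  upos <- sort(unique(pos))
  flagged <- rep(FALSE, length(upos))
  hi <- findInterval(upos + (win - 1L), upos)
  for (i in seq_along(upos)) {
    if (hi[i] - i + 1L >= k) flagged[i:hi[i]] <- TRUE
  }
  pos %in% upos[flagged]
}

#' Apply the two-rule germline filter
#'
#' A call is removed as germline iff (a) its allele fraction is at or
#' above `vaf_germline_cut` (default 0.97) and it is not a whitelisted
#' hotspot, or (b) its population-database allele frequency is at or
#' above `popdb_cut` (default 1%), or (c) its panel-of-normals
#' occurrence fraction is at or above `pon_cut` (default 3% of 480).
#' The hotspot exemption applies to the high-VAF rule only. Sites absent
#' from a resource are treated as frequency zero.
#'
#' @param calls annotated call table ([annotate_effects()] provides the
#'   `hotspot` column; if absent, no call is exempt).
#' @param resources an `nb_resources`.
#' @param config an `nb_config`.
#' @return the call table with `filter_status` / `filter_reason` updated.
#' @export
filter_germline <- function(calls, resources = default_population_resources(),
                            config = pipeline_config()) {
  calls <- copy(as.data.table(calls))
  if (!"hotspot" %in% names(calls)) calls[, hotspot := FALSE]
  calls[is.na(hotspot), hotspot := FALSE]
  pop <- resources$popdb[calls[, .(chrom, pos, ref, alt)],
                         on = .(chrom, pos, ref, alt)]$pop_af
  pon <- resources$pon[calls[, .(chrom, pos, ref, alt)],
                       on = .(chrom, pos, ref, alt)]$pon_count
  pop[is.na(pop)] <- 0
  pon[is.na(pon)] <- 0
  live <- calls$filter_status == "pass"
  vaf_hit <- live & calls$allele_fraction >= config$vaf_germline_cut & !calls$hotspot
  pop_hit <- live & pop >= config$popdb_cut
  pon_hit <- live & pon / resources$pon_n >= config$pon_cut
  calls[vaf_hit, `:=`(filter_status = "removed", filter_reason = "germline_vaf")]
  calls[pop_hit & filter_status == "pass",
        `:=`(filter_status = "removed", filter_reason = "popdb")]
  calls[pon_hit & filter_status == "pass",
        `:=`(filter_status = "removed", filter_reason = "pon")]
  calls[]
}

#' Extract the retained (somatic) calls
#' @param calls a filtered call table.
#' @return rows with `filter_status == "pass"`.
#' @export
somatic_calls <- function(calls) {
  as.data.table(calls)[filter_status == "pass"]
}
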