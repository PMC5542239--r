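#' Score MYCN amplification from FISH signal counts
#'
#' MYCN is not on the sequencing panel; amplification status comes from
#' interphase FISH on fifty non-overlapping nuclei, with a chromosome-2
#' centromere probe (CEP2) as reference. The ratio is computed from
#' summed signals across nuclei (robust to CEP2-null nuclei); a tumor is
#' amplified when MYCN signals are increased at least
#' `fold_threshold`-fold (default 10) over the reference.
#'
#' @param counts `data.table` with per-nucleus `mycn_signals` and
#'   `cep2_signals` for one sample (see [simulate_fish_counts()]).
#' @param fold_threshold amplification boundary, inclusive (default 10).
#' @return list: `ratio`, `amplified`, `n_nuclei`.
#' @export
score_mycn <- function(counts, fold_threshold = 10) {
  counts <- as.data.table(counts)
  if (any(counts$mycn_signals < 0) || any(counts$cep2_signals < 0))
    stopf("score_mycn: negative signal counts")
  tot_ref <- sum(counts$cep2_signals)
  if (tot_ref <= 0)
    stopf("score_mycn: zero total CEP2 signals (hybridization failure)")
  ratio <- sum(counts$mycn_signals) / tot_ref
  list(ratio = ratio, amplified = ratio >= fold_threshold,
       n_nuclei = nrow(counts))
}

#' Read a FISH signal-count CSV
#'
#' Expected columns: `sample_id, nucleus, mycn_signals, cep2_signals`
#' (one row per scored nucleus).
#'
#' @param path CSV file.
#' @return `data.table` keyed by `sample_id`.
#' @export
read_fish_counts <- function(path) {
  x <- fread(path)
  need <- c("sample_id", "mycn_signals", "cep2_signals")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stopf("read_fish_counts: %s lacks column(s) %s", path,
          paste(miss, collapse = ", "))
  setkey(x, sample_id)
  x[]
}

#' Score every sample in a FISH count table
#'
#' @param counts long table as from [read_fish_counts()].
#' @param fold_threshold see [score_mycn()].
#' @return `data.table(sample_id, mycn_ratio, mycn_amplified, n_nuclei)`.
#' @export
score_mycn_all <- function(counts, fold_threshold = 10) {
  as.data.table(counts)[, {
    s <- score_mycn(.SD, fold_threshold)
    .(mycn_ratio = s$ratio, mycn_amplified = s$amplified, n_nuclei = s$n_nuclei)
  }, by = sample_id]
}
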