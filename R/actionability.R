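#' Build the patient-by-gene alteration matrix
#'
#' One cell per (patient, gene): `none`, `snv_indel`, `cn_gain`,
#' `cn_loss`, or `both` (a sequence alteration together with a
#' copy-number alteration in the same gene). Synonymous variants are
#' excluded; a patient with several variants in a gene still occupies a
#' single cell, since prevalence counts patients, not variants.
#'
#' @param somatic variant table of retained, annotated calls (must carry
#'   `sample_id`, `gene`, `effect`).
#' @param cnv copy-number calls with `sample_id, gene, class` (only
#'   `loss`/`gain` rows contribute).
#' @param patient_ids full cohort roster; every call must belong to it.
#' @return `data.table(patient_id, gene, cell)` containing only non-`none`
#'   cells, with the roster attached as attribute `patients`.
#' @export
build_alteration_matrix <- function(somatic, cnv, patient_ids) {
  somatic <- as.data.table(somatic)
  cnv <- as.data.table(cnv)
  bad <- setdiff(unique(c(somatic$sample_id, cnv$sample_id)), patient_ids)
  if (length(bad))
    stopf("build_alteration_matrix: call(s) for unknown patient(s): %s",
          paste(head(bad, 3L), collapse = ", "))
  snv <- unique(somatic[!is.na(gene) & !effect %chin% c("synonymous"),
                        .(patient_id = sample_id, gene, has_snv = TRUE)])
  cn <- unique(cnv[class %chin% c("loss", "gain"),
                   .(patient_id = sample_id, gene,
                     cn_cell = fifelse(class == "gain", "cn_gain", "cn_loss"))])
  cells <- merge(snv, cn, by = c("patient_id", "gene"), all = TRUE)
  cells[, cell := fifelse(!is.na(has_snv) & !is.na(cn_cell), "both",
                          fifelse(!is.na(has_snv), "snv_indel", cn_cell))]
  out <- cells[, .(patient_id, gene, cell)]
  setattr(out, "patients", patient_ids)
  setattr(out, "class", unique(c("nb_matrix", class(out))))
  out[]
}

#' The packaged actionability rule set
#'
#' Encodes the drug-matching list of the study: activating ALK point
#' mutations (R1275Q, F1174I, R1192G) or ALK copy-number gain match ALK
#' inhibitors; BRCA1 truncating mutations and ATM copy-number loss match
#' PARP inhibitors; HRAS Q61R matches RAS-pathway inhibition; a MET
#' exon-14 skipping variant matches MET inhibitors; ERBB2 copy-number
#' gain matches HER2-directed therapy; STK11 copy-number loss matches
#' mTOR inhibition.
#'
#' @return `data.table(gene, trigger, value, therapy_class)` where
#'   `trigger` is one of `protein_change`, `truncating`, `cn_gain`,
#'   `cn_loss`, `exon_skip` and `value` holds `|`-separated protein
#'   changes for `protein_change` triggers.
#' @export
default_actionability_rules <- function() {
  rbind(
    data.table(gene = "ALK", trigger = "protein_change",
               value = "R1275Q|F1174I|R1192G", therapy_class = "ALK inhibitor"),
    data.table(gene = "ALK", trigger = "cn_gain", value = NA_character_,
               therapy_class = "ALK inhibitor"),
    data.table(gene = "BRCA1", trigger = "truncating", value = NA_character_,
               therapy_class = "PARP inhibitor"),
    data.table(gene = "ATM", trigger = "cn_loss", value = NA_character_,
               therapy_class = "PARP inhibitor"),
    data.table(gene = "HRAS", trigger = "protein_change", value = "Q61R",
               therapy_class = "RAS pathway inhibitor"),
    data.table(gene = "MET", trigger = "exon_skip", value = NA_character_,
               therapy_class = "MET inhibitor"),
    data.table(gene = "ERBB2", trigger = "cn_gain", value = NA_character_,
               therapy_class = "HER2-directed therapy"),
    data.table(gene = "STK11", trigger = "cn_loss", value = NA_character_,
               therapy_class = "mTOR inhibitor"))
}

#' Classify molecular target candidates
#'
#' A patient is a target candidate iff at least one rule fires on their
#' retained calls. Matches are deduplicated per (patient, therapy class);
#' adding alterations can only add candidacies, never remove one.
#'
#' @param somatic retained annotated variant calls (`sample_id, gene,
#'   protein_change, truncating, exon_skip`).
#' @param cnv copy-number calls (`sample_id, gene, class`).
#' @param rules rule table, see [default_actionability_rules()].
#' @return `data.table(patient_id, gene, trigger, therapy_class)`, one
#'   row per (patient, therapy class), plus attribute `candidates`: the
#'   vector of candidate patient ids.
#' @export
classify_actionable <- function(somatic, cnv,
                                rules = default_actionability_rules()) {
  somatic <- as.data.table(somatic)
  cnv <- as.data.table(cnv)
  hits <- list()
  for (i in seq_len(nrow(rules))) {
    ru <- rules[i]
    h <- switch(
      ru$trigger,
      protein_change = somatic[gene == ru$gene &
                                 protein_change %chin% strsplit(ru$value, "|", fixed = TRUE)[[1L]],
                               .(patient_id = sample_id)],
      truncating = somatic[gene == ru$gene & truncating == TRUE,
                           .(patient_id = sample_id)],
      exon_skip = somatic[gene == ru$gene & exon_skip == TRUE,
                          .(patient_id = sample_id)],
      cn_gain = cnv[gene == ru$gene & class == "gain",
                    .(patient_id = sample_id)],
      cn_loss = cnv[gene == ru$gene & class == "loss",
                    .(patient_id = sample_id)],
      stopf("unknown trigger '%s'", ru$trigger))
    if (nrow(h))
      hits[[length(hits) + 1L]] <-
        unique(h)[, `:=`(gene = ru$gene, trigger = ru$trigger,
                         therapy_class = ru$therapy_class)]
  }
  out <- if (length(hits)) rbindlist(hits)
  else data.table(patient_id = character(), gene = character(),
                  trigger = character(), therapy_class = character())
  out <- unique(out, by = c("patient_id", "therapy_class"))
  setorder(out, patient_id, therapy_class)
  setattr(out, "candidates", unique(out$patient_id))
  out[]
}
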