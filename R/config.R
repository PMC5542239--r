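#' Pipeline configuration
#'
#' Collects every numeric threshold of the analysis so that none is a
#' hard-coded literal: the two-rule germline filter, the copy-number
#' class boundaries, the FISH fold threshold and the survival horizon.
#' The defaults are the values used in the neuroblastoma panel study this
#' package reimplements.
#'
#' @param vaf_germline_cut variants with allele fraction at or above this
#'   are treated as germline unless they are whitelisted hotspots
#'   (default 0.97).
#' @param popdb_cut population-database allele frequency at or above
#'   which a variant is filtered as a presumed polymorphism (default 0.01).
#' @param pon_cut panel-of-normals occurrence fraction at or above which
#'   a variant is filtered (default 0.03).
#' @param pon_n size of the panel of normals (default 480 healthy subjects).
#' @param loss_below copy-number below which a gene is a loss (default 1).
#' @param gain_above copy-number above which a gene is a gain (default 4);
#'   both thresholds are strict inequalities.
#' @param fish_fold_threshold MYCN/CEP2 signal ratio at or above which a
#'   tumor is scored amplified (default 10).
#' @param survival_horizon_months horizon for "3-year" survival summaries
#'   (default 36 months).
#' @param strand_bias_p two-sided exact binomial p-value below which alt
#'   reads are considered strand biased (default 1e-3).
#' @param strand_bias_fraction minimum fraction of alt reads on one strand
#'   for the strand-bias artifact call (default 0.95).
#' @param cluster_window_bp window width for the clustered-call artifact
#'   filter (default 10 bp).
#' @param cluster_min_calls minimum distinct calls within the window
#'   (default 3).
#' @param min_callers minimum number of supporting callers to keep a
#'   merged call (default 1: union merge).
#' @param purity_grid candidate tumor purities for the grid search
#'   (default 0.05 to 1.00 in steps of 0.01).
#' @param cn_max largest integer copy number entertained by the purity
#'   fit (default 10).
#' @param seed integer seed from which all randomness derives.
#' @return object of class `nb_config` (a named list).
#' @export
pipeline_config <- function(vaf_germline_cut = 0.97,
                            popdb_cut = 0.01,
                            pon_cut = 0.03,
                            pon_n = 480L,
                            loss_below = 1,
                            gain_above = 4,
                            fish_fold_threshold = 10,
                            survival_horizon_months = 36,
                            strand_bias_p = 1e-3,
                            strand_bias_fraction = 0.95,
                            cluster_window_bp = 10L,
                            cluster_min_calls = 3L,
                            min_callers = 1L,
                            purity_grid = seq(0.05, 1.00, by = 0.01),
                            cn_max = 10L,
                            seed = 1L) {
  check_fraction(vaf_germline_cut, "vaf_germline_cut")
  check_fraction(popdb_cut, "popdb_cut")
  check_fraction(pon_cut, "pon_cut")
  check_fraction(strand_bias_fraction, "strand_bias_fraction")
  if (!is.numeric(loss_below) || !is.numeric(gain_above) || loss_below >= gain_above)
    stopf("loss_below (%s) must be smaller than gain_above (%s)", loss_below, gain_above)
  if (pon_n < 1) stopf("pon_n must be a positive count")
  if (length(purity_grid) == 0L || any(purity_grid <= 0) || any(purity_grid > 1))
    stopf("purity_grid must be non-empty with values in (0, 1]")
  cfg <- list(
    vaf_germline_cut = vaf_germline_cut, popdb_cut = popdb_cut,
    pon_cut = pon_cut, pon_n = as.integer(pon_n),
    loss_below = loss_below, gain_above = gain_above,
    fish_fold_threshold = fish_fold_threshold,
    survival_horizon_months = survival_horizon_months,
    strand_bias_p = strand_bias_p,
    strand_bias_fraction = strand_bias_fraction,
    cluster_window_bp = as.integer(cluster_window_bp),
    cluster_min_calls = as.integer(cluster_min_calls),
    min_callers = as.integer(min_callers),
    purity_grid = purity_grid, cn_max = as.integer(cn_max),
    seed = as.integer(seed))
  class(cfg) <- "nb_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' `read_config()` loads a YAML file and validates it through
#' [pipeline_config()]; unknown keys are rejected so typos do not
#' silently fall back to defaults. `write_config()` is its inverse.
#'
#' @param path YAML file path.
#' @return `read_config()` returns an `nb_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config an `nb_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nb_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.nb_config <- function(x, ...) {
  cat("<nb_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (length(v) > 6L) v <- c(format(head(v, 3L)), "...", format(tail(v, 1L)))
    cat(sprintf("  %-24s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
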