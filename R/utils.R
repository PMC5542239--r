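#' Derive a deterministic child seed
#'
#' All randomness in the package flows from a single integer seed; each
#' module (and each sample within a module) draws from its own child seed
#' derived here, so that adding draws in one module never perturbs
#' another. A small multiplicative hash keeps results inside the 32-bit
#' integer range R requires of `set.seed()`.
#'
#' @param seed parent integer seed.
#' @param ... integers or strings identifying the consumer (module name,
#'   sample index, replicate index).
#' @return an integer in `[0, 2^31 - 1)` usable with `set.seed()`.
#' @export
child_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(paste(p, collapse = ""))) else p <- as.double(p)
    # 48271: MINSTD multiplier, full period modulo 2^31 - 1
    h <- (h * 48271 + p + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoization store for packaged defaults derived from a panel; keyed on
# cheap panel fingerprints, cleared on reload
.nb_cache <- new.env(parent = emptyenv())
.nb_cache$annotation <- list()
.nb_cache$resources <- list()

panel_cache_key <- function(panel) {
  sprintf("%d_%s_%s", nrow(panel), panel$gene[1L],
          format(sum(as.double(panel$start)) + sum(panel$end - panel$start)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("%s must lie in [0, 1]", name)
  invisible(x)
}
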