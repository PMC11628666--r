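#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed configuration error naming the offending field
#' @noRd
config_error <- function(field, msg) {
  stop(structure(
    class = c("invex_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field '%s': %s", field, msg),
         call = sys.call(-1), field = field)
  ))
}

#' Derive a deterministic substream seed from a master seed and a key
#'
#' One master seed drives the whole simulation; each component (counts per
#' tissue, variants, histology per bird, ...) uses a seed derived from the
#' master seed and a string key, so components are reproducible in isolation
#' and insensitive to the order in which they are generated.
#' @noRd
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Validate a karyotype vector against the merged three-class vocabulary
#' @noRd
check_karyotypes <- function(x) {
  x <- as.character(x)
  # tolerate the starred spellings used for the merged derived class
  x[x %in% c("AB*", "A/B", "AB")] <- "AB"
  x[x %in% c("B*B*", "BB")] <- "BB"
  bad <- setdiff(unique(x), c("AA", "AB", "BB"))
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown karyotype label(s): %s; expected AA, AB or BB (derived B and C haplotypes are merged into the B class, so e.g. 'AC' should be recorded as 'AB')",
      paste(bad, collapse = ", ")
    ))
  }
  x
}

KARYOTYPES <- c("AA", "AB", "BB")
STAGES <- c("inactive", "accelerating_I", "accelerating_II", "active")
STAGE_GROUPS <- c("EARLY", "LATE")
TISSUES <- c("testis", "liver")
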