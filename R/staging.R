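#' Testis maturation index from histology counts
#'
#' The maturation index summarises the balance between elongating spermatids
#' (ES, late stages of spermatogenesis) and spermatogonia (SP, the earliest
#' cells) in histological sections of a testis:
#' \deqn{MI = (ES - SP) / (ES + SP)}
#' which scales between -1 (only spermatogonia, immature) and 1 (only
#' elongating spermatids, fully mature). Counts should be pooled (summed)
#' across the sections of a bird before calling this function.
#'
#' @param es Count of elongating spermatids (nonnegative).
#' @param sp Count of spermatogonia (nonnegative).
#' @return The maturation index, a number in \[-1, 1\]. Vectorised.
#' @examples
#' maturation_index(10, 10) # 0
#' maturation_index(3, 17)  # -0.7
#' @export
maturation_index <- function(es, sp) {
  if (any(es < 0) || any(sp < 0)) stop("ES and SP counts must be nonnegative")
  tot <- es + sp
  if (any(tot == 0)) {
    stop("maturation index undefined for ES + SP = 0; an empty section set cannot be staged by index (use the no-elongating-spermatids rule instead)")
  }
  (es - sp) / tot
}

#' Assign a developmental stage from histology evidence
#'
#' Stages follow the histological definitions used for juvenile testis
#' development: `inactive` (no signs of spermatogenesis), `accelerating_I`
#' (spermatocyte division visible but no elongating spermatids),
#' `accelerating_II` (elongating spermatids visible, maturation index in
#' \[-0.7, 0.1\]) and `active` (elongating spermatids visible, maturation index
#' in (0.1, 0.7\]). The boundary value 0.1 belongs to `accelerating_II`.
#'
#' @param mi Maturation index for the bird (may be `NA` when `has_es` is
#'   `FALSE`, since the index plays no role without elongating spermatids).
#' @param has_es Were elongating spermatids observed?
#' @param has_division Was spermatocyte division observed? (An external
#'   histology call, not derivable from the two counts.)
#' @return A list with `stage` (one of `inactive`, `accelerating_I`,
#'   `accelerating_II`, `active`, or `NA` when unstageable) and `unstageable`
#'   (`TRUE` when `has_es` is `TRUE` but `mi` falls outside \[-0.7, 0.7\]).
#' @export
assign_stage <- function(mi, has_es, has_division) {
  if (!has_es) {
    stage <- if (has_division) "accelerating_I" else "inactive"
    return(list(stage = stage, unstageable = FALSE))
  }
  if (is.na(mi) || mi < -1 || mi > 1) {
    stop("with elongating spermatids present a maturation index in [-1, 1] is required")
  }
  if (mi < -0.7 || mi > 0.7) {
    return(list(stage = NA_character_, unstageable = TRUE))
  }
  stage <- if (mi <= 0.1) "accelerating_II" else "active"
  list(stage = stage, unstageable = FALSE)
}

#' Pool developmental stages into EARLY and LATE analysis groups
#'
#' With few birds per stage, the four stages are pooled into two groups for
#' the differential-expression design: `inactive` and `accelerating_I` form
#' EARLY; `accelerating_II` and `active` form LATE.
#'
#' @param stages Character vector of stage labels.
#' @return Character vector of `"EARLY"` / `"LATE"` labels.
#' @export
pool_stage_groups <- function(stages) {
  if (length(stages) == 0) return(character(0))
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad) > 0) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  ifelse(stages %in% c("inactive", "accelerating_I"), "EARLY", "LATE")
}

#' Stage all birds of a histology table
#'
#' Pools section counts per bird (a depth-weighted aggregation: deeper
#' sections contribute more), computes the maturation index, and assigns
#' stage and stage group. Birds with zero elongating spermatids everywhere
#' are staged by the `has_es` / `has_division` rules rather than the index.
#'
#' @param histology Data frame with columns `bird_id`, `section_id`, `es`,
#'   `sp`.
#' @param division Named logical vector: was spermatocyte division observed
#'   per bird? Defaults to `FALSE` for birds not named.
#' @return Data frame with one row per bird: `bird_id`, `mi`, `stage`,
#'   `stage_group`, `unstageable`.
#' @export
stage_birds <- function(histology, division = NULL) {
  stopifnot(all(c("bird_id", "es", "sp") %in% names(histology)))
  birds <- unique(histology$bird_id)
  out <- lapply(birds, function(b) {
    rows <- histology[histology$bird_id == b, , drop = FALSE]
    es <- sum(rows$es)
    sp <- sum(rows$sp)
    has_es <- es > 0
    has_div <- isTRUE(division[[b]])
    mi <- if (es + sp > 0) (es - sp) / (es + sp) else NA_real_
    call <- assign_stage(mi, has_es, has_div)
    data.frame(
      bird_id = b, mi = mi, stage = call$stage,
      stage_group = if (is.na(call$stage)) NA_character_ else pool_stage_groups(call$stage),
      unstageable = call$unstageable, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
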