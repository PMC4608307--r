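#' Canonical stimulation conditions
#'
#' The four levels of the stimulation factor: unstimulated medium control,
#' FcR stimulation by immobilized IgG, IL-12 stimulation, and the combined
#' FcR + IL-12 co-stimulation.
#'
#' @return Character vector of the four canonical condition labels, in order.
#' @export
nk_conditions <- function() {
  c("medium", "IgG", "IL12", "IgG_IL12")
}

#' Default condition synonym map
#'
#' Maps common spellings of the stimulation conditions onto the canonical
#' vocabulary used throughout the package. Matching is case-insensitive.
#'
#' @return Named character vector: names are lower-cased synonyms, values are
#'   canonical labels.
#' @export
condition_synonyms <- function() {
  c(
    "medium" = "medium", "media" = "medium", "none" = "medium",
    "unstimulated" = "medium", "control" = "medium",
    "igg" = "IgG", "fcr" = "IgG", "immobilized_igg" = "IgG",
    "il12" = "IL12", "il-12" = "IL12", "il_12" = "IL12",
    "igg_il12" = "IgG_IL12", "igg+il12" = "IgG_IL12",
    "igg_il-12" = "IgG_IL12", "igg+il-12" = "IgG_IL12",
    "combo" = "IgG_IL12", "combined" = "IgG_IL12"
  )
}

#' Canonicalize condition labels
#'
#' @param x character vector of condition labels.
#' @param synonyms named character map as from [condition_synonyms()].
#' @return Character vector of canonical labels.
#' @export
canonical_condition <- function(x, synonyms = condition_synonyms()) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(synonyms[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(nk_conditions(), collapse = ", "),
         " (or a registered synonym)", call. = FALSE)
  }
  out
}

# seeded RNG used by every simulator: one explicit algorithm so results are
# identical across platforms and R versions
with_sim_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# row medians of a numeric matrix; even counts use the mean of the two
# central order statistics (stats::median semantics)
row_medians <- function(m) {
  apply(m, 1L, stats::median)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
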