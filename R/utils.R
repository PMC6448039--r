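#' @keywords internal
"_PACKAGE"

## Canonical nerve labels: right/left sural, right/left peroneal.
NERVES <- c("RSN", "LSN", "RPN", "LPN")

## The five per-electrode signal features, in stable column order.
SF_NAMES <- c("n1_latency", "p1n1_slope", "p1n1_amplitude",
              "hf_peak_count", "hf_integral")

#' Nerve and signal-feature vocabularies
#'
#' `nerve_labels()` returns the four nerve classes (right/left sural and
#' peroneal); `sf_names()` returns the five signal-feature names in the
#' stable order used for feature-table columns.
#'
#' @return A character vector.
#' @export
nerve_labels <- function() NERVES

#' @rdname nerve_labels
#' @export
sf_names <- function() SF_NAMES

nerve_side <- function(nerve) ifelse(substr(nerve, 1, 1) == "R", "R", "L")
nerve_type <- function(nerve) ifelse(substr(nerve, 2, 2) == "S", "sural", "peroneal")

#' Derive a reproducible child seed
#'
#' Chains one or more integer keys onto a root seed with a Lehmer-style
#' recurrence, so that every trial, repeat and fold gets its own
#' deterministic RNG stream. Results stay within the 31-bit integer range.
#'
#' @param seed Integer root seed.
#' @param ... Integer keys (e.g. animal index, repeat number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  x <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(x)
}

## Evaluate `code` under a temporary RNG state; the caller's stream is
## untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Column name for one (electrode, feature) input, e.g. "e4_hf_integral".
feature_column <- function(electrode, sf) sprintf("e%d_%s", electrode, sf)

#' Names of the 35 feature columns
#'
#' @param electrodes Integer vector of electrode indices (1-7).
#' @param sfs Character vector of signal-feature names (see [sf_names()]).
#' @return Character vector of column names, electrode-major.
#' @export
input_columns <- function(electrodes = 1:7, sfs = sf_names()) {
  stopifnot(all(electrodes %in% 1:7), all(sfs %in% SF_NAMES))
  as.vector(t(outer(electrodes, sfs, feature_column)))
}

#' The 35-candidate input space
#'
#' One row per (electrode, signal feature) pair: the full input space from
#' which classifier inputs are drawn.
#'
#' @return A data frame with columns `electrode`, `sf`, `column`.
#' @export
candidate_grid <- function() {
  g <- expand.grid(sf = SF_NAMES, electrode = 1:7,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("electrode", "sf")]
  g$column <- feature_column(g$electrode, g$sf)
  g
}
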