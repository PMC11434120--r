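# broom-style accessors for pipeline results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline result
#'
#' One row per annotation, with the residue codes flattened to a single
#' `residues` string.
#'
#' @param x A `cdp_pipeline` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cdp_pipeline <- function(x, ...) {
  ann <- x$annotations
  ann$residues <- purrr::map_chr(ann$codes, paste, collapse = "-")
  dplyr::select(ann, "node_id", "name", "residues", "formula",
                "theoretical_mz", "observed_mz", "ppm_error", "rt", "level",
                "tier", "evidence", "score", "unnatural", "isomer_tag", "path")
}

#' One-row summary of a pipeline result
#'
#' Annotation totals and the three-way provenance partition (database /
#' de novo / deep-mined, the latter combining enumeration, propagation and
#' revision).
#'
#' @param x A `cdp_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.cdp_pipeline <- function(x, ...) {
  x$counts
}
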