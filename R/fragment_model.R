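# Diagnostic-ion prediction for cyclic dipeptides, b/y ions for linear
# peptides, and peak matching.

#' Immonium ion m/z of a residue
#'
#' The immonium ion has composition residue - CO + H and carries one positive
#' charge (one electron removed), the standard low-mass reporter for an
#' amino-acid residue in CID spectra.
#'
#' @param code Residue code.
#' @param library A residue library from [residue_library()].
#' @return m/z in Da.
#' @examples
#' immonium_mz("Pro") # 70.065
#' @export
immonium_mz <- function(code, library = residue_library()) {
  r <- residue(code, library)
  comp <- r$composition[[1]]
  if (!all(c("C", "O") %in% names(comp)) || comp[["C"]] < 1L || comp[["O"]] < 1L) {
    stop("residue ", code, " has no CO to lose; immonium ion undefined", call. = FALSE)
  }
  r$immonium_mz
}

#' Build a cyclic dipeptide candidate
#'
#' A cyclic dipeptide (2,5-diketopiperazine) is an unordered pair of residues
#' joined head-to-tail; its elemental formula is exactly the sum of the two
#' in-chain residue compositions (cyclization neither adds nor removes water
#' relative to the residues). Symmetric in its arguments: `cyclo(A-B)` and
#' `cyclo(B-A)` are the same candidate.
#'
#' @param a,b Residue codes.
#' @param library A residue library from [residue_library()].
#' @return An object of class `cdp`: a list with `codes` (sorted), `name`
#'   (`"cyclo(A-B)"`), `composition`, `formula`, `mz` (theoretical \[M+H\]+)
#'   and `residues` (two-row tibble).
#' @examples
#' make_cdp("Gly", "Pro")
#' @export
make_cdp <- function(a, b, library = residue_library()) {
  ra <- residue(a, library)
  rb <- residue(b, library)
  rows <- dplyr::bind_rows(ra, rb)
  rows <- rows[order(rows$code), ]
  comp <- rows$composition[[1]] + rows$composition[[2]]
  structure(
    list(
      codes = rows$code,
      name = paste0("cyclo(", rows$code[1], "-", rows$code[2], ")"),
      composition = comp,
      formula = format_formula(comp),
      mz = protonated_mz(comp),
      residues = rows
    ),
    class = "cdp"
  )
}

#' @export
print.cdp <- function(x, ...) {
  cat("<cdp> ", x$name, "  ", x$formula,
      "  [M+H]+ ", formatC(x$mz, format = "f", digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predicted fragment ions of a cyclic dipeptide
#'
#' Returns the protonated precursor; the generic ring neutral losses (-H2O,
#' -CO, -(H2O+CO)); the immonium ion of each residue; and residue-specific
#' diagnostics from the library rule table (the Pro companion ion at 98.06,
#' the Tyr side-chain loss, the methanol losses of a methyl-ester residue,
#' etc.). Every row carries the residue or loss that generated it.
#'
#' @param cdp A `cdp` candidate from [make_cdp()].
#' @return A tibble with columns `label`, `kind` (one of `precursor`,
#'   `neutral_loss`, `immonium`, `diagnostic`), `mz`, `provenance`.
#' @examples
#' cdp_fragments(make_cdp("MeEGlu", "Hyp"))
#' @export
cdp_fragments <- function(cdp) {
  stopifnot(inherits(cdp, "cdp"))
  prec <- cdp$mz
  frag <- list(tibble::tibble(
    label = "[M+H]", kind = "precursor", mz = prec, provenance = "precursor"
  ))
  ring_losses <- c("[M+H-H2O]" = "H2O", "[M+H-CO]" = "CO", "[M+H-CO-H2O]" = "CH2O2")
  frag <- c(frag, list(tibble::tibble(
    label = names(ring_losses),
    kind = "neutral_loss",
    mz = prec - purrr::map_dbl(unname(ring_losses), ~ monoisotopic_mass(parse_formula(.x))),
    provenance = "ring"
  )))
  for (i in 1:2) {
    r <- cdp$residues[i, ]
    frag <- c(frag, list(tibble::tibble(
      label = paste0("imm(", r$code, ")"),
      kind = "immonium",
      mz = r$immonium_mz,
      provenance = r$code
    )))
    rules <- r$diagnostics[[1]]
    if (nrow(rules) > 0) {
      frag <- c(frag, list(tibble::tibble(
        label = rules$label,
        kind = ifelse(rules$type == "loss", "neutral_loss", "diagnostic"),
        mz = purrr::map2_dbl(rules$type, rules$formula, function(type, f) {
          if (type == "loss") prec - monoisotopic_mass(parse_formula(f))
          else cation_mz(parse_formula(f))
        }),
        provenance = r$code
      )))
    }
  }
  out <- dplyr::distinct(dplyr::bind_rows(frag), .data$label, .keep_all = TRUE)
  out[out$mz > 0, ]
}

#' Predicted b/y ions of a linear peptide
#'
#' `b_i` is the sum of the first i residue masses plus a proton; `y_i` is the
#' sum of the last i residue masses plus water plus a proton. Emits
#' `b_1..b_(n-1)` and `y_1..y_n` (so `y_n` is the protonated full peptide),
#' plus the proline immonium ion at 70.07 when the sequence contains Pro.
#'
#' @param sequence Character vector of residue codes, N- to C-terminus.
#' @param modifications Optional numeric mass tags (signed Da) applied to the
#'   whole molecule; added to the precursor/`y_n` mass.
#' @param library A residue library from [residue_library()].
#' @return A tibble with columns `label`, `kind` (`b`, `y` or `immonium`),
#'   `mz`, `provenance`.
#' @examples
#' linear_fragments(c("Leu", "Pro", "Pro", "Leu"))
#' @export
linear_fragments <- function(sequence, modifications = NULL,
                             library = residue_library()) {
  if (length(sequence) < 1L) stop("sequence must have at least one residue", call. = FALSE)
  masses <- purrr::map_dbl(sequence, ~ residue(.x, library)$mass)
  n <- length(masses)
  proton <- physical_constants()$proton
  h2o <- monoisotopic_mass(parse_formula("H2O"))
  mod <- sum(modifications %||% 0)
  frag <- list()
  if (n > 1L) {
    b <- cumsum(masses)[seq_len(n - 1L)] + proton
    frag <- c(frag, list(tibble::tibble(
      label = paste0("b", seq_len(n - 1L)), kind = "b", mz = b,
      provenance = purrr::map_chr(seq_len(n - 1L), ~ paste(sequence[1:.x], collapse = "-"))
    )))
  }
  ymz <- cumsum(rev(masses)) + h2o + proton # y_i uses the *last* i residues
  ymz[n] <- ymz[n] + mod                    # whole-molecule tags sit on the full peptide
  frag <- c(frag, list(tibble::tibble(
    label = paste0("y", seq_len(n)), kind = "y", mz = ymz,
    provenance = purrr::map_chr(seq_len(n), ~ paste(rev(rev(sequence)[1:.x]), collapse = "-"))
  )))
  if (any(sequence %in% c("Pro", "P"))) {
    frag <- c(frag, list(tibble::tibble(
      label = "imm(Pro)", kind = "immonium",
      mz = immonium_mz("Pro", library), provenance = "Pro"
    )))
  }
  dplyr::bind_rows(frag)
}

#' Match predicted fragments against an observed peak list
#'
#' Greedy nearest-m/z assignment: candidate (fragment, peak) pairs within the
#' tolerance window are ranked by absolute m/z distance (ties broken by lower
#' predicted m/z) and assigned in order, each observed peak and each predicted
#' fragment used at most once. Deterministic and invariant under permutation
#' of the input peak list.
#'
#' @param spectrum A spectrum (list with `precursor_mz`, `peaks`) or a peaks
#'   tibble/data frame with columns `mz`, `intensity`.
#' @param predicted A fragment tibble as returned by [cdp_fragments()] or
#'   [linear_fragments()].
#' @param tol Tolerance value (default 0.02 Da, the conventional CID fragment
#'   tolerance).
#' @param unit `"da"` or `"ppm"`.
#' @return A list of class `match_result`: `matched` (fragments joined to
#'   their observed peak), `unmatched` (predicted fragments with no peak),
#'   `tol`, `unit`.
#' @export
match_peaks <- function(spectrum, predicted, tol = 0.02, unit = c("da", "ppm")) {
  unit <- match.arg(unit)
  stopifnot(tol > 0)
  peaks <- if ("peaks" %in% names(spectrum)) {
    p <- spectrum[["peaks"]]
    if (is.data.frame(p)) p else p[[1]]
  } else {
    spectrum
  }
  empty <- structure(
    list(matched = dplyr::mutate(predicted[0, ],
                                 obs_mz = numeric(0), intensity = numeric(0)),
         unmatched = predicted, tol = tol, unit = unit),
    class = "match_result"
  )
  if (nrow(predicted) == 0L) {
    empty$unmatched <- predicted
    return(empty)
  }
  if (is.null(peaks) || nrow(peaks) == 0L) return(empty)
  peaks <- dplyr::arrange(peaks, .data$mz)
  win <- function(mz) if (unit == "da") tol else mz * tol * 1e-6
  cand <- purrr::map_dfr(seq_len(nrow(predicted)), function(i) {
    mz <- predicted$mz[i]
    j <- which(abs(peaks$mz - mz) <= win(mz))
    if (length(j) == 0L) return(NULL)
    tibble::tibble(frag = i, peak = j, dist = abs(peaks$mz[j] - mz), pred_mz = mz)
  })
  if (nrow(cand) == 0L) return(empty)
  cand <- dplyr::arrange(cand, .data$dist, .data$pred_mz, .data$peak)
  used_f <- logical(nrow(predicted)); used_p <- logical(nrow(peaks))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    f <- cand$frag[k]; p <- cand$peak[k]
    if (!used_f[f] && !used_p[p]) {
      keep[k] <- TRUE; used_f[f] <- TRUE; used_p[p] <- TRUE
    }
  }
  cand <- cand[keep, ]
  matched <- predicted[cand$frag, ]
  matched$obs_mz <- peaks$mz[cand$peak]
  matched$intensity <- peaks$intensity[cand$peak]
  matched <- dplyr::arrange(matched, .data$mz)
  structure(
    list(matched = matched, unmatched = predicted[!used_f, ], tol = tol, unit = unit),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$matched), " matched / ",
      nrow(x$matched) + nrow(x$unmatched), " predicted (tol ",
      x$tol, " ", x$unit, ")\n", sep = "")
  invisible(x)
}
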