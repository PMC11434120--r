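# Seeded synthetic-data generation: MGF spectra, node/edge tables and ground
# truth with planted CDP identities, plus the packaged reference set of CDPs
# reported from L. reuteri.

#' Describe a synthetic fixture
#'
#' Bundles the compound list and generation parameters for
#' [generate_network()]. Seeded generation is reproducible bit for bit.
#'
#' @param compounds A tibble with columns `codes` (list of residue-code
#'   vectors: length 2 = CDP, otherwise a linear peptide) and `rt` (minutes).
#'   A character vector of `"cyclo(A-B)"` names is also accepted.
#' @param dropout Per-fragment dropout probability in `[0, 1)` (the precursor
#'   ion is never dropped).
#' @param noise_n Number of uniform noise peaks per spectrum.
#' @param ppm_sd Gaussian perturbation (ppm) of the observed precursor,
#'   truncated at `ppm_max`.
#' @param ppm_max Truncation bound for the precursor perturbation (default 10
#'   ppm, the precursor match tolerance).
#' @param edge_threshold Minimum number of shared predicted fragment m/z
#'   values (rounded to 2 d.p.) for two nodes to be joined by an edge.
#' @param seed Integer random seed.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(compounds, dropout = 0, noise_n = 0, ppm_sd = 5,
                         ppm_max = 10, edge_threshold = 2, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1)
  if (is.character(compounds)) {
    compounds <- tibble::tibble(
      codes = purrr::map(compounds, parse_cyclo_name),
      rt = seq(2, by = 0.8, length.out = length(compounds))
    )
  }
  stopifnot(nrow(compounds) >= 1, all(c("codes", "rt") %in% names(compounds)))
  structure(
    list(compounds = tibble::as_tibble(compounds), dropout = dropout,
         noise_n = noise_n, ppm_sd = ppm_sd, ppm_max = ppm_max,
         edge_threshold = edge_threshold, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

parse_cyclo_name <- function(name) {
  m <- stringr::str_match(name, "^cyclo\\(([^-]+)-([^)]+)\\)$")
  if (is.na(m[1, 1])) stop("cannot parse compound name: ", dQuote(name), call. = FALSE)
  c(m[1, 2], m[1, 3])
}

predicted_for <- function(codes, library) {
  if (length(codes) == 2) {
    cdp_fragments(make_cdp(codes[1], codes[2], library))
  } else {
    linear_fragments(codes, library = library)
  }
}

#' Generate one synthetic spectrum for a compound
#'
#' Peaks are the compound's predicted fragments minus independent dropout
#' draws, plus uniform noise peaks over `[50, precursor + 5]` whose
#' intensities sit below the 10th percentile of the true peaks. Intensities
#' follow a log-normal model (precursor loudest). The reported precursor m/z
#' is the theoretical value perturbed by a truncated Gaussian in ppm. The
#' caller controls the RNG state (use `set.seed()` or [generate_network()]).
#'
#' @param codes Residue codes (length 2 for a CDP) or a `"cyclo(A-B)"` name.
#' @param rt Retention time in minutes.
#' @param id Spectrum id.
#' @param spec A `fixture_spec` (its `compounds` field is ignored here).
#' @param library A residue library.
#' @return A one-row spectra tibble (`id`, `precursor_mz`, `rt`, `peaks`).
#' @export
generate_spectrum <- function(codes, rt = 5, id = "S1",
                              spec = fixture_spec(tibble::tibble(codes = list(codes), rt = rt)),
                              library = residue_library()) {
  if (is.character(codes) && length(codes) == 1 && grepl("^cyclo", codes)) {
    codes <- parse_cyclo_name(codes)
  }
  predicted <- predicted_for(codes, library)
  theor <- if (length(codes) == 2) {
    make_cdp(codes[1], codes[2], library)$mz
  } else {
    max(predicted$mz)
  }
  keep <- predicted$kind == "precursor" |
    stats::runif(nrow(predicted)) >= spec$dropout
  frag <- predicted[keep, ]
  inten <- stats::rlnorm(nrow(frag), meanlog = ifelse(frag$kind == "precursor", 9, 7),
                         sdlog = 0.5)
  peaks <- tibble::tibble(mz = frag$mz, intensity = inten)
  if (spec$noise_n > 0) {
    floor_int <- if (nrow(peaks) > 0) stats::quantile(peaks$intensity, 0.1) else 100
    noise <- tibble::tibble(
      mz = stats::runif(spec$noise_n, 50, theor + 5),
      intensity = stats::runif(spec$noise_n, 0, unname(floor_int))
    )
    peaks <- dplyr::bind_rows(peaks, noise)
  }
  ppm <- if (spec$ppm_sd > 0) {
    max(min(stats::rnorm(1, 0, spec$ppm_sd), spec$ppm_max), -spec$ppm_max)
  } else 0
  tibble::tibble(
    id = id,
    precursor_mz = theor * (1 + ppm * 1e-6),
    rt = rt,
    peaks = list(dplyr::arrange(peaks, .data$mz))
  )
}

#' Generate a synthetic molecular network with planted ground truth
#'
#' One node per compound. Edges join nodes that share at least
#' `edge_threshold` predicted fragment m/z values (rounded to 2 d.p.) — so
#' CDPs sharing a residue cluster through their common immonium/diagnostic
#' ions, as structural analogs do in a real feature-based molecular network.
#' Clusters are the connected components of that edge set. Deterministic for
#' a fixed spec (the seed is set internally).
#'
#' @param spec A `fixture_spec`.
#' @param out_dir Optional directory: writes `spectra.mgf`, `nodes.tsv`,
#'   `edges.tsv`, `truth.tsv` in the formats the readers consume.
#' @param library A residue library.
#' @return A list with `spectra` (tibble), `network` (`molecular_network`)
#'   and `truth` (tibble: `id`, `name`, `formula`, `theoretical_mz`).
#' @export
generate_network <- function(spec, out_dir = NULL, library = residue_library()) {
  stopifnot(inherits(spec, "fixture_spec"))
  comp <- spec$compounds
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  ids <- paste0("N", seq_len(nrow(comp)))
  spectra <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    generate_spectrum(comp$codes[[i]], comp$rt[i], ids[i], spec, library)
  })
  pred2 <- purrr::map(comp$codes, function(cd) {
    unique(round_half_up(predicted_for(cd, library)$mz, 2))
  })
  pairs <- which(upper.tri(diag(nrow(comp))), arr.ind = TRUE)
  edges <- purrr::map2_dfr(pairs[, 1], pairs[, 2], function(i, j) {
    shared <- length(intersect(pred2[[i]], pred2[[j]]))
    if (shared < spec$edge_threshold) return(NULL)
    tibble::tibble(
      from = ids[i], to = ids[j],
      cosine = round(shared / min(length(pred2[[i]]), length(pred2[[j]])), 3)
    )
  })
  if (nrow(edges) == 0) edges <- tibble::tibble(from = character(0), to = character(0),
                                               cosine = numeric(0))
  nodes <- tibble::tibble(id = ids, precursor_mz = spectra$precursor_mz,
                          rt = spectra$rt)
  net <- molecular_network(nodes, edges)
  truth <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    cd <- comp$codes[[i]]
    if (length(cd) == 2) {
      c2 <- make_cdp(cd[1], cd[2], library)
      tibble::tibble(id = ids[i], name = c2$name, formula = c2$formula,
                     theoretical_mz = c2$mz)
    } else {
      fr <- linear_fragments(cd, library = library)
      tibble::tibble(id = ids[i], name = paste(cd, collapse = "-"),
                     formula = NA_character_, theoretical_mz = max(fr$mz))
    }
  })
  out <- list(spectra = spectra, network = net, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    readr::write_tsv(net$nodes, file.path(out_dir, "nodes.tsv"))
    readr::write_tsv(net$edges, file.path(out_dir, "edges.tsv"))
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"))
  }
  out
}

#' The reference set of 53 CDPs reported from *L. reuteri*
#'
#' The curated list of 53 cyclic dipeptides with their published observed m/z
#' and retention times, used for isomer/unnatural classification checks.
#' Elemental formulas and theoretical m/z are *derived from the residue
#' compositions*; where the published table's printed formula or m/z
#' disagrees with the compound's own name the discrepancy is flagged
#' (`formula_mismatch`, `mz_mismatch`) rather than copied.
#'
#' @param library A residue library.
#' @return An annotations-style tibble (53 rows) with `node_id`, `name`
#'   (canonical), `display_name` (as published), `codes`, `formula`
#'   (derived), `printed_formula`, `theoretical_mz`, `observed_mz`, `rt`,
#'   `level`, `unnatural`, `novel`, `isomer_printed`, `formula_mismatch`,
#'   `mz_mismatch`.
#' @export
cdp_reference_set <- function(library = residue_library()) {
  path <- system.file("extdata", "reuteri_cdps.tsv", package = "cdpmine")
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- purrr::map_dfr(seq_len(nrow(df)), function(i) {
    codes <- parse_cyclo_name(df$display_name[i])
    cdp <- make_cdp(codes[1], codes[2], library)
    tibble::tibble(
      node_id = paste0("R", df$no[i]),
      name = cdp$name,
      display_name = df$display_name[i],
      codes = list(cdp$codes),
      formula = cdp$formula,
      printed_formula = df$printed_formula[i],
      theoretical_mz = cdp$mz,
      observed_mz = df$observed_mz[i],
      rt = df$rt[i],
      level = "database",
      unnatural = any(cdp$residues$unnatural),
      novel = df$novel[i],
      isomer_printed = df$isomer_printed[i],
      formula_mismatch = df$printed_formula[i] != cdp$formula,
      mz_mismatch = abs(df$observed_mz[i] - cdp$mz) / cdp$mz * 1e6 > 20
    )
  })
  out
}
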