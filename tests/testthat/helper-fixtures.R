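# Shared fixtures: noise-free spectra built straight from predicted fragment
# lists, and small hand-assembled networks.

test_library <- residue_library()
test_pairs <- cdp_pair_table(test_library)
test_rules <- build_delta_rules(test_library)

# Noise-free spectrum of a CDP: every predicted fragment present at its
# theoretical m/z, flat intensities. `observed_mz` lets tests plant the
# published (slightly off-calc) precursor value.
spectrum_from_cdp <- function(a, b, id = "S1", rt = 5, observed_mz = NULL,
                              drop_labels = character(0)) {
  cdp <- make_cdp(a, b, test_library)
  fr <- cdp_fragments(cdp)
  fr <- fr[!fr$label %in% drop_labels, ]
  tibble::tibble(
    id = id,
    precursor_mz = observed_mz %||% cdp$mz,
    rt = rt,
    peaks = list(tibble::tibble(mz = sort(fr$mz), intensity = 100))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The worked 3-node network: seed cyclo(Val-Pro) at its published precursor,
# unknowns at the published cyclo(Ala-Pro) / cyclo(Leu-Pro) values.
three_node_fixture <- function() {
  nodes <- tibble::tibble(
    id = c("VP", "AP", "LP"),
    precursor_mz = c(197.1286, 169.0971, 211.1436),
    rt = c(12.7, 5.1, 18.8)
  )
  edges <- tibble::tibble(from = c("VP", "VP"), to = c("AP", "LP"))
  net <- molecular_network(nodes, edges)
  spectra <- dplyr::bind_rows(
    spectrum_from_cdp("Val", "Pro", "VP", 12.7, observed_mz = 197.1286),
    spectrum_from_cdp("Ala", "Pro", "AP", 5.1, observed_mz = 169.0971),
    spectrum_from_cdp("Leu", "Pro", "LP", 18.8, observed_mz = 211.1436)
  )
  seeds <- seed_annotation("VP", "Val", "Pro", net, spectra,
                           library = test_library)
  list(net = net, spectra = spectra, seeds = seeds)
}

# Strip Leu/Ile ambiguity for recovery accounting.
leuile_normalize <- function(x) {
  x <- gsub("Leu/Ile", "Leu", x, fixed = TRUE)
  gsub("Ile", "Leu", x, fixed = TRUE)
}
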