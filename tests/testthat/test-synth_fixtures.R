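test_that("noise-free generation reproduces the predicted fragment list exactly", {
  set.seed(1)
  sp <- generate_spectrum(c("MeEGlu", "Hyp"), rt = 8.8, id = "X",
                          spec = fixture_spec(
                            tibble::tibble(codes = list(c("MeEGlu", "Hyp")), rt = 8.8),
                            dropout = 0, noise_n = 0, ppm_sd = 0
                          ),
                          library = test_library)
  pred <- cdp_fragments(make_cdp("MeEGlu", "Hyp", test_library))
  expect_equal(sp$peaks[[1]]$mz, sort(pred$mz))
  expect_equal(sp$precursor_mz, make_cdp("MeEGlu", "Hyp", test_library)$mz)
  # near-total dropout leaves (at least) the precursor
  set.seed(2)
  sp2 <- generate_spectrum(c("MeEGlu", "Hyp"),
                           spec = fixture_spec(
                             tibble::tibble(codes = list(c("MeEGlu", "Hyp")), rt = 1),
                             dropout = 1 - 1e-9, ppm_sd = 0
                           ),
                           library = test_library)
  expect_true(make_cdp("MeEGlu", "Hyp", test_library)$mz %in% sp2$peaks[[1]]$mz)
  expect_lt(nrow(sp2$peaks[[1]]), nrow(pred))
})

test_that("seeded generation is reproducible and perturbation respects bounds", {
  compounds <- tibble::tibble(
    codes = list(c("Val", "Pro"), c("Leu", "Pro"), c("Ala", "Pro")),
    rt = c(12.7, 18.8, 5.1)
  )
  spec <- fixture_spec(compounds, dropout = 0.3, noise_n = 5, ppm_sd = 5, seed = 99)
  a <- generate_network(spec, library = test_library)
  b <- generate_network(spec, library = test_library)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$network$nodes, b$network$nodes)
  expect_identical(a$network$edges, b$network$edges)
  # precursor perturbation truncated at ppm_max
  ppm_off <- abs(a$network$nodes$precursor_mz - a$truth$theoretical_mz[
    match(a$network$nodes$id, a$truth$id)]) /
    a$truth$theoretical_mz[match(a$network$nodes$id, a$truth$id)] * 1e6
  expect_true(all(ppm_off <= spec$ppm_max + 1e-9))
})

test_that("edges follow the shared-fragment rule so analogs cluster together", {
  # three Pro CDPs share the Pro immonium/companion ions -> all pairwise edges
  pro_family <- fixture_spec(
    tibble::tibble(codes = list(c("Val", "Pro"), c("Leu", "Pro"), c("Ala", "Pro")),
                   rt = c(1, 2, 3)), ppm_sd = 0, seed = 4)
  fx <- generate_network(pro_family, library = test_library)
  expect_equal(nrow(fx$network$edges), 3)
  expect_equal(length(unique(fx$network$nodes$cluster)), 1)
  # two compounds sharing no residues: shared 2 d.p. fragments below threshold
  apart <- fixture_spec(
    tibble::tibble(codes = list(c("Gly", "Ala"), c("Phe", "Tyr")), rt = c(1, 2)),
    ppm_sd = 0, seed = 4)
  shared <- length(intersect(
    round_half_up(cdp_fragments(make_cdp("Gly", "Ala", test_library))$mz, 2),
    round_half_up(cdp_fragments(make_cdp("Phe", "Tyr", test_library))$mz, 2)
  ))
  fx2 <- generate_network(apart, library = test_library)
  expect_lt(shared, 2)
  expect_equal(nrow(fx2$network$edges), 0)
  # single compound: one node, no edges
  solo <- fixture_spec(tibble::tibble(codes = list(c("Gly", "Pro")), rt = 1),
                       seed = 4)
  fx3 <- generate_network(solo, library = test_library)
  expect_equal(nrow(fx3$network$nodes), 1)
  expect_equal(nrow(fx3$network$edges), 0)
})

test_that("generated artifacts round-trip through the file readers", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(
    tibble::tibble(codes = list(c("Val", "Pro"), c("Ala", "Pro")), rt = c(2, 4)),
    noise_n = 3, seed = 12)
  fx <- generate_network(spec, out_dir = dir, library = test_library)
  spectra <- read_mgf(file.path(dir, "spectra.mgf"))
  expect_equal(spectra$precursor_mz, fx$spectra$precursor_mz, tolerance = 1e-4)
  net <- read_network(file.path(dir, "nodes.tsv"), file.path(dir, "edges.tsv"))
  expect_setequal(net$nodes$id, fx$network$nodes$id)
  expect_equal(nrow(net$edges), nrow(fx$network$edges))
})

test_that("the packaged reference set derives formulas and flags discrepancies", {
  ref <- cdp_reference_set(test_library)
  expect_equal(nrow(ref), 53)
  r41 <- ref[ref$node_id == "R41", ]
  expect_identical(r41$display_name, "cyclo(MeEGlu-Hyp)")
  expect_equal(r41$rt, 8.80)
  expect_identical(r41$formula, "C11H16N2O5") # derived, not the printed cell
  expect_true(r41$formula_mismatch)
  r1 <- ref[ref$node_id == "R1", ]
  expect_identical(r1$display_name, "cyclo(Gly-Pro)")
  expect_equal(r1$rt, 3.62)
  expect_false(r1$formula_mismatch)
  expect_equal(sum(ref$novel), 4)
  # enumeration completeness: every row's named candidate is recovered from
  # its m/z at 20 ppm (derived m/z where the printed value is itself flagged)
  for (i in seq_len(nrow(ref))) {
    mz <- if (ref$mz_mismatch[i]) ref$theoretical_mz[i] else ref$observed_mz[i]
    cand <- enumerate_candidates(mz, 20, test_library, test_pairs)
    expect_true(ref$name[i] %in% cand$name, label = ref$display_name[i])
  }
})
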