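# Brute-force propagation oracle for small networks: instead of constructing
# residue-exchanged candidates from an annotated neighbor (what propagate()
# does), enumerate *all* CDP candidates for each open node's precursor, keep
# those consistent with some delta rule on an edge to an annotated neighbor,
# and take the maximum-evidence assignment; iterate to fixpoint.
oracle_propagate <- function(net, seeds, spectra, delta_tol = 0.01,
                             ppm = 10, frag_tol = 0.02) {
  cluster_of <- stats::setNames(net$nodes$cluster, net$nodes$id)
  mz_of <- stats::setNames(net$nodes$precursor_mz, net$nodes$id)
  ed <- net$edges[cluster_of[net$edges$from] == cluster_of[net$edges$to], ]
  nbrs <- function(id) unique(c(ed$to[ed$from == id], ed$from[ed$to == id]))
  ann <- stats::setNames(
    lapply(seq_len(nrow(seeds)), function(i) {
      list(name = seeds$name[i], codes = seeds$codes[[i]])
    }),
    seeds$node_id
  )
  exchange_consistent <- function(cand_codes, nb_codes, d) {
    # cand differs from neighbor by exactly one residue whose mass delta
    # matches the edge delta
    shared <- intersect(cand_codes, nb_codes)
    for (s in unique(shared)) {
      a <- cand_codes[-match(s, cand_codes)]
      b <- nb_codes[-match(s, nb_codes)]
      da <- residue(a, test_library)$mass
      db <- residue(b, test_library)$mass
      if (abs(abs(da - db) - d) <= delta_tol && a != b) return(TRUE)
    }
    FALSE
  }
  repeat {
    changed <- FALSE
    for (id in setdiff(net$nodes$id, names(ann))) {
      sp <- spectra[spectra$id == id, ]
      if (nrow(sp) == 0) next
      cand <- enumerate_candidates(mz_of[[id]], ppm, test_library, test_pairs)
      if (nrow(cand) == 0) next
      best <- NULL
      for (k in seq_len(nrow(cand))) {
        ok <- FALSE
        for (nb in intersect(nbrs(id), names(ann))) {
          d <- abs(mz_of[[id]] - mz_of[[nb]])
          if (exchange_consistent(c(cand$code_a[k], cand$code_b[k]),
                                  ann[[nb]]$codes, d)) { ok <- TRUE; break }
        }
        if (!ok) next
        cdp <- make_cdp(cand$code_a[k], cand$code_b[k], test_library)
        sc <- score_annotation(sp, cdp, frag_tol, ppm)
        if (sc$tier == "weak") next
        if (is.null(best) || sc$total > best$total) {
          best <- list(name = cdp$name, codes = cdp$codes, total = sc$total)
        }
      }
      if (!is.null(best)) {
        ann[[id]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  tibble::tibble(
    node_id = unname(names(ann)),
    name = unname(purrr::map_chr(ann, "name"))
  )
}
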