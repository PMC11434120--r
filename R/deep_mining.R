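# The annotation engine: exact-mass candidate enumeration, evidence scoring,
# residue-exchange delta rules, network propagation, de novo reconciliation,
# isomer and unnatural-residue classification, and the pipeline driver.

.tier_rank <- c(weak = 0L, candidate = 1L, confident = 2L)

default_weights <- function() list(imm = 2, loss = 1, diag = 1)

#' All cyclic-dipeptide candidates of a residue library
#'
#' Enumerates every unordered residue pair (with replacement) and its
#' theoretical protonated precursor m/z. Leu and Ile are distinct entries
#' with identical mass, so both expansions are always present.
#'
#' @param library A residue library from [residue_library()].
#' @return A tibble with `code_a`, `code_b`, `name`, `formula`, `mz`,
#'   `unnatural`.
#' @export
cdp_pair_table <- function(library = residue_library()) {
  n <- nrow(library)
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  purrr::map2_dfr(idx[, 1], idx[, 2], function(i, j) {
    comp <- library$composition[[i]] + library$composition[[j]]
    codes <- sort(c(library$code[i], library$code[j]))
    tibble::tibble(
      code_a = codes[1], code_b = codes[2],
      name = paste0("cyclo(", codes[1], "-", codes[2], ")"),
      formula = format_formula(comp),
      mz = protonated_mz(comp),
      unnatural = library$unnatural[i] || library$unnatural[j]
    )
  })
}

#' Enumerate CDP candidates for an observed precursor m/z
#'
#' @param precursor Observed precursor m/z (singly protonated assumed).
#' @param tol_ppm Precursor tolerance in ppm (default 10).
#' @param library A residue library from [residue_library()].
#' @param pairs Optional precomputed [cdp_pair_table()] (for repeated calls).
#' @return Candidates within tolerance, sorted by absolute ppm error, with a
#'   `ppm_error` column.
#' @examples
#' enumerate_candidates(257.1123)
#' @export
enumerate_candidates <- function(precursor, tol_ppm = 10,
                                 library = residue_library(),
                                 pairs = cdp_pair_table(library)) {
  stopifnot(precursor > 0)
  out <- dplyr::mutate(pairs, ppm_error = (precursor - .data$mz) / .data$mz * 1e6)
  out <- dplyr::filter(out, abs(.data$ppm_error) <= tol_ppm)
  dplyr::arrange(out, abs(.data$ppm_error), .data$name)
}

#' Score a CDP candidate against an observed spectrum
#'
#' Predicts the candidate's fragments, matches them against the peak list and
#' counts matches by class. The weighted total is
#' `w_imm * immonium + w_loss * neutral_loss + w_diag * diagnostic`.
#' The tier is `confident` when the immonium ions of both residues are
#' matched (or one immonium plus at least two neutral losses), `candidate`
#' when at least two predicted fragments besides the precursor are matched,
#' `weak` otherwise. A precursor outside the ppm tolerance forces `weak`
#' (flagged, not an error). Intensities are carried for reporting but do not
#' enter the score.
#'
#' @param spectrum A one-row spectra tibble / list with `precursor_mz` and
#'   `peaks`.
#' @param cdp A `cdp` candidate.
#' @param frag_tol Fragment tolerance in Da (default 0.02).
#' @param precursor_ppm Precursor tolerance in ppm (default 10).
#' @param weights Named list `imm`, `loss`, `diag`.
#' @return An `evidence_score` list: counts `imm`, `loss`, `diag`, logical
#'   `both_immonium`, `total`, `tier`, `precursor_ok`, `ppm_error`, and the
#'   underlying `match` result.
#' @export
score_annotation <- function(spectrum, cdp, frag_tol = 0.02, precursor_ppm = 10,
                             weights = default_weights()) {
  prec_obs <- spectrum$precursor_mz[[1]]
  ppm_error <- (prec_obs - cdp$mz) / cdp$mz * 1e6
  precursor_ok <- is.finite(ppm_error) && abs(ppm_error) <= precursor_ppm
  predicted <- cdp_fragments(cdp)
  m <- match_peaks(spectrum, predicted, tol = frag_tol)
  mt <- m$matched[m$matched$kind != "precursor", ]
  imm <- sum(mt$kind == "immonium")
  loss <- sum(mt$kind == "neutral_loss")
  diag <- sum(mt$kind == "diagnostic")
  imm_res <- unique(mt$provenance[mt$kind == "immonium"])
  both_imm <- all(unique(cdp$codes) %in% imm_res)
  total <- weights$imm * imm + weights$loss * loss + weights$diag * diag
  tier <- if (!precursor_ok) "weak"
    else if (both_imm || (imm >= 1 && loss >= 2)) "confident"
    else if (imm + loss + diag >= 2) "candidate"
    else "weak"
  structure(
    list(imm = imm, loss = loss, diag = diag, both_immonium = both_imm,
         total = total, tier = tier, precursor_ok = precursor_ok,
         ppm_error = ppm_error, match = m),
    class = "evidence_score"
  )
}

#' @export
print.evidence_score <- function(x, ...) {
  cat("<evidence_score> tier ", x$tier, ": ", x$imm, " immonium, ", x$loss,
      " neutral-loss, ", x$diag, " diagnostic (total ", x$total, ")\n", sep = "")
  invisible(x)
}

#' Residue-exchange mass-delta rules
#'
#' All pairwise residue exchanges in the library, expressed as a signed
#' composition delta and its monoisotopic mass. Exchanging a lighter residue
#' for a heavier one along a network edge whose precursor mass difference
#' equals the delta is the propagation move (e.g. Ala -> Val is +C2H4,
#' +28.031 Da; Glu -> PyroGlu is -H2O). Zero-mass exchanges (Leu/Ile) are
#' excluded. Rules are oriented from lighter to heavier residue and
#' deduplicated.
#'
#' @param library A residue library from [residue_library()].
#' @return A tibble with `from`, `to`, `delta_formula`, `delta_mass`
#'   (positive; mass of `to` minus mass of `from`).
#' @examples
#' rules <- build_delta_rules()
#' rules[rules$from == "Ala" & rules$to == "Val", ]
#' @export
build_delta_rules <- function(library = residue_library()) {
  n <- nrow(library)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[library$mass[grid$j] > library$mass[grid$i] + 1e-9, ]
  out <- purrr::map2_dfr(grid$i, grid$j, function(i, j) {
    d <- library$composition[[j]] - library$composition[[i]]
    tibble::tibble(
      from = library$code[i], to = library$code[j],
      delta_formula = format_formula(d),
      delta_mass = delta_mass(d)
    )
  })
  dplyr::arrange(dplyr::distinct(out), .data$delta_mass, .data$from, .data$to)
}

# Build one annotation row (the schema used across the engine).
annotation_row <- function(node_id, cdp, score, level, observed_mz, rt,
                           path = NA_character_, isomer_tag = NA_character_) {
  sc <- score # keep out of tibble()'s data mask (a column is also named score)
  score <- NULL
  tibble::tibble(
    node_id = node_id,
    name = cdp$name,
    codes = list(cdp$codes),
    formula = cdp$formula,
    theoretical_mz = cdp$mz,
    observed_mz = observed_mz,
    rt = rt,
    level = level,
    evidence = sc$imm + sc$loss + sc$diag,
    score = sc$total,
    tier = sc$tier,
    ppm_error = sc$ppm_error,
    unnatural = any(cdp$residues$unnatural),
    isomer_tag = isomer_tag,
    path = path
  )
}

#' Build a seed annotation for a network node
#'
#' Seeds are externally supplied identifications (database matches, de novo
#' calls) attached to network nodes; they anchor propagation and are never
#' overwritten.
#'
#' @param node_id Node id in the network.
#' @param a,b Residue codes of the seeded CDP.
#' @param net A `molecular_network`.
#' @param spectra Spectra tibble (from [read_mgf()]); used to attach evidence.
#' @param level Provenance level (default `"database"`).
#' @param library,frag_tol,precursor_ppm Passed to [score_annotation()].
#' @return A one-row annotations tibble.
#' @export
seed_annotation <- function(node_id, a, b, net, spectra, level = "database",
                            library = residue_library(), frag_tol = 0.02,
                            precursor_ppm = 10) {
  node <- net$nodes[net$nodes$id == node_id, ]
  if (nrow(node) == 0) stop("seed references unknown node: ", node_id, call. = FALSE)
  cdp <- make_cdp(a, b, library)
  sp <- spectrum_for(spectra, node_id)
  score <- if (!is.null(sp)) {
    score_annotation(sp, cdp, frag_tol, precursor_ppm)
  } else {
    list(imm = 0L, loss = 0L, diag = 0L, total = 0, tier = "candidate",
         ppm_error = (node$precursor_mz - cdp$mz) / cdp$mz * 1e6)
  }
  annotation_row(node_id, cdp, score, level, node$precursor_mz, node$rt,
                 path = "seed")
}

spectrum_for <- function(spectra, id) {
  i <- which(spectra$id == id)
  if (length(i) == 0) return(NULL)
  spectra[i[1], ]
}

#' Propagate annotations across the molecular network
#'
#' Breadth-first over edges within each cluster, starting from the seed
#' annotations: for an unannotated neighbor whose precursor mass difference
#' matches a residue-exchange delta rule within tolerance, the residue-
#' exchanged candidate is proposed and accepted when its evidence tier is at
#' least `candidate` against the neighbor's spectrum. Iterates to a fixpoint;
#' seeds are never overwritten; every accepted annotation records its
#' propagation path. A second pass considers node pairs *across* clusters for
#' deltas on a whitelist (water by default, the pyroglutamate signature).
#' Conflicting proposals keep the highest weighted total; exact ties are
#' emitted for both candidates, marked unresolved.
#'
#' @param net A `molecular_network`.
#' @param seeds An annotations tibble (e.g. rows from [seed_annotation()]).
#' @param spectra Spectra tibble from [read_mgf()].
#' @param rules Delta rules from [build_delta_rules()].
#' @param library Residue library.
#' @param delta_tol Tolerance on edge mass differences in Da (default 0.01).
#' @param frag_tol,precursor_ppm,weights Scoring parameters.
#' @param cross_cluster_deltas Character vector of neutral formulas allowed to
#'   link nodes across clusters (default `"H2O"`); `NULL` disables the pass.
#' @return The combined annotations tibble (seeds plus accepted propagations,
#'   level `"propagated"`).
#' @export
propagate <- function(net, seeds, spectra, rules = NULL,
                      library = residue_library(), delta_tol = 0.01,
                      frag_tol = 0.02, precursor_ppm = 10,
                      weights = default_weights(),
                      cross_cluster_deltas = "H2O") {
  if (is.null(rules)) rules <- build_delta_rules(library)
  stopifnot(all(seeds$node_id %in% net$nodes$id))
  nodes <- net$nodes
  cluster_of <- stats::setNames(nodes$cluster, nodes$id)
  mz_of <- stats::setNames(nodes$precursor_mz, nodes$id)
  rt_of <- stats::setNames(nodes$rt, nodes$id)
  # undirected adjacency restricted to intra-cluster edges
  ed <- net$edges[cluster_of[net$edges$from] == cluster_of[net$edges$to], ]
  adj <- dplyr::bind_rows(
    tibble::tibble(a = ed$from, b = ed$to),
    tibble::tibble(a = ed$to, b = ed$from)
  )
  ann <- seeds
  ann$path[is.na(ann$path)] <- "seed"

  propose <- function(source_row, target_id) {
    # residue-exchange proposals from one annotated node to one target node
    d_signed <- mz_of[[target_id]] - source_row$observed_mz
    codes <- source_row$codes[[1]]
    hits <- rules[abs(rules$delta_mass - abs(d_signed)) <= delta_tol, ]
    if (nrow(hits) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(hits)), function(k) {
      r <- hits[k, ]
      old <- if (d_signed > 0) r$from else r$to   # residue being swapped out
      new <- if (d_signed > 0) r$to else r$from
      if (!old %in% codes) return(NULL)
      other <- if (codes[1] == old) codes[2] else codes[1]
      cdp <- make_cdp(other, new, library)
      sp <- spectrum_for(spectra, target_id)
      if (is.null(sp)) return(NULL)
      sc <- score_annotation(sp, cdp, frag_tol, precursor_ppm, weights)
      if (.tier_rank[sc$tier] < .tier_rank["candidate"]) return(NULL)
      annotation_row(
        target_id, cdp, sc, "propagated", mz_of[[target_id]], rt_of[[target_id]],
        path = paste0(source_row$path, " -> ", source_row$node_id,
                      " [", ifelse(d_signed > 0, "+", "-"), r$delta_formula, "]")
      )
    })
  }

  frontier <- ann$node_id
  while (length(frontier) > 0) {
    proposals <- purrr::map_dfr(frontier, function(src) {
      nb <- setdiff(adj$b[adj$a == src], ann$node_id)
      if (length(nb) == 0) return(NULL)
      src_row <- ann[ann$node_id == src, ][1, ]
      purrr::map_dfr(nb, ~ propose(src_row, .x))
    })
    if (nrow(proposals) == 0) break
    accepted <- resolve_proposals(proposals)
    accepted <- accepted[!accepted$node_id %in% ann$node_id, ]
    if (nrow(accepted) == 0) break
    ann <- dplyr::bind_rows(ann, accepted)
    frontier <- unique(accepted$node_id)
  }

  if (!is.null(cross_cluster_deltas) && length(cross_cluster_deltas) > 0) {
    wl <- purrr::map_dbl(cross_cluster_deltas, ~ monoisotopic_mass(parse_formula(.x)))
    open <- setdiff(nodes$id, ann$node_id)
    proposals <- purrr::map_dfr(open, function(tid) {
      d <- abs(mz_of[[tid]] - ann$observed_mz)
      srcs <- ann$node_id[cluster_of[ann$node_id] != cluster_of[[tid]] &
                            purrr::map_lgl(d, ~ any(abs(.x - wl) <= delta_tol))]
      purrr::map_dfr(srcs, function(src) {
        src_row <- ann[ann$node_id == src, ][1, ]
        p <- propose(src_row, tid)
        if (is.null(p) || nrow(p) == 0) return(NULL)
        # cross-cluster moves must themselves be whitelist deltas
        p[grepl(paste(paste0("\\[[+-]", cross_cluster_deltas, "\\]"),
                      collapse = "|"), p$path), ]
      })
    })
    if (nrow(proposals) > 0) {
      accepted <- resolve_proposals(proposals)
      accepted <- accepted[!accepted$node_id %in% ann$node_id, ]
      ann <- dplyr::bind_rows(ann, accepted)
    }
  }
  ann
}

# Keep, per node, the proposal(s) with the highest weighted total; distinct
# tied candidates are all kept, marked unresolved.
resolve_proposals <- function(proposals) {
  proposals |>
    dplyr::group_by(.data$node_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::distinct(df, .data$name, .keep_all = TRUE)
      best <- df[df$score == max(df$score), , drop = FALSE]
      if (nrow(best) > 1) best$isomer_tag <- "unresolved"
      best
    }) |>
    dplyr::ungroup()
}

#' Reconcile de novo dipeptide calls with their cyclic forms
#'
#' A de novo dipeptide carrying a dehydration tag (-18.01 Da) — or whose
#' precursor mass already equals the residue sum plus a proton — has the mass
#' of the cyclic dipeptide; de novo engines report it as a dehydrated linear
#' peptide because they cannot call ring structures. Each such hit is
#' rescored as the corresponding CDP and, when the candidate's residues allow
#' it, as the pyroglutamyl linear alternative (Glu - H2O). The revision to a
#' CDP is accepted when the CDP evidence tier is at least `candidate` and the
#' node's cluster already contains a CDP-annotated node; accepted revisions
#' carry level `"revised"` and retain the original linear call in `path`.
#' Hits longer than two residues pass through unchanged as level `"denovo"`.
#'
#' @param hits De novo hits from [read_denovo_table()].
#' @param net A `molecular_network`.
#' @param spectra Spectra tibble.
#' @param annotations Existing annotations (used for the cluster-context
#'   test); may be empty.
#' @param library,frag_tol,precursor_ppm,weights Scoring parameters.
#' @return An annotations tibble for the hits (levels `denovo` / `revised`).
#' @export
revise_linear_to_cyclic <- function(hits, net, spectra, annotations = NULL,
                                    library = residue_library(),
                                    frag_tol = 0.02, precursor_ppm = 10,
                                    weights = default_weights()) {
  if (is.null(annotations)) annotations <- empty_annotations()
  nodes <- net$nodes
  cluster_of <- stats::setNames(nodes$cluster, nodes$id)
  cdp_clusters <- unique(cluster_of[annotations$node_id[
    purrr::map_lgl(annotations$codes, ~ length(.x) == 2)]])
  proton <- physical_constants()$proton
  purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    node_id <- match_hit_to_node(h, net)
    if (is.na(node_id)) return(NULL)
    node <- nodes[nodes$id == node_id, ]
    seqs <- h$sequence[[1]]
    linear_name <- paste(seqs, collapse = "-")
    if (length(seqs) != 2) {
      return(linear_annotation(node_id, seqs, h, node, library, "denovo"))
    }
    res_sum <- sum(purrr::map_dbl(seqs, ~ residue(.x, library)$mass))
    mass_is_cyclic <- abs(node$precursor_mz - (res_sum + proton)) <=
      node$precursor_mz * precursor_ppm * 1e-6
    if (!isTRUE(h$dehydrated) && !mass_is_cyclic) {
      return(linear_annotation(node_id, seqs, h, node, library, "denovo"))
    }
    sp <- spectrum_for(spectra, node_id)
    if (is.null(sp)) {
      return(linear_annotation(node_id, seqs, h, node, library, "denovo"))
    }
    cdp <- make_cdp(seqs[1], seqs[2], library)
    sc_cdp <- score_annotation(sp, cdp, frag_tol, precursor_ppm, weights)
    # pyroglutamate formation explains the same -H2O; score the alternative
    sc_pyro <- NULL; pyro_cdp <- NULL
    if ("Glu" %in% seqs) {
      alt <- replace(seqs, match("Glu", seqs), "PyroGlu")
      pyro_cdp <- make_cdp(alt[1], alt[2], library)
      sc_pyro <- score_annotation(sp, pyro_cdp, frag_tol, precursor_ppm, weights)
    }
    in_cdp_cluster <- cluster_of[[node_id]] %in% cdp_clusters
    if (!is.null(sc_pyro) && sc_pyro$total > sc_cdp$total) {
      cdp <- pyro_cdp; sc_cdp <- sc_pyro
    }
    if (.tier_rank[sc_cdp$tier] >= .tier_rank["candidate"] && in_cdp_cluster) {
      annotation_row(node_id, cdp, sc_cdp, "revised", node$precursor_mz,
                     node$rt,
                     path = paste0("revised from de novo ", linear_name,
                                   ifelse(isTRUE(h$dehydrated), " (-H2O)", "")))
    } else {
      linear_annotation(node_id, seqs, h, node, library, "denovo")
    }
  })
}

match_hit_to_node <- function(hit, net, ppm = 10, rt_tol = 0.25) {
  if (hit$feature_id %in% net$nodes$id) return(hit$feature_id)
  # fallback join on (precursor m/z within ppm, RT within rt_tol minutes)
  if (!is.null(hit$precursor_mz) && !is.na(hit$precursor_mz %||% NA)) {
    cand <- net$nodes[abs(net$nodes$precursor_mz - hit$precursor_mz) <=
                        net$nodes$precursor_mz * ppm * 1e-6, ]
    if (!is.null(hit$rt) && !is.na(hit$rt %||% NA)) {
      cand <- cand[!is.na(cand$rt) & abs(cand$rt - hit$rt) <= rt_tol, ]
    }
    if (nrow(cand) > 0) return(cand$id[1])
  }
  NA_character_
}

linear_annotation <- function(node_id, seqs, hit, node, library, level) {
  comp <- purrr::reduce(purrr::map(seqs, ~ residue(.x, library)$composition[[1]]),
                        `+`) + parse_formula("H2O")
  tibble::tibble(
    node_id = node_id,
    name = paste(seqs, collapse = "-"),
    codes = list(seqs),
    formula = format_formula(comp),
    theoretical_mz = protonated_mz(comp) + sum(hit$mods[[1]] %||% 0),
    observed_mz = node$precursor_mz,
    rt = node$rt,
    level = level,
    evidence = NA_integer_,
    score = NA_real_,
    tier = NA_character_,
    ppm_error = NA_real_,
    unnatural = any(purrr::map_lgl(seqs, ~ residue(.x, library)$unnatural)),
    isomer_tag = NA_character_,
    path = paste0("de novo (ALC ", hit$alc, ")")
  )
}

empty_annotations <- function() {
  tibble::tibble(
    node_id = character(0), name = character(0), codes = list(),
    formula = character(0), theoretical_mz = numeric(0),
    observed_mz = numeric(0), rt = numeric(0), level = character(0),
    evidence = integer(0), score = numeric(0), tier = character(0),
    ppm_error = numeric(0), unnatural = logical(0),
    isomer_tag = character(0), path = character(0)
  )
}

#' Group annotations into isomer classes
#'
#' Annotations are grouped by elemental formula. Within a formula group,
#' members with the *same named residue composition* and exactly two distinct
#' retention times form a diastereomer pair (same residues, different
#' stereochemistry, resolved on reversed-phase C18). Members with the same
#' formula but *different* residue composition (e.g. cyclo(Tyr-Hyp) vs
#' cyclo(Glu-Phe), or Leu vs Ile variants) are positional isomers. Anything
#' else sharing a formula is reported unresolved.
#'
#' With `leu_ile_rt = TRUE`, within a positional Leu/Ile pair the earlier-
#' eluting member is assigned the Ile variant (an elution-order heuristic;
#' the output marks it as such).
#'
#' @param annotations An annotations tibble with `name`, `formula`, `rt`.
#' @param leu_ile_rt Enable the Leu/Ile elution-order heuristic.
#' @return A tibble of groups: `formula`, `name`, `relation` (one of
#'   `diastereomer_pair`, `positional_isomers`, `unresolved`), `n`,
#'   `node_ids` (list), `rts` (list), `note`.
#' @export
classify_isomers <- function(annotations, leu_ile_rt = FALSE) {
  empty_groups <- tibble::tibble(formula = character(0), name = character(0),
                                 relation = character(0), n = integer(0),
                                 node_ids = list(), rts = list(),
                                 note = character(0))
  ann <- annotations[!is.na(annotations$formula), ]
  if (nrow(ann) == 0) return(empty_groups)
  if (leu_ile_rt) ann <- apply_leu_ile_heuristic(ann)
  out <- ann |>
    dplyr::group_by(.data$formula) |>
    dplyr::group_modify(function(df, key) {
      n_names <- length(unique(df$name))
      purrr::map_dfr(unique(df$name), function(nm) {
        sub <- df[df$name == nm, ]
        relation <- if (nrow(sub) == 2 && length(unique(sub$rt)) == 2) {
          "diastereomer_pair"
        } else if (n_names > 1) {
          "positional_isomers"
        } else if (nrow(sub) > 1) {
          "unresolved"
        } else {
          NA_character_
        }
        if (is.na(relation)) return(NULL)
        note <- if (leu_ile_rt && any(grepl("heuristic", sub$isomer_tag %||% ""))) {
          "Leu/Ile assigned by elution order (heuristic)"
        } else NA_character_
        tibble::tibble(name = nm, relation = relation, n = nrow(sub),
                       node_ids = list(sub$node_id), rts = list(sub$rt),
                       note = note)
      })
    }) |>
    dplyr::ungroup()
  if (!"relation" %in% names(out)) return(empty_groups) # no co-isomeric rows
  out
}

# Within each formula, if exactly two members differ only by a Leu<->Ile swap,
# give the earlier-eluting one the Ile name.
apply_leu_ile_heuristic <- function(ann) {
  swap <- function(nm) {
    if (grepl("Ile", nm)) sub("Ile", "Leu", nm)
    else if (grepl("Leu", nm)) sub("Leu", "Ile", nm)
    else NA_character_
  }
  for (f in unique(ann$formula)) {
    i <- which(ann$formula == f)
    if (length(i) != 2) next
    nms <- ann$name[i]
    if (is.na(swap(nms[1])) || swap(nms[1]) != nms[2]) next
    earlier <- i[which.min(ann$rt[i])]
    later <- setdiff(i, earlier)
    ile_name <- if (grepl("Ile", nms[1])) nms[1] else nms[2]
    leu_name <- if (grepl("Leu", nms[1])) nms[1] else nms[2]
    ann$name[earlier] <- ile_name
    ann$name[later] <- leu_name
    ann$isomer_tag[c(earlier, later)] <- "Leu/Ile by RT heuristic"
  }
  ann
}

#' Flag and count unnatural-residue annotations
#'
#' An annotation is unnatural when at least one of its residues carries the
#' unnatural flag (Hyp, MeEGlu, PyroGlu in the default library).
#'
#' @param annotations An annotations tibble with a `codes` list-column.
#' @param library A residue library.
#' @return A list with `annotations` (flag recomputed) and `counts`, a
#'   one-row tibble `total`, `unnatural`, `natural`.
#' @export
classify_unnatural <- function(annotations, library = residue_library()) {
  flag <- purrr::map_lgl(annotations$codes, function(codes) {
    any(purrr::map_lgl(codes, ~ residue(.x, library)$unnatural))
  })
  annotations$unnatural <- flag
  list(
    annotations = annotations,
    counts = tibble::tibble(
      total = nrow(annotations),
      unnatural = sum(flag),
      natural = sum(!flag)
    )
  )
}

#' Run the full deep-mining pipeline
#'
#' Executes the annotation workflow end to end: seed ingestion (database and
#' de novo layers supplied as tables) -> exact-mass enumeration and evidence
#' scoring of unannotated nodes -> delta-rule propagation -> de novo
#' revision -> isomer and unnatural-residue classification -> report. The run
#' is deterministic given fixed inputs and configuration; nodes are processed
#' in ascending precursor m/z, then RT.
#'
#' @param mgf,nodes,edges Paths to the MGF file and the node/edge tables (or
#'   pass `spectra =` and `network =` directly).
#' @param denovo Optional path to a de novo result table.
#' @param seeds Optional seed table: path or tibble with columns `node_id`,
#'   `residue_a`, `residue_b` and optionally `level`.
#' @param spectra,network Optional pre-loaded inputs (override the paths).
#' @param config Optional list (or YAML path) overriding any of
#'   `precursor_ppm`, `frag_tol`, `delta_tol`, `min_alc`, `weights`,
#'   `cross_cluster_deltas`, `leu_ile_rt`, `residues` (library overrides).
#' @return An object of class `cdp_pipeline`: list with `annotations`,
#'   `isomer_groups`, `counts` (per-level and unnatural counts),
#'   `network`, and `params`.
#' @export
run_pipeline <- function(mgf = NULL, nodes = NULL, edges = NULL, denovo = NULL,
                         seeds = NULL, spectra = NULL, network = NULL,
                         config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- utils::modifyList(list(
    precursor_ppm = 10, frag_tol = 0.02, delta_tol = 0.01, min_alc = 50,
    weights = default_weights(), cross_cluster_deltas = "H2O",
    leu_ile_rt = FALSE, residues = NULL
  ), config)
  library <- residue_library(p$residues)
  pairs <- cdp_pair_table(library)
  rules <- build_delta_rules(library)
  if (is.null(spectra)) spectra <- read_mgf(mgf)
  if (is.null(network)) network <- read_network(nodes, edges)
  hits <- if (!is.null(denovo)) {
    read_denovo_table(denovo, min_alc = p$min_alc, library = library)
  } else NULL

  # stage 1: seed ingestion
  ann <- empty_annotations()
  if (!is.null(seeds)) {
    if (is.character(seeds)) {
      seeds <- readr::read_tsv(seeds, show_col_types = FALSE, progress = FALSE)
    }
    ann <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
      seed_annotation(as.character(seeds$node_id[i]), seeds$residue_a[i],
                      seeds$residue_b[i], network, spectra,
                      level = seeds$level[i] %||% "database",
                      library = library, frag_tol = p$frag_tol,
                      precursor_ppm = p$precursor_ppm)
    })
  }
  message("seeds: ", nrow(ann))

  # stage 2: exact-mass enumeration + scoring of unannotated nodes
  open <- dplyr::arrange(
    network$nodes[!network$nodes$id %in% ann$node_id, ],
    .data$precursor_mz, .data$rt
  )
  mined <- purrr::map_dfr(seq_len(nrow(open)), function(i) {
    node <- open[i, ]
    sp <- spectrum_for(spectra, node$id)
    if (is.null(sp)) return(NULL)
    cand <- enumerate_candidates(node$precursor_mz, p$precursor_ppm, library, pairs)
    if (nrow(cand) == 0) return(NULL)
    scored <- purrr::map_dfr(seq_len(nrow(cand)), function(k) {
      cdp <- make_cdp(cand$code_a[k], cand$code_b[k], library)
      sc <- score_annotation(sp, cdp, p$frag_tol, p$precursor_ppm, p$weights)
      if (.tier_rank[sc$tier] < .tier_rank["candidate"]) return(NULL)
      annotation_row(node$id, cdp, sc, "deep_mined", node$precursor_mz, node$rt,
                     path = "exact-mass enumeration")
    })
    if (nrow(scored) == 0) return(NULL)
    resolve_leu_ile(scored[scored$score == max(scored$score), ])
  })
  ann <- dplyr::bind_rows(ann, mined)
  message("deep-mined by enumeration: ", nrow(mined))

  # stage 3: propagation
  before <- nrow(ann)
  if (nrow(ann) > 0) {
    ann <- propagate(network, ann, spectra, rules, library,
                     delta_tol = p$delta_tol, frag_tol = p$frag_tol,
                     precursor_ppm = p$precursor_ppm, weights = p$weights,
                     cross_cluster_deltas = p$cross_cluster_deltas)
  }
  message("propagated: ", nrow(ann) - before)

  # stage 4: de novo revision
  if (!is.null(hits) && nrow(hits) > 0) {
    rev_ann <- revise_linear_to_cyclic(hits, network, spectra, ann, library,
                                       p$frag_tol, p$precursor_ppm, p$weights)
    rev_ann <- rev_ann[!rev_ann$node_id %in% ann$node_id, ]
    ann <- dplyr::bind_rows(ann, rev_ann)
    message("de novo layer: ", nrow(rev_ann))
  }

  # stage 5: classification
  cdp_ann <- ann[purrr::map_lgl(ann$codes, ~ length(.x) == 2), ]
  iso <- classify_isomers(cdp_ann, leu_ile_rt = p$leu_ile_rt)
  un <- classify_unnatural(ann, library)
  ann <- un$annotations
  ann <- dplyr::arrange(ann, .data$observed_mz, .data$rt)

  counts <- tibble::tibble(
    nodes = nrow(network$nodes),
    annotated = length(unique(ann$node_id)),
    cdps = nrow(cdp_ann),
    database = sum(ann$level == "database"),
    denovo = sum(ann$level == "denovo"),
    deep_mined = sum(ann$level %in% c("deep_mined", "propagated", "revised")),
    diastereomer_pairs = sum(iso$relation == "diastereomer_pair"),
    unnatural = un$counts$unnatural
  )
  structure(
    list(annotations = ann, isomer_groups = iso, counts = counts,
         network = network, params = p),
    class = "cdp_pipeline"
  )
}

# Collapse a Leu/Ile tie on one node into a single "Leu/Ile" annotation.
resolve_leu_ile <- function(rows) {
  if (nrow(rows) == 2) {
    nm <- sort(rows$name)
    if (identical(sub("Ile", "Leu", nm[1]), sub("Ile", "Leu", nm[2])) &&
        !identical(nm[1], nm[2])) {
      keep <- rows[grepl("Leu", rows$name), ][1, ]
      keep$name <- sub("Leu", "Leu/Ile", keep$name)
      keep$isomer_tag <- "Leu/Ile ambiguous"
      return(keep)
    }
  }
  if (nrow(rows) > 1) rows$isomer_tag <- "unresolved"
  rows
}

#' @export
print.cdp_pipeline <- function(x, ...) {
  cat("<cdp_pipeline> ", x$counts$annotated, "/", x$counts$nodes,
      " nodes annotated; ", x$counts$cdps, " CDP annotations (",
      x$counts$unnatural, " unnatural), ",
      x$counts$diastereomer_pairs, " diastereomer pair(s)\n", sep = "")
  invisible(x)
}
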