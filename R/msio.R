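# MGF spectra, molecular-network node/edge tables, de novo result tables,
# and the annotation report.

#' Read an MGF (Mascot Generic Format) file
#'
#' Parses the GNPS/FBMN dialect: `BEGIN IONS`/`END IONS` blocks with
#' `PEPMASS`, optional `RTINSECONDS`, optional `TITLE`/`FEATURE_ID`/`SCANS`,
#' and whitespace-separated `m/z intensity` peak rows. Retention time is
#' converted to minutes; peaks are sorted ascending by m/z on load. Records
#' without a PEPMASS line are skipped with a warning.
#'
#' @param path Path to an MGF file.
#' @return A tibble with one row per spectrum: `id`, `precursor_mz`, `rt`
#'   (minutes, `NA` when absent) and `peaks` (list of tibbles with `mz`,
#'   `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("cannot read MGF file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  recs <- purrr::map(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    header <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[header], "=", fixed = TRUE)
    keys <- toupper(purrr::map_chr(kv, 1))
    vals <- purrr::map_chr(kv, ~ paste(.x[-1], collapse = "="))
    if (!"PEPMASS" %in% keys) {
      warning("MGF record ", k, " has no PEPMASS; skipped", call. = FALSE)
      return(NULL)
    }
    pep <- as.numeric(strsplit(trimws(vals[keys == "PEPMASS"][1]), "\\s+")[[1]][1])
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[keys == "RTINSECONDS"][1]) / 60
    } else NA_real_
    id <- if ("FEATURE_ID" %in% keys) vals[keys == "FEATURE_ID"][1]
      else if ("SCANS" %in% keys) vals[keys == "SCANS"][1]
      else if ("TITLE" %in% keys) vals[keys == "TITLE"][1]
      else as.character(k)
    pk <- block[!header & nzchar(trimws(block))]
    peaks <- if (length(pk) > 0) {
      mat <- do.call(rbind, strsplit(trimws(pk), "\\s+"))
      tibble::tibble(mz = as.numeric(mat[, 1]), intensity = as.numeric(mat[, 2]))
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    tibble::tibble(id = id, precursor_mz = pep, rt = rt,
                   peaks = list(dplyr::arrange(peaks, .data$mz)))
  })
  dplyr::bind_rows(recs)
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] up to float formatting: m/z values are written at
#' 5 decimal places so a round trip reproduces them to 4 d.p. Spectra without
#' a retention time omit the RTINSECONDS line.
#'
#' @param spectra A spectra tibble as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  out <- purrr::map(seq_len(nrow(spectra)), function(i) {
    s <- spectra[i, ]
    pk <- s$peaks[[1]]
    c("BEGIN IONS",
      paste0("FEATURE_ID=", s$id),
      paste0("PEPMASS=", formatC(s$precursor_mz, format = "f", digits = 5)),
      if (!is.na(s$rt)) paste0("RTINSECONDS=", formatC(s$rt * 60, format = "f", digits = 3)),
      paste(formatC(pk$mz, format = "f", digits = 5),
            formatC(pk$intensity, format = "f", digits = 1)),
      "END IONS", "")
  })
  writeLines(as.character(unlist(out)), path)
  invisible(path)
}

#' Read a molecular network from node and edge tables
#'
#' Reads delimited node and edge tables (GNPS/Cytoscape-style exports).
#' Column names are mapped through `col_map` so the common dialects
#' (`cluster index` vs `componentindex` etc.) load without editing files.
#' Self-loop edges are dropped with a message; an edge referencing an unknown
#' node is an error. When the node table has no cluster column, cluster ids
#' are assigned from the connected components of the edge set. Every loaded
#' edge is checked for consistency between its stored mass difference and the
#' absolute difference of its endpoints' precursor m/z (0.01 Da).
#'
#' @param nodes_path,edges_path Paths to delimited text files with a header.
#' @param col_map Named list mapping the internal names `id`, `mz`, `rt`,
#'   `cluster`, `from`, `to`, `cosine`, `delta` to column names in the files;
#'   defaults cover GNPS exports and this package's own fixtures.
#' @param delim Field delimiter (default tab; `","` for csv).
#' @return A list of class `molecular_network` with tibbles `nodes`
#'   (`id`, `precursor_mz`, `rt`, `cluster`) and `edges`
#'   (`from`, `to`, `cosine`, `delta_mz`).
#' @export
read_network <- function(nodes_path, edges_path, col_map = list(), delim = "\t") {
  defaults <- list(
    id = c("id", "feature_id", "cluster index", "row ID", "shared name"),
    mz = c("precursor_mz", "mz", "precursor mass", "parent mass", "row m/z"),
    rt = c("rt", "RTMean", "rtmean", "row retention time"),
    cluster = c("cluster", "componentindex", "component"),
    from = c("from", "CLUSTERID1", "node1"),
    to = c("to", "CLUSTERID2", "node2"),
    cosine = c("cosine", "Cosine", "cosine_score"),
    delta = c("delta_mz", "DeltaMZ", "mass_difference", "MassDiff")
  )
  for (k in names(col_map)) defaults[[k]] <- col_map[[k]]
  pick <- function(df, key, required = TRUE) {
    hit <- intersect(defaults[[key]], names(df))
    if (length(hit) == 0) {
      if (required) stop("no column for ", key, " in table (tried: ",
                         paste(defaults[[key]], collapse = ", "), ")", call. = FALSE)
      return(NULL)
    }
    df[[hit[1]]]
  }
  nd <- readr::read_delim(nodes_path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  ed <- readr::read_delim(edges_path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  nodes <- tibble::tibble(
    id = as.character(pick(nd, "id")),
    precursor_mz = as.numeric(pick(nd, "mz")),
    rt = as.numeric(pick(nd, "rt", required = FALSE) %||% rep(NA_real_, nrow(nd)))
  )
  clus <- pick(nd, "cluster", required = FALSE)
  edges <- tibble::tibble(
    from = as.character(pick(ed, "from")),
    to = as.character(pick(ed, "to")),
    cosine = as.numeric(pick(ed, "cosine", required = FALSE) %||% rep(NA_real_, nrow(ed))),
    delta_mz = as.numeric(pick(ed, "delta", required = FALSE) %||% rep(NA_real_, nrow(ed)))
  )
  loops <- edges$from == edges$to
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop edge(s)")
    edges <- edges[!loops, ]
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(unknown) > 0) {
    stop("edge table references unknown node id(s): ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  mz_of <- stats::setNames(nodes$precursor_mz, nodes$id)
  computed <- abs(mz_of[edges$from] - mz_of[edges$to])
  edges$delta_mz <- ifelse(is.na(edges$delta_mz), computed, edges$delta_mz)
  off <- abs(edges$delta_mz - computed) > 0.01
  if (any(off)) {
    stop("stored edge mass difference disagrees with node m/z difference for ",
         sum(off), " edge(s)", call. = FALSE)
  }
  if (is.null(clus)) {
    nodes$cluster <- network_components(nodes$id, edges)
  } else {
    nodes$cluster <- as.integer(clus)
  }
  nodes <- dplyr::arrange(nodes, .data$precursor_mz, .data$rt, .data$id)
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "molecular_network")
}

# Deterministic connected-component labels (1, 2, ... by smallest member id).
network_components <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  relabel <- stats::setNames(seq_along(unique(comp[order(ids)])), unique(comp[order(ids)]))
  as.integer(relabel[as.character(comp)])
}

#' Construct a molecular network from in-memory tables
#'
#' @param nodes Tibble with `id`, `precursor_mz`, `rt` and optionally `cluster`.
#' @param edges Tibble with `from`, `to` and optionally `cosine`, `delta_mz`.
#' @return A `molecular_network`.
#' @export
molecular_network <- function(nodes, edges) {
  nodes$id <- as.character(nodes$id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"rt" %in% names(nodes)) nodes$rt <- NA_real_
  if (!"cosine" %in% names(edges)) edges$cosine <- NA_real_
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  mz_of <- stats::setNames(nodes$precursor_mz, nodes$id)
  edges$delta_mz <- abs(mz_of[edges$from] - mz_of[edges$to])
  if (!"cluster" %in% names(nodes)) {
    nodes$cluster <- network_components(nodes$id, edges)
  }
  structure(list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("<molecular_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", length(unique(x$nodes$cluster)), " cluster(s)\n", sep = "")
  invisible(x)
}

#' Read a de novo sequencing result table
#'
#' Reads a delimited table of de novo peptide calls (feature id, peptide
#' string, ALC score). Peptide strings are residue codes joined by `-`, with
#' optional inline modification tags in parentheses, e.g.
#' `"Tyr-Pro(-18.01)"` for a dehydrated dipeptide. Rows below the ALC
#' threshold are excluded; rows whose sequence cannot be parsed are skipped
#' with a warning.
#'
#' @param path Path to a delimited file with columns `feature_id` (or `id`),
#'   `sequence` (or `peptide`), `alc` (or `ALC`), and optionally `mods`.
#' @param min_alc Minimum average local confidence to keep, in percent
#'   (default 50, the usual de novo screening threshold).
#' @param delim Field delimiter.
#' @param library A residue library from [residue_library()].
#' @return A tibble with `feature_id`, `sequence` (list of residue code
#'   vectors), `mods` (list of signed Da numeric vectors), `alc`,
#'   `dehydrated` (TRUE when a tag within 0.02 Da of -18.011 is present).
#' @export
read_denovo_table <- function(path, min_alc = 50, delim = "\t",
                              library = residue_library()) {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(feature_id = character(0), sequence = list(),
                          mods = list(), alc = numeric(0), dehydrated = logical(0)))
  }
  nm <- names(df)
  col <- function(cands) { h <- intersect(cands, nm); if (length(h)) df[[h[1]]] else NULL }
  ids <- as.character(col(c("feature_id", "id", "Feature", "scan")))
  seqs <- as.character(col(c("sequence", "peptide", "Peptide")))
  alcs <- as.numeric(col(c("alc", "ALC", "ALC (%)")))
  extra_mods <- col(c("mods", "modifications"))
  if (is.null(ids) || is.null(seqs) || is.null(alcs)) {
    stop("de novo table needs feature_id, sequence and alc columns", call. = FALSE)
  }
  h2o <- monoisotopic_mass(parse_formula("H2O"))
  rows <- purrr::map(seq_along(seqs), function(i) {
    if (is.na(alcs[i]) || alcs[i] < min_alc) return(NULL)
    s <- seqs[i]
    tags <- as.numeric(stringr::str_match_all(s, "\\(([+-]?[0-9.]+)\\)")[[1]][, 2])
    if (!is.null(extra_mods) && !is.na(extra_mods[i]) && nzchar(extra_mods[i])) {
      tags <- c(tags, as.numeric(strsplit(as.character(extra_mods[i]), ";")[[1]]))
    }
    bare <- stringr::str_remove_all(s, "\\([+-]?[0-9.]+\\)")
    codes <- strsplit(bare, "-", fixed = TRUE)[[1]]
    ok <- tryCatch({ purrr::walk(codes, residue, library = library); TRUE },
                   error = function(e) FALSE)
    if (!ok || length(codes) == 0) {
      warning("unparseable de novo sequence skipped: ", dQuote(s), call. = FALSE)
      return(NULL)
    }
    tibble::tibble(
      feature_id = ids[i], sequence = list(codes), mods = list(tags),
      alc = alcs[i],
      dehydrated = any(abs(tags + h2o) <= 0.02)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write an annotation report
#'
#' Tab-separated report with one row per annotation, ordered by observed m/z
#' then retention time, matching the layout of published CDP tables: name,
#' Hill formula, theoretical and observed m/z, RT, annotation level, evidence
#' count, isomer tag and unnatural-residue flag.
#'
#' @param annotations An annotations tibble (see [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- c("name", "formula", "theoretical_mz", "observed_mz", "rt",
            "level", "evidence", "isomer_tag", "unnatural")
  if (nrow(annotations) == 0) {
    empty <- stats::setNames(replicate(length(cols), character(0), simplify = FALSE), cols)
    readr::write_tsv(tibble::as_tibble(empty), path)
    return(invisible(path))
  }
  out <- tibble::tibble(
    name = annotations$name,
    formula = annotations$formula,
    theoretical_mz = round_half_up(annotations$theoretical_mz, 4),
    observed_mz = round_half_up(annotations$observed_mz, 4),
    rt = annotations$rt,
    level = annotations$level,
    evidence = annotations$evidence,
    isomer_tag = annotations$isomer_tag %||% NA_character_,
    unnatural = annotations$unnatural
  )
  out <- dplyr::arrange(out, .data$observed_mz, .data$rt)
  readr::write_tsv(out, path)
  invisible(path)
}
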