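# Elemental formula arithmetic, monoisotopic masses, and the residue library.

# Monoisotopic atomic masses (Da), CODATA/IUPAC values to >= 6 d.p.
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163,
  Se = 79.9165213
)

#' Physical constants used for m/z arithmetic
#'
#' Monoisotopic atomic masses together with the proton and electron masses.
#' Protonation of a neutral species adds one proton (an H atom minus an
#' electron), which is the convention that reproduces printed accurate
#' [M+H]+ values at 4 decimal places.
#'
#' @return A list with elements `proton`, `electron` and `atomic` (a named
#'   numeric vector of monoisotopic atomic masses in Da).
#' @examples
#' physical_constants()$proton
#' @export
physical_constants <- function() {
  electron <- 0.00054857990946
  list(
    proton = .element_masses[["H"]] - electron,
    electron = electron,
    atomic = .element_masses
  )
}

.proton_mass <- .element_masses[["H"]] - 0.00054857990946
.electron_mass <- 0.00054857990946

#' Create an element-count vector
#'
#' An element-count vector is a named integer vector keyed by element symbol.
#' Counts of a molecular species are all non-negative; a *delta* (the
#' difference of two species, e.g. a residue exchange) may carry negative
#' counts and is handled by the same arithmetic.
#'
#' @param ... Named integer counts, e.g. `element_counts(C = 11, H = 16)`.
#' @return A named integer vector of class `element_counts`.
#' @examples
#' element_counts(H = 2, O = 1)
#' @export
element_counts <- function(...) {
  x <- c(...)
  if (is.null(x)) x <- integer(0)
  new_element_counts(x)
}

new_element_counts <- function(x) {
  if (length(x) > 0) {
    bad <- setdiff(names(x), names(.element_masses))
    if (length(bad) > 0) {
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    storage.mode(x) <- "integer"
    x <- x[x != 0L]
    # canonical storage order: Hill (C, H, then alphabetical)
    x <- x[order(match(names(x), c("C", "H")), names(x), na.last = TRUE)]
  }
  structure(as.integer(x), names = names(x), class = "element_counts")
}

#' @export
`+.element_counts` <- function(e1, e2) {
  all_el <- union(names(e1), names(e2))
  v <- stats::setNames(integer(length(all_el)), all_el)
  v[names(e1)] <- v[names(e1)] + unclass(e1)
  v[names(e2)] <- v[names(e2)] + unclass(e2)
  new_element_counts(v)
}

#' @export
`-.element_counts` <- function(e1, e2) {
  if (missing(e2)) {
    return(new_element_counts(stats::setNames(-unclass(e1), names(e1))))
  }
  e1 + new_element_counts(stats::setNames(-unclass(e2), names(e2)))
}

#' @export
`==.element_counts` <- function(e1, e2) {
  d <- e1 - e2
  length(d) == 0L
}

#' @export
print.element_counts <- function(x, ...) {
  cat("<element_counts> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Parse a molecular formula string
#'
#' Parses a Hill-style concatenation of element symbols with optional positive
#' integer counts (e.g. `"C11H16N2O5"`) into an element-count vector.
#'
#' @param text A formula string.
#' @return An `element_counts` vector.
#' @examples
#' parse_formula("C11H16N2O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (text == "" || grepl("[-]", text)) {
    stop("cannot parse formula: ", dQuote(text), call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", text)[[1]]
  pieces <- regmatches(text, list(m))[[1]]
  if (paste(pieces, collapse = "") != text) {
    stop("cannot parse formula: ", dQuote(text), call. = FALSE)
  }
  syms <- sub("\\d+$", "", pieces)
  cnts <- as.integer(ifelse(grepl("\\d+$", pieces), sub("^[A-Za-z]+", "", pieces), "1"))
  if (any(cnts <= 0L)) {
    stop("zero or negative count in formula: ", dQuote(text), call. = FALSE)
  }
  bad <- setdiff(syms, names(.element_masses))
  if (length(bad) > 0) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- tapply(cnts, syms, sum)
  new_element_counts(stats::setNames(as.integer(v), names(v)))
}

#' Format an element-count vector as a canonical Hill string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; a count
#' of one is omitted. `parse_formula(format_formula(x))` round-trips.
#'
#' @param f An `element_counts` vector.
#' @return A single string.
#' @examples
#' format_formula(parse_formula("O5N2H16C11"))
#' @export
format_formula <- function(f) {
  if (length(f) == 0L) return("")
  n <- names(f)
  v <- unclass(f)
  paste0(n, ifelse(abs(v) == 1L, ifelse(v < 0L, "-", ""), v), collapse = "")
}

#' Monoisotopic mass of a composition
#'
#' @param f An `element_counts` vector (all counts must be non-negative), or a
#'   formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("H2O"))
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  if (any(unclass(f) < 0L)) {
    stop("negative element count: monoisotopic mass is defined for species, not deltas",
         call. = FALSE)
  }
  delta_mass(f)
}

# Signed mass of a composition delta; negative counts allowed.
delta_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  sum(.element_masses[names(f)] * unclass(f))
}

#' Singly protonated m/z of a neutral composition
#'
#' Adds the proton mass (H atom minus electron, 1.007276 Da); singly charged
#' positive species assumed throughout.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Da.
#' @examples
#' protonated_mz(parse_formula("C11H16N2O5"))
#' @export
protonated_mz <- function(f) {
  monoisotopic_mass(f) + .proton_mass
}

# m/z of a cation whose *ion* composition (charge carried, electron already
# counted out) is given: mass minus one electron.
cation_mz <- function(f) {
  monoisotopic_mass(f) - .electron_mass
}

#' Round half away from zero
#'
#' Printed m/z values in the literature use round-half-up; base `round()`
#' rounds half to even, which disagrees at exact .5 boundaries.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# residue composition = free amino acid minus H2O (the in-chain residue)
.residue_defs <- tibble::tribble(
  ~code,      ~one,  ~name,                         ~formula,    ~unnatural,
  "Gly",      "G",   "glycine",                     "C2H3NO",    FALSE,
  "Ala",      "A",   "alanine",                     "C3H5NO",    FALSE,
  "Ser",      "S",   "serine",                      "C3H5NO2",   FALSE,
  "Pro",      "P",   "proline",                     "C5H7NO",    FALSE,
  "Val",      "V",   "valine",                      "C5H9NO",    FALSE,
  "Thr",      "T",   "threonine",                   "C4H7NO2",   FALSE,
  "Cys",      "C",   "cysteine",                    "C3H5NOS",   FALSE,
  "Leu",      "L",   "leucine",                     "C6H11NO",   FALSE,
  "Ile",      "I",   "isoleucine",                  "C6H11NO",   FALSE,
  "Asn",      "N",   "asparagine",                  "C4H6N2O2",  FALSE,
  "Asp",      "D",   "aspartate",                   "C4H5NO3",   FALSE,
  "Gln",      "Q",   "glutamine",                   "C5H8N2O2",  FALSE,
  "Lys",      "K",   "lysine",                      "C6H12N2O",  FALSE,
  "Glu",      "E",   "glutamate",                   "C5H7NO3",   FALSE,
  "Met",      "M",   "methionine",                  "C5H9NOS",   FALSE,
  "His",      "H",   "histidine",                   "C6H7N3O",   FALSE,
  "Phe",      "F",   "phenylalanine",               "C9H9NO",    FALSE,
  "Arg",      "R",   "arginine",                    "C6H12N4O",  FALSE,
  "Tyr",      "Y",   "tyrosine",                    "C9H9NO2",   FALSE,
  "Trp",      "W",   "tryptophan",                  "C11H10N2O", FALSE,
  "Hyp",      NA,    "4-hydroxyproline",            "C5H7NO2",   TRUE,
  "MeEGlu",   NA,    "glutamate 5-methyl ester",    "C6H9NO3",   TRUE,
  "PyroGlu",  NA,    "pyroglutamate",               "C5H5NO2",   TRUE
)

#' The amino-acid residue library
#'
#' Returns the 20 canonical residues plus the three unnatural residues seen in
#' lactic-acid-bacteria cyclic dipeptides: 4-hydroxyproline (Hyp = Pro + O),
#' glutamate 5-methyl ester (MeEGlu = Glu + CH2) and pyroglutamate
#' (PyroGlu = Glu - H2O). Every residue carries its in-chain composition
#' (free amino acid minus water), monoisotopic residue mass, immonium ion m/z
#' and any residue-specific diagnostic-ion rules.
#'
#' @param config Optional overrides/extensions: a named list (or path to a
#'   YAML/JSON file) mapping residue code to a list with elements `formula`
#'   (required for new residues), and optionally `name`, `unnatural`, and
#'   `diagnostics` (a list of `list(label=, type="ion"|"loss", formula=)`).
#' @return A tibble with columns `code`, `one`, `name`, `formula`,
#'   `composition` (list of `element_counts`), `mass`, `unnatural`,
#'   `immonium_mz`, and `diagnostics` (list of tibbles `label`, `type`,
#'   `formula`).
#' @examples
#' lib <- residue_library()
#' lib[lib$code == "Pro", c("formula", "mass")]
#' @export
residue_library <- function(config = NULL) {
  lib <- .residue_defs
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      config <- if (grepl("\\.json$", config)) {
        jsonlite::read_json(config)
      } else {
        yaml::read_yaml(config)
      }
    }
    if (!is.list(config) || is.null(names(config)) || any(names(config) == "")) {
      stop("residue config must be a named list keyed by residue code", call. = FALSE)
    }
    for (code in names(config)) {
      entry <- config[[code]]
      if (!is.list(entry)) stop("malformed override for ", code, call. = FALSE)
      is_new <- !code %in% lib$code
      if (is_new && is.null(entry$formula)) {
        stop("new residue ", code, " needs a formula", call. = FALSE)
      }
      row <- tibble::tibble(
        code = code,
        one = NA_character_,
        name = entry$name %||% code,
        formula = entry$formula %||% lib$formula[lib$code == code],
        unnatural = isTRUE(entry$unnatural %||%
                             (if (is_new) TRUE else lib$unnatural[lib$code == code]))
      )
      lib <- dplyr::bind_rows(dplyr::filter(lib, .data$code != !!code), row)
    }
  }
  lib$composition <- purrr::map(lib$formula, parse_formula)
  lib$formula <- purrr::map_chr(lib$composition, format_formula)
  lib$mass <- purrr::map_dbl(lib$composition, monoisotopic_mass)
  if (any(lib$mass <= 0)) stop("residue with non-positive mass", call. = FALSE)
  lib$immonium_mz <- purrr::map_dbl(lib$composition, function(comp) {
    cation_mz(comp - parse_formula("CO") + element_counts(H = 1))
  })
  extra <- if (!is.null(config)) {
    purrr::imap_dfr(config, function(entry, code) {
      if (is.null(entry$diagnostics)) return(NULL)
      purrr::map_dfr(entry$diagnostics, function(d) {
        tibble::tibble(code = code, label = d$label, type = d$type, formula = d$formula)
      })
    })
  } else NULL
  rules <- dplyr::bind_rows(.fixed_diagnostic_rules(), extra)
  lib$diagnostics <- purrr::map(lib$code, function(code) {
    dplyr::select(dplyr::filter(rules, .data$code == !!code), -"code")
  })
  lib
}

# Residue-specific diagnostic rules beyond the always-present immonium ion.
# type "ion": a fixed-m/z cation with the given ion composition.
# type "loss": a neutral loss applied to the protonated precursor.
.fixed_diagnostic_rules <- function() {
  tibble::tribble(
    ~code,     ~label,          ~type,  ~formula,
    "Pro",     "Pro-98",        "ion",  "C5H8NO",   # residue + H companion ion
    "Ile",     "Ile-sc-86",     "ion",  "C5H12N",   # side-chain iminium (shared with Leu in practice)
    "Ile",     "Ile-sc-69",     "ion",  "C5H9",
    "Tyr",     "loss-C7H6O",    "loss", "C7H6O",    # quinone-methide side-chain loss
    "MeEGlu",  "loss-CH3OH",    "loss", "CH4O",     # methyl ester
    "MeEGlu",  "loss-CH3OH-CO", "loss", "C2H4O2"    # CH3OH + CO combined
  )
}

#' Look up a residue by code
#'
#' @param code Residue code (three-letter for canonicals, `Hyp`, `MeEGlu`,
#'   `PyroGlu` for unnaturals; one-letter codes also resolve).
#' @param library A residue library from [residue_library()].
#' @return A one-row tibble.
#' @export
residue <- function(code, library = residue_library()) {
  hit <- dplyr::filter(library, .data$code == !!code | (!is.na(.data$one) & .data$one == !!code))
  if (nrow(hit) == 0L) {
    stop("residue not found in library: ", dQuote(code), call. = FALSE)
  }
  hit[1, ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
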