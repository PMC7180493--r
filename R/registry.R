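#' Standard atomic weights used for molecular-weight arithmetic
#'
#' A fixed table of standard atomic weights (two to three decimals) covering
#' the elements present in the packaged compound registry. Fixing one table
#' keeps molecular-weight fixtures reproducible across environments.
#'
#' @return A tibble with columns `element` and `weight_g_mol`.
#' @export
#' @examples
#' atomic_weights()
atomic_weights <- function() {
  if (is.null(the$atomic_weights)) {
    the$atomic_weights <- readr::read_csv(
      data_file("atomic_weights.csv"),
      col_types = readr::cols(
        element = readr::col_character(),
        weight_g_mol = readr::col_double()
      )
    )
  }
  the$atomic_weights
}

#' Parse a molecular formula string
#'
#' Converts a plain Hill-style formula such as `"C5H14ClNO"` into a named
#' count vector. Only element symbols with optional integer counts are
#' supported; no brackets, charges or isotopes.
#'
#' @param formula A single formula string.
#' @return A named numeric vector of element counts.
#' @export
#' @examples
#' parse_formula("C5H14ClNO")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  matches <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(matches))[[1]]
  if (length(tokens) == 0L || sum(attr(matches, "match.length")) != nchar(formula)) {
    abort(sprintf("cannot parse formula '%s'", formula))
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.numeric(sub("^[A-Za-z]+", "", tokens))
  counts[is.na(counts)] <- 1
  out <- setNames(numeric(0), character(0))
  for (i in seq_along(elements)) {
    prev <- if (elements[i] %in% names(out)) out[[elements[i]]] else 0
    out[elements[i]] <- prev + counts[i]
  }
  out
}

as_element_counts <- function(formula) {
  if (is.character(formula)) {
    return(parse_formula(formula))
  }
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(formula)
  }
  abort("`formula` must be a formula string or a named numeric vector of element counts")
}

#' Molecular weight from an elemental composition
#'
#' @param formula A formula string (e.g. `"CH4N2O"`) or a named numeric
#'   vector of element counts (fractional counts are allowed, so
#'   mole-fraction-averaged mixture formulas work too).
#' @param weights Atomic-weight table, as returned by [atomic_weights()].
#' @return Molecular weight in g/mol.
#' @export
#' @examples
#' molecular_weight("H2O")
#' molecular_weight(c(C = 1, H = 4, N = 2, O = 1))
molecular_weight <- function(formula, weights = atomic_weights()) {
  counts <- as_element_counts(formula)
  if (any(counts < 0)) {
    abort("element counts must be non-negative")
  }
  unknown <- setdiff(names(counts), weights$element)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "unknown element symbol%s: %s",
      if (length(unknown) > 1L) "s" else "", paste(unknown, collapse = ", ")
    ))
  }
  w <- setNames(weights$weight_g_mol, weights$element)
  sum(counts * w[names(counts)])
}

load_compounds <- function() {
  if (is.null(the$compounds)) {
    raw <- jsonlite::fromJSON(data_file("compounds.json"), simplifyVector = FALSE)
    the$compounds <- tibble(
      compound = purrr::map_chr(raw, "name"),
      formula = purrr::map_chr(raw, "formula"),
      groups = map(raw, function(r) {
        g <- r$groups
        setNames(as.numeric(unlist(g, use.names = FALSE) %||% numeric(0)), names(g))
      }),
      direct = map(raw, function(r) r$properties)
    ) %>%
      mutate(mw_g_mol = map_dbl(.data$formula, molecular_weight))
  }
  the$compounds
}

#' Registry of pure components
#'
#' The packaged hydrogen-bond acceptors, donors and water, with molecular
#' formulas, molecular weights and stored group decompositions under the
#' modified Lydersen--Joback--Reid scheme. Decompositions are shipped as
#' data rather than derived from structure: no structure parser is provided
#' or intended.
#'
#' @return A tibble with columns `compound`, `formula`, `mw_g_mol`,
#'   `direct` (TRUE for compounds whose critical properties are supplied
#'   directly rather than estimated, i.e. water) and a `groups` list-column
#'   of named count vectors.
#' @seealso [compound_groups()] for the decompositions in long format.
#' @export
compound_registry <- function() {
  load_compounds() %>%
    mutate(direct = !purrr::map_lgl(.data$direct, is.null)) %>%
    select("compound", "formula", "mw_g_mol", "direct", "groups")
}

#' Group decompositions of the registry compounds, one row per group
#'
#' @return A tibble with columns `compound`, `group`, `count`.
#' @export
compound_groups <- function() {
  reg <- compound_registry()
  tidyr::unnest(
    mutate(reg, group = map(.data$groups, names),
           count = map(.data$groups, as.numeric)) %>%
      select("compound", "group", "count"),
    c("group", "count")
  )
}

load_des <- function() {
  if (is.null(the$des)) {
    the$des <- readr::read_csv(
      data_file("des_registry.csv"),
      col_types = readr::cols(
        des_id = readr::col_character(),
        dataset = readr::col_character(),
        component = readr::col_character(),
        role = readr::col_character(),
        ratio_part = readr::col_double(),
        n_data = readr::col_double()
      )
    )
  }
  the$des
}

#' Registry of deep eutectic solvents
#'
#' One summary row per packaged DES: identifier, training/test assignment,
#' hydrogen-bond acceptor and donor(s), molar ratio and the number of
#' experimental speed-of-sound observations reported for it in the
#' literature compilation the package mirrors.
#'
#' @return A tibble with columns `des_id`, `dataset`, `hba`, `hbd`,
#'   `ratio` and `n_data`.
#' @export
#' @examples
#' des_registry()
des_registry <- function() {
  load_des() %>%
    group_by(.data$des_id, .data$dataset, .data$n_data) %>%
    summarise(
      hba = .data$component[.data$role == "HBA"][1],
      hbd = paste(.data$component[.data$role != "HBA"], collapse = "/"),
      ratio = paste(.data$ratio_part, collapse = ":"),
      .groups = "drop"
    ) %>%
    arrange(des_number(.data$des_id)) %>%
    select("des_id", "dataset", "hba", "hbd", "ratio", "n_data")
}

des_number <- function(des_id) as.integer(sub("^DES", "", des_id))

#' Component records of one or more registry DESs
#'
#' @param des_id Character vector of DES identifiers (`"DES1"` ...
#'   `"DES39"`), or `NULL` for the whole registry.
#' @return A tibble with one row per component: `des_id`, `dataset`,
#'   `component`, `role`, `ratio_part`, `mole_fraction`, `n_data`.
#' @export
des_components <- function(des_id = NULL) {
  reg <- load_des()
  if (!is.null(des_id)) {
    bad <- setdiff(des_id, unique(reg$des_id))
    if (length(bad) > 0L) {
      abort(sprintf(
        "unknown DES id%s %s; valid ids are DES1..DES%d",
        if (length(bad) > 1L) "s" else "",
        paste(bad, collapse = ", "),
        max(des_number(reg$des_id))
      ))
    }
    reg <- filter(reg, .data$des_id %in% !!des_id)
  }
  reg %>%
    group_by(.data$des_id) %>%
    mutate(mole_fraction = .data$ratio_part / sum(.data$ratio_part)) %>%
    ungroup() %>%
    arrange(des_number(.data$des_id))
}

#' Look up a single DES definition
#'
#' @param des_id A single DES identifier, e.g. `"DES21"`.
#' @return The component rows of that DES (see [des_components()]).
#' @export
#' @examples
#' lookup_des("DES21")
lookup_des <- function(des_id) {
  stopifnot(is.character(des_id), length(des_id) == 1L)
  des_components(des_id)
}

#' Mole fractions from molar-ratio parts
#'
#' Converts the integer ratio parts of a DES definition (e.g. 1:2) into
#' mole fractions.
#'
#' @param x A numeric vector of ratio parts, or a components tibble with a
#'   `ratio_part` column (as returned by [lookup_des()]).
#' @return Numeric vector of mole fractions summing to 1.
#' @export
#' @examples
#' mole_fractions(c(1, 2))
#' mole_fractions(lookup_des("DES20"))
mole_fractions <- function(x) {
  if (is.data.frame(x)) {
    if (!"ratio_part" %in% names(x)) {
      abort("components table must have a `ratio_part` column")
    }
    x <- x$ratio_part
  }
  if (length(x) == 0L) {
    abort("at least one ratio part is required")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("ratio parts must be positive and finite")
  }
  x / sum(x)
}

#' Read and write compound records
#'
#' Compound records are interchanged as JSON mirroring the packaged
#' registry format: an array of objects with `name`, `formula`, a `groups`
#' map and optionally a `properties` map for compounds whose critical
#' properties are supplied directly.
#'
#' @param path File path.
#' @return `read_compounds()` returns a registry-shaped tibble (see
#'   [compound_registry()]); `write_compounds()` returns `path` invisibly.
#' @export
read_compounds <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tibble(
    compound = purrr::map_chr(raw, "name"),
    formula = purrr::map_chr(raw, "formula"),
    mw_g_mol = purrr::map_dbl(raw, function(r) molecular_weight(r$formula)),
    direct = purrr::map_lgl(raw, function(r) !is.null(r$properties)),
    groups = map(raw, function(r) {
      g <- r$groups
      setNames(as.numeric(unlist(g, use.names = FALSE) %||% numeric(0)), names(g))
    })
  )
}

#' @param x A compound tibble as returned by [compound_registry()] or
#'   [read_compounds()].
#' @rdname read_compounds
#' @export
write_compounds <- function(x, path) {
  recs <- pmap(
    list(x$compound, x$formula, x$groups),
    function(name, formula, groups) {
      list(name = name, formula = formula, groups = as.list(groups))
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read and write DES definitions as CSV
#'
#' The CSV schema is the packaged registry layout: one row per component
#' with columns `des_id`, `dataset`, `component`, `role`, `ratio_part`
#' (and optionally `n_data`).
#'
#' @param path File path.
#' @export
read_des_definitions <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols())
  need <- c("des_id", "component", "ratio_part")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    abort(sprintf("DES definition CSV lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"dataset" %in% names(x)) x$dataset <- "unassigned"
  as_tibble(x)
}

#' @rdname read_des_definitions
#' @param x A DES components tibble.
#' @export
write_des_definitions <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
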