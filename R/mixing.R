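#' Lee--Kesler pseudo-critical properties of a mixture
#'
#' Combines pure-component critical properties into the pseudo-component
#' properties of a mixture with the Lee--Kesler combining rules:
#' \itemize{
#'   \item `Vc,m = sum_ij x_i x_j Vc_ij`, with
#'     `Vc_ij = ((Vc_i^(1/3) + Vc_j^(1/3)) / 2)^3`
#'   \item `Tc,m = Vc,m^(-1/4) * sum_ij x_i x_j Vc_ij^(1/4) sqrt(Tc_i Tc_j)`
#'   \item `omega_m = sum_i x_i omega_i`
#'   \item `Pc,m = (0.2905 - 0.085 omega_m) R Tc,m / Vc,m`, R = 83.14
#'     cm3 bar / (mol K), so `Pc,m` is in bar
#'   \item `Mw,m = sum_i x_i Mw_i`
#' }
#'
#' @param props A tibble of pure-component properties with columns `tc_k`,
#'   `vc_cm3_mol`, `omega`, `mw_g_mol` (one row per component), e.g. from
#'   [compound_properties()].
#' @param x Mole fractions, same length as `nrow(props)`, summing to 1.
#' @return A one-row tibble with `tc_k`, `pc_bar`, `vc_cm3_mol`, `omega`,
#'   `mw_g_mol`.
#' @export
#' @examples
#' mix_properties(compound_properties(c("choline chloride", "urea")),
#'                mole_fractions(c(1, 2)))
mix_properties <- function(props, x) {
  need <- c("tc_k", "vc_cm3_mol", "omega", "mw_g_mol")
  missing <- setdiff(need, names(props))
  if (length(missing) > 0L) {
    abort(sprintf("`props` lacks columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(props) < 1L) abort("`props` must have at least one component")
  if (length(x) != nrow(props)) {
    abort("`x` must have one mole fraction per component")
  }
  if (abs(sum(x) - 1) > 1e-8) abort("mole fractions must sum to 1")
  if (any(x < 0)) abort("mole fractions must be non-negative")
  if (any(props$tc_k <= 0) || any(props$vc_cm3_mol <= 0)) {
    abort("pure-component Tc and Vc must be positive")
  }
  v13 <- props$vc_cm3_mol^(1 / 3)
  vij <- ((outer(v13, v13, `+`)) / 2)^3
  tij <- sqrt(outer(props$tc_k, props$tc_k))
  xx <- outer(x, x)
  vcm <- sum(xx * vij)
  tcm <- sum(xx * vij^0.25 * tij) / vcm^0.25
  omm <- sum(x * props$omega)
  r <- mljr_constants()$r_cm3_bar_mol_k
  pcm <- (0.2905 - 0.085 * omm) * r * tcm / vcm
  tibble(tc_k = tcm, pc_bar = pcm, vc_cm3_mol = vcm, omega = omm,
         mw_g_mol = sum(x * props$mw_g_mol))
}

#' Pseudo-critical properties of an arbitrary component mixture
#'
#' Full chain for a user-defined mixture: stored (or supplied) group
#' decompositions to pure-component properties, then Lee--Kesler mixing.
#'
#' @param components A tibble with columns `component` and `ratio_part`
#'   naming registry compounds.
#' @return One-row property tibble as from [mix_properties()].
#' @export
mixture_properties <- function(components) {
  if (nrow(components) < 1L) abort("at least one component is required")
  props <- compound_properties(components$component)
  mix_properties(props, mole_fractions(components$ratio_part))
}

#' Pseudo-critical properties of registry DESs
#'
#' Runs the whole estimation chain (decomposition, group-contribution
#' estimates, Lee--Kesler mixing) for the requested DESs.
#'
#' @param des_id Character vector of DES ids, or `NULL` for all 39.
#' @return A tibble with `des_id`, `dataset`, `tc_k`, `pc_bar`,
#'   `vc_cm3_mol`, `omega`, `mw_g_mol`.
#' @export
#' @examples
#' des_properties("DES21")
des_properties <- function(des_id = NULL) {
  comps <- des_components(des_id)
  comps %>%
    group_by(.data$des_id, .data$dataset) %>%
    dplyr::group_modify(function(d, key) {
      mixture_properties(d)
    }) %>%
    ungroup() %>%
    arrange(des_number(.data$des_id))
}

#' Reference pseudo-critical property table
#'
#' The packaged reference values of Tc, Pc, Vc, the acentric factor and the
#' molecular weight of all 39 registry DESs, used to validate the
#' estimation chain (see [validate_fixtures()]).
#'
#' @return A tibble with `des_id`, `tc_k`, `pc_bar`, `vc_cm3_mol`, `omega`,
#'   `mw_g_mol`.
#' @export
reference_properties <- function() {
  if (is.null(the$reference)) {
    the$reference <- readr::read_csv(
      data_file("reference_properties.csv"),
      col_types = readr::cols(des_id = readr::col_character(),
                              .default = readr::col_double())
    )
  }
  the$reference
}

#' Recompute the reference property table and report deviations
#'
#' Recomputes Tc, Pc, Vc, omega and Mw for every registry DES through the
#' full chain and compares each cell against [reference_properties()].
#'
#' @param rel_tol Relative tolerance for Tc, Pc, Vc and omega (default 1%).
#' @param mw_tol Absolute tolerance for Mw in g/mol (default 0.02).
#' @return A tibble with one row per cell: `des_id`, `quantity`,
#'   `computed`, `reference`, `deviation` (relative for the critical
#'   properties, absolute for Mw) and `within`. The attribute `"ok"` is
#'   TRUE when every cell is within tolerance.
#' @export
validate_fixtures <- function(rel_tol = 0.01, mw_tol = 0.02) {
  computed <- des_properties()
  ref <- reference_properties()
  long <- function(d, label) {
    tidyr::pivot_longer(
      select(d, "des_id", "tc_k", "pc_bar", "vc_cm3_mol", "omega", "mw_g_mol"),
      -"des_id", names_to = "quantity", values_to = label
    )
  }
  out <- left_join(long(computed, "computed"), long(ref, "reference"),
                   by = c("des_id", "quantity")) %>%
    mutate(
      deviation = ifelse(
        .data$quantity == "mw_g_mol",
        .data$computed - .data$reference,
        (.data$computed - .data$reference) / .data$reference
      ),
      within = ifelse(.data$quantity == "mw_g_mol",
                      abs(.data$deviation) <= mw_tol,
                      abs(.data$deviation) <= rel_tol)
    )
  attr(out, "ok") <- all(out$within)
  class(out) <- c("des_validation", class(out))
  out
}

#' @export
print.des_validation <- function(x, ...) {
  ok <- attr(x, "ok")
  worst <- x[which.max(abs(x$deviation) /
                         ifelse(x$quantity == "mw_g_mol", 0.02, 0.01)), ]
  cat(sprintf(
    "Fixture validation: %d cells, %d within tolerance (%s)\n",
    nrow(x), sum(x$within), if (ok) "OK" else "FAILED"
  ))
  cat(sprintf(
    "Largest deviation: %s %s (computed %.4g, reference %.4g)\n",
    worst$des_id, worst$quantity, worst$computed, worst$reference
  ))
  invisible(x)
}
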