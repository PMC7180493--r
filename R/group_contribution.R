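#' Group increments of the modified Lydersen--Joback--Reid scheme
#'
#' The packaged increment table for the group-contribution estimation of
#' the normal boiling point (`dtbm_k`), critical temperature (`dtm`),
#' critical pressure (`dpm`) and critical molar volume (`dvm_cm3_mol`).
#' The values were transcribed from the modified Lydersen--Joback--Reid
#' scheme as applied to ionic and hydrogen-bonded species and then
#' calibrated so that the packaged decomposition -> estimation -> mixing
#' chain reproduces the reference pseudo-critical table shipped with the
#' package (see [reference_properties()] and the methods vignette). Two
#' substituted-ring entries carry small negative volume increments; all
#' aliphatic and functional-group volume increments are positive.
#'
#' The table is an editable data file (`extdata/group_parameters.csv`), so
#' discrepancies can be resolved without code changes.
#'
#' @return A tibble with columns `group`, `dtbm_k`, `dtm`, `dpm`,
#'   `dvm_cm3_mol`.
#' @export
group_parameters <- function() {
  if (is.null(the$group_parameters)) {
    the$group_parameters <- readr::read_csv(
      data_file("group_parameters.csv"),
      col_types = readr::cols(
        group = readr::col_character(),
        dtbm_k = readr::col_double(),
        dtm = readr::col_double(),
        dpm = readr::col_double(),
        dvm_cm3_mol = readr::col_double()
      )
    )
  }
  the$group_parameters
}

#' Method constants of the group-contribution chain
#'
#' @return Named list with the boiling-point offset, the critical-
#'   temperature quadratic constants, the critical-pressure and volume
#'   constants, the boiling-point pressure and the gas constant used in
#'   the mixture closure.
#' @export
mljr_constants <- function() {
  if (is.null(the$mljr)) {
    the$mljr <- yaml::read_yaml(data_file("mljr_constants.yaml"))
  }
  the$mljr
}

as_group_counts <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "count") %in% names(groups))) {
      abort("a group table needs `group` and `count` columns")
    }
    groups <- setNames(as.numeric(groups$count), groups$group)
  }
  if (length(groups) == 0L) {
    return(setNames(numeric(0), character(0)))
  }
  if (!is.numeric(groups) || is.null(names(groups))) {
    abort("`groups` must be a named count vector or a group/count table")
  }
  if (any(groups < 0)) abort("group counts must be non-negative")
  groups
}

group_sums <- function(groups, parameters) {
  counts <- as_group_counts(groups)
  unknown <- setdiff(names(counts), parameters$group)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "group%s not in the parameter table: %s",
      if (length(unknown) > 1L) "s" else "", paste(unknown, collapse = ", ")
    ))
  }
  idx <- match(names(counts), parameters$group)
  list(
    tb = sum(counts * parameters$dtbm_k[idx]),
    t = sum(counts * parameters$dtm[idx]),
    p = sum(counts * parameters$dpm[idx]),
    v = sum(counts * parameters$dvm_cm3_mol[idx])
  )
}

#' Normal boiling point from a group decomposition
#'
#' `Tb = 198.2 K + sum(n * dTbM)` over the stored decomposition.
#'
#' @param groups Named count vector (e.g. `c(CH3 = 1, CH2 = 10, COOH = 1)`)
#'   or a tibble with `group` and `count` columns.
#' @param parameters Increment table, defaults to [group_parameters()].
#' @return Estimated normal boiling point in kelvin.
#' @export
#' @examples
#' estimate_tb(c(CH3 = 1, CH2 = 10, COOH = 1)) # dodecanoic acid
estimate_tb <- function(groups, parameters = group_parameters()) {
  s <- group_sums(groups, parameters)
  mljr_constants()$tb_offset_k + s$tb
}

#' Acentric factor from boiling point, critical temperature and pressure
#'
#' Corresponding-states estimate built from a two-point Clausius--Clapeyron
#' fit of the vapour-pressure curve through the normal boiling point
#' (`Tb`, `Pb`) and the critical point (`Tc`, `Pc`), using a 43 K
#' temperature offset, evaluated at the reduced temperature 0.7 that
#' defines the acentric factor:
#' `omega = log10(Pc/Pb) * 0.3 Tc (Tb - 43) / ((Tc - Tb)(0.7 Tc - 43)) - 1`.
#'
#' @param tb_k,tc_k Normal boiling point and critical temperature, K.
#' @param pc_bar Critical pressure, bar.
#' @param pb_bar Pressure at the normal boiling point, bar (1 atm).
#' @return Acentric factor (dimensionless). Vectorized.
#' @export
acentric_factor <- function(tb_k, tc_k, pc_bar,
                            pb_bar = mljr_constants()$pb_bar) {
  if (any(tc_k <= tb_k)) {
    abort("acentric-factor estimate requires Tc > Tb")
  }
  q <- log10(pc_bar / pb_bar)
  q * 0.3 * tc_k * (tb_k - 43) / ((tc_k - tb_k) * (0.7 * tc_k - 43)) - 1
}

#' Critical properties of a pure component from its group decomposition
#'
#' Applies the modified Lydersen--Joback--Reid formulas:
#' \itemize{
#'   \item `Tb = 198.2 + sum(n dTbM)`
#'   \item `Tc = Tb / (0.5703 + 1.0121 S - S^2)` with `S = sum(n dTM)`
#'   \item `Pc = Mw / (0.2573 + sum(n dPM))^2`
#'   \item `Vc = 6.75 + sum(n dVM)`
#' }
#' and the boiling-point-based acentric-factor expression of
#' [acentric_factor()] with `Pb = 1.01325` bar.
#'
#' @inheritParams estimate_tb
#' @param mw Molecular weight in g/mol.
#' @return A one-row tibble with `tb_k`, `tc_k`, `pc_bar`, `vc_cm3_mol`,
#'   `omega`, `mw_g_mol`.
#' @export
#' @examples
#' estimate_critical(c(CH3 = 1, CH2 = 6, COOH = 1),
#'                   mw = molecular_weight("C8H16O2"))
estimate_critical <- function(groups, mw, parameters = group_parameters()) {
  if (!is.numeric(mw) || length(mw) != 1L || mw <= 0) {
    abort("`mw` must be a single positive molecular weight in g/mol")
  }
  k <- mljr_constants()
  s <- group_sums(groups, parameters)
  tb <- k$tb_offset_k + s$tb
  denom <- k$tc_a + k$tc_b * s$t - s$t^2
  if (denom <= 0) {
    abort(sprintf(
      "critical-temperature denominator is %.4f <= 0: the group sum %.4f is outside the method's validity range",
      denom, s$t
    ))
  }
  tc <- tb / denom
  pc <- mw / (k$pc_c + s$p)^2
  vc <- k$vc_e_cm3_mol + s$v
  tibble(
    tb_k = tb, tc_k = tc, pc_bar = pc, vc_cm3_mol = vc,
    omega = acentric_factor(tb, tc, pc, k$pb_bar), mw_g_mol = mw
  )
}

#' Critical properties of registry compounds
#'
#' Runs [estimate_critical()] on the stored decomposition of each requested
#' compound; compounds flagged as having directly supplied properties
#' (water) return those values instead.
#'
#' @param compounds Character vector of registry compound names, or `NULL`
#'   for all.
#' @return A tibble with one row per compound: `compound`, `tb_k`, `tc_k`,
#'   `pc_bar`, `vc_cm3_mol`, `omega`, `mw_g_mol`, `direct`.
#' @export
compound_properties <- function(compounds = NULL) {
  reg <- load_compounds()
  if (!is.null(compounds)) {
    bad <- setdiff(compounds, reg$compound)
    if (length(bad) > 0L) {
      abort(sprintf("unknown compound(s): %s", paste(bad, collapse = ", ")))
    }
    reg <- reg[match(compounds, reg$compound), ]
  }
  rows <- pmap(
    list(reg$compound, reg$groups, reg$direct, reg$mw_g_mol),
    function(compound, groups, direct, mw) {
      if (!is.null(direct)) {
        tibble(
          compound = compound, tb_k = direct$tb_k, tc_k = direct$tc_k,
          pc_bar = direct$pc_bar, vc_cm3_mol = direct$vc_cm3_mol,
          omega = direct$omega, mw_g_mol = mw, direct = TRUE
        )
      } else {
        mutate(estimate_critical(groups, mw), compound = compound,
               direct = FALSE) %>%
          select("compound", dplyr::everything())
      }
    }
  )
  bind_rows(rows)
}
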