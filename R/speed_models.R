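#' Coefficients of the proposed speed-of-sound correlation
#'
#' The correlation is
#' `u = omega * (c1 * Mw + c2 * T) + c3 * Vc + c4`
#' with `u` in m/s, `Mw` in g/mol, `T` in K and `Vc` in cm3/mol. The
#' defaults are the published coefficient values; [refit()] produces
#' alternatives from data.
#'
#' @param omega_mw Coefficient on the `omega * Mw` cross term (c1).
#' @param omega_t Coefficient on the `omega * T` cross term (c2).
#' @param vc Coefficient on the critical molar volume (c3).
#' @param intercept Intercept in m/s (c4).
#' @return Named numeric vector of length 4.
#' @export
proposed_coefficients <- function(omega_mw = 7.378, omega_t = -2.012,
                                  vc = -2.911, intercept = 2514.2) {
  c(omega_mw = omega_mw, omega_t = omega_t, vc = vc, intercept = intercept)
}

as_coefficients <- function(coefficients) {
  if (inherits(coefficients, "des_refit")) {
    coefficients <- coefficients$coefficients
  }
  if (!is.numeric(coefficients) || length(coefficients) != 4L) {
    abort("`coefficients` must be 4 numbers: omega_mw, omega_t, vc, intercept")
  }
  if (any(!is.finite(coefficients))) abort("coefficients must be finite")
  if (is.null(names(coefficients))) {
    names(coefficients) <- c("omega_mw", "omega_t", "vc", "intercept")
  }
  coefficients[c("omega_mw", "omega_t", "vc", "intercept")]
}

#' Speed of sound from the proposed corresponding-states correlation
#'
#' @param omega Acentric factor of the (pseudo-)component.
#' @param mw_g_mol Molecular weight, g/mol.
#' @param vc_cm3_mol Critical molar volume, cm3/mol.
#' @param t_k Temperature, K.
#' @param coefficients Correlation coefficients, see
#'   [proposed_coefficients()].
#' @return Speed of sound in m/s. Vectorized over all inputs.
#' @export
#' @examples
#' speed_proposed(0.6509, 86.58, 254.37, 298.15)
speed_proposed <- function(omega, mw_g_mol, vc_cm3_mol, t_k,
                           coefficients = proposed_coefficients()) {
  if (any(t_k <= 0)) abort("temperature must be positive (kelvin)")
  k <- as_coefficients(coefficients)
  omega * (k[["omega_mw"]] * mw_g_mol + k[["omega_t"]] * t_k) +
    k[["vc"]] * vc_cm3_mol + k[["intercept"]]
}

#' Curl--Pitzer corresponding-states surface tension
#'
#' `sigma = Pc^(2/3) Tc^(1/3) ((1.86 + 1.18 omega)/19.05) *
#'  ((3.75 + 0.91 omega)/(0.291 - 0.08 omega))^(2/3) * (1 - Tr)^(11/9)`
#'
#' With `Pc` in bar and `Tc` in K the result is in mN/m.
#'
#' @param tc_k Critical temperature, K.
#' @param pc_bar Critical pressure, bar.
#' @param omega Acentric factor; must be below 0.291/0.08.
#' @param t_k Temperature, K; must satisfy `0 < t_k < tc_k`.
#' @return Surface tension in mN/m. Vectorized over `t_k`.
#' @export
surface_tension <- function(tc_k, pc_bar, omega, t_k) {
  if (any(omega >= 0.291 / 0.08)) {
    abort("acentric factor is outside the Curl-Pitzer validity range (omega < 0.291/0.08)")
  }
  if (any(t_k <= 0)) abort("temperature must be positive (kelvin)")
  if (any(t_k >= tc_k)) {
    abort("surface tension is undefined at or above the critical temperature")
  }
  tr <- t_k / tc_k
  pc_bar^(2 / 3) * tc_k^(1 / 3) * ((1.86 + 1.18 * omega) / 19.05) *
    ((3.75 + 0.91 * omega) / (0.291 - 0.08 * omega))^(2 / 3) *
    (1 - tr)^(11 / 9)
}

check_constants <- function(values, names_needed, model, source) {
  missing <- names_needed[vapply(
    names_needed, function(nm) is.null(values[[nm]]) || !is.finite(values[[nm]]),
    logical(1)
  )]
  if (length(missing) > 0L) {
    abort(sprintf(
      "constants %s for the %s model are not set; transcribe them from %s into the constants config (see literature_constants())",
      paste(missing, collapse = ", "), model, source
    ))
  }
  invisible(values)
}

#' Load the literature-model constants configuration
#'
#' The four ionic-liquid models need fitted constants that belong to their
#' original publications; the package ships the config empty, with unit
#' declarations, and validates completeness when a model is run.
#'
#' @param path Path to a YAML config; default is the packaged (empty)
#'   template.
#' @return Nested list with entries `gardas`, `hekayati`, `singh`,
#'   `haghbakhsh`.
#' @export
literature_constants <- function(path = NULL) {
  yaml::read_yaml(path %||% data_file("literature_constants.yaml"))
}

#' Gardas--Coutinho speed-of-sound model
#'
#' `log10(u) = alpha * log10(sigma * rho) + beta`.
#'
#' @param sigma Surface tension (units per the constants' source).
#' @param rho Density (units per the constants' source).
#' @param constants List with `alpha` and `beta`.
#' @return Speed of sound, m/s.
#' @export
speed_gardas <- function(sigma, rho, constants) {
  check_constants(constants, c("alpha", "beta"), "Gardas-Coutinho",
                  "Gardas & Coutinho's ionic-liquid correlation paper")
  if (any(sigma * rho <= 0)) abort("sigma * rho must be positive")
  10^(constants$alpha * log10(sigma * rho) + constants$beta)
}

#' Singh--Singh speed-of-sound model
#'
#' `log10(u) = psi * log10(sigma * rho) + xi`.
#'
#' @inheritParams speed_gardas
#' @param constants List with `psi` and `xi`.
#' @export
speed_singh <- function(sigma, rho, constants) {
  check_constants(constants, c("psi", "xi"), "Singh-Singh",
                  "Singh & Singh's ionic-liquid correlation paper")
  if (any(sigma * rho <= 0)) abort("sigma * rho must be positive")
  10^(constants$psi * log10(sigma * rho) + constants$xi)
}

#' Hekayati--Esmaeilzadeh speed-of-sound model
#'
#' `ln(u) = (a + b Mw) ln(sigma rho) + c Mw + d Mw^2 - e T + f`. The
#' `mw_term` entry of the constants switches the leading term between the
#' product reading `a + b * Mw` (default) and the quotient reading
#' `a + b / Mw`.
#'
#' @inheritParams speed_gardas
#' @param mw_g_mol Molecular weight, g/mol.
#' @param t_k Temperature, K.
#' @param constants List with `a` ... `f` and optionally `mw_term`.
#' @export
speed_hekayati <- function(sigma, rho, mw_g_mol, t_k, constants) {
  check_constants(constants, c("a", "b", "c", "d", "e", "f"),
                  "Hekayati-Esmaeilzadeh",
                  "Hekayati & Esmaeilzadeh's ionic-liquid correlation paper")
  if (any(sigma * rho <= 0)) abort("sigma * rho must be positive")
  lead <- switch(constants$mw_term %||% "product",
    product = constants$a + constants$b * mw_g_mol,
    inverse = constants$a + constants$b / mw_g_mol,
    abort("`mw_term` must be 'product' or 'inverse'")
  )
  exp(lead * log(sigma * rho) + constants$c * mw_g_mol +
        constants$d * mw_g_mol^2 - constants$e * t_k + constants$f)
}

#' Haghbakhsh et al. atomic-contribution speed-of-sound model
#'
#' `u = A * Mw + B * T`, with `A = sum(n_i dA_i)` and `B = sum(n_i dB_i)`
#' accumulated over atom counts `n_i` per element. For a mixture, pass the
#' mole-fraction-weighted atom counts (see [mixture_formula()]). The
#' `mw_term` entry switches between `A * Mw` (default) and `A / Mw`.
#'
#' @param formula Named numeric vector of atom counts per element
#'   (fractional counts allowed), or a formula string.
#' @param t_k Temperature, K.
#' @param constants List with increment maps `dA` and `dB` keyed by
#'   element, and optionally `mw_term`.
#' @param mw_g_mol Molecular weight, g/mol; computed from `formula` by
#'   default.
#' @export
speed_haghbakhsh <- function(formula, t_k, constants,
                             mw_g_mol = molecular_weight(formula)) {
  counts <- as_element_counts(formula)
  for (map_name in c("dA", "dB")) {
    inc <- constants[[map_name]]
    if (is.null(inc)) {
      abort(sprintf(
        "increment map %s for the atomic-contribution model is not set; transcribe it from Haghbakhsh et al.'s ionic-liquid paper",
        map_name
      ))
    }
    missing <- setdiff(names(counts), names(inc))
    if (length(missing) > 0L) {
      abort(sprintf(
        "element%s %s missing from the %s increment map",
        if (length(missing) > 1L) "s" else "",
        paste(missing, collapse = ", "), map_name
      ))
    }
  }
  a <- sum(counts * unlist(constants$dA)[names(counts)])
  b <- sum(counts * unlist(constants$dB)[names(counts)])
  amw <- switch(constants$mw_term %||% "product",
    product = a * mw_g_mol,
    inverse = a / mw_g_mol,
    abort("`mw_term` must be 'product' or 'inverse'")
  )
  amw + b * t_k
}

#' Mole-fraction-averaged elemental formula of a registry DES
#'
#' @param des_id A single DES id.
#' @return Named numeric vector of (fractional) atom counts per mole of
#'   pseudo-component.
#' @export
mixture_formula <- function(des_id) {
  comps <- lookup_des(des_id)
  reg <- load_compounds()
  x <- comps$mole_fraction
  counts <- map(comps$component,
                function(nm) parse_formula(reg$formula[reg$compound == nm]))
  elements <- unique(unlist(map(counts, names)))
  out <- setNames(numeric(length(elements)), elements)
  for (i in seq_along(counts)) {
    out[names(counts[[i]])] <- out[names(counts[[i]])] + x[i] * counts[[i]]
  }
  out
}

#' A constant-density provider
#'
#' Convenience constructor for the pluggable density argument of
#' [predict_speed()]: density models for DESs live in their own
#' publications, so the package ships no coefficients and accepts any
#' function of temperature instead.
#'
#' @param value Density value (units per the constants' source, typically
#'   g/cm3).
#' @return A function of temperature returning `value`.
#' @export
density_constant <- function(value) {
  force(value)
  function(t_k) rep(value, length(t_k))
}

#' Predict the speed of sound of registry DESs
#'
#' High-level prediction across DESs, temperatures and models. The proposed
#' correlation and the atomic-contribution model need only the packaged
#' registry; the three surface-tension/density models additionally need a
#' density provider and their literature constants.
#'
#' @param des_id Character vector of DES ids.
#' @param t_k Numeric vector of temperatures in K (predictions are made on
#'   the crossing of `des_id` and `t_k`).
#' @param models Character subset of `"proposed"`, `"gardas"`,
#'   `"hekayati"`, `"singh"`, `"haghbakhsh"`.
#' @param coefficients Coefficients for the proposed model.
#' @param constants Literature-model constants, see
#'   [literature_constants()].
#' @param density A function of temperature (K) returning density, or a
#'   single number; required for the Gardas--Coutinho, Hekayati--
#'   Esmaeilzadeh and Singh--Singh models.
#' @param properties Optional precomputed property table from
#'   [des_properties()] (avoids recomputation in loops).
#' @return A tibble with `des_id`, `model`, `t_k`, `u_ms`.
#' @export
#' @examples
#' predict_speed("DES21", t_k = 298.15)
predict_speed <- function(des_id, t_k,
                          models = "proposed",
                          coefficients = proposed_coefficients(),
                          constants = literature_constants(),
                          density = NULL,
                          properties = NULL) {
  models <- match.arg(models, c("proposed", "gardas", "hekayati", "singh",
                                "haghbakhsh"), several.ok = TRUE)
  props <- properties %||% des_properties(des_id)
  props <- filter(props, .data$des_id %in% !!des_id)
  if (is.numeric(density)) density <- density_constant(density)
  needs_rho <- intersect(models, c("gardas", "hekayati", "singh"))
  if (length(needs_rho) > 0L && is.null(density)) {
    abort(sprintf(
      "model%s %s need%s a density provider: pass `density =` a number or a function of temperature",
      if (length(needs_rho) > 1L) "s" else "",
      paste(needs_rho, collapse = ", "),
      if (length(needs_rho) > 1L) "" else "s"
    ))
  }
  grid <- tidyr::expand_grid(des_id = unique(props$des_id), t_k = t_k) %>%
    left_join(props, by = "des_id")
  out <- map(models, function(m) {
    u <- switch(m,
      proposed = speed_proposed(grid$omega, grid$mw_g_mol, grid$vc_cm3_mol,
                                grid$t_k, coefficients),
      gardas = speed_gardas(
        surface_tension(grid$tc_k, grid$pc_bar, grid$omega, grid$t_k),
        density(grid$t_k), constants$gardas
      ),
      singh = speed_singh(
        surface_tension(grid$tc_k, grid$pc_bar, grid$omega, grid$t_k),
        density(grid$t_k), constants$singh
      ),
      hekayati = speed_hekayati(
        surface_tension(grid$tc_k, grid$pc_bar, grid$omega, grid$t_k),
        density(grid$t_k), grid$mw_g_mol, grid$t_k, constants$hekayati
      ),
      haghbakhsh = {
        forms <- map(unique(grid$des_id), mixture_formula)
        names(forms) <- unique(grid$des_id)
        map_dbl(seq_len(nrow(grid)), function(i) {
          speed_haghbakhsh(forms[[grid$des_id[i]]], grid$t_k[i],
                           constants$haghbakhsh,
                           mw_g_mol = grid$mw_g_mol[i])
        })
      }
    )
    tibble(des_id = grid$des_id, model = m, t_k = grid$t_k, u_ms = u)
  })
  bind_rows(out) %>% arrange(des_number(.data$des_id), .data$model, .data$t_k)
}
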