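#' Generate a synthetic speed-of-sound dataset
#'
#' Builds a dataset with the structure the correlation assumes:
#' `u_exp = u_model * (1 + eps)`, `eps ~ Normal(0, noise)`, on a crossing
#' of DESs and temperatures. Useful for self-tests (noise-free data must
#' be refit exactly) and for exercising the evaluation harness at
#' realistic sizes.
#'
#' @param des_id DES ids, or `NULL` for the whole registry.
#' @param t_k Temperature grid in K; the default spans 293.15--333.15 K in
#'   5 K steps, the range typical of reported DES speed-of-sound
#'   measurements.
#' @param coefficients Generating coefficients (defaults to the published
#'   values).
#' @param noise Relative standard deviation of the multiplicative noise
#'   (0 = exact model data).
#' @param seed Integer seed; required when `noise > 0`.
#' @param registry_sizes If TRUE, ignore `t_k` and emulate the literature
#'   compilation instead: each DES contributes as many records as its
#'   registry `n_data`, on an evenly spaced temperature grid across the
#'   default range.
#' @param source Value for the `source` column.
#' @return A tibble with `des_id`, `dataset` (split tag from the
#'   registry), `T_K`, `u_exp_ms`, `source`.
#' @export
#' @examples
#' generate_synthetic("DES21", t_k = c(298.15, 308.15))
generate_synthetic <- function(des_id = NULL,
                               t_k = seq(293.15, 333.15, by = 5),
                               coefficients = proposed_coefficients(),
                               noise = 0, seed = NULL,
                               registry_sizes = FALSE,
                               source = "synthetic") {
  if (noise < 0) abort("`noise` must be >= 0")
  if (noise > 0 && is.null(seed)) {
    abort("`seed` is required when `noise` > 0")
  }
  props <- des_properties(des_id)
  grid <- if (registry_sizes) {
    reg <- des_registry()
    reg <- filter(reg, .data$des_id %in% props$des_id)
    tidyr::unnest(
      mutate(reg, T_K = map(.data$n_data, function(n) {
        seq(293.15, 333.15, length.out = n)
      })),
      "T_K"
    ) %>%
      select("des_id", "T_K")
  } else {
    tidyr::expand_grid(des_id = props$des_id, T_K = t_k)
  }
  d <- left_join(grid, props, by = "des_id")
  u <- speed_proposed(d$omega, d$mw_g_mol, d$vc_cm3_mol, d$T_K, coefficients)
  if (noise > 0) {
    eps <- withr::with_seed(seed, rnorm(length(u), sd = noise))
    u <- u * (1 + eps)
  }
  tibble(des_id = d$des_id, dataset = d$dataset, T_K = d$T_K,
         u_exp_ms = u, source = source) %>%
    arrange(des_number(.data$des_id), .data$T_K)
}
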