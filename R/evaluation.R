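#' Average absolute relative deviation (percent)
#'
#' `AARD% = 100/N * sum |u_exp - u_cal| / |u_exp|`. This is also the
#' objective function minimized when refitting the correlation
#' coefficients (see [objective()] and [refit()]).
#'
#' @param u_exp Experimental values (all nonzero).
#' @param u_cal Calculated values, same length.
#' @return A single percentage.
#' @export
#' @examples
#' aard(c(100, 200), c(110, 180))
aard <- function(u_exp, u_cal) {
  if (length(u_exp) == 0L) abort("empty input")
  if (length(u_exp) != length(u_cal)) {
    abort("`u_exp` and `u_cal` must have the same length")
  }
  if (any(u_exp == 0)) abort("experimental values must be nonzero")
  100 * mean(abs((u_exp - u_cal) / u_exp))
}

#' Signed relative deviation (percent)
#'
#' `RD% = 100 * (u_exp - u_cal) / u_exp`; positive when the model
#' underestimates.
#'
#' @inheritParams aard
#' @return Vector of signed percentages.
#' @export
#' @examples
#' rd(100, 90)
rd <- function(u_exp, u_cal) {
  if (any(u_exp == 0)) abort("experimental values must be nonzero")
  100 * (u_exp - u_cal) / u_exp
}

assert_speed_dataset <- function(dataset) {
  need <- c("des_id", "T_K", "u_exp_ms")
  missing <- setdiff(need, names(dataset))
  if (length(missing) > 0L) {
    abort(sprintf("dataset lacks columns: %s", paste(missing, collapse = ", ")))
  }
  if (nrow(dataset) == 0L) abort("dataset is empty")
  if (any(dataset$u_exp_ms <= 0)) abort("speeds of sound must be positive")
  if (any(dataset$T_K <= 0)) abort("temperatures must be positive (kelvin)")
  key <- if ("source" %in% names(dataset)) {
    paste(dataset$des_id, dataset$T_K, dataset$source)
  } else {
    paste(dataset$des_id, dataset$T_K)
  }
  if (anyDuplicated(key)) {
    abort("dataset has duplicate (des_id, T_K, source) records")
  }
  invisible(dataset)
}

#' Read and write speed-of-sound datasets
#'
#' CSV schema: `des_id`, `T_K`, `u_exp_ms` and optionally `source`.
#' Validation enforces positive speeds and temperatures and uniqueness of
#' (des_id, T_K, source).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_speed_dataset <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols())
  assert_speed_dataset(as_tibble(x))
}

#' @rdname read_speed_dataset
#' @param x A dataset tibble.
#' @export
write_speed_dataset <- function(x, path) {
  readr::write_csv(assert_speed_dataset(x), path)
  invisible(path)
}

dataset_predictions <- function(dataset, coefficients, properties) {
  missing_props <- setdiff(unique(dataset$des_id), properties$des_id)
  if (length(missing_props) > 0L) {
    abort(sprintf("no properties available for: %s",
                  paste(missing_props, collapse = ", ")))
  }
  d <- left_join(dataset, properties, by = "des_id")
  speed_proposed(d$omega, d$mw_g_mol, d$vc_cm3_mol, d$T_K, coefficients)
}

#' Optimization objective: AARD of the proposed model on a dataset
#'
#' Identical functional to [aard()], evaluated on the proposed-model
#' predictions under a given coefficient set. This is the function the
#' coefficient search of [refit()] minimizes.
#'
#' @param dataset A speed dataset (see [read_speed_dataset()]).
#' @param coefficients Correlation coefficients.
#' @param properties Property table covering every `des_id` in the
#'   dataset; defaults to the registry chain.
#' @return A single percentage.
#' @export
objective <- function(dataset, coefficients = proposed_coefficients(),
                      properties = des_properties()) {
  assert_speed_dataset(dataset)
  u_cal <- dataset_predictions(dataset, coefficients, properties)
  aard(dataset$u_exp_ms, u_cal)
}

#' Evaluate speed-of-sound models against a dataset
#'
#' Scores one or more models on an experimental (or synthetic) dataset:
#' per-record signed deviations, per-DES AARD, and AARD by training/test
#' split (split labels come from the packaged registry unless the dataset
#' carries its own `dataset` column).
#'
#' @inheritParams predict_speed
#' @param dataset A speed dataset.
#' @return An object of class `des_eval`: a list with tibbles `records`
#'   (per-record predictions and RD%), `by_des` (per-DES AARD) and
#'   `by_split` (AARD for training, test and overall). `tidy()` returns
#'   the per-DES table, `glance()` the split summary in wide form.
#' @export
evaluate_models <- function(dataset, models = "proposed",
                            coefficients = proposed_coefficients(),
                            constants = literature_constants(),
                            density = NULL,
                            properties = NULL) {
  assert_speed_dataset(dataset)
  props <- properties %||% des_properties(unique(dataset$des_id))
  has_split <- "dataset" %in% names(dataset)
  split_map <- if (has_split) {
    distinct(dataset, .data$des_id, split = .data$dataset)
  } else {
    select(des_registry(), "des_id", split = "dataset")
  }
  records <- map(models, function(m) {
    pred <- predict_speed(
      unique(dataset$des_id), t_k = unique(dataset$T_K), models = m,
      coefficients = coefficients, constants = constants, density = density,
      properties = props
    )
    left_join(dataset, rename(pred, u_cal_ms = "u_ms"),
              by = c("des_id", "T_K" = "t_k")) %>%
      mutate(rd_pct = rd(.data$u_exp_ms, .data$u_cal_ms))
  }) %>%
    bind_rows() %>%
    left_join(split_map, by = "des_id")
  by_des <- records %>%
    group_by(.data$model, .data$des_id) %>%
    summarise(n = n(), aard_pct = aard(.data$u_exp_ms, .data$u_cal_ms),
              .groups = "drop") %>%
    arrange(.data$model, des_number(.data$des_id))
  by_split <- bind_rows(
    records %>%
      group_by(.data$model, split = .data$split) %>%
      summarise(n = n(), aard_pct = aard(.data$u_exp_ms, .data$u_cal_ms),
                .groups = "drop"),
    records %>%
      group_by(.data$model) %>%
      summarise(split = "overall", n = n(),
                aard_pct = aard(.data$u_exp_ms, .data$u_cal_ms),
                .groups = "drop")
  ) %>%
    arrange(.data$model, match(.data$split, c("training", "test", "overall")))
  structure(
    list(records = records, by_des = by_des, by_split = by_split,
         models = models),
    class = "des_eval"
  )
}

#' @export
print.des_eval <- function(x, ...) {
  cat(sprintf("Speed-of-sound evaluation: %d records, %d DES(s), model(s): %s\n",
              nrow(x$records) / length(x$models),
              length(unique(x$records$des_id)),
              paste(x$models, collapse = ", ")))
  print(as.data.frame(x$by_split), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.des_eval <- function(x, ...) x$by_des

#' @export
glance.des_eval <- function(x, ...) {
  tidyr::pivot_wider(x$by_split, names_from = "split",
                     values_from = c("n", "aard_pct"))
}

#' Per-DES evaluation table in wide (report) layout
#'
#' One row per DES, one AARD column per model, mirroring the layout of a
#' model-comparison table.
#'
#' @param x A `des_eval` object.
#' @return A tibble.
#' @export
eval_table <- function(x) {
  stopifnot(inherits(x, "des_eval"))
  tidyr::pivot_wider(select(x$by_des, -"n"), names_from = "model",
                     values_from = "aard_pct")
}
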