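#' Descriptive statistics per trait, location and environment
#'
#' Min, max, mean and sample standard deviation (n - 1 denominator) of every
#' trait, computed over plot-level records within each grouping cell. This
#' mirrors the conventional "basic statistics" table of a multi-environment
#' trial report: one block per location, rows per trait, statistics per
#' environment.
#'
#' @inheritParams validate_trials
#' @param group Grouping columns; defaults to location and environment.
#' @param traits Trait codes to summarise; defaults to all present.
#' @return A tibble with `trait`, the grouping columns, `n`, `min`, `max`,
#'   `mean`, `sd`. Groups with no non-missing value for a trait are omitted
#'   with a warning.
#' @export
describe_traits <- function(data, group = c("location", "environment"),
                            traits = intersect(trait_codes(), names(data))) {
  stopifnot_df(data, c(group, traits))
  if (!nrow(data)) abort("`data` is empty.", class = "metstress_value_error")
  long <- data |>
    dplyr::select(dplyr::all_of(c(group, traits))) |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value")
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("trait", group)))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n == 0)) {
    warn(sprintf("%d trait-by-group cell(s) had no observations and were omitted.",
                 sum(out$n == 0)))
    out <- dplyr::filter(out, .data$n > 0)
  }
  out |>
    dplyr::mutate(trait = factor(.data$trait, levels = trait_codes())) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(group)), .data$trait) |>
    dplyr::mutate(trait = as.character(.data$trait))
}

#' Tidy per-plot values of one trait for distribution plots
#'
#' One row per plot-level observation of `trait`, with its genotype,
#' location and environment: the input expected by box/violin plots of
#' genotype performance across environments. No aggregation is performed.
#'
#' @inheritParams genotype_env_means
#' @return A tibble with `value`, `genotype`, `location`, `environment`
#'   (and `year`, `replicate` for traceability), in input row order.
#' @export
distribution_data <- function(data, trait) {
  stopifnot_df(data, key_cols())
  check_trait(data, trait)
  tibble::tibble(
    value = data[[trait]],
    genotype = data$genotype,
    location = data$location,
    environment = data$environment,
    year = data$year,
    replicate = data$replicate
  )
}
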