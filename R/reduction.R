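#' Percent reduction from optimum to stress
#'
#' `100 * (x_oe - x_stress) / x_oe`, the signed relative loss of a trait
#' under stress; negative values are gains under stress and are preserved,
#' not clamped. Vectorised.
#'
#' @param x_oe Trait value under the optimum environment (must be positive).
#' @param x_stress Trait value under stress.
#' @return Percent reduction.
#' @export
#' @examples
#' percent_reduction(100, 80)  # 20
#' percent_reduction(100, 120) # -20: gain under stress
percent_reduction <- function(x_oe, x_stress) {
  if (any(!is.na(x_oe) & x_oe == 0)) {
    abort("`x_oe` must be positive: percent reduction is undefined at 0.",
          class = "metstress_value_error")
  }
  100 * (x_oe - x_stress) / x_oe
}

#' Per-trait summary of percent reductions under stress
#'
#' For one location and one stress contrast (`OE - HSE` or `OE - HDSE`),
#' computes the percent reduction of every trait per genotype on pooled
#' genotype-by-environment means (years and replicates pooled via
#' [genotype_env_means()]), then summarises min, max and mean across
#' genotypes. The mean is the unweighted mean of per-genotype reductions
#' (mean of ratios), not the reduction of the population means
#' (ratio of means); on heterogeneous genotypes the two differ, and this
#' function deliberately reports the former. Genotypes missing either arm
#' of the contrast for a trait are excluded for that trait.
#'
#' @inheritParams validate_trials
#' @param location Location to analyse.
#' @param stress_env Stress environment defining the contrast, `"HSE"` or
#'   `"HDSE"`.
#' @param traits Trait codes to summarise; defaults to all present.
#' @return A tibble of class `met_reduction` with `trait`, `contrast`, `n`,
#'   `min`, `max`, `mean` (all in percent).
#' @export
reduction_summary <- function(data, location, stress_env = c("HSE", "HDSE"),
                              traits = intersect(trait_codes(), names(data))) {
  stress_env <- match.arg(stress_env)
  per_gen <- genotype_reductions(data, location, stress_env, traits)
  if (!nrow(per_gen)) {
    abort(sprintf("No genotype has both OE and %s observations at `%s`.",
                  stress_env, location), class = "metstress_value_error")
  }
  out <- per_gen |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      contrast = sprintf("OE-%s", stress_env),
      n = dplyr::n(),
      min = min(.data$reduction),
      max = max(.data$reduction),
      mean = mean(.data$reduction),
      .groups = "drop"
    ) |>
    dplyr::mutate(trait = factor(.data$trait, levels = trait_codes())) |>
    dplyr::arrange(.data$trait) |>
    dplyr::mutate(trait = as.character(.data$trait))
  structure(out, class = c("met_reduction", class(out)),
            location = location, stress_env = stress_env)
}

#' Per-genotype percent reductions for every trait
#'
#' The genotype-level records behind [reduction_summary()]: one row per
#' genotype and trait with the reduction of its pooled mean from OE to the
#' stress environment.
#'
#' @inheritParams reduction_summary
#' @return A tibble with `genotype`, `trait`, `contrast`, `x_oe`,
#'   `x_stress`, `reduction`.
#' @export
genotype_reductions <- function(data, location, stress_env = c("HSE", "HDSE"),
                                traits = intersect(trait_codes(), names(data))) {
  stress_env <- match.arg(stress_env)
  stopifnot_df(data, c(key_cols(), traits))
  if (!location %in% data$location) {
    abort(sprintf("Location `%s` is not present in the data.", location),
          class = "metstress_value_error")
  }
  sub <- dplyr::filter(data, .data$location == .env$location,
                       .data$environment %in% c("OE", stress_env))
  if (!all(c("OE", stress_env) %in% sub$environment)) {
    abort(sprintf("Both OE and %s must be present at location `%s`.",
                  stress_env, location), class = "metstress_value_error")
  }
  purrr::map_dfr(traits, function(tr) {
    wide <- sub |>
      genotype_env_means(tr) |>
      dplyr::select("genotype", "environment", "mean") |>
      tidyr::pivot_wider(names_from = "environment", values_from = "mean")
    if (!all(c("OE", stress_env) %in% names(wide))) return(tibble::tibble())
    wide <- wide[complete.cases(wide[c("OE", stress_env)]) & wide$OE > 0, ]
    tibble::tibble(
      genotype = wide$genotype,
      trait = tr,
      contrast = sprintf("OE-%s", stress_env),
      x_oe = wide$OE,
      x_stress = wide[[stress_env]],
      reduction = percent_reduction(wide$OE, wide[[stress_env]])
    )
  })
}
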