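#' Read a long-format trial phenotype table
#'
#' Reads a plot-level multi-environment trial CSV: one row per genotype x
#' location x year x environment x replicate x block, with one column per
#' trait (see [trait_codes()]). The file is validated on read: environment
#' labels must be `OE`, `HSE` or `HDSE`, the design key
#' (genotype, location, year, environment, replicate) must be unique, trait
#' values must be non-negative and `HI` must lie in `[0, 100]`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional column mapping when the file does not use the
#'   canonical column names: either a named character vector
#'   (`c(canonical = "file_column", ...)`) or the path to a YAML file holding
#'   such a mapping.
#' @return A validated tibble of plot-level records. Year is always kept as
#'   an opaque season label (character), never parsed as a number.
#' @seealso [write_trials()], [validate_trials()], [trial_design()]
#' @export
read_trials <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File `%s` does not exist.", path), class = "metstress_io_error")
  }
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && is.null(names(schema)) && length(schema) == 1) {
      schema <- unlist(yaml::read_yaml(schema))
    }
    schema <- schema[schema %in% names(data)]
    data <- dplyr::rename(data, !!!rlang::set_names(schema, names(schema)))
  }
  stopifnot_df(data, key_cols(), what = basename(path))
  traits <- intersect(trait_codes(), names(data))
  if (!length(traits)) {
    abort("No trait columns found after schema mapping.",
          class = "metstress_schema_error")
  }
  data <- data |>
    dplyr::mutate(
      dplyr::across(dplyr::all_of(c("replicate", "block")), as.integer),
      dplyr::across(dplyr::all_of(traits), as.numeric),
      year = as.character(.data$year)
    ) |>
    dplyr::select(dplyr::all_of(c(key_cols(), traits)))
  validate_trials(data)
}

#' Validate a trial phenotype table
#'
#' Checks the record-level invariants of a plot-level trial table and either
#' returns the data invisibly or raises a classed error naming the offending
#' rows. A stored harvest index that deviates from `100 * SY / BY` by more
#' than 0.5 percentage points triggers a warning (the stored value is kept).
#'
#' @param data A plot-level trial table (see [read_trials()]).
#' @return `data`, invisibly, if all checks pass.
#' @export
validate_trials <- function(data) {
  stopifnot_df(data, key_cols())
  traits <- intersect(trait_codes(), names(data))

  bad_env <- which(!data$environment %in% env_levels())
  if (length(bad_env)) {
    abort(sprintf(
      "Unknown environment label `%s` at row %d (expected one of %s).",
      data$environment[bad_env[1]], bad_env[1],
      paste(env_levels(), collapse = ", ")
    ), class = "metstress_value_error")
  }

  key <- data[c("genotype", "location", "year", "environment", "replicate")]
  dup <- duplicated(key)
  if (any(dup)) {
    abort(sprintf(
      "Duplicate design key (genotype, location, year, environment, replicate) at row %d.",
      which(dup)[1]
    ), class = "metstress_uniqueness_error")
  }

  for (tr in traits) {
    neg <- which(!is.na(data[[tr]]) & data[[tr]] < 0)
    if (length(neg)) {
      abort(sprintf("Trait `%s` is negative at row %d.", tr, neg[1]),
            class = "metstress_value_error")
    }
  }
  if ("HI" %in% traits) {
    out <- which(!is.na(data$HI) & data$HI > 100)
    if (length(out)) {
      abort(sprintf("`HI` exceeds 100%% at row %d.", out[1]),
            class = "metstress_value_error")
    }
  }
  if (all(c("DFF", "DM") %in% traits)) {
    bad <- which(!is.na(data$DFF) & !is.na(data$DM) & data$DM < data$DFF)
    if (length(bad)) {
      abort(sprintf("`DM` < `DFF` at row %d (maturity before flowering).", bad[1]),
            class = "metstress_value_error")
    }
  }
  if (all(c("SY", "BY", "HI") %in% traits)) {
    ok <- complete.cases(data[c("SY", "BY", "HI")]) & data$BY > 0
    dev <- abs(data$HI[ok] - 100 * data$SY[ok] / data$BY[ok])
    if (any(dev > 0.5)) {
      warn(sprintf(
        "%d record(s) have a stored HI deviating by > 0.5 points from 100 * SY / BY; stored values kept.",
        sum(dev > 0.5)
      ))
    }
  }
  invisible(data)
}

#' Summarise the trial design
#'
#' Counts the distinct design levels present in a trial table and reports
#' whether the layout is balanced, i.e. whether every genotype appears
#' exactly once in every (location, year, environment, replicate) cell.
#'
#' @inheritParams validate_trials
#' @return A one-row tibble with `n_genotypes`, `n_locations`, `n_years`,
#'   `n_environments`, `n_replicates`, `blocks_per_replicate` and `balanced`.
#' @export
trial_design <- function(data) {
  stopifnot_df(data, key_cols())
  counts <- dplyr::count(data, .data$location, .data$year, .data$environment,
                         .data$replicate, .data$genotype)
  cells <- dplyr::count(data, .data$location, .data$year, .data$environment,
                        .data$replicate)
  n_gen <- dplyr::n_distinct(data$genotype)
  balanced <- nrow(data) > 0 &&
    all(counts$n == 1L) &&
    all(cells$n == n_gen) &&
    nrow(cells) == dplyr::n_distinct(data[c("location", "year", "environment")]) *
      dplyr::n_distinct(data$replicate)
  tibble::tibble(
    n_genotypes = n_gen,
    n_locations = dplyr::n_distinct(data$location),
    n_years = dplyr::n_distinct(data$year),
    n_environments = dplyr::n_distinct(data$environment),
    n_replicates = dplyr::n_distinct(data$replicate),
    blocks_per_replicate = dplyr::n_distinct(data$block),
    balanced = balanced
  )
}

#' Write a trial phenotype table to CSV
#'
#' Writes the canonical long-format CSV: one header row, one row per plot
#' record, design keys first then trait columns in canonical order. Only
#' trait columns present in `data` are written, so a dataset without e.g.
#' `HI` yields a file without an `HI` column. `read_trials(write_trials(d))`
#' round-trips to an identical table.
#'
#' @inheritParams validate_trials
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(data, path) {
  stopifnot_df(data, key_cols())
  traits <- intersect(trait_codes(), names(data))
  out <- dplyr::select(data, dplyr::all_of(c(key_cols(), traits)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Harvest index from seed and biological yield
#'
#' `HI = 100 * SY / BY`: the percentage of above-ground biomass that is
#' grain. Vectorised. A zero biological yield is an error; `sy > by`
#' (harvest index above 100%) is physiologically implausible and triggers a
#' warning, but the value is returned unchanged.
#'
#' @param sy Seed yield per plot (g).
#' @param by Biological yield per plot (g).
#' @return Harvest index in percent.
#' @export
#' @examples
#' derive_harvest_index(500, 2000)
derive_harvest_index <- function(sy, by) {
  if (any(!is.na(by) & by == 0)) {
    abort("`by` must be positive: harvest index is undefined at BY = 0.",
          class = "metstress_value_error")
  }
  if (any(!is.na(sy) & !is.na(by) & sy > by)) {
    warn("`sy` exceeds `by` for some plots: HI > 100% is physiologically implausible.")
  }
  100 * sy / by
}

#' Genotype means per location and environment
#'
#' Pools years and replicates: the mean of all plot records for each
#' (genotype, location, environment) cell, with the number of non-missing
#' observations behind each mean. Cells with no observed value are reported
#' as missing (`NA`), never as zero. The result is invariant to record
#' order.
#'
#' @inheritParams validate_trials
#' @param trait A trait code present in `data`.
#' @return A tibble with `genotype`, `location`, `environment`, `mean`, `n`,
#'   one row per cell present in the data.
#' @export
genotype_env_means <- function(data, trait) {
  stopifnot_df(data, key_cols())
  check_trait(data, trait)
  data |>
    dplyr::group_by(.data$genotype, .data$location, .data$environment) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data[[trait]]))) mean(.data[[trait]], na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data[[trait]])),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$location, .data$environment, .data$genotype)
}
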