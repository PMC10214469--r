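#' Stress tolerance and susceptibility indices
#'
#' Scalar (vectorised) forms of the six selection indices used to contrast a
#' genotype's yield under optimum (`yp`) and stress (`ys`) conditions,
#' relative to the population means over all entries (`yp_bar`, `ys_bar`):
#'
#' * `sti()` — stress tolerance index, `yp * ys / yp_bar^2`. High values mark
#'   genotypes combining yield potential and stress tolerance.
#' * `ssi()` — stress susceptibility index, `(1 - ys/yp) / SI` with stress
#'   intensity `SI = 1 - ys_bar/yp_bar`. A value of 1 means the genotype
#'   loses yield at exactly the population rate; > 1 is more susceptible.
#' * `mp()` — mean productivity, `(yp + ys) / 2`.
#' * `tol()` — tolerance, `yp - ys` (signed; negative values mean a yield
#'   gain under stress).
#' * `msti()` — modified stress tolerance index, `(ys / ys_bar)^2 * STI`,
#'   re-weighting STI towards performance under stress.
#' * `gmp()` — geometric mean productivity, `sqrt(yp * ys)`.
#'
#' @param yp Yield under optimum conditions (g/plot), per genotype.
#' @param ys Yield under stress (g/plot), per genotype.
#' @param yp_bar,ys_bar Population mean yields over all entries under
#'   optimum and stress.
#' @return A numeric vector, one value per genotype.
#' @name stress_index
#' @examples
#' sti(1000, 500, 1000)     # 0.5
#' ssi(1000, 800, 1000, 800) # 1: loss equals the population loss
#' mp(1000, 500)            # 750
#' tol(1000, 500)           # 500
#' msti(1000, 1000, 1000, 500) # 4
#' gmp(100, 400)            # 200
NULL

#' @rdname stress_index
#' @export
sti <- function(yp, ys, yp_bar) {
  if (any(!is.na(yp_bar) & yp_bar == 0)) {
    abort("`yp_bar` must be positive: STI is undefined at a zero population mean.",
          class = "metstress_value_error")
  }
  yp * ys / yp_bar^2
}

#' @rdname stress_index
#' @export
ssi <- function(yp, ys, yp_bar, ys_bar) {
  si <- 1 - ys_bar / yp_bar
  if (any(!is.na(yp) & yp == 0)) {
    abort("`yp` must be positive: SSI is undefined at zero optimum yield.",
          class = "metstress_value_error")
  }
  if (any(!is.na(si) & si <= 0)) {
    abort("Stress intensity 1 - ys_bar/yp_bar must be positive: no stress contrast.",
          class = "metstress_no_stress_error")
  }
  (1 - ys / yp) / si
}

#' @rdname stress_index
#' @export
mp <- function(yp, ys) (yp + ys) / 2

#' @rdname stress_index
#' @export
tol <- function(yp, ys) yp - ys

#' @rdname stress_index
#' @export
msti <- function(yp, ys, yp_bar, ys_bar) {
  if (any(!is.na(ys_bar) & ys_bar == 0)) {
    abort("`ys_bar` must be positive.", class = "metstress_value_error")
  }
  (ys / ys_bar)^2 * sti(yp, ys, yp_bar)
}

#' @rdname stress_index
#' @export
gmp <- function(yp, ys) sqrt(yp * ys)

#' Per-genotype optimum and stress yields at one location
#'
#' Builds the yield contrast behind the stress indices: per-genotype mean
#' yield under the optimum environment (`yp`) and under one stress
#' environment (`ys`), pooling years and replicates via
#' [genotype_env_means()]; the population means over all entries with both
#' arms observed; and the stress intensity `SI = 1 - ys_bar/yp_bar`.
#'
#' @inheritParams validate_trials
#' @param location Location to analyse.
#' @param stress_env Stress environment, `"HSE"` or `"HDSE"`.
#' @param trait Yield trait; defaults to `SY`.
#' @return A tibble of class `yield_summary` with `genotype`, `yp`, `ys` and
#'   attributes `yp_bar`, `ys_bar`, `si`, `location`, `stress_env`, `trait`.
#'   Genotypes missing either arm are excluded with a warning; a
#'   non-positive stress intensity is an error (no stress contrast).
#' @export
yield_summary <- function(data, location, stress_env = c("HSE", "HDSE"),
                          trait = "SY") {
  stress_env <- match.arg(stress_env)
  check_trait(data, trait)
  if (!location %in% data$location) {
    abort(sprintf("Location `%s` is not present in the data.", location),
          class = "metstress_value_error")
  }
  cells <- data |>
    dplyr::filter(.data$location == .env$location,
                  .data$environment %in% c("OE", stress_env)) |>
    genotype_env_means(trait)
  if (!all(c("OE", stress_env) %in% cells$environment)) {
    abort(sprintf("Both OE and %s must be present at location `%s`.",
                  stress_env, location), class = "metstress_value_error")
  }
  wide <- cells |>
    dplyr::select("genotype", "environment", "mean") |>
    tidyr::pivot_wider(names_from = "environment", values_from = "mean")
  keep <- complete.cases(wide[c("OE", stress_env)])
  if (any(!keep)) {
    warn(sprintf("%d genotype(s) missing one arm of the contrast were excluded.",
                 sum(!keep)))
  }
  wide <- wide[keep, ]
  out <- tibble::tibble(genotype = wide$genotype,
                        yp = wide$OE, ys = wide[[stress_env]])
  yp_bar <- mean(out$yp)
  ys_bar <- mean(out$ys)
  si <- 1 - ys_bar / yp_bar
  if (!is.finite(si) || si <= 0) {
    abort(sprintf(
      "Stress intensity is %.3f: %s yields are not below OE yields at `%s` (no stress contrast).",
      si, stress_env, location
    ), class = "metstress_no_stress_error")
  }
  structure(out,
            class = c("yield_summary", class(out)),
            yp_bar = yp_bar, ys_bar = ys_bar, si = si,
            location = location, stress_env = stress_env, trait = trait)
}

#' Stress intensity of a yield summary
#'
#' @param summary A [yield_summary()] object.
#' @return The stress intensity `1 - ys_bar/yp_bar`.
#' @export
stress_intensity <- function(summary) attr(summary, "si")

#' Compute all stress indices for every genotype
#'
#' One row per genotype with `yp`, `ys` and the six indices STI, SSI, MP,
#' TOL, MSTI and GMP (see [sti()] and friends). A genotype with `yp = 0`
#' gets a missing SSI, the other indices are still computed. A negative TOL
#' (yield gain under stress) is kept and flagged in the `stress_gain`
#' column rather than clamped.
#'
#' @param summary A [yield_summary()] object.
#' @return A tibble of class `index_table` carrying the provenance
#'   attributes of `summary`.
#' @export
index_table <- function(summary) {
  if (!inherits(summary, "yield_summary")) {
    abort("`summary` must be a `yield_summary` object.")
  }
  yp_bar <- attr(summary, "yp_bar")
  ys_bar <- attr(summary, "ys_bar")
  out <- tibble::tibble(
    genotype = summary$genotype,
    yp = summary$yp,
    ys = summary$ys,
    sti = sti(summary$yp, summary$ys, yp_bar),
    ssi = ifelse(summary$yp > 0,
                 (1 - summary$ys / summary$yp) / (1 - ys_bar / yp_bar),
                 NA_real_),
    mp = mp(summary$yp, summary$ys),
    tol = tol(summary$yp, summary$ys),
    msti = msti(summary$yp, summary$ys, yp_bar, ys_bar),
    gmp = gmp(summary$yp, summary$ys),
    stress_gain = tol(summary$yp, summary$ys) < 0
  )
  structure(out,
            class = c("index_table", class(tibble::tibble())),
            yp_bar = yp_bar, ys_bar = ys_bar, si = attr(summary, "si"),
            location = attr(summary, "location"),
            stress_env = attr(summary, "stress_env"),
            trait = attr(summary, "trait"))
}

# shared tie-break ordering: key desc, then ys desc, then genotype id asc
index_order <- function(table, key) {
  order(-table[[key]], -table$ys, table$genotype)
}

#' Rank genotypes and label tolerant and susceptible selections
#'
#' Ranks genotypes by a tolerance key (default STI, descending: high STI =
#' tolerant and high-yielding) and by a susceptibility key (default SSI,
#' descending: high SSI = susceptible), labelling the top `k` of each. Ties
#' are broken by higher stress yield `ys`, then by genotype identifier.
#'
#' @param table An [index_table()].
#' @param k Number of genotypes to select on each side (default 5).
#' @param tolerant_by,susceptible_by Index columns used for the two
#'   rankings.
#' @return `table` with added columns `rank` (by `tolerant_by`),
#'   `tolerant` and `susceptible` logical labels.
#' @export
rank_and_select <- function(table, k = 5, tolerant_by = "sti",
                            susceptible_by = "ssi") {
  if (!inherits(table, "index_table")) abort("`table` must be an `index_table`.")
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("`k` must be a positive integer.", class = "metstress_value_error")
  }
  k <- as.integer(k)
  if (k > nrow(table)) {
    abort(sprintf("`k` = %d exceeds the %d genotypes available.", k, nrow(table)),
          class = "metstress_value_error")
  }
  ord_tol <- index_order(table, tolerant_by)
  ord_sus <- index_order(table, susceptible_by)
  out <- table
  out$rank <- integer(nrow(out))
  out$rank[ord_tol] <- seq_len(nrow(out))
  out$tolerant <- out$rank <= k
  out$susceptible <- FALSE
  out$susceptible[ord_sus[seq_len(k)]] <- TRUE
  attr(out, "k") <- k
  out
}

#' Mean row over the selected top-k genotypes
#'
#' The unweighted arithmetic mean of each index column over the `k` selected
#' genotypes, rounded half-away-from-zero at report precision: yields, MP,
#' TOL and GMP to integers; STI and SSI to 2 decimals; MSTI to 1 decimal.
#' Internal computation is always full precision; only this report row is
#' rounded.
#'
#' @param table An [index_table()], ranked with [rank_and_select()] (if not,
#'   it is ranked here with defaults).
#' @param k Number of top genotypes to average (default 5).
#' @return A one-row tibble of rounded column means.
#' @export
top_k_summary <- function(table, k = 5) {
  if (!inherits(table, "index_table")) abort("`table` must be an `index_table`.")
  if (!"tolerant" %in% names(table)) table <- rank_and_select(table, k = k)
  sel <- dplyr::filter(table, .data$rank <= .env$k)
  if (!nrow(sel)) abort("No selected records to summarise.",
                        class = "metstress_value_error")
  tibble::tibble(
    n = nrow(sel),
    yp = round_half_away(mean(sel$yp)),
    ys = round_half_away(mean(sel$ys)),
    sti = round_half_away(mean(sel$sti), 2),
    ssi = round_half_away(mean(sel$ssi), 2),
    mp = round_half_away(mean(sel$mp)),
    tol = round_half_away(mean(sel$tol)),
    msti = round_half_away(mean(sel$msti), 1),
    gmp = round_half_away(mean(sel$gmp))
  )
}

#' One-call index table for a location and stress environment
#'
#' Convenience wrapper chaining [yield_summary()], [index_table()] and
#' [rank_and_select()].
#'
#' @inheritParams yield_summary
#' @inheritParams rank_and_select
#' @return A ranked and labelled [index_table()].
#' @export
stress_indices <- function(data, location, stress_env = c("HSE", "HDSE"),
                           trait = "SY", k = 5) {
  data |>
    yield_summary(location, stress_env, trait) |>
    index_table() |>
    rank_and_select(k = k)
}
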