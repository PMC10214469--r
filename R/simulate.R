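# Seeded generator of study-shaped multi-environment trials.
#
# Generative model for a plot value of a yield-type trait t, genotype i,
# location j, year k, environment m:
#
#   x = (mu_tj + y_tk + g_ti + gl_tij + gy_tik + ge_tim + rep + block + eps)
#       * m_tim,   with m_tim = 1 - (1 - mult_tm) * s_i
#
# where mult_tm is the environment stress multiplier of the trait (1 under
# OE) and s_i a per-genotype susceptibility factor, centred to mean 1 so
# that the population stress intensity equals 1 - mult exactly in
# expectation. Designated "true tolerant" genotypes get s_i shrunk by the
# tolerance bonus before centring. Phenology (DFF) responds by an additive
# shift instead, and DM = DFF + a positive maturity gap that shortens under
# stress. BY is generated as SY + straw (both non-negative), and HI is
# derived as 100 * SY / BY, so HI always lies in (0, 100).

#' Default simulation configuration for a study-shaped trial
#'
#' Returns the configuration of the default synthetic experiment: 34
#' genotypes, 2 locations (Banda, Jhansi), 2 seasons, 3 environments (OE,
#' HSE, HDSE), 2 replicates each split into 2 incomplete blocks (816 plots).
#' Trait means and standard deviations are anchored to the magnitudes
#' reported for such trials (seed yield 790 g/plot, SD 242 g at the
#' higher-yielding location under OE); seed-yield stress multipliers default
#' to 0.80 (HSE) and 0.64 (HDSE), i.e. expected yield reductions of 20% and
#' 36%. Variance is split across genotype, genotype-by-location, -year and
#' -environment interactions, plot error, year, block and replicate effects
#' as fixed fractions of each trait's SD.
#'
#' @param n_genotypes,n_years,n_replicates,blocks_per_replicate Design
#'   counts.
#' @param n_true_tolerant Number of genotypes planted as truly
#'   stress-tolerant.
#' @param tolerance_bonus Fraction of the stress penalty removed for true
#'   tolerants (0 = none, 1 = fully stress-proof). Default 0.8.
#' @param susceptibility_sd SD of the per-genotype susceptibility jitter
#'   around 1. Default 0.03.
#' @param noise_scale Multiplier on the plot-error SD fraction; 1 is the
#'   calibrated default, larger values degrade all recoveries.
#' @param varfrac Named fractions of each trait SD assigned to the effect
#'   components `G`, `GL`, `GY`, `GE`, `eps`, `year`, `block`, `rep`.
#' @return A list of class `sim_config`; `$traits` is a tibble one row per
#'   generated trait that may be edited before simulation.
#' @seealso [simulate_met()], [no_stress()]
#' @export
sim_config <- function(n_genotypes = 34,
                       n_years = 2,
                       n_replicates = 2,
                       blocks_per_replicate = 2,
                       n_true_tolerant = 5,
                       tolerance_bonus = 0.8,
                       susceptibility_sd = 0.03,
                       noise_scale = 1,
                       varfrac = c(G = 0.25, GL = 0.08, GY = 0.08, GE = 0.11,
                                   eps = 0.33, year = 0.40, block = 0.06,
                                   rep = 0.04)) {
  traits <- tibble::tribble(
    ~trait, ~mean_banda, ~mean_jhansi, ~sd, ~response, ~hse, ~hdse, ~loading,
    "DFF",    88,   85,   4.7, "shift",       -9,  -14, 0,
    "PH",    112,  103,  17.7, "multiplicative", 0.96, 0.90, 0,
    "NT",     11,    8,   2.5, "multiplicative", 0.76, 0.73, 0,
    "SL",      9,    8,   1.4, "multiplicative", 0.93, 0.82, 0,
    "NSS",    19,   18,   1.7, "multiplicative", 0.96, 0.92, 0,
    "NGS",    45,   46,  10.2, "multiplicative", 0.93, 0.79, 0.80,
    "TKW",     4,    3,   0.7, "multiplicative", 0.92, 0.87, 0.50,
    "SY",    790,  598, 242.4, "multiplicative", 0.80, 0.64, 0.85,
    "STRAW", 1487, 1595, 540,  "multiplicative", 0.86, 0.62, 0.30
  )
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    locations = c("Banda", "Jhansi"),
    years = if (n_years == 2) c("2020-21", "2021-22") else paste0("Y", seq_len(n_years)),
    n_replicates = as.integer(n_replicates),
    blocks_per_replicate = as.integer(blocks_per_replicate),
    traits = traits,
    # maturity gap DM - DFF (days) per environment, and its plot-level SD
    maturity_gap = c(OE = 49, HSE = 33, HDSE = 32),
    maturity_gap_sd = 2,
    varfrac = varfrac,
    n_true_tolerant = as.integer(n_true_tolerant),
    tolerance_bonus = tolerance_bonus,
    susceptibility_sd = susceptibility_sd,
    susceptible_traits = c("SY", "STRAW"),
    noise_scale = noise_scale
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  tr <- cfg$traits
  if (any(tr$sd <= 0)) {
    abort("Trait SDs must be positive.", class = "metstress_config_error")
  }
  m <- tr[tr$response == "multiplicative", ]
  if (any(m$hse <= 0 | m$hse > 1 | m$hdse <= 0 | m$hdse > 1)) {
    abort("Stress multipliers must lie in (0, 1].", class = "metstress_config_error")
  }
  if (any(cfg$varfrac < 0) || cfg$susceptibility_sd < 0 ||
      cfg$tolerance_bonus < 0 || cfg$tolerance_bonus > 1) {
    abort("Variance fractions and susceptibility must be non-negative; the tolerance bonus must lie in [0, 1].",
          class = "metstress_config_error")
  }
  if (cfg$n_true_tolerant > cfg$n_genotypes) {
    abort("`n_true_tolerant` cannot exceed `n_genotypes`.",
          class = "metstress_config_error")
  }
  invisible(cfg)
}

#' Remove all stress responses from a simulation configuration
#'
#' Sets every stress multiplier to 1, every phenology shift to 0, keeps the
#' maturity gap at its optimum value in all environments, and disables
#' tolerance and susceptibility heterogeneity. Useful as the null
#' configuration for type-I-error and variance-component recovery studies,
#' where every environment is exchangeable.
#'
#' @param config A [sim_config()].
#' @return The modified configuration.
#' @export
no_stress <- function(config) {
  tr <- config$traits
  tr$hse[tr$response == "multiplicative"] <- 1
  tr$hdse[tr$response == "multiplicative"] <- 1
  tr$hse[tr$response == "shift"] <- 0
  tr$hdse[tr$response == "shift"] <- 0
  config$traits <- tr
  config$maturity_gap[] <- config$maturity_gap[["OE"]]
  config$tolerance_bonus <- 0
  config$susceptibility_sd <- 0
  config$n_true_tolerant <- 0L
  config
}

#' Simulate a study-shaped multi-environment trial
#'
#' Generates a balanced plot-level dataset under the model described in
#' [sim_config()], together with the ground truth used to plant it.
#' Identical `(config, seed)` pairs yield bit-identical datasets. One master
#' stream (seeded by `seed`) draws all genotype-level and year-level
#' effects; per-location sub-seeds derived from it drive the
#' location-specific draws, so a location's data only depend on the master
#' seed and its own sub-stream.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed governing all randomness.
#' @return A list of class `met_sim` with `data` (plot-level tibble in
#'   canonical long format, 11 trait columns) and `truth` (list: tolerant
#'   genotype ids, susceptibility factors, per-genotype effective SY
#'   multipliers per environment, genotype effects per trait, expected
#'   stress intensities, the config and seed).
#' @export
#' @examples
#' sim <- simulate_met(sim_config(), seed = 1)
#' nrow(sim$data) # 34 genotypes x 2 locations x 2 years x 3 envs x 2 reps
simulate_met <- function(config = sim_config(), seed) {
  validate_config(config)
  if (missing(seed)) abort("`seed` is required: all randomness is explicit.")
  set.seed(as.integer(seed))
  cfg <- config
  nG <- cfg$n_genotypes
  nY <- length(cfg$years)
  nR <- cfg$n_replicates
  nB <- cfg$blocks_per_replicate
  envs <- env_levels()
  genotypes <- sprintf("G%02d", seq_len(nG))
  tr <- cfg$traits
  vf <- cfg$varfrac

  # --- master-stream draws: genotype- and year-level effects -------------
  z0 <- rnorm(nG)                       # shared yield "sink strength" latent
  g_eff <- sapply(seq_len(nrow(tr)), function(i) {
    lam <- tr$loading[i]
    tr$sd[i] * vf[["G"]] * (lam * z0 + sqrt(1 - lam^2) * rnorm(nG))
  })
  colnames(g_eff) <- tr$trait
  year_eff <- matrix(vapply(tr$sd, function(s) rnorm(nY, 0, s * vf[["year"]]),
                            numeric(nY)), nrow = nY)
  gy_eff <- lapply(tr$sd, function(s) matrix(rnorm(nG * nY, 0, s * vf[["GY"]]), nG))
  ge_eff <- lapply(tr$sd, function(s) matrix(rnorm(nG * 3, 0, s * vf[["GE"]]), nG))
  names(gy_eff) <- names(ge_eff) <- tr$trait

  tolerant <- if (cfg$n_true_tolerant > 0) sort(sample(nG, cfg$n_true_tolerant)) else integer(0)
  s_fac <- 1 + rnorm(nG, 0, cfg$susceptibility_sd)
  s_fac[tolerant] <- s_fac[tolerant] * (1 - cfg$tolerance_bonus)
  s_fac <- pmax(s_fac, 0)
  if (mean(s_fac) > 0) s_fac <- s_fac / mean(s_fac)

  loc_seeds <- sample.int(.Machine$integer.max - 1, length(cfg$locations))

  # per-trait per-env multiplier / shift lookup
  mult_of <- function(i, env) {
    if (tr$response[i] != "multiplicative") return(rep(1, nG))
    base <- switch(env, OE = 1, HSE = tr$hse[i], HDSE = tr$hdse[i])
    s <- if (tr$trait[i] %in% cfg$susceptible_traits) s_fac else rep(1, nG)
    1 - (1 - base) * s
  }
  shift_of <- function(i, env) {
    if (tr$response[i] != "shift") return(0)
    switch(env, OE = 0, HSE = tr$hse[i], HDSE = tr$hdse[i])
  }

  n_truncated <- 0L
  n_values <- 0L
  out <- vector("list", length(cfg$locations))
  for (li in seq_along(cfg$locations)) {
    set.seed(loc_seeds[li])
    loc <- cfg$locations[li]
    mean_loc <- if (loc == "Banda") tr$mean_banda
      else if (loc == "Jhansi") tr$mean_jhansi
      else (tr$mean_banda + tr$mean_jhansi) / 2
    gl_eff <- sapply(tr$sd, function(s) rnorm(nG, 0, s * vf[["GL"]]))
    colnames(gl_eff) <- tr$trait

    cells <- tidyr::expand_grid(year = cfg$years, environment = envs,
                                replicate = seq_len(nR))
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      yk <- match(cells$year[ci], cfg$years)
      env <- cells$environment[ci]
      ei <- match(env, envs)
      rep_eff <- rnorm(1, 0, vf[["rep"]])      # unit scale, scaled per trait
      block_alloc <- rep(seq_len(nB), length.out = nG)[sample.int(nG)]
      block_eff_u <- rnorm(nB)                 # unit scale block effects
      plot <- tibble::tibble(
        genotype = genotypes,
        location = loc,
        year = cells$year[ci],
        environment = env,
        replicate = cells$replicate[ci],
        block = block_alloc
      )
      for (i in seq_len(nrow(tr))) {
        s <- tr$sd[i]
        base <- mean_loc[i] + shift_of(i, env) + year_eff[yk, i] +
          g_eff[, i] + gl_eff[, i] + gy_eff[[i]][, yk] + ge_eff[[i]][, ei] +
          s * rep_eff + s * vf[["block"]] * block_eff_u[block_alloc] +
          rnorm(nG, 0, s * vf[["eps"]] * cfg$noise_scale)
        val <- base * mult_of(i, env)
        n_values <- n_values + nG
        n_truncated <- n_truncated + sum(val < 0)
        plot[[tr$trait[i]]] <- pmax(val, 0)
      }
      # phenology: DM from DFF plus a positive, stress-shortened gap
      gap <- cfg$maturity_gap[[env]] +
        rnorm(nG, 0, cfg$maturity_gap_sd * cfg$noise_scale)
      plot$DM <- plot$DFF + pmax(gap, 1)
      rows[[ci]] <- plot
    }
    out[[li]] <- dplyr::bind_rows(rows)
  }
  data <- dplyr::bind_rows(out)
  data$BY <- data$SY + data$STRAW
  data$HI <- ifelse(data$BY > 0, 100 * data$SY / data$BY, NA_real_)
  data$STRAW <- NULL
  data <- dplyr::select(data, dplyr::all_of(c(key_cols(), trait_codes())))

  if (n_truncated / n_values > 0.01) {
    warn(sprintf("%.1f%% of simulated values were truncated at 0.",
                 100 * n_truncated / n_values))
  }

  sy_row <- match("SY", tr$trait)
  truth <- list(
    seed = as.integer(seed),
    config = cfg,
    tolerant = genotypes[tolerant],
    susceptibility = setNames(s_fac, genotypes),
    sy_multipliers = tibble::tibble(
      genotype = genotypes,
      OE = mult_of(sy_row, "OE"),
      HSE = mult_of(sy_row, "HSE"),
      HDSE = mult_of(sy_row, "HDSE")
    ),
    genotype_effects = tibble::as_tibble(cbind(
      tibble::tibble(genotype = genotypes), as.data.frame(g_eff)
    )),
    expected_si = c(HSE = 1 - tr$hse[sy_row], HDSE = 1 - tr$hdse[sy_row]),
    variance_components = c(
      G = (tr$sd[sy_row] * vf[["G"]])^2,
      GL = (tr$sd[sy_row] * vf[["GL"]])^2,
      GY = (tr$sd[sy_row] * vf[["GY"]])^2,
      GE = (tr$sd[sy_row] * vf[["GE"]])^2,
      error = (tr$sd[sy_row] * vf[["eps"]] * cfg$noise_scale)^2
    )
  )
  structure(list(data = data, truth = truth), class = "met_sim")
}

#' @export
print.met_sim <- function(x, ...) {
  d <- trial_design(x$data)
  cat(sprintf(
    "Synthetic trial: %d plots (%d genotypes x %d locations x %d years x %d environments x %d reps)\n",
    nrow(x$data), d$n_genotypes, d$n_locations, d$n_years, d$n_environments,
    d$n_replicates))
  if (length(x$truth$tolerant)) {
    cat("True tolerants:", paste(x$truth$tolerant, collapse = ", "), "\n")
  }
  invisible(x)
}
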