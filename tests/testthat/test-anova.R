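test_that("one-way fit matches the hand-computed decomposition", {
  fit <- fit_met_anova(oneway_trial(), "SY", terms = c(genotype = "Gen"))
  tab <- tidy(fit)
  expect_equal(tab$df, c(1L, 2L))
  expect_equal(tab$sumsq, c(16, 4))
  expect_equal(tab$statistic[1], 8)
})

test_that("a constant response yields zero SS and no F statistics", {
  d <- oneway_trial()
  d$SY <- 5
  fit <- fit_met_anova(d, "SY", terms = c(genotype = "Gen"))
  expect_equal(tidy(fit)$sumsq, c(0, 0))
  expect_true(all(is.na(tidy(fit)$statistic)))
})

test_that("the pooled model reproduces the design degrees of freedom", {
  sim <- simulate_met(sim_config(), seed = 21)
  fit <- fit_met_anova(sim$data, "SY")
  tab <- tidy(fit)
  df_of <- function(term) tab$df[tab$term == term]
  expect_equal(df_of("Gen"), 33L)
  expect_equal(df_of("Env"), 2L)
  expect_equal(df_of("Env:Gen"), 66L)
  expect_equal(df_of("Location:Year"), 1L)
  expect_equal(df_of("Rep"), 1L)
  expect_equal(df_of("Block(Rep)"), 2L)
  expect_equal(df_of("Residuals"), 405L)
  # df conservation
  expect_equal(sum(tab$df), nrow(sim$data) - 1L)
})

test_that("per-location fits have the expected structure", {
  sim <- simulate_met(sim_config(), seed = 22)
  fit <- fit_location_anova(sim$data, "NGS", "Jhansi")
  tab <- tidy(fit)
  expect_equal(tab$df[tab$term == "Gen"], 33L)
  expect_equal(tab$df[tab$term == "Year:Env:Gen"], 66L)
  expect_equal(sum(tab$df), 408L - 1L)
  expect_error(fit_location_anova(sim$data, "NGS", "Karnal"),
               class = "metstress_value_error")
})

test_that("sequential SS agree with an explicit group-mean decomposition", {
  d <- toy_factorial()
  fit <- fit_met_anova(d, "SY",
                       terms = c(environment = "Env", genotype = "Gen",
                                 "environment:genotype" = "Env:Gen"))
  tab <- tidy(fit)
  # independent oracle: balanced two-way decomposition from cell means
  y <- d$SY
  grand <- mean(y)
  ge <- tapply(y, list(d$genotype, d$environment), mean)
  gm <- rowMeans(ge)
  em <- colMeans(ge)
  ss_env <- 6 * sum((em - grand)^2)
  ss_gen <- 4 * sum((gm - grand)^2)
  ss_int <- 2 * sum((ge - outer(gm, rep(1, 2)) - outer(rep(1, 3), em) + grand)^2)
  ss_res <- sum((y - ge[cbind(d$genotype, d$environment)])^2)
  expect_equal(tab$sumsq[tab$term == "Env"], ss_env)
  expect_equal(tab$sumsq[tab$term == "Gen"], ss_gen)
  expect_equal(tab$sumsq[tab$term == "Env:Gen"], ss_int)
  expect_equal(tab$sumsq[tab$term == "Residuals"], ss_res)
})

test_that("unbalanced data are rejected, not silently refitted", {
  sim <- small_sim(seed = 23)
  expect_error(fit_met_anova(sim$data[-10, ], "SY"),
               class = "metstress_design_error")
})

test_that("SS are invariant to shifts and quadratic under scaling", {
  sim <- small_sim(seed = 24)
  base <- tidy(fit_met_anova(sim$data, "SY"))$sumsq
  shifted <- sim$data
  shifted$SY <- shifted$SY + 1000
  expect_equal(tidy(fit_met_anova(shifted, "SY"))$sumsq, base, tolerance = 1e-8)
  scaled <- sim$data
  scaled$SY <- scaled$SY * 3
  expect_equal(tidy(fit_met_anova(scaled, "SY"))$sumsq, 9 * base,
               tolerance = 1e-8)
})

test_that("with no planted G-by-E variance the Env:Gen F is near 1", {
  cfg <- no_stress(sim_config(n_genotypes = 12))
  cfg$varfrac[["GE"]] <- 0
  f <- vapply(1:40, function(s) {
    d <- simulate_met(cfg, seed = s)$data
    d <- d[d$location == "Banda", ]
    tab <- tidy(fit_location_anova(d, "SY", "Banda"))
    tab$statistic[tab$term == "Env:Gen"]
  }, numeric(1))
  expect_gt(mean(f), 0.85)
  expect_lt(mean(f), 1.2)
})

test_that("variance components solve the EMS equations", {
  mk_fit <- function(ms) {
    structure(list(
      table = tibble::tibble(
        term = names(ms), df = 1L, sumsq = unname(ms), meansq = unname(ms),
        statistic = NA_real_, p.value = NA_real_, stars = ""
      ),
      design = tibble::tibble(n_genotypes = 10, n_locations = 2, n_years = 2,
                              n_environments = 3, n_replicates = 2,
                              blocks_per_replicate = 2, balanced = TRUE),
      trait = "SY"
    ), class = "met_anova")
  }
  # null model: every MS equals the residual MS -> all components zero
  null <- variance_components(mk_fit(c(
    Gen = 5, `Location:Gen` = 5, `Year:Gen` = 5, `Env:Gen` = 5, Residuals = 5
  )))
  expect_equal(null$variance[null$component != "error"], c(0, 0, 0, 0))
  expect_equal(null$variance[null$component == "error"], 5)
  expect_false(any(null$truncated))

  # hand-solved case: MS chosen so that sigma2_G = 10, GL = 1, GY = 2, GE = 3
  ms_res <- 4
  ms_gl <- ms_res + 12 * 1
  ms_gy <- ms_res + 12 * 2
  ms_ge <- ms_res + 8 * 3
  ms_g <- ms_gl + ms_gy + ms_ge - 2 * ms_res + 24 * 10
  vc <- variance_components(mk_fit(c(
    Gen = ms_g, `Location:Gen` = ms_gl, `Year:Gen` = ms_gy,
    `Env:Gen` = ms_ge, Residuals = ms_res
  )))
  expect_equal(vc$variance, c(10, 1, 2, 3, 4))

  # sampled MS_Gen below the interaction MS -> truncated to 0 and flagged
  tr <- variance_components(mk_fit(c(
    Gen = 5, `Location:Gen` = 9, `Year:Gen` = 9, `Env:Gen` = 9, Residuals = 5
  )))
  expect_equal(tr$variance[tr$component == "G"], 0)
  expect_true(tr$truncated[tr$component == "G"])

  expect_error(variance_components(mk_fit(c(Gen = 5, Residuals = 5))),
               class = "metstress_value_error")
})

test_that("heritability follows the entry-mean formula and its limits", {
  mk_vc <- function(v, l = 1, y = 1, e = 3, r = 2) {
    structure(
      tibble::tibble(component = names(v), variance = unname(v),
                     truncated = FALSE),
      class = c("met_varcomp", class(tibble::tibble())),
      l = l, y = y, e = e, r = r, trait = "SY"
    )
  }
  h <- heritability(mk_vc(c(G = 90, error = 10)))
  expect_equal(h$H2, 100 * 90 / (90 + 10 / 6), tolerance = 1e-12)
  expect_equal(round(h$H2, 1), 98.2)
  expect_equal(heritability(mk_vc(c(G = 0, error = 10)))$H2, 0)
  expect_equal(heritability(mk_vc(c(G = 33, GL = 0, GY = 0, GE = 0, error = 0)))$H2, 100)
  expect_warning(h0 <- heritability(mk_vc(c(G = 0, error = 0))), "zero")
  expect_equal(h0$H2, 0)
})

test_that("variance components recover under multiplicative attenuation", {
  # under stress multipliers the additive genotype variance seen by the
  # pooled ANOVA is scaled by the mean squared multiplier across envs
  cfg <- sim_config()
  cfg$tolerance_bonus <- 0
  cfg$susceptibility_sd <- 0
  cfg$n_true_tolerant <- 0L
  est <- vapply(1:40, function(s) {
    sim <- simulate_met(cfg, seed = s)
    vc <- variance_components(fit_met_anova(sim$data, "SY"))
    vc$variance[vc$component == "G"]
  }, numeric(1))
  # genotype main effects are scaled by the mean multiplier across envs
  m2 <- mean(c(1, 0.80, 0.64))^2
  truth <- unname(simulate_met(cfg, seed = 1)$truth$variance_components["G"])
  expect_lt(abs(median(est) / (m2 * truth) - 1), 0.25)
})
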