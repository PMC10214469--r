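test_that("index formulas match hand arithmetic and edge conventions", {
  for (x in c(1, 50, 790)) expect_equal(sti(x, x, x), 1)
  expect_equal(sti(1000, 500, 1000), 0.5)
  expect_equal(sti(0, 700, 800), 0)
  expect_error(sti(10, 10, 0), class = "metstress_value_error")

  expect_equal(ssi(900, 900, 1000, 800), 0)
  expect_equal(ssi(1000, 800, 1000, 800), 1)
  expect_equal(ssi(1000, 600, 790, 634), 0.4 / (1 - 634 / 790), tolerance = 1e-12)
  expect_equal(round(ssi(1000, 600, 790, 634), 3), 2.026)
  expect_error(ssi(0, 10, 100, 50), class = "metstress_value_error")
  expect_error(ssi(100, 90, 100, 100), class = "metstress_no_stress_error")

  expect_equal(mp(7, 7), 7)
  expect_equal(mp(1000, 500), 750)
  expect_equal(tol(7, 7), 0)
  expect_equal(tol(1000, 500), 500)
  expect_equal(tol(500, 1000), -500)
  # algebraic identity
  expect_equal(mp(1000, 640) - tol(1000, 640) / 2, 640)

  expect_equal(msti(1000, 500, 1000, 500), 0.5)
  expect_equal(msti(1000, 1000, 1000, 500), 4)
  expect_error(msti(10, 10, 10, 0), class = "metstress_value_error")

  expect_equal(gmp(9, 9), 9)
  expect_equal(gmp(100, 400), 200)
})

test_that("AM-GM: geometric mean productivity never exceeds mean productivity", {
  set.seed(1)
  yp <- runif(100, 100, 1200)
  ys <- runif(100, 50, 1100)
  expect_true(all(gmp(yp, ys) <= mp(yp, ys) + 1e-12))
})

test_that("yield summaries pool correctly and compute stress intensity", {
  d <- dplyr::bind_rows(
    make_trial(c("A", "B"), "OE", c(800, 1200)),
    make_trial(c("A", "B"), "HSE", c(400, 600))
  )
  ys <- yield_summary(d, "Banda", "HSE")
  expect_equal(attr(ys, "yp_bar"), 1000)
  expect_equal(attr(ys, "ys_bar"), 500)
  expect_equal(stress_intensity(ys), 0.5)

  # stress equal to optimum -> no contrast
  d2 <- dplyr::bind_rows(
    make_trial(c("A", "B"), "OE", c(800, 1200)),
    make_trial(c("A", "B"), "HSE", c(800, 1200))
  )
  expect_error(yield_summary(d2, "Banda", "HSE"),
               class = "metstress_no_stress_error")
})

test_that("simulated stress intensity tracks the planted multiplier", {
  sis <- vapply(1:12, function(s) {
    d <- simulate_met(sim_config(), seed = s)$data
    stress_intensity(yield_summary(d, "Banda", "HSE"))
  }, numeric(1))
  expect_lt(abs(mean(sis) - 0.2), 3 * max(sd(sis) / sqrt(12), 0.003))
})

test_that("the index table matches an independent scalar recomputation", {
  sim <- simulate_met(sim_config(), seed = 31)
  ys <- yield_summary(sim$data, "Banda", "HDSE")
  tab <- index_table(ys)
  yp_bar <- mean(ys$yp)
  ys_bar <- mean(ys$ys)
  for (i in seq_len(nrow(tab))) {
    yp <- ys$yp[i]; s <- ys$ys[i]
    expect_equal(tab$sti[i], yp * s / yp_bar^2, tolerance = 1e-12)
    expect_equal(tab$ssi[i], (1 - s / yp) / (1 - ys_bar / yp_bar),
                 tolerance = 1e-12)
    expect_equal(tab$mp[i], (yp + s) / 2, tolerance = 1e-12)
    expect_equal(tab$tol[i], yp - s, tolerance = 1e-12)
    expect_equal(tab$msti[i], (s / ys_bar)^2 * yp * s / yp_bar^2,
                 tolerance = 1e-12)
    expect_equal(tab$gmp[i]^2, yp * s, tolerance = 1e-9)
  }
})

test_that("indices obey their scale invariances", {
  t1 <- manual_index_table(c("A", "B", "C"), c(800, 1000, 1200), c(500, 650, 500))
  t2 <- manual_index_table(c("A", "B", "C"), 2 * c(800, 1000, 1200),
                           2 * c(500, 650, 500))
  expect_equal(t2$sti, t1$sti)
  expect_equal(t2$ssi, t1$ssi)
  expect_equal(t2$msti, t1$msti)
  expect_equal(t2$mp, 2 * t1$mp)
  expect_equal(t2$tol, 2 * t1$tol)
  expect_equal(t2$gmp, 2 * t1$gmp)
})

test_that("a stress-gaining genotype is flagged, not clamped", {
  tab <- manual_index_table(c("A", "B"), c(500, 1000), c(1000, 600))
  expect_equal(tab$tol[1], -500)
  expect_true(tab$stress_gain[1])
  expect_false(tab$stress_gain[2])
})

test_that("STI ranks genotypes exactly as GMP at a fixed population mean", {
  tab <- manual_index_table(sprintf("G%d", 1:6),
                            c(800, 950, 1000, 1100, 700, 1200),
                            c(600, 480, 700, 300, 660, 520))
  expect_equal(order(tab$sti), order(tab$gmp))
})

test_that("selection reproduces the published heat-tolerant ordering", {
  # five printed STI values with the study's genotype names; the remaining
  # entries are planted strictly lower
  gen <- c("Local-17", "PDW 274", "HI-8802", "HI-8713", "Local-5",
           sprintf("Other-%02d", 1:29))
  sti_vals <- c(2.16, 1.88, 1.83, 1.54, 1.32, seq(1.2, 0.2, length.out = 29))
  yp <- 1000 * sqrt(sti_vals)  # consistent yp*ys/ybar^2 with ys = yp
  tab <- manual_index_table(gen, yp, yp * 0.8)
  sel <- rank_and_select(tab, k = 5)
  expect_equal(sel$genotype[order(sel$rank)][1:5],
               c("Local-17", "PDW 274", "HI-8802", "HI-8713", "Local-5"))
  expect_setequal(sel$genotype[sel$tolerant],
                  c("Local-17", "PDW 274", "HI-8802", "HI-8713", "Local-5"))
})

test_that("ties are broken by stress yield, then genotype identifier", {
  tab <- manual_index_table(c("B", "A", "C"), c(1000, 1000, 1000),
                            c(500, 500, 500))
  # all indices equal -> order by genotype id
  sel <- rank_and_select(tab, k = 1)
  expect_equal(sel$genotype[sel$rank == 1], "A")
  # higher ys wins before the id
  tab2 <- manual_index_table(c("A", "B"), c(1000, 800), c(400, 500))
  tab2$sti <- c(1, 1)
  sel2 <- rank_and_select(tab2, k = 1)
  expect_equal(sel2$genotype[sel2$rank == 1], "B")
})

test_that("selection boundaries behave", {
  tab <- manual_index_table(c("A", "B", "C"), c(1, 2, 3), c(0.5, 1, 1.5))
  expect_true(all(rank_and_select(tab, k = 3)$tolerant))
  expect_error(rank_and_select(tab, k = 0), class = "metstress_value_error")
  expect_error(rank_and_select(tab, k = 9), class = "metstress_value_error")
})

test_that("top-k summaries average and round at report precision", {
  tab <- manual_index_table(sprintf("G%d", 1:5),
                            c(1279, 1165, 1118, 1035, 957) / 0.79,
                            c(1279, 1165, 1118, 1035, 957) * 0.79)
  s1 <- top_k_summary(tab, k = 1)
  r1 <- dplyr::arrange(rank_and_select(tab, 1), rank)[1, ]
  expect_equal(s1$n, 1L)
  expect_equal(s1$sti, round(r1$sti, 2))
  expect_equal(s1$mp, round(r1$mp))
  # half-away-from-zero at 2 dp: mean of {2.16, 1.88, 1.83, 1.54, 1.32} is
  # 1.746 and must print as 1.75
  tab$sti <- c(2.16, 1.88, 1.83, 1.54, 1.32)
  tab$rank <- 1:5; tab$tolerant <- TRUE; tab$susceptible <- FALSE
  expect_equal(top_k_summary(tab, k = 5)$sti, 1.75)
})

test_that("one-call stress_indices chains the pipeline", {
  sim <- simulate_met(sim_config(), seed = 33)
  idx <- stress_indices(sim$data, "Jhansi", "HSE", k = 5)
  expect_s3_class(idx, "index_table")
  expect_equal(nrow(idx), 34)
  expect_equal(sum(idx$tolerant), 5)
  expect_equal(sort(idx$rank), 1:34)
})
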