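# fixtures built in code; all randomness behind explicit seeds

# minimal valid trial frame from vectors (recycled), single loc/year unless given
make_trial <- function(genotype, environment, value, trait = "SY",
                       location = "Banda", year = "2020-21",
                       replicate = 1L, block = 1L) {
  d <- tibble::tibble(
    genotype = genotype, location = location, year = year,
    environment = environment, replicate = as.integer(replicate),
    block = as.integer(block)
  )
  d[[trait]] <- value
  d
}

# balanced 2-genotype one-way layout: A = {1, 3}, B = {5, 7}
oneway_trial <- function() {
  make_trial(
    genotype = rep(c("A", "B"), each = 2),
    environment = "OE",
    value = c(1, 3, 5, 7),
    replicate = rep(1:2, 2)
  )
}

# 3 genotypes x 2 environments x 2 reps, deterministic values
toy_factorial <- function() {
  g <- rep(c("A", "B", "C"), each = 4)
  e <- rep(rep(c("OE", "HSE"), each = 2), 3)
  r <- rep(1:2, 6)
  val <- c(10, 12, 6, 8,   20, 18, 11, 9,   15, 17, 10, 12)
  make_trial(g, e, val, replicate = r)
}

# small fast simulation for pipeline tests
small_sim <- function(seed = 1, ...) {
  simulate_met(sim_config(n_genotypes = 8, ...), seed = seed)
}

# an index_table built directly from yp/ys vectors (bypasses trial data)
manual_index_table <- function(genotype, yp, ys) {
  s <- structure(
    tibble::tibble(genotype = genotype, yp = yp, ys = ys),
    class = c("yield_summary", class(tibble::tibble())),
    yp_bar = mean(yp), ys_bar = mean(ys), si = 1 - mean(ys) / mean(yp),
    location = "Banda", stress_env = "HSE", trait = "SY"
  )
  index_table(s)
}
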