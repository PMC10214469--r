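# Fixed-effects factorial ANOVA for balanced multi-environment trials.
#
# All factors are treated as fixed at the estimation step (OLS, sequential
# type-I sums of squares, F against the residual mean square), which is what
# the classical mean-squares layout of an alpha-lattice trial report shows.
# The random nature of locations/years/environments is honoured downstream,
# in the expected-mean-squares solve of variance_components().

# pooled-model term list, in reporting order; names are formula terms,
# values are display labels
pooled_terms <- function() {
  c("location"                          = "Location",
    "year"                              = "Year",
    "environment"                       = "Env",
    "genotype"                          = "Gen",
    "location:genotype"                 = "Location:Gen",
    "year:genotype"                     = "Year:Gen",
    "environment:genotype"              = "Env:Gen",
    "location:environment"              = "Location:Env",
    "location:year"                     = "Location:Year",
    "year:environment"                  = "Year:Env",
    "location:year:genotype"            = "Location:Year:Gen",
    "location:environment:genotype"     = "Location:Env:Gen",
    "year:environment:genotype"         = "Year:Env:Gen",
    "location:year:environment"         = "Location:Year:Env",
    "location:year:environment:genotype" = "Location:Year:Env:Gen",
    "replicate"                         = "Rep",
    "replicate:block"                   = "Block(Rep)")
}

location_terms <- function() {
  c("year"                      = "Year",
    "environment"               = "Env",
    "genotype"                  = "Gen",
    "year:genotype"             = "Year:Gen",
    "environment:genotype"      = "Env:Gen",
    "year:environment"          = "Year:Env",
    "year:environment:genotype" = "Year:Env:Gen",
    "replicate"                 = "Rep",
    "replicate:block"           = "Block(Rep)")
}

check_balanced <- function(data) {
  if (!trial_design(data)$balanced) {
    abort(paste0(
      "The design is unbalanced: every genotype must appear exactly once in ",
      "every (location, year, environment, replicate) cell. Sequential sums ",
      "of squares are only reported for balanced data."
    ), class = "metstress_design_error")
  }
  invisible(data)
}

fit_anova_terms <- function(data, trait, terms) {
  check_trait(data, trait)
  factors <- unique(unlist(strsplit(names(terms), ":", fixed = TRUE)))
  stopifnot_df(data, factors)
  check_balanced(data)
  df <- data
  for (f in factors) df[[f]] <- factor(df[[f]])
  # terms involving a constant factor carry no df; drop them
  single <- factors[vapply(factors, function(f) nlevels(df[[f]]) < 2, logical(1))]
  if (length(single)) {
    keep <- !vapply(strsplit(names(terms), ":", fixed = TRUE),
                    function(fs) any(fs %in% single), logical(1))
    terms <- terms[keep]
    if (!length(terms)) {
      abort("No model term has more than one level.", class = "metstress_design_error")
    }
  }
  if (any(is.na(df[[trait]]))) {
    abort(sprintf("Trait `%s` has missing values; the balanced ANOVA requires complete data.",
                  trait), class = "metstress_value_error")
  }
  rhs <- paste(names(terms), collapse = " + ")
  fit <- lm(as.formula(paste0("`", trait, "` ~ ", rhs)), data = df)
  if (fit$df.residual == 0) {
    abort("Residual degrees of freedom are zero; the model saturates the data.",
          class = "metstress_design_error")
  }
  aov_tab <- suppressWarnings(anova(fit))
  lab <- c(terms[rownames(aov_tab)[-nrow(aov_tab)]], "Residuals")
  ms_res <- aov_tab[nrow(aov_tab), "Mean Sq"]
  zero_var <- all(abs(df[[trait]] - mean(df[[trait]])) < .Machine$double.eps^0.5 *
                    (1 + abs(mean(df[[trait]]))))
  tab <- tibble::tibble(
    term = unname(lab),
    df = as.integer(aov_tab$Df),
    sumsq = aov_tab$`Sum Sq`,
    meansq = aov_tab$`Mean Sq`,
    statistic = aov_tab$`F value`,
    p.value = aov_tab$`Pr(>F)`
  )
  if (zero_var) {
    tab$statistic <- NA_real_
    tab$p.value <- NA_real_
  }
  tab$stars <- p_stars(tab$p.value)
  tab$stars[tab$term == "Residuals"] <- ""
  tab <- tab[order(match(tab$term, c(unname(terms), "Residuals"))), ]
  structure(
    list(table = tab, trait = trait, terms = terms,
         ms_residual = ms_res, df_residual = fit$df.residual,
         design = trial_design(data), n = nrow(df)),
    class = "met_anova"
  )
}

#' Pooled factorial ANOVA across locations, years and environments
#'
#' Fits the combined fixed-effects model for one trait on a balanced trial:
#' sequential (type-I) sums of squares for, in order, Location, Year, Env,
#' Gen, their printed two-, three- and four-way interactions with genotype,
#' Rep and Block(Rep) (the intra-block term of the alpha lattice), with F
#' tests against the residual mean square and significance codes at
#' 0.05 (`*`), 0.01 (`**`) and 0.001 (`***`). Interactions not in this list
#' are absorbed by the residual. Unbalanced data are rejected rather than
#' silently switched to another sum-of-squares type.
#'
#' @inheritParams genotype_env_means
#' @return An object of class `met_anova`: a list with `table` (tibble of
#'   term, df, sumsq, meansq, statistic, p.value, stars), `ms_residual`,
#'   `df_residual`, `design` and `trait`. Use [tidy()] / [glance()] to
#'   extract tibbles.
#' @param terms Optional named character vector giving the ordered model
#'   terms: names are formula terms built from the design columns (e.g.
#'   `"environment:genotype"`), values the display labels. Defaults to the
#'   full pooled term list.
#' @export
fit_met_anova <- function(data, trait, terms = pooled_terms()) {
  fit_anova_terms(data, trait, terms)
}

#' Per-location factorial ANOVA across environments
#'
#' As [fit_met_anova()], restricted to one location, with term list Year,
#' Env, Gen, Year:Gen, Env:Gen, Year:Env:Gen, Rep, Block(Rep).
#'
#' @inheritParams fit_met_anova
#' @param location Location to analyse.
#' @export
fit_location_anova <- function(data, trait, location) {
  if (!location %in% data$location) {
    abort(sprintf("Location `%s` is not present in the data.", location),
          class = "metstress_value_error")
  }
  fit <- fit_anova_terms(dplyr::filter(data, .data$location == .env$location),
                         trait, location_terms())
  fit$location <- location
  fit
}

#' @export
print.met_anova <- function(x, ...) {
  cat(sprintf("Factorial ANOVA for %s (%d plots, residual df %d)\n",
              x$trait, x$n, x$df_residual))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' @rdname fit_met_anova
#' @param x A `met_anova` object.
#' @param ... Unused.
#' @export
tidy.met_anova <- function(x, ...) x$table

#' @rdname fit_met_anova
#' @export
glance.met_anova <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    n = x$n,
    df_residual = x$df_residual,
    ms_residual = x$ms_residual,
    total_ss = sum(x$table$sumsq)
  )
}

#' Variance components from expected mean squares
#'
#' Method-of-moments solve of the expected-mean-squares equations of the
#' balanced factorial, treating genotypes and their interactions with
#' location, year and environment as random. With `l` locations, `y` years,
#' `e` environments and `r` replicates:
#' \deqn{\hat\sigma^2_{GL} = (MS_{GL} - MS_e)/(y e r)}
#' \deqn{\hat\sigma^2_{GY} = (MS_{GY} - MS_e)/(l e r)}
#' \deqn{\hat\sigma^2_{GE} = (MS_{GE} - MS_e)/(l y r)}
#' \deqn{\hat\sigma^2_{G} = (MS_G - MS_{GL} - MS_{GY} - MS_{GE} + 2 MS_e)/(l y e r)}
#' For a single-location fit the `GL` term is absent and drops out of the
#' solve. Negative solutions are truncated to zero and flagged.
#'
#' @param fit A `met_anova` object from [fit_met_anova()] (or
#'   [fit_location_anova()]).
#' @return A tibble of class `met_varcomp` with `component`, `variance`,
#'   `truncated`, and the design divisors as attributes.
#' @export
variance_components <- function(fit) {
  if (!inherits(fit, "met_anova")) abort("`fit` must be a `met_anova` object.")
  tab <- fit$table
  ms <- function(term) {
    i <- match(term, tab$term)
    if (is.na(i)) abort(sprintf("Required ANOVA term `%s` is missing.", term),
                        class = "metstress_value_error")
    tab$meansq[i]
  }
  d <- fit$design
  l <- d$n_locations; y <- d$n_years; e <- d$n_environments; r <- d$n_replicates
  has_gl <- "Location:Gen" %in% tab$term
  ms_res <- ms("Residuals")
  raw <- c(
    G = NA_real_,
    GL = if (has_gl) (ms("Location:Gen") - ms_res) / (y * e * r) else NA_real_,
    GY = (ms("Year:Gen") - ms_res) / (l * e * r),
    GE = (ms("Env:Gen") - ms_res) / (l * y * r),
    error = ms_res
  )
  raw["G"] <- if (has_gl) {
    (ms("Gen") - ms("Location:Gen") - ms("Year:Gen") - ms("Env:Gen") + 2 * ms_res) /
      (l * y * e * r)
  } else {
    (ms("Gen") - ms("Year:Gen") - ms("Env:Gen") + ms_res) / (y * e * r)
  }
  keep <- !is.na(raw)
  out <- tibble::tibble(
    component = names(raw)[keep],
    variance = unname(pmax(raw[keep], 0)),
    truncated = unname(raw[keep] < 0)
  )
  structure(out, class = c("met_varcomp", class(out)),
            l = l, y = y, e = e, r = r, trait = fit$trait)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GL}/l + \sigma^2_{GY}/y
#'   + \sigma^2_{GE}/e + \sigma^2_\varepsilon/(l y e r)} \times 100}
#' the proportion of variance among genotype (entry) means across the whole
#' trial that is genotypic, as a percentage clamped to \[0, 100\]. Components
#' absent from `vc` (e.g. `GL` in a single-location fit) contribute zero.
#'
#' @param vc A `met_varcomp` tibble from [variance_components()].
#' @return A one-row tibble with `H2` (percent), the components used and the
#'   divisors `l`, `y`, `e`, `r`.
#' @export
heritability <- function(vc) {
  if (!inherits(vc, "met_varcomp")) abort("`vc` must be a `met_varcomp` object.")
  get <- function(cmp) {
    v <- vc$variance[match(cmp, vc$component)]
    if (is.na(v)) 0 else v
  }
  l <- attr(vc, "l"); y <- attr(vc, "y"); e <- attr(vc, "e"); r <- attr(vc, "r")
  s2g <- get("G")
  denom <- s2g + get("GL") / l + get("GY") / y + get("GE") / e +
    get("error") / (l * y * e * r)
  if (denom == 0) {
    warn("All variance components are zero; H2 reported as 0.")
    h2 <- 0
  } else {
    h2 <- min(max(100 * s2g / denom, 0), 100)
  }
  tibble::tibble(trait = attr(vc, "trait"), H2 = h2,
                 sigma2_G = s2g, denominator = denom,
                 l = l, y = y, e = e, r = r)
}

#' Pairwise post-hoc comparisons with LSD or Tukey HSD
#'
#' Compares the levels of one factor after a one-way fit on balanced groups.
#' The least-significant-difference critical value is
#' \eqn{t_{1-\alpha/2,\,df_e} \sqrt{2 MS_e / n}} and the Tukey
#' honest-significant-difference critical value is
#' \eqn{q_{\alpha,\,k,\,df_e} \sqrt{MS_e / n}}, with `n` the common group
#' size. A pair is significant only when its absolute mean difference
#' strictly exceeds the critical value. A compact letter display groups
#' levels whose means are not significantly different; because the critical
#' value is common to all pairs in a balanced layout, the letter groups are
#' the maximal runs of the sorted means whose range does not exceed it.
#'
#' @inheritParams genotype_env_means
#' @param factor_col Column whose levels are compared (e.g. `"genotype"`,
#'   `"environment"`).
#' @param method `"LSD"` or `"TukeyHSD"`.
#' @param alpha Significance level (default 0.05).
#' @param ms_error,df_error Optional error mean square and df to use (e.g.
#'   the residual of a [fit_met_anova()]); by default the one-way residual.
#' @return A list of class `met_posthoc`: `pairs` (tibble of level pairs,
#'   difference, critical value, significance), `groups` (tibble of level,
#'   mean, letters), `critical`, `method`, `alpha`.
#' @export
post_hoc <- function(data, trait, factor_col, method = c("LSD", "TukeyHSD"),
                     alpha = 0.05, ms_error = NULL, df_error = NULL) {
  method <- match.arg(method)
  check_trait(data, trait)
  stopifnot_df(data, factor_col)
  groups <- data |>
    dplyr::filter(!is.na(.data[[trait]])) |>
    dplyr::group_by(level = .data[[factor_col]]) |>
    dplyr::summarise(mean = mean(.data[[trait]]), n = dplyr::n(), .groups = "drop")
  k <- nrow(groups)
  if (k < 2) abort("At least two factor levels are required.",
                   class = "metstress_value_error")
  if (dplyr::n_distinct(groups$n) != 1) {
    abort("Groups must be balanced (equal n).", class = "metstress_design_error")
  }
  n <- groups$n[1]
  if (is.null(ms_error) || is.null(df_error)) {
    fml <- as.formula(paste0("`", trait, "` ~ factor(`", factor_col, "`)"))
    fit <- lm(fml, data = data)
    ms_error <- sum(fit$residuals^2) / fit$df.residual
    df_error <- fit$df.residual
  }
  crit <- switch(method,
    LSD = qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n),
    TukeyHSD = qtukey(1 - alpha, k, df_error) * sqrt(ms_error / n)
  )
  pairs <- utils::combn(seq_len(k), 2)
  pair_tab <- tibble::tibble(
    level1 = groups$level[pairs[1, ]],
    level2 = groups$level[pairs[2, ]],
    difference = groups$mean[pairs[1, ]] - groups$mean[pairs[2, ]],
    critical = crit,
    significant = abs(groups$mean[pairs[1, ]] - groups$mean[pairs[2, ]]) > crit
  )
  groups <- dplyr::arrange(groups, dplyr::desc(.data$mean))
  # maximal non-significant runs over sorted means -> letters; ends[] is
  # monotone because the means are sorted, so run i is maximal iff it
  # reaches further than run i - 1
  ends <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && groups$mean[i] - groups$mean[j + 1] <= crit) j <- j + 1
    as.integer(j)
  }, integer(1))
  starts <- which(ends > dplyr::lag(ends, default = 0L))
  letters_vec <- rep("", k)
  for (ri in seq_along(starts)) {
    idx <- starts[ri]:ends[starts[ri]]
    letters_vec[idx] <- paste0(letters_vec[idx], letters[(ri - 1) %% 26 + 1])
  }
  groups$letters <- letters_vec
  structure(list(pairs = pair_tab, groups = groups, critical = crit,
                 method = method, alpha = alpha,
                 ms_error = ms_error, df_error = df_error),
            class = "met_posthoc")
}

#' @export
print.met_posthoc <- function(x, ...) {
  cat(sprintf("%s comparisons (alpha = %g, critical value %.4g)\n",
              x$method, x$alpha, x$critical))
  print(x$groups)
  invisible(x)
}
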