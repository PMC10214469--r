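# Trait association within an environment.
#
# The unit of analysis is the genotype mean within one environment, pooled
# over locations, years and replicates (n = number of genotypes), which is
# the scale at which trial reports correlate agronomic traits; plot-level
# correlation is available behind `unit = "plot"`.

env_unit_data <- function(data, environment, unit = c("genotype", "plot"),
                          traits = intersect(trait_codes(), names(data))) {
  unit <- match.arg(unit)
  stopifnot_df(data, c(key_cols(), traits))
  if (!environment %in% data$environment) {
    abort(sprintf("Environment `%s` is not present in the data.", environment),
          class = "metstress_value_error")
  }
  sub <- dplyr::filter(data, .data$environment == .env$environment)
  if (unit == "plot") {
    return(dplyr::select(sub, dplyr::all_of(c("genotype", traits))))
  }
  sub |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Pearson correlation matrix of traits within an environment
#'
#' Pairwise-complete Pearson correlations between all traits on genotype
#' means within one environment (pooled over locations and years), with
#' two-sided t-test p-values on `n - 2` degrees of freedom and significance
#' stars at 0.05 (`*`) and 0.01 (`**`). Traits with zero variance are
#' reported as missing with a warning.
#'
#' @inheritParams validate_trials
#' @param environment Environment label (`OE`, `HSE` or `HDSE`).
#' @param unit `"genotype"` (default: genotype means) or `"plot"`.
#' @param traits Trait codes to correlate; defaults to all present.
#' @return An object of class `met_cor`: list with matrices `r`, `p`,
#'   `n`, `stars` and the environment. Use [tidy()] for a long tibble.
#' @export
trait_correlations <- function(data, environment, unit = c("genotype", "plot"),
                               traits = intersect(trait_codes(), names(data))) {
  ud <- env_unit_data(data, environment, unit, traits)
  traits <- intersect(traits, names(ud))
  m <- as.matrix(ud[traits])
  if (nrow(m) < 3) {
    abort("At least 3 observations are required per trait pair.",
          class = "metstress_value_error")
  }
  const <- vapply(traits, function(tr) {
    v <- m[, tr][!is.na(m[, tr])]
    length(v) > 0 && sd(v) == 0
  }, logical(1))
  if (any(const)) {
    warn(sprintf("Trait(s) with zero variance reported as missing: %s.",
                 paste(traits[const], collapse = ", ")))
  }
  k <- length(traits)
  r <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        r[i, j] <- 1; nn[i, j] <- sum(!is.na(m[, i]))
        next
      }
      if (const[i] || const[j]) next
      ok <- complete.cases(m[, c(i, j)])
      nij <- sum(ok)
      nn[i, j] <- nij
      if (nij < 3) next
      r[i, j] <- cor(m[ok, i], m[ok, j])
      tstat <- r[i, j] * sqrt((nij - 2) / max(1 - r[i, j]^2, .Machine$double.eps))
      p[i, j] <- 2 * pt(-abs(tstat), nij - 2)
    }
  }
  stars <- matrix(p_stars(p, c("0.01" = "**", "0.05" = "*")), k, k,
                  dimnames = dimnames(p))
  structure(list(r = r, p = p, n = nn, stars = stars,
                 environment = environment, unit = match.arg(unit)),
            class = "met_cor")
}

#' @export
print.met_cor <- function(x, ...) {
  cat(sprintf("Pearson correlations (%s, %s means)\n", x$environment, x$unit))
  disp <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  print(noquote(disp))
  invisible(x)
}

#' @rdname trait_correlations
#' @param x A `met_cor` object.
#' @param ... Unused.
#' @export
tidy.met_cor <- function(x, ...) {
  traits <- rownames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    environment = x$environment,
    trait1 = traits[idx[, 1]],
    trait2 = traits[idx[, 2]],
    r = x$r[idx],
    n = x$n[idx],
    p.value = x$p[idx],
    stars = x$stars[idx]
  )
}

#' Simple regression of seed yield on one trait
#'
#' Ordinary least squares of the response (default `SY`) on a single
#' predictor trait, on genotype means within one environment. The reported
#' `r.squared` equals the squared Pearson correlation of the pair.
#'
#' @inheritParams trait_correlations
#' @param predictor Predictor trait code.
#' @param response Response trait code (default `SY`).
#' @return A one-row tibble with `environment`, `predictor`, `response`,
#'   `slope`, `intercept`, `r.squared`, `n`.
#' @export
yield_regression <- function(data, environment, predictor, response = "SY",
                             unit = c("genotype", "plot")) {
  check_trait(data, predictor)
  check_trait(data, response)
  ud <- env_unit_data(data, environment, unit, c(predictor, response))
  ok <- complete.cases(ud[c(predictor, response)])
  ud <- ud[ok, ]
  if (sd(ud[[predictor]]) == 0) {
    abort(sprintf("Predictor `%s` has zero variance.", predictor),
          class = "metstress_value_error")
  }
  fit <- lm(ud[[response]] ~ ud[[predictor]])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ud[[response]] - mean(ud[[response]]))^2)
  tibble::tibble(
    environment = environment,
    predictor = predictor,
    response = response,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r.squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    n = nrow(ud)
  )
}

#' Rank single-trait predictors of seed yield
#'
#' Fits [yield_regression()] for every candidate predictor within one
#' environment and orders them by decreasing R-squared (ties broken by
#' trait code). Zero-variance predictors are skipped with a warning.
#'
#' @inheritParams yield_regression
#' @param predictors Candidate predictor traits; defaults to every trait
#'   present except the response.
#' @return A tibble of regression results, best predictor first.
#' @export
rank_predictors <- function(data, environment, response = "SY",
                            predictors = setdiff(intersect(trait_codes(), names(data)),
                                                 response),
                            unit = c("genotype", "plot")) {
  if (length(predictors) < 1) {
    abort("At least one predictor is required.", class = "metstress_value_error")
  }
  rows <- purrr::map(predictors, function(pr) {
    tryCatch(yield_regression(data, environment, pr, response, unit),
             metstress_value_error = function(e) NULL)
  })
  skipped <- predictors[vapply(rows, is.null, logical(1))]
  if (length(skipped)) {
    warn(sprintf("Skipped zero-variance predictor(s): %s.",
                 paste(skipped, collapse = ", ")))
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(dplyr::desc(.data$r.squared), .data$predictor)
}
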