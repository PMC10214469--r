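# internal helpers shared across modules

# round half away from zero at d decimals (report-table convention; base
# round() is half-to-even and would turn 1.75 -> 1.8 but 4.65 -> 4.6)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# significance codes for p-values; `levels` gives the cut/star pairs in
# decreasing stringency. The trial reports use three stars for ANOVA and
# two for correlations.
p_stars <- function(p, levels = c("0.001" = "***", "0.01" = "**", "0.05" = "*")) {
  cuts <- as.numeric(names(levels))
  out <- rep("", length(p))
  for (i in rev(seq_along(cuts))) out[!is.na(p) & p < cuts[i]] <- levels[[i]]
  out[is.na(p)] <- NA_character_
  out
}

stopifnot_df <- function(data, cols, what = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf(
      "Missing mandatory column%s in `%s`: %s.",
      if (length(missing) > 1) "s" else "", what,
      paste0("`", missing, "`", collapse = ", ")
    ), class = "metstress_schema_error")
  }
  invisible(data)
}

check_trait <- function(data, trait) {
  if (!is.character(trait) || length(trait) != 1) {
    abort("`trait` must be a single trait code.")
  }
  if (!trait %in% names(data)) {
    abort(sprintf("Trait `%s` is not present in the data.", trait),
          class = "metstress_value_error")
  }
  invisible(trait)
}
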