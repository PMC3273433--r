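#' Round half away from zero
#'
#' Deterministic half-up rounding (0.5 rounds away from zero), as used for
#' every printed percentage in the assay tables; base `round()` uses
#' round-half-even and would disagree on ties. A guard of 1e-9 units in the
#' scaled value absorbs binary representation error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return `x` rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Fertility of a cross as a percentage
#'
#' Fertility is pupae generated divided by total eggs laid, reported as an
#' integer percentage (half-up).
#'
#' @param rec a [fecundity_record()].
#' @return A list with `percent` (integer-rounded) and `raw` (unrounded
#'   percentage).
#' @examples
#' fertility_percent(fecundity_record("none", 107, eggs = 6109, pupae = 1568))
#' @export
fertility_percent <- function(rec) {
  stopifnot(inherits(rec, "fecundity_record"))
  if (rec$eggs == 0) {
    abort_domain("fertility undefined: record '%s' has zero eggs", rec$label)
  }
  raw <- 100 * rec$pupae / rec$eggs
  list(percent = as.integer(round_half_up(raw)), raw = raw)
}

#' Progeny-class frequency as a percentage
#'
#' Proportion of a scored class (e.g. X0 sons) among total progeny, times
#' 100, half-up rounded.
#'
#' @param count class count.
#' @param total total progeny scored.
#' @param decimals decimal places to round to (1 for cross tables).
#' @return A single rounded percentage.
#' @examples
#' class_frequency_percent(146, 1283)  # 11.4
#' @export
class_frequency_percent <- function(count, total, decimals = 1) {
  count <- check_count(count, "count")
  total <- check_count(total, "total")
  if (total == 0) abort_domain("class frequency undefined: total is zero")
  if (count > total) {
    abort_validation("count (%d) exceeds total (%d)", count, total)
  }
  round_half_up(100 * count / total, decimals)
}

#' Excess nullo-X statistic
#'
#' Nullo-X eggs without associated diplo-X eggs: `n_x0 - n_xxy`.
#' Nondisjunction produces nullo-X and diplo-X eggs in equal numbers, so any
#' excess of X0 sons over XXY daughters indicates DSB-induced X-chromosome
#' loss rather than symmetric nondisjunction. A negative excess is reported
#' signed, with a warning.
#'
#' @param counts a [cross_counts()] object.
#' @return An object of class `excess_nullo_result` with `excess_count`,
#'   `excess_percent` (of total progeny, 1 decimal) and unset test fields
#'   (`chi2`, `p_value`, `tier` are `NA` until a control comparison is run).
#' @examples
#' excess_nullo(cross_counts("none", 99, 1283, 146, 106))  # 40 (3.1%)
#' @export
excess_nullo <- function(counts) {
  stopifnot(inherits(counts, "cross_counts"))
  if (counts$total_progeny == 0) {
    abort_domain("excess undefined: cross '%s' has zero progeny", counts$label)
  }
  exc <- counts$n_x0 - counts$n_xxy
  if (exc < 0) {
    warn_nullox("cross '%s': negative excess nullo-X (%d); more XXY daughters than X0 sons",
                counts$label, exc)
  }
  structure(
    list(label = counts$label,
         excess_count = exc,
         excess_percent = round_half_up(100 * exc / counts$total_progeny, 1),
         chi2 = NA_real_, p_value = NA_real_, tier = NA_character_),
    class = "excess_nullo_result")
}

#' @export
print.excess_nullo_result <- function(x, ...) {
  cat(sprintf("<excess_nullo_result> %s: excess %d (%.1f%%)", x$label,
              x$excess_count, x$excess_percent))
  if (!is.na(x$p_value)) {
    cat(sprintf(", chi2 = %.4g, P = %.2g [%s]", x$chi2, x$p_value, x$tier))
  }
  cat("\n")
  invisible(x)
}

# Pearson chi-square on a 2x2 table, no continuity correction.
# Any zero margin makes every cell's expectation equal its observation under
# independence, so the statistic is defined as 0 (p = 1).
pearson_2x2 <- function(m) {
  n <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(chi2 = 0, p_value = 1, expected = m * 0, warned = FALSE))
  }
  expected <- outer(rs, cs) / n
  chi2 <- sum((m - expected)^2 / expected)
  warned <- any(expected < 5)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = expected, warned = warned)
}

fisher_2x2 <- function(m) {
  stats::fisher.test(m)$p.value
}

#' Chi-square test of the excess nullo-X statistic against a control
#'
#' Tests whether a cross shows more excess nullo-X progeny than the control
#' cross, on the 2x2 table
#' `[[excess_test, rest_test], [excess_control, rest_control]]` where
#' "rest" is the remaining progeny. Pearson statistic, 1 df, no continuity
#' correction — the construction that reproduces the published P values.
#' A warning is emitted when any expected cell is below 5, and a Fisher
#' exact P value is then reported alongside (never substituted).
#'
#' @param test,control [cross_counts()] objects.
#' @param fisher also compute the Fisher exact P value regardless of cell
#'   sizes.
#' @return A list with `chi2`, `p_value`, `df`, `tier`, `table`, and
#'   `fisher_p` (`NA` unless requested or triggered by small cells).
#' @examples
#' none <- cross_counts("none", 99, 1283, 146, 106)
#' at2  <- cross_counts("AtSPO11-2", 71, 1187, 178, 88)
#' chi_square_excess(at2, none)$p_value  # ~6.9e-07
#' @export
chi_square_excess <- function(test, control, fisher = FALSE) {
  stopifnot(inherits(test, "cross_counts"), inherits(control, "cross_counts"))
  if (test$total_progeny == 0 || control$total_progeny == 0) {
    abort_domain("chi-square undefined: a cross has zero progeny")
  }
  e_t <- test$n_x0 - test$n_xxy
  e_c <- control$n_x0 - control$n_xxy
  if (e_t < 0 || e_c < 0) {
    warn_nullox("negative excess nullo-X count truncated to 0 for the contingency table")
  }
  e_t <- max(0L, e_t)
  e_c <- max(0L, e_c)
  m <- matrix(c(e_t, test$total_progeny - e_t,
                e_c, control$total_progeny - e_c),
              nrow = 2, byrow = TRUE,
              dimnames = list(c(test$label, control$label),
                              c("excess", "rest")))
  res <- pearson_2x2(m)
  if (res$warned) {
    warn_nullox("expected cell count below 5 in excess chi-square ('%s' vs '%s'); Fisher exact P reported alongside",
                test$label, control$label)
  }
  fp <- if (fisher || res$warned) fisher_2x2(m) else NA_real_
  list(chi2 = res$chi2, p_value = res$p_value, df = 1L,
       tier = significance_tier(res$p_value), table = m, fisher_p = fp)
}

#' Chi-square test of cytology proportions against a control
#'
#' Pearson chi-square (no continuity correction) on the 2x2 table of
#' positive/negative oocyte-nucleus counts for a transgene genotype versus
#' the no-transgene control, as used to assign significance tiers to the
#' DSB-signal and karyosome-defect frequencies.
#'
#' @param test,control [cytology_counts()] objects (same endpoint expected;
#'   a mismatch warns).
#' @return A list with `chi2`, `p_value`, `df`, `tier`, `table`.
#' @export
chi_square_cytology <- function(test, control) {
  stopifnot(inherits(test, "cytology_counts"),
            inherits(control, "cytology_counts"))
  if (test$n_total == 0 || control$n_total == 0) {
    abort_domain("chi-square undefined: zero oocyte nuclei observed")
  }
  if (test$endpoint != control$endpoint) {
    warn_nullox("comparing different cytology endpoints ('%s' vs '%s')",
                test$endpoint, control$endpoint)
  }
  m <- matrix(c(test$n_positive, test$n_total - test$n_positive,
                control$n_positive, control$n_total - control$n_positive),
              nrow = 2, byrow = TRUE,
              dimnames = list(c(test$label, control$label),
                              c("positive", "negative")))
  res <- pearson_2x2(m)
  if (res$warned) {
    warn_nullox("expected cell count below 5 in cytology chi-square ('%s' vs '%s')",
                test$label, control$label)
  }
  list(chi2 = res$chi2, p_value = res$p_value, df = 1L,
       tier = significance_tier(res$p_value), table = m)
}

#' Significance tier label for a P value
#'
#' The star convention of the assay figures: `"***"` for P < 1e-3, `"**"`
#' for 1e-3 <= P < 1e-2, `"*"` for 1e-2 <= P < 5e-2, `"ns"` otherwise.
#' Boundary values fall in the weaker tier (P = 1e-3 is `"**"`).
#'
#' @param p_value a probability.
#' @return One of `"***"`, `"**"`, `"*"`, `"ns"`.
#' @export
significance_tier <- function(p_value) {
  p_value <- check_probability(p_value, "p_value")
  if (p_value < 1e-3) "***"
  else if (p_value < 1e-2) "**"
  else if (p_value < 5e-2) "*"
  else "ns"
}

#' Wilson score interval for a binomial proportion
#'
#' @param count successes.
#' @param total trials (> 0).
#' @param level confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' binomial_ci(254, 278)  # around 0.914
#' @export
binomial_ci <- function(count, total, level = 0.95) {
  count <- check_count(count, "count")
  total <- check_count(total, "total")
  if (total == 0) abort_domain("binomial interval undefined: total is zero")
  if (count > total) abort_validation("count (%d) exceeds total (%d)", count, total)
  level <- check_probability(level, "level")
  if (level <= 0 || level >= 1) {
    abort_domain("confidence level must be in (0, 1), got %s", format(level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- count / total
  z2 <- z^2
  centre <- (p + z2 / (2 * total)) / (1 + z2 / total)
  half <- z * sqrt(p * (1 - p) / total + z2 / (4 * total^2)) / (1 + z2 / total)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
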