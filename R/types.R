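#' Scored progeny counts of one cross
#'
#' Container for the progeny classes scored in an X-chromosome
#' nondisjunction assay: mothers carrying a recessive X-linked marker are
#' crossed to wild-type males, nullo-X eggs are detected as X0 sons and
#' diplo-X eggs as XXY daughters. All remaining progeny are pooled in
#' `n_other`.
#'
#' @param label genotype/transgene identifier.
#' @param mothers number of mothers crossed.
#' @param total_progeny total progeny scored.
#' @param n_x0 number of X0 sons (nullo-X eggs).
#' @param n_xxy number of XXY daughters (diplo-X eggs).
#' @return An object of class `cross_counts` with fields `label`, `mothers`,
#'   `total_progeny`, `n_x0`, `n_xxy` and the derived `n_other`.
#' @examples
#' cross_counts("none", mothers = 99, total_progeny = 1283,
#'              n_x0 = 146, n_xxy = 106)
#' @export
cross_counts <- function(label, mothers, total_progeny, n_x0, n_xxy) {
  stopifnot(is.character(label), length(label) == 1L)
  mothers       <- check_count(mothers, "mothers")
  total_progeny <- check_count(total_progeny, "total_progeny")
  n_x0          <- check_count(n_x0, "n_x0")
  n_xxy         <- check_count(n_xxy, "n_xxy")
  if (n_x0 + n_xxy > total_progeny) {
    abort_validation(
      "cross '%s': n_x0 (%d) + n_xxy (%d) exceeds total_progeny (%d)",
      label, n_x0, n_xxy, total_progeny)
  }
  structure(
    list(label = label, mothers = mothers, total_progeny = total_progeny,
         n_x0 = n_x0, n_xxy = n_xxy,
         n_other = total_progeny - n_x0 - n_xxy),
    class = "cross_counts")
}

#' @export
print.cross_counts <- function(x, ...) {
  cat(sprintf("<cross_counts> %s: %d mothers, %d progeny (X0 sons %d, XXY daughters %d, other %d)\n",
              x$label, x$mothers, x$total_progeny, x$n_x0, x$n_xxy, x$n_other))
  invisible(x)
}

#' Fecundity record of one cross
#'
#' Eggs laid and pupae generated for a set of mothers; the ratio defines
#' fertility (see [fertility_percent()]).
#'
#' @param label genotype/transgene identifier.
#' @param mothers number of mothers crossed.
#' @param eggs total eggs laid.
#' @param pupae pupae generated from those eggs.
#' @return An object of class `fecundity_record`.
#' @export
fecundity_record <- function(label, mothers, eggs, pupae) {
  stopifnot(is.character(label), length(label) == 1L)
  mothers <- check_count(mothers, "mothers")
  eggs    <- check_count(eggs, "eggs")
  pupae   <- check_count(pupae, "pupae")
  if (pupae > eggs) {
    abort_validation("record '%s': pupae (%d) exceed eggs laid (%d)",
                     label, pupae, eggs)
  }
  structure(list(label = label, mothers = mothers, eggs = eggs, pupae = pupae),
            class = "fecundity_record")
}

#' @export
print.fecundity_record <- function(x, ...) {
  cat(sprintf("<fecundity_record> %s: %d mothers, %d eggs, %d pupae\n",
              x$label, x$mothers, x$eggs, x$pupae))
  invisible(x)
}

#' Oocyte-nucleus cytology counts
#'
#' Number of oocyte nuclei positive for a cytological endpoint — gamma-H2Av
#' DSB foci (`"dsb_signal"`, scored in stage 2-8 egg chambers) or defective
#' karyosome morphology (`"karyosome_defect"`, stage 3-8) — out of all
#' oocyte nuclei observed across the dissected ovaries.
#'
#' @param label genotype/transgene identifier.
#' @param endpoint `"dsb_signal"` or `"karyosome_defect"`.
#' @param stage_range free-text egg-chamber stage range, e.g. `"2-8"`.
#' @param n_positive nuclei positive for the endpoint.
#' @param n_total nuclei observed.
#' @param ovaries number of ovaries scored (carried metadata).
#' @return An object of class `cytology_counts`.
#' @export
cytology_counts <- function(label, endpoint, stage_range,
                            n_positive, n_total, ovaries) {
  stopifnot(is.character(label), length(label) == 1L)
  endpoint <- match.arg(endpoint, c("dsb_signal", "karyosome_defect"))
  stopifnot(is.character(stage_range), length(stage_range) == 1L)
  n_positive <- check_count(n_positive, "n_positive")
  n_total    <- check_count(n_total, "n_total")
  ovaries    <- check_count(ovaries, "ovaries")
  if (n_positive > n_total) {
    abort_validation("cytology '%s': n_positive (%d) exceeds n_total (%d)",
                     label, n_positive, n_total)
  }
  structure(
    list(label = label, endpoint = endpoint, stage_range = stage_range,
         n_positive = n_positive, n_total = n_total, ovaries = ovaries),
    class = "cytology_counts")
}

#' @export
print.cytology_counts <- function(x, ...) {
  cat(sprintf("<cytology_counts> %s [%s, stages %s]: %d/%d positive (%d ovaries)\n",
              x$label, x$endpoint, x$stage_range,
              x$n_positive, x$n_total, x$ovaries))
  invisible(x)
}
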