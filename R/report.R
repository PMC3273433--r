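# Table-shaped analysis of cross / fecundity / cytology count lists, and
# assembly of the full report the CLI emits.

find_control <- function(labels, control_label) {
  idx <- which(labels == control_label)
  if (length(idx) == 0) {
    abort_config("unknown control label '%s'; available labels: %s",
                 control_label, paste(unique(labels), collapse = ", "))
  }
  idx[1]
}

#' Analyze a set of crosses against a control
#'
#' Reproduces the derived columns of a nondisjunction assay table: nullo-X
#' and diplo-X egg frequencies (as percentages of total progeny), the excess
#' nullo-X count and percentage, and for every non-control row the
#' chi-square test of the excess against the control with its significance
#' tier. Optionally appends maximum-likelihood estimates of the
#' nondisjunction and loss rates per row.
#'
#' @param crosses list of [cross_counts()] (e.g. from [read_cross_table()]).
#' @param control_label label of the control cross.
#' @param alpha retained in the report metadata; tiers use the fixed star
#'   convention of [significance_tier()].
#' @param fit if `TRUE`, add `d_hat`, `l_hat` and boundary flags per row.
#' @return A data.frame with one row per cross; the control row has `NA`
#'   test fields.
#' @examples
#' crosses <- read_cross_table(
#'   system.file("extdata", "crosses_exp1.tsv", package = "nullox"))
#' analyze_cross(crosses, control_label = "none")
#' @export
analyze_cross <- function(crosses, control_label, alpha = 0.05, fit = FALSE) {
  stopifnot(length(crosses) > 0)
  labels <- vapply(crosses, `[[`, "", "label")
  ctrl <- crosses[[find_control(labels, control_label)]]
  rows <- lapply(crosses, function(cc) {
    exc <- excess_nullo(cc)
    row <- data.frame(
      label = cc$label,
      mothers = cc$mothers,
      total_progeny = cc$total_progeny,
      n_x0_sons = cc$n_x0,
      pct_nullo = class_frequency_percent(cc$n_x0, cc$total_progeny),
      n_xxy_daughters = cc$n_xxy,
      pct_diplo = class_frequency_percent(cc$n_xxy, cc$total_progeny),
      excess_count = exc$excess_count,
      excess_percent = exc$excess_percent,
      chi2 = NA_real_, p_value = NA_real_, tier = NA_character_)
    if (cc$label != control_label) {
      ct <- chi_square_excess(cc, ctrl)
      row$chi2 <- ct$chi2
      row$p_value <- ct$p_value
      row$tier <- ct$tier
    }
    if (fit) {
      f <- fit_mle(cc)
      row$d_hat <- f$d_hat
      row$l_hat <- f$l_hat
      row$l_at_boundary <- unname(f$at_boundary["l"])
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "control_label") <- control_label
  attr(out, "alpha") <- alpha
  out
}

#' Analyze fecundity records
#'
#' @param records list of [fecundity_record()].
#' @return A data.frame with integer `fertility_percent` and the unrounded
#'   `fertility_raw` per row.
#' @export
analyze_fecundity <- function(records) {
  stopifnot(length(records) > 0)
  do.call(rbind, lapply(records, function(r) {
    f <- fertility_percent(r)
    data.frame(label = r$label, mothers = r$mothers, eggs = r$eggs,
               pupae = r$pupae, fertility_percent = f$percent,
               fertility_raw = f$raw)
  }))
}

#' Analyze cytology counts against a control
#'
#' Within each endpoint, compares every genotype to the control genotype by
#' Pearson chi-square on positive/negative nuclei.
#'
#' @param records list of [cytology_counts()].
#' @param control_label label of the no-transgene control.
#' @return A data.frame with percentages, chi-square results and tiers; the
#'   control rows have `NA` test fields.
#' @export
analyze_cytology <- function(records, control_label) {
  stopifnot(length(records) > 0)
  labels <- vapply(records, `[[`, "", "label")
  find_control(labels, control_label)  # fail early if absent entirely
  endpoints <- vapply(records, `[[`, "", "endpoint")
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    row <- data.frame(
      label = r$label, endpoint = r$endpoint, stage_range = r$stage_range,
      n_positive = r$n_positive, n_total = r$n_total, ovaries = r$ovaries,
      pct_positive = class_frequency_percent(r$n_positive, r$n_total),
      chi2 = NA_real_, p_value = NA_real_, tier = NA_character_)
    if (r$label != control_label) {
      j <- which(labels == control_label & endpoints == r$endpoint)
      if (length(j) == 0) {
        warn_nullox("no '%s' control for endpoint '%s'; test fields left unset",
                    control_label, r$endpoint)
      } else {
        ct <- chi_square_cytology(r, records[[j[1]]])
        row$chi2 <- ct$chi2
        row$p_value <- ct$p_value
        row$tier <- ct$tier
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "control_label") <- control_label
  out
}

# Rolling checksum of the configuration string; metadata only.
config_checksum <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble an analysis report
#'
#' Bundles the cross, fecundity and cytology analyses with run metadata
#' (package version, seed, configuration checksum). Every derived value in
#' the report is recomputable from the raw counts carried in the same
#' report.
#'
#' @param crosses list of [cross_counts()], or `NULL`.
#' @param fecundity list of [fecundity_record()], or `NULL`.
#' @param cytology list of [cytology_counts()], or `NULL`.
#' @param control_label control label for cross/cytology comparisons.
#' @param alpha nominal significance level recorded in metadata.
#' @param fit add MLE rate estimates to the cross table.
#' @param seed seed recorded in metadata (`NA` for purely deterministic runs).
#' @return An object of class `analysis_report`: named list of data.frames
#'   plus `metadata`.
#' @export
build_report <- function(crosses = NULL, fecundity = NULL, cytology = NULL,
                         control_label = NULL, alpha = 0.05, fit = FALSE,
                         seed = NA_integer_) {
  if (is.null(crosses) && is.null(fecundity) && is.null(cytology)) {
    abort_config("nothing to report: supply at least one table")
  }
  if ((!is.null(crosses) || !is.null(cytology)) && is.null(control_label)) {
    abort_config("control_label is required for cross or cytology analysis")
  }
  sections <- list()
  if (!is.null(crosses)) {
    sections$cross <- analyze_cross(crosses, control_label, alpha, fit)
  }
  if (!is.null(fecundity)) {
    sections$fecundity <- analyze_fecundity(fecundity)
  }
  if (!is.null(cytology)) {
    sections$cytology <- analyze_cytology(cytology, control_label)
  }
  cfg <- paste(c(control_label, alpha, fit, seed,
                 vapply(sections, function(s) paste(dim(s), collapse = "x"), "")),
               collapse = "|")
  sections$metadata <- data.frame(
    package = "nullox",
    version = as.character(utils::packageVersion("nullox")),
    seed = seed,
    control_label = if (is.null(control_label)) NA_character_ else control_label,
    alpha = alpha,
    config_checksum = config_checksum(cfg))
  structure(sections, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("##", nm, "\n")
    print.data.frame(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' Write an analysis report to TSV or JSON
#'
#' The TSV rendering writes each section under a `# section: <name>` comment
#' line; the JSON rendering mirrors the same tables with floats serialized
#' to 10 significant digits. Outputs are byte-identical across runs with
#' identical inputs and seed.
#'
#' @param report an [build_report()] result.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, dataframe = "rows",
                         digits = NA, auto_unbox = TRUE, na = "null",
                         always_decimal = FALSE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    first <- TRUE
    for (nm in names(report)) {
      if (!first) writeLines("", con)
      first <- FALSE
      writeLines(paste0("# section: ", nm), con)
      df <- report[[nm]]
      is_num <- vapply(df, is.double, logical(1))
      df[is_num] <- lapply(df[is_num], function(x) {
        ifelse(is.na(x), "NA", formatC(signif(x, 10), format = "g", digits = 10))
      })
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
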