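# Canonical on-disk format: UTF-8 TSV, tab-separated, '.' decimal mark,
# '#' comment lines skipped, fixed headers per table kind.

read_tsv_rows <- function(path, required) {
  if (!file.exists(path)) abort_config("input file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort_validation("file '%s' has no header line", path)
  }
  header <- strsplit(lines[keep[1]], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort_validation("file '%s': missing required column(s): %s",
                     path, paste(missing_cols, collapse = ", "))
  }
  body <- keep[-1]
  if (length(body) == 0) {
    warn_nullox("file '%s' contains a header but no data rows", path)
    return(list(rows = list(), lineno = integer(0), header = header))
  }
  rows <- lapply(lines[body], function(x) strsplit(x, "\t", fixed = TRUE)[[1]])
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != length(header)) {
      abort_validation("file '%s', line %d: expected %d fields, found %d",
                       path, body[i], length(header), length(rows[[i]]))
    }
    names(rows[[i]]) <- header
  }
  list(rows = rows, lineno = body, header = header)
}

parse_count_field <- function(value, col, path, lineno) {
  if (!grepl("^[0-9]+$", value)) {
    abort_validation("file '%s', line %d: column '%s' must be a non-negative integer, got '%s'",
                     path, lineno, col, value)
  }
  as.integer(value)
}

#' Read a cross-counts table
#'
#' TSV with header
#' `label<TAB>mothers<TAB>total_progeny<TAB>n_x0_sons<TAB>n_xxy_daughters`;
#' `#` comment lines are skipped. `n_other` is derived and every row is
#' validated against the cross-counts invariants.
#'
#' @param path path to the TSV file.
#' @return A list of [cross_counts()] objects.
#' @examples
#' path <- system.file("extdata", "crosses_exp1.tsv", package = "nullox")
#' read_cross_table(path)
#' @export
read_cross_table <- function(path) {
  req <- c("label", "mothers", "total_progeny", "n_x0_sons", "n_xxy_daughters")
  parsed <- read_tsv_rows(path, req)
  mapply(function(row, ln) {
    tryCatch(
      cross_counts(row[["label"]],
                   parse_count_field(row[["mothers"]], "mothers", path, ln),
                   parse_count_field(row[["total_progeny"]], "total_progeny", path, ln),
                   parse_count_field(row[["n_x0_sons"]], "n_x0_sons", path, ln),
                   parse_count_field(row[["n_xxy_daughters"]], "n_xxy_daughters", path, ln)),
      nullox_validation_error = function(e) {
        abort_validation("file '%s', line %d: %s", path, ln, conditionMessage(e))
      })
  }, parsed$rows, parsed$lineno, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read a fecundity table
#'
#' TSV with header `label<TAB>mothers<TAB>eggs<TAB>pupae`.
#'
#' @inheritParams read_cross_table
#' @return A list of [fecundity_record()] objects.
#' @export
read_fecundity_table <- function(path) {
  req <- c("label", "mothers", "eggs", "pupae")
  parsed <- read_tsv_rows(path, req)
  mapply(function(row, ln) {
    tryCatch(
      fecundity_record(row[["label"]],
                       parse_count_field(row[["mothers"]], "mothers", path, ln),
                       parse_count_field(row[["eggs"]], "eggs", path, ln),
                       parse_count_field(row[["pupae"]], "pupae", path, ln)),
      nullox_validation_error = function(e) {
        abort_validation("file '%s', line %d: %s", path, ln, conditionMessage(e))
      })
  }, parsed$rows, parsed$lineno, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Read a cytology table
#'
#' TSV with header
#' `label<TAB>endpoint<TAB>stage_range<TAB>n_positive<TAB>n_total<TAB>ovaries`.
#'
#' @inheritParams read_cross_table
#' @return A list of [cytology_counts()] objects.
#' @export
read_cytology_table <- function(path) {
  req <- c("label", "endpoint", "stage_range", "n_positive", "n_total", "ovaries")
  parsed <- read_tsv_rows(path, req)
  mapply(function(row, ln) {
    tryCatch(
      cytology_counts(row[["label"]], row[["endpoint"]], row[["stage_range"]],
                      parse_count_field(row[["n_positive"]], "n_positive", path, ln),
                      parse_count_field(row[["n_total"]], "n_total", path, ln),
                      parse_count_field(row[["ovaries"]], "ovaries", path, ln)),
      nullox_validation_error = function(e) {
        abort_validation("file '%s', line %d: %s", path, ln, conditionMessage(e))
      })
  }, parsed$rows, parsed$lineno, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(x) {
    ifelse(is.na(x), "NA", formatC(signif(x, 10), format = "g", digits = 10))
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write count tables back to TSV
#'
#' Writers matching the three readers, so simulated and real tables are
#' interchangeable and write-then-read is the identity.
#'
#' @param x a list of `cross_counts`, `fecundity_record` or
#'   `cytology_counts` objects (a bare object is wrapped).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cross_table <- function(x, path) {
  if (inherits(x, "cross_counts")) x <- list(x)
  df <- data.frame(
    label = vapply(x, `[[`, "", "label"),
    mothers = vapply(x, `[[`, 0L, "mothers"),
    total_progeny = vapply(x, `[[`, 0L, "total_progeny"),
    n_x0_sons = vapply(x, `[[`, 0L, "n_x0"),
    n_xxy_daughters = vapply(x, `[[`, 0L, "n_xxy"))
  write_tsv_table(df, path)
}

#' @rdname write_cross_table
#' @export
write_fecundity_table <- function(x, path) {
  if (inherits(x, "fecundity_record")) x <- list(x)
  df <- data.frame(
    label = vapply(x, `[[`, "", "label"),
    mothers = vapply(x, `[[`, 0L, "mothers"),
    eggs = vapply(x, `[[`, 0L, "eggs"),
    pupae = vapply(x, `[[`, 0L, "pupae"))
  write_tsv_table(df, path)
}

#' @rdname write_cross_table
#' @export
write_cytology_table <- function(x, path) {
  if (inherits(x, "cytology_counts")) x <- list(x)
  df <- data.frame(
    label = vapply(x, `[[`, "", "label"),
    endpoint = vapply(x, `[[`, "", "endpoint"),
    stage_range = vapply(x, `[[`, "", "stage_range"),
    n_positive = vapply(x, `[[`, 0L, "n_positive"),
    n_total = vapply(x, `[[`, 0L, "n_total"),
    ovaries = vapply(x, `[[`, 0L, "ovaries"))
  write_tsv_table(df, path)
}
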