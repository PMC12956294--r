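#' Read a timecourse matrix from delimited text
#'
#' Expects `T` rows by `M` numeric columns (tab, comma or whitespace
#' delimited). A single non-numeric first row is treated as a header and
#' skipped; comment lines starting with `#` are ignored. Any non-finite or
#' non-numeric cell is a parse error naming its location.
#'
#' @param path File path.
#' @param tr_seconds Repetition time in seconds (from the manifest/config);
#'   optional.
#' @param subject_id Optional label.
#' @return A `cddfip_timecourses` object: list with `values` (`T x M`
#'   matrix), `tr_seconds`, `subject_id`.
#' @export
read_timecourses <- function(path, tr_seconds = NA_real_,
                             subject_id = NA_character_) {
  if (!file.exists(path)) {
    abort(sprintf("timecourse file not found: %s", path),
          class = "cddfip_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(sprintf("no data rows in %s", path), class = "cddfip_io_error")
  }
  split_row <- function(l) strsplit(trimws(l), "[\t,]+|\\s+")[[1]]
  first <- suppressWarnings(as.numeric(split_row(lines[1])))
  header <- any(is.na(first))
  if (header) lines <- lines[-1]
  rows <- lapply(lines, split_row)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1) {
    abort(sprintf("ragged rows in %s (widths %s).", path,
                  paste(ncols, collapse = ", ")),
          class = "cddfip_io_error")
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  )
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric or non-finite value at row %d, column %d of %s",
                  bad[1, 1], bad[1, 2], path),
          class = "cddfip_io_error")
  }
  zerovar <- which(apply(vals, 2, sd) == 0)
  if (length(zerovar) > 0) {
    warn(sprintf("column(s) %s of %s have zero variance.",
                 paste(zerovar, collapse = ", "), path))
  }
  structure(
    list(values = vals, tr_seconds = tr_seconds, subject_id = subject_id),
    class = "cddfip_timecourses"
  )
}

#' @export
print.cddfip_timecourses <- function(x, ...) {
  cat(sprintf("<timecourses: %d timepoints x %d networks, TR = %s s>\n",
              nrow(x$values), ncol(x$values),
              if (is.na(x$tr_seconds)) "?" else format(x$tr_seconds)))
  invisible(x)
}

#' Read and validate a subject manifest
#'
#' A manifest CSV has columns `subject_id`, `group`, covariates (`age`,
#' `sex`, `site`), `path` and optionally `seed`. Subject ids must be unique
#' and every path must resolve (relative paths are resolved against the
#' manifest's directory).
#'
#' @param path Manifest CSV path.
#' @param groups Optional declared label set; group values outside it error.
#' @return Tibble with resolved paths.
#' @export
read_manifest <- function(path, groups = NULL) {
  m <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("subject_id", "group", "path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cddfip_io_error")
  }
  if (anyDuplicated(m$subject_id)) {
    abort("duplicate subject_id in manifest.", class = "cddfip_io_error")
  }
  if (!is.null(groups) && !all(m$group %in% groups)) {
    abort("manifest contains groups outside the declared label set.",
          class = "cddfip_io_error")
  }
  base <- dirname(normalizePath(path))
  m$path <- ifelse(file.exists(m$path), m$path, file.path(base, m$path))
  missing_files <- m$subject_id[!file.exists(m$path)]
  if (length(missing_files) > 0) {
    abort(sprintf("missing data file for subject(s): %s",
                  paste(missing_files, collapse = ", ")),
          class = "cddfip_io_error")
  }
  m
}

# write a numeric matrix as TSV with a provenance comment header
write_matrix_tsv <- function(x, path, provenance = NULL) {
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), path)
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, append = !is.null(provenance))
  invisible(path)
}
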