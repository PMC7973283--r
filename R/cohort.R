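#' Cohort table of biomarker measurements
#'
#' A `cohort_table` holds one row per subject: a chronological age (CA, years),
#' an optional group label (e.g. sex), and a numeric matrix of biomarker
#' values in which `NA` marks a missing measurement. Missing cells are allowed
#' throughout the pipeline; it is not necessary to have every biomarker for
#' every subject.
#'
#' @param values numeric matrix, subjects x biomarkers, with column names;
#'   `NA` encodes a missing cell.
#' @param ca numeric vector of chronological ages in years, one per subject;
#'   must be finite and positive.
#' @param subject_id optional character vector of subject labels; synthetic
#'   labels `S1, S2, ...` are generated when absent.
#' @param group optional vector of stratum labels (e.g. sex), one per subject.
#' @param ca_label name used for the CA column when the table is written out.
#' @return An object of class `cohort_table`.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
cohort_table <- function(values, ca, subject_id = NULL, group = NULL,
                         ca_label = "CA") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyNA(colnames(values))) {
    stop("biomarker columns must be named")
  }
  ca <- as.numeric(ca)
  if (length(ca) != nrow(values)) {
    stop("length of `ca` must equal the number of subject rows")
  }
  if (any(!is.finite(ca)) || any(ca <= 0)) {
    stop("chronological age must be finite and positive for every subject")
  }
  if (nrow(values) < 2L) stop("a cohort needs at least 2 subjects")
  if (ncol(values) < 1L) stop("a cohort needs at least 1 biomarker")
  if (is.null(subject_id)) subject_id <- paste0("S", seq_len(nrow(values)))
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("subject identifiers must be unique")
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(values)) {
      stop("length of `group` must equal the number of subjects")
    }
  }
  rownames(values) <- subject_id
  structure(
    list(values = values, ca = ca, subject_id = subject_id,
         group = group, ca_label = ca_label),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d subjects x %d biomarkers\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  CA (%s): %.1f-%.1f years\n", x$ca_label,
              min(x$ca), max(x$ca)))
  cat(sprintf("  biomarkers: %s\n",
              paste(colnames(x$values), collapse = ", ")))
  nmiss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$values)))
  if (!is.null(x$group)) {
    cat("  groups: ")
    print(table(x$group))
  }
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$values)

#' Biomarker names of a cohort table
#' @param table a [cohort_table()].
#' @return Character vector of biomarker column names.
#' @export
biomarkers <- function(table) colnames(table$values)

# subset a cohort table by a logical/integer subject index
subset_subjects <- function(table, idx) {
  cohort_table(table$values[idx, , drop = FALSE], table$ca[idx],
               table$subject_id[idx],
               if (!is.null(table$group)) table$group[idx],
               table$ca_label)
}

# subset to a set of biomarker columns
subset_biomarkers <- function(table, keep) {
  stopifnot(all(keep %in% biomarkers(table)))
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out
}

#' Read a cohort table from CSV
#'
#' Reads a rectangular cohort spreadsheet (header row, one subject per row)
#' with a designated chronological-age column. Empty cells, `"NA"`, `"NaN"`
#' and `"n/a"` are treated as missing; non-numeric biomarker cells become
#' missing with a warning logged to stderr; subjects with missing or
#' non-numeric CA are dropped with a logged warning. If the CA label is not
#' found in the header but appears in the first column, the file is assumed
#' to be transposed (biomarkers as rows) and is transposed to the canonical
#' subjects-as-rows orientation.
#'
#' @param path path to a CSV file (UTF-8, header row).
#' @param ca_column name of the chronological-age column. Fatal error when
#'   absent from both header and first column.
#' @param group_column optional name of a stratum column (e.g. sex).
#' @param id_column optional name of a subject-identifier column. When `NULL`,
#'   a column named `id`, `subject`, `subject_id`, `client` or `sample`
#'   (case-insensitive) is used if present; otherwise synthetic ids are
#'   generated.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, ca_column = "CA", group_column = NULL,
                        id_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  na_strings <- c("", "NA", "NaN", "nan", "na", "n/a", "N/A")
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = na_strings)
  if (!(ca_column %in% names(df))) {
    first <- trimws(as.character(df[[1]]))
    if (ca_column %in% first) {
      # transposed orientation: biomarkers as rows, subjects as columns
      labs <- first
      mat <- t(as.matrix(df[, -1, drop = FALSE]))
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      names(df) <- labs
      rownames(df) <- NULL
      bp_log("read_cohort: transposed input detected; canonicalized to subjects-as-rows")
    } else {
      stop("CA column '", ca_column, "' not found in header or first column")
    }
  }
  as_cohort_table(df, ca_column = ca_column, group_column = group_column,
                  id_column = id_column)
}

#' Coerce a data frame to a cohort table
#'
#' @param df a data frame, one subject per row.
#' @inheritParams read_cohort
#' @return A [cohort_table()].
#' @export
as_cohort_table <- function(df, ca_column = "CA", group_column = NULL,
                            id_column = NULL) {
  if (inherits(df, "cohort_table")) return(df)
  if (!(ca_column %in% names(df))) {
    stop("CA column '", ca_column, "' not found")
  }
  n_input <- nrow(df)
  if (is.null(id_column)) {
    cand <- names(df)[tolower(names(df)) %in%
                        c("id", "subject", "subject_id", "client", "sample")]
    if (length(cand)) id_column <- cand[[1]]
  }
  subject_id <- if (!is.null(id_column) && id_column %in% names(df)) {
    as.character(df[[id_column]])
  } else NULL
  group <- if (!is.null(group_column)) {
    if (!(group_column %in% names(df))) {
      stop("group column '", group_column, "' not found")
    }
    as.character(df[[group_column]])
  } else NULL

  ca_raw <- df[[ca_column]]
  ca <- suppressWarnings(as.numeric(as.character(ca_raw)))
  ok <- is.finite(ca) & ca > 0
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    bp_log("read_cohort: dropped %d subject(s) with missing/non-numeric CA (%d retained of %d)",
           n_drop, sum(ok), n_input)
  }
  if (sum(ok) < 2L) stop("fewer than 2 subjects with valid CA")

  bm_cols <- setdiff(names(df), c(ca_column, id_column, group_column))
  vals <- lapply(df[bm_cols], function(col) {
    v <- suppressWarnings(as.numeric(as.character(col)))
    n_bad <- sum(!is.na(col) & is.na(v) & !(trimws(as.character(col)) == ""))
    if (n_bad > 0) {
      bp_log("read_cohort: %d non-numeric cell(s) set to missing", n_bad)
    }
    v
  })
  # columns that are entirely non-numeric are labels, not biomarkers
  all_na_numeric <- vapply(seq_along(vals), function(i) {
    all(is.na(vals[[i]])) && !all(is.na(df[[bm_cols[i]]]))
  }, logical(1))
  if (any(all_na_numeric)) {
    bp_log("read_cohort: dropped non-numeric column(s): %s",
           paste(bm_cols[all_na_numeric], collapse = ", "))
    vals <- vals[!all_na_numeric]
    bm_cols <- bm_cols[!all_na_numeric]
  }
  if (!length(bm_cols)) stop("no biomarker columns found")
  values <- do.call(cbind, vals)
  colnames(values) <- bm_cols

  tab <- cohort_table(values[ok, , drop = FALSE], ca[ok],
                      subject_id = if (!is.null(subject_id)) subject_id[ok],
                      group = if (!is.null(group)) group[ok],
                      ca_label = ca_column)
  attr(tab, "n_input") <- n_input
  attr(tab, "n_dropped") <- n_drop
  tab
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes subject id, CA, optional group, and one
#' column per biomarker, with missing cells left empty. Reading the result
#' back yields an identical table.
#'
#' @param table a [cohort_table()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(table, path) {
  df <- data.frame(subject_id = table$subject_id, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[[table$ca_label]] <- table$ca
  if (!is.null(table$group)) df[["group"]] <- table$group
  for (bm in biomarkers(table)) df[[bm]] <- table$values[, bm]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
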