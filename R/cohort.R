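#' Construct a validated mixed-type cohort
#'
#' A cohort couples a subjects-by-features table with a [cohort_schema()].
#' Continuous columns are stored as doubles; categorical columns as factors
#' whose levels come from the schema (ordered factors for ordinal features).
#' Missing values are allowed everywhere.
#'
#' @param data A data frame with one row per subject. The column named by
#'   `subject_col` holds unique subject identifiers; every other column must
#'   be listed in the schema.
#' @param schema A [cohort_schema()] describing every feature column.
#' @param subject_col Name of the identifier column (default `"subject"`); if
#'   absent, identifiers `S1, S2, ...` are created.
#' @return A tibble of class `tda_cohort` with a `subject` column followed by
#'   the feature columns; the schema is attached as attribute `"schema"`.
#' @export
#' @examples
#' sch <- cohort_schema(c("age", "sex"), c("continuous", "binary_symmetric"),
#'                      list(NULL, c("F", "M")))
#' cohort(data.frame(subject = c("a", "b"), age = c(40, 62), sex = c("F", "M")),
#'        sch)
cohort <- function(data, schema, subject_col = "subject") {
  data <- as_tibble(data)
  if (subject_col %in% names(data)) {
    subj <- as.character(data[[subject_col]])
    data[[subject_col]] <- NULL
  } else {
    subj <- paste0("S", seq_len(nrow(data)))
  }
  if (anyDuplicated(subj))
    abort("data error: subject identifiers must be unique",
          class = "tda_data_error")
  if (nrow(data) < 2L)
    abort("data error: a cohort needs at least 2 subjects",
          class = "tda_data_error")
  extra <- setdiff(names(data), schema$feature)
  if (length(extra))
    abort(paste0("data error: column(s) not listed in the schema: ",
                 paste(extra, collapse = ", ")), class = "tda_data_error")
  miss <- setdiff(schema$feature, names(data))
  if (length(miss))
    abort(paste0("data error: schema feature(s) absent from the table: ",
                 paste(miss, collapse = ", ")), class = "tda_data_error")
  if (!nrow(schema))
    abort("data error: a cohort needs at least 1 feature",
          class = "tda_data_error")

  out <- tibble(subject = subj)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$feature[i]
    tp <- schema$type[i]
    x <- data[[nm]]
    if (tp == "continuous") {
      if (is.character(x)) {
        xx <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(xx))
        if (length(bad))
          abort(paste0("data error: non-numeric value '", x[bad[1]],
                       "' for continuous feature '", nm, "' (row ", bad[1], ")"),
                class = "tda_data_error")
        x <- xx
      }
      out[[nm]] <- as.double(x)
    } else {
      lv <- schema$levels[[i]]
      x <- as.character(x)
      bad <- which(!is.na(x) & !x %in% lv)
      if (length(bad))
        abort(paste0("data error: value '", x[bad[1]], "' for feature '", nm,
                     "' (row ", bad[1], ") is outside its declared levels: ",
                     paste(lv, collapse = ", ")), class = "tda_data_error")
      out[[nm]] <- factor(x, levels = lv, ordered = tp == "ordinal")
    }
  }
  attr(out, "schema") <- schema
  class(out) <- c("tda_cohort", class(tibble()))
  out
}

#' Retrieve the schema attached to a cohort
#' @param x A `tda_cohort`.
#' @return The [cohort_schema()] tibble.
#' @export
schema_of <- function(x) {
  sch <- attr(x, "schema")
  if (is.null(sch)) abort("not a tda_cohort: no schema attached",
                          class = "tda_usage_error")
  sch
}

feature_cols <- function(x) setdiff(names(x), "subject")

#' @export
print.tda_cohort <- function(x, ...) {
  sch <- attr(x, "schema")
  cat("<tda_cohort> ", nrow(x), " subjects x ", nrow(sch), " features (",
      paste(sprintf("%s: %d", names(table(sch$type)), table(sch$type)),
            collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' Read a cohort table and its schema from disk
#'
#' The table is delimited text with a header row (comma- or tab-separated,
#' chosen by extension or by `delim`). Every non-subject column must appear
#' in the schema. Empty strings and any token in `na_tokens` are read as
#' missing.
#'
#' @param table_path CSV/TSV file with one row per subject.
#' @param schema_path JSON/YAML schema file (see [read_schema()]).
#' @param na_tokens Strings mapped to missing; default `c("", "NA")`.
#' @param subject_col Identifier column name (default `"subject"`).
#' @param delim Field delimiter; default guesses `"\t"` for `.tsv`, `","`
#'   otherwise.
#' @return A [cohort()].
#' @export
read_cohort <- function(table_path, schema_path, na_tokens = c("", "NA"),
                        subject_col = "subject", delim = NULL) {
  if (!file.exists(table_path))
    abort(paste0("cohort table not found: ", table_path),
          class = "tda_usage_error")
  schema <- read_schema(schema_path)
  if (is.null(delim))
    delim <- if (tolower(tools::file_ext(table_path)) == "tsv") "\t" else ","
  tab <- readr::read_delim(table_path, delim = delim, na = na_tokens,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  cohort(tab, schema, subject_col = subject_col)
}

#' Write a cohort table (and optionally its schema) to disk
#'
#' The canonical writer round-trips with [read_cohort()]: values are written
#' as their labels, missing cells as empty fields.
#'
#' @param x A `tda_cohort`.
#' @param table_path Output CSV/TSV path.
#' @param schema_path Optional schema output path.
#' @return `table_path`, invisibly.
#' @export
write_cohort <- function(x, table_path, schema_path = NULL) {
  out <- as_tibble(x)
  for (nm in feature_cols(out))
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  delim <- if (tolower(tools::file_ext(table_path)) == "tsv") "\t" else ","
  readr::write_delim(out, table_path, delim = delim, na = "")
  if (!is.null(schema_path)) write_schema(schema_of(x), schema_path)
  invisible(table_path)
}

#' Median-dichotomize a continuous feature
#'
#' Replaces a continuous feature by a symmetric binary one: values at or
#' below the median of the non-missing values become `"Low"`, values above it
#' `"High"`. Ties at the median go to `"Low"`, matching the clinical
#' convention that places the cutoff value in the low-risk group. Missing
#' values stay missing.
#'
#' @param x A `tda_cohort`.
#' @param feature Name of a continuous feature.
#' @return The modified cohort.
#' @export
dichotomize_median <- function(x, feature) {
  sch <- schema_of(x)
  i <- match(feature, sch$feature)
  if (is.na(i))
    abort(paste0("usage error: no feature named '", feature, "'"),
          class = "tda_usage_error")
  if (sch$type[i] != "continuous")
    abort(paste0("usage error: dichotomize_median requires a continuous ",
                 "feature; '", feature, "' is ", sch$type[i]),
          class = "tda_usage_error")
  v <- x[[feature]]
  if (!any(!is.na(v)))
    abort(paste0("usage error: feature '", feature, "' is entirely missing"),
          class = "tda_usage_error")
  med <- median(v, na.rm = TRUE)
  lab <- ifelse(is.na(v), NA_character_, ifelse(v <= med, "Low", "High"))
  x[[feature]] <- factor(lab, levels = c("Low", "High"))
  sch$type[i] <- "binary_symmetric"
  sch$levels[[i]] <- c("Low", "High")
  sch$positive_level[i] <- NA_character_
  attr(x, "schema") <- validate_schema(sch)
  x
}

#' Numeric encoding of a cohort
#'
#' Converts every feature to a numeric vector: continuous features unchanged;
#' ordinal features to rank codes `0..k-1`; binary features to `{0, 1}`
#' following the level order (for asymmetric binary features the
#' `positive_level` maps to 1); nominal features with more than two levels to
#' integer codes `0..k-1` in level order. Nominal codes are unordered labels:
#' they are suitable for sector averaging of each level indicator but carry
#' no metric meaning and are never used for distances. Missing values map to
#' `NA`.
#'
#' @param x A `tda_cohort`.
#' @return A tibble with the `subject` column and one numeric column per
#'   feature.
#' @export
to_numeric <- function(x) {
  sch <- schema_of(x)
  out <- tibble(subject = x$subject)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$feature[i]
    tp <- sch$type[i]
    v <- x[[nm]]
    out[[nm]] <- switch(tp,
      continuous = as.double(v),
      ordinal = ,
      nominal = as.double(unclass(v)) - 1,
      binary_symmetric = as.double(unclass(v)) - 1,
      binary_asymmetric = {
        lv <- sch$levels[[i]]
        pos <- sch$positive_level[i]
        as.double(as.character(v) == pos)
      })
  }
  out
}

#' Names of the binary features of a cohort
#'
#' @param x A `tda_cohort`.
#' @return Character vector of features whose type is symmetric or asymmetric
#'   binary.
#' @export
binary_features <- function(x) {
  sch <- schema_of(x)
  sch$feature[grepl("^binary", sch$type)]
}
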