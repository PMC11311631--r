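#' Feature schemas for mixed-type cohort tables
#'
#' A schema declares, for every column of a cohort table, which of the five
#' mixed-data feature types it carries. The type drives both the numeric
#' encoding and the Gower distance contribution of the feature:
#'
#' * `continuous` — real-valued; Gower contribution is the absolute difference
#'   scaled by the feature's observed range.
#' * `ordinal` — ordered categories; replaced by rank codes and then treated
#'   like a range-scaled continuous feature.
#' * `nominal` — unordered categories; contributes 0 on a match, 1 otherwise.
#' * `binary_symmetric` — two categories where both levels are equally
#'   informative (e.g. sex); treated like a two-level nominal feature.
#' * `binary_asymmetric` — two categories where only the `positive_level`
#'   carries similarity information (e.g. presence of a rare abnormality);
#'   pairs where both subjects are at the non-positive level are excluded from
#'   the Gower average altogether.
#'
#' @param feature Character vector of feature (column) names.
#' @param type Character vector of feature types, one of `"continuous"`,
#'   `"ordinal"`, `"nominal"`, `"binary_symmetric"`, `"binary_asymmetric"`.
#' @param levels List of character vectors giving the category labels for
#'   non-continuous features (`NULL` for continuous ones). For ordinal
#'   features the order of `levels` is the category order.
#' @param positive_level Character vector naming, for asymmetric binary
#'   features, the level that counts as "present" (`NA` otherwise).
#'
#' @return A tibble of class `tda_schema` with columns `feature`, `type`,
#'   `levels` (list column) and `positive_level`.
#' @export
#' @examples
#' cohort_schema(
#'   feature = c("age", "stage", "sex"),
#'   type = c("continuous", "ordinal", "binary_symmetric"),
#'   levels = list(NULL, paste("Stage", 0:4), c("Female", "Male"))
#' )
cohort_schema <- function(feature, type, levels = NULL, positive_level = NULL) {
  n <- length(feature)
  if (is.null(levels)) levels <- rep(list(NULL), n)
  if (is.null(positive_level)) positive_level <- rep(NA_character_, n)
  sch <- tibble(
    feature = as.character(feature),
    type = as.character(type),
    levels = levels,
    positive_level = as.character(positive_level)
  )
  validate_schema(sch)
}

feature_types <- c("continuous", "ordinal", "nominal",
                   "binary_symmetric", "binary_asymmetric")

validate_schema <- function(sch) {
  if (anyDuplicated(sch$feature))
    abort("schema error: duplicated feature names", class = "tda_schema_error")
  bad <- setdiff(sch$type, feature_types)
  if (length(bad))
    abort(paste0("schema error: unknown feature type(s): ",
                 paste(bad, collapse = ", ")),
          class = "tda_schema_error")
  for (i in seq_len(nrow(sch))) {
    lv <- sch$levels[[i]]
    tp <- sch$type[i]
    nm <- sch$feature[i]
    if (tp == "continuous") {
      if (!is.null(lv) && length(lv))
        abort(paste0("schema error: continuous feature '", nm,
                     "' must not declare levels"), class = "tda_schema_error")
    } else {
      if (is.null(lv) || !length(lv))
        abort(paste0("schema error: feature '", nm, "' of type ", tp,
                     " must declare levels"), class = "tda_schema_error")
      if (anyDuplicated(lv))
        abort(paste0("schema error: feature '", nm, "' has duplicated levels"),
              class = "tda_schema_error")
      if (grepl("^binary", tp) && length(lv) != 2L)
        abort(paste0("schema error: binary feature '", nm,
                     "' must have exactly 2 levels"), class = "tda_schema_error")
      if (tp == "binary_asymmetric") {
        pl <- sch$positive_level[i]
        if (is.na(pl) || !pl %in% lv)
          abort(paste0("schema error: binary_asymmetric feature '", nm,
                       "' needs positive_level drawn from its levels"),
                class = "tda_schema_error")
      }
    }
  }
  class(sch) <- c("tda_schema", class(tibble()))
  sch
}

#' Read a feature schema from JSON or YAML
#'
#' The document is a list of entries, each with fields `feature` (or `name`),
#' `type`, optional `levels`, and `positive_level` for asymmetric binary
#' features.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [cohort_schema()] tibble.
#' @export
read_schema <- function(path) {
  if (!file.exists(path))
    abort(paste0("schema file not found: ", path), class = "tda_schema_error")
  ext <- tolower(tools::file_ext(path))
  entries <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  if (!length(entries))
    abort("schema error: empty schema document", class = "tda_schema_error")
  cohort_schema(
    feature = vapply(entries, function(e) {
      nm <- e$feature %||% e$name
      if (is.null(nm)) abort("schema error: entry without feature name",
                             class = "tda_schema_error")
      as.character(nm)
    }, ""),
    type = vapply(entries, function(e) as.character(e$type %||% NA_character_), ""),
    levels = lapply(entries, function(e)
      if (is.null(e$levels)) NULL else as.character(unlist(e$levels))),
    positive_level = vapply(entries, function(e)
      as.character(e$positive_level %||% NA_character_), "")
  )
}

#' Write a feature schema to JSON or YAML
#'
#' @param schema A [cohort_schema()] tibble.
#' @param path Output path; format chosen by extension (`.json` default).
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(feature = schema$feature[i], type = schema$type[i])
    if (!is.null(schema$levels[[i]])) e$levels <- as.list(schema$levels[[i]])
    if (!is.na(schema$positive_level[i]))
      e$positive_level <- schema$positive_level[i]
    e
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(entries, path)
  } else {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
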