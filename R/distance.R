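#' Gower ("daisy") dissimilarity between subjects
#'
#' Computes the Gower general dissimilarity over a mixed-type cohort,
#' delegating to [cluster::daisy()] — the standard implementation for
#' mixed-type clinical data. For subjects \eqn{i, j} the dissimilarity is
#' \deqn{d(i,j) = \sum_k \delta_{ijk} d_{ijk} / \sum_k \delta_{ijk}}
#' where continuous and ordinal features contribute
#' \eqn{|x_{ik} - x_{jk}| / R_k} (ordinal values first replaced by rank
#' codes, \eqn{R_k} the observed range), nominal and symmetric binary
#' features contribute 0 on a match and 1 otherwise, and
#' \eqn{\delta_{ijk} = 0} when either value is missing — and additionally,
#' for asymmetric binary features, when both subjects sit at the
#' non-positive level. All dissimilarities lie in \eqn{[0, 1]}.
#'
#' Continuous or ordinal features with zero observed range carry no
#' information for this metric and are dropped with a warning. A pair of
#' subjects sharing no usable feature has an undefined distance and raises
#' an error naming the pair.
#'
#' @param x A [cohort()].
#' @param weights Optional non-negative feature weights (default uniform).
#' @return A [stats::dist] object labelled by subject, with attribute
#'   `"metric" = "gower"`.
#' @export
daisy_distance <- function(x, weights = NULL) {
  sch <- schema_of(x)
  if (nrow(x) < 2L)
    abort("usage error: need at least 2 subjects", class = "tda_usage_error")
  keep <- rep(TRUE, nrow(sch))
  for (i in seq_len(nrow(sch))) {
    if (sch$type[i] %in% c("continuous", "ordinal")) {
      v <- x[[sch$feature[i]]]
      vv <- if (is.factor(v)) as.double(unclass(v)) else v
      rng <- suppressWarnings(diff(range(vv, na.rm = TRUE)))
      if (!is.finite(rng) || rng == 0) {
        warn(paste0("feature '", sch$feature[i],
                    "' has zero observed range and is dropped from the ",
                    "Gower sum"))
        keep[i] <- FALSE
      }
    }
  }
  sch <- sch[keep, , drop = FALSE]
  if (!nrow(sch))
    abort("usage error: no usable features remain", class = "tda_usage_error")
  if (!is.null(weights)) {
    weights <- weights[keep]
    if (length(weights) != nrow(sch) || any(weights < 0))
      abort("usage error: weights must be non-negative, one per feature",
            class = "tda_usage_error")
  }

  df <- as.data.frame(x[, sch$feature, drop = FALSE])
  asymm <- character(0)
  for (i in seq_len(nrow(sch))) {
    nm <- sch$feature[i]
    if (sch$type[i] == "binary_asymmetric") {
      # daisy's asymmetric-binary type wants 0/1 with 1 = the positive level
      df[[nm]] <- as.integer(as.character(df[[nm]]) == sch$positive_level[i])
      asymm <- c(asymm, nm)
    }
  }
  typ <- if (length(asymm)) list(asymm = asymm) else list()
  d <- suppressWarnings(cluster::daisy(
    df, metric = "gower", type = typ,
    weights = if (is.null(weights)) rep(1, ncol(df)) else weights))
  dm <- as.matrix(d)
  if (anyNA(dm)) {
    bad <- which(is.na(dm), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    abort(paste0("undefined distance: subjects '", x$subject[bad[1, 1]],
                 "' and '", x$subject[bad[1, 2]],
                 "' share no usable feature"),
          class = "tda_distance_error")
  }
  out <- as.dist(dm)
  attr(out, "Labels") <- x$subject
  attr(out, "metric") <- "gower"
  out
}

#' Distances between binary features
#'
#' Computes a feature-by-feature distance matrix over the binary features of
#' a cohort, using pairwise-complete observations per feature pair:
#'
#' * `sokal_michener`: 1 − (matches / comparisons), the simple matching
#'   distance;
#' * `pearson`: (1 − r) / 2 with r the Pearson correlation of the two 0/1
#'   vectors (option `pearson_transform = "one_minus"` uses 1 − r instead).
#'
#' Both lie in \eqn{[0, 1]} under the default transform. If a feature is
#' constant on the pairwise-complete subset, the Pearson correlation is
#' undefined; that entry is reported as `NA` with a warning.
#'
#' @param x A [cohort()].
#' @param metric `"sokal_michener"` or `"pearson"`.
#' @param features Feature names to use (default: all binary features).
#' @param pearson_transform `"half"` for (1 − r)/2 (default) or
#'   `"one_minus"` for 1 − r.
#' @return A [stats::dist] over features.
#' @export
binary_feature_distance <- function(x, metric = c("sokal_michener", "pearson"),
                                    features = NULL,
                                    pearson_transform = c("half", "one_minus")) {
  metric <- match.arg(metric)
  pearson_transform <- match.arg(pearson_transform)
  sch <- schema_of(x)
  if (is.null(features)) features <- binary_features(x)
  bad <- features[!features %in% sch$feature[grepl("^binary", sch$type)]]
  if (length(bad))
    abort(paste0("usage error: not binary feature(s): ",
                 paste(bad, collapse = ", ")), class = "tda_usage_error")
  if (length(features) < 2L)
    abort("usage error: need at least 2 binary features",
          class = "tda_usage_error")
  num <- as.matrix(to_numeric(x)[, features, drop = FALSE])
  p <- length(features)
  dm <- matrix(0, p, p, dimnames = list(features, features))
  warned <- FALSE
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(num[, i]) & !is.na(num[, j])
    a <- num[ok, i]; b <- num[ok, j]
    if (metric == "sokal_michener") {
      dm[i, j] <- dm[j, i] <-
        if (!length(a)) NA_real_ else 1 - mean(a == b)
    } else {
      if (!length(a) || sd(a) == 0 || sd(b) == 0) {
        dm[i, j] <- dm[j, i] <- NA_real_
        warned <- TRUE
      } else {
        r <- cor(a, b)
        dm[i, j] <- dm[j, i] <-
          if (pearson_transform == "half") (1 - r) / 2 else 1 - r
      }
    }
  }
  if (warned)
    warn("Pearson distance undefined for feature pair(s) constant on their pairwise-complete subset; reported as NA")
  out <- as.dist(dm)
  attr(out, "metric") <- metric
  out
}

#' Export a distance matrix as square CSV
#' @param d A [stats::dist] or square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  m <- as.matrix(d)
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Export a distance matrix as PHYLIP lower-triangle text
#' @inheritParams write_distance_csv
#' @export
write_distance_phylip <- function(d, path) {
  m <- as.matrix(d)
  n <- nrow(m)
  labs <- rownames(m) %||% paste0("S", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    row <- if (i > 1) paste(sprintf("%.10f", m[i, seq_len(i - 1)]),
                            collapse = " ") else ""
    writeLines(trimws(paste(formatC(labs[i], width = -10), row)), con)
  }
  invisible(path)
}
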