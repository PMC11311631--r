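#' Pairwise chi-squared dependence of binary features
#'
#' For every pair of binary features, builds the 2x2 contingency table on
#' pairwise-complete subjects and tests independence with the chi-squared
#' test (Yates continuity correction by default, matching R's own default
#' for 2x2 tables). Pairs whose table has an empty row or column margin are
#' undefined; their p-value is set to 1 and flagged. The diagonal p-value
#' is 1 by convention so that `-log10(p)` heatmaps have a blank diagonal.
#'
#' @param x A [cohort()].
#' @param features Binary features (default all; at least 2).
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, displaying raw p-values).
#' @return An object of class `tda_dependence` with fields `features`,
#'   `chi2`, `pvals`, `neglog10p` (symmetric matrices) and `flags`;
#'   `tidy()` returns the long pair table.
#' @export
pairwise_chi2 <- function(x, features = NULL, correct = TRUE,
                          adjust = "none") {
  if (is.null(features)) features <- binary_features(x)
  if (length(features) < 2)
    abort("usage error: need at least 2 binary features",
          class = "tda_usage_error")
  bad <- setdiff(features, binary_features(x))
  if (length(bad))
    abort(paste0("usage error: not binary: ", paste(bad, collapse = ", ")),
          class = "tda_usage_error")
  p <- length(features)
  chi2 <- matrix(NA_real_, p, p, dimnames = list(features, features))
  pv <- matrix(1, p, p, dimnames = list(features, features))
  flags <- matrix(NA_character_, p, p, dimnames = list(features, features))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    a <- x[[features[i]]]
    b <- x[[features[j]]]
    ok <- !is.na(a) & !is.na(b)
    tab <- table(droplevels(a[ok]), droplevels(b[ok]))
    if (any(dim(tab) < 2)) {
      flags[i, j] <- flags[j, i] <- "empty_margin"
      pv[i, j] <- pv[j, i] <- 1
      next
    }
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    chi2[i, j] <- chi2[j, i] <- unname(ct$statistic)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  if (adjust != "none") {
    up <- upper.tri(pv)
    pv[up] <- stats::p.adjust(pv[up], method = adjust)
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  diag(pv) <- 1
  structure(list(features = features, chi2 = chi2, pvals = pv,
                 neglog10p = -log10(pv), flags = flags, correct = correct),
            class = "tda_dependence")
}

#' @export
print.tda_dependence <- function(x, ...) {
  cat("<tda_dependence> ", length(x$features), " binary features, ",
      sum(upper.tri(x$pvals)), " pairs\n", sep = "")
  print(head(tidy(x), 5))
  invisible(x)
}

#' @rdname pairwise_chi2
#' @param ... Unused.
#' @method tidy tda_dependence
#' @export
tidy.tda_dependence <- function(x, ...) {
  idx <- which(upper.tri(x$pvals), arr.ind = TRUE)
  out <- tibble(
    feature_1 = x$features[idx[, 1]],
    feature_2 = x$features[idx[, 2]],
    chi2 = x$chi2[idx],
    p_value = x$pvals[idx],
    neglog10p = x$neglog10p[idx],
    flag = x$flags[idx]
  )
  out[order(out$p_value), ]
}

#' @rdname pairwise_chi2
#' @param object A `tda_dependence`.
#' @method autoplot tda_dependence
#' @export
autoplot.tda_dependence <- function(object, ...) {
  df <- as.data.frame(as.table(object$neglog10p))
  names(df) <- c("feature_1", "feature_2", "neglog10p")
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_1, .data$feature_2,
                                   fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise chi-squared dependence")
}

#' Silhouette widths of a clustering
#'
#' Per-subject silhouette width \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)},
#' where \eqn{a_i} is the mean within-cluster distance to the other members
#' and \eqn{b_i} the smallest mean distance to another cluster. Widths near
#' 1 indicate well-classified subjects; negative widths poorly classified
#' ones. Members of singleton clusters score 0. Delegates to
#' [cluster::silhouette()].
#'
#' @param d A [stats::dist] or distance matrix.
#' @param labels Cluster labels (≥ 2 distinct values).
#' @return A tibble: `subject`, `cluster`, `neighbor`, `width`.
#' @export
silhouette_widths <- function(d, labels) {
  m <- as_distance_matrix(d)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2)
    abort("usage error: silhouette needs at least 2 clusters",
          class = "tda_usage_error")
  if (length(labels) != nrow(m))
    abort("usage error: one label per subject required",
          class = "tda_usage_error")
  sil <- cluster::silhouette(labels, dist = as.dist(m))
  tibble(subject = rownames(m), cluster = as.integer(sil[, 1]),
         neighbor = as.integer(sil[, 2]), width = as.double(sil[, 3]))
}

#' Cluster binary features under two metrics and report the agreement
#'
#' Average-linkage hierarchical clustering of the binary features under
#' both the Sokal-Michener and the Pearson feature distance, each cut to
#' `k` clusters. The agreement report lists the groups of features that
#' are co-clustered under *both* metrics (connected components of the
#' intersection of the two co-membership relations) — the feature blocks a
#' heatmap ordered by either metric would show.
#'
#' @param x A [cohort()].
#' @param k Number of clusters to cut each tree into (default 3).
#' @param features Binary features (default all).
#' @return A list of class `tda_feature_clusters`: `memberships` (tibble
#'   with one row per feature and a column per metric), `orderings`
#'   (dendrogram leaf orders), `agreement` (list of feature groups found
#'   by both metrics, singletons dropped), `trees`.
#' @export
cluster_features <- function(x, k = 3, features = NULL) {
  if (is.null(features)) features <- binary_features(x)
  if (length(features) < 2) {
    return(structure(list(
      memberships = tibble(feature = features, sokal_michener = 1L,
                           pearson = 1L),
      orderings = list(sokal_michener = features, pearson = features),
      agreement = list(), trees = list()),
      class = "tda_feature_clusters"))
  }
  k <- min(k, length(features))
  ds <- binary_feature_distance(x, "sokal_michener", features)
  dp <- binary_feature_distance(x, "pearson", features)
  dpm <- as.matrix(dp)
  dpm[is.na(dpm)] <- 1  # undefined correlations treated as maximal distance
  diag(dpm) <- 0
  hs <- hclust(as.dist(as.matrix(ds)), method = "average")
  hp <- hclust(as.dist(dpm), method = "average")
  ms <- cutree(hs, k = k)
  mp <- cutree(hp, k = k)
  # features co-clustered under both metrics: components of the intersected
  # co-membership graph
  pfeat <- length(features)
  adj <- outer(ms, ms, "==") & outer(mp, mp, "==")
  comp <- rep(0L, pfeat)
  cid <- 0L
  for (i in seq_len(pfeat)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (comp[v] == 0L) {
          comp[v] <- cid
          stack <- c(stack, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  groups <- split(features, comp)
  agreement <- unname(groups[lengths(groups) > 1])
  structure(list(
    memberships = tibble(feature = features, sokal_michener = unname(ms),
                         pearson = unname(mp)),
    orderings = list(sokal_michener = features[hs$order],
                     pearson = features[hp$order]),
    agreement = agreement,
    trees = list(sokal_michener = hs, pearson = hp)),
    class = "tda_feature_clusters")
}

#' @export
print.tda_feature_clusters <- function(x, ...) {
  cat("<tda_feature_clusters> ", nrow(x$memberships), " features; ",
      length(x$agreement), " group(s) found by both metrics\n", sep = "")
  for (g in x$agreement) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}
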