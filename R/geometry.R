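#' Low-dimensional embedding of a distance matrix
#'
#' Classical (metric) multidimensional scaling — the eigendecomposition of
#' the double-centred squared-distance matrix — or Kruskal nonmetric MDS
#' (via [MASS::isoMDS()], started from the classical solution) as the
#' nonlinear alternative. Both are deterministic for a given input, so
#' repeated calls reproduce the same coordinates exactly. Axis orientation
#' is arbitrary (signs of eigenvectors); downstream statistics are either
#' rotation-invariant or reported relative to the embedding's own frame.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param method `"mds"` (classical, default) or `"nmds"` (nonmetric).
#' @param k Embedding dimension, 2 or 3 (must be < n).
#' @return A tibble of class `tda_embedding` with columns `subject` and
#'   `X1..Xk`; attribute `"method"` records the method.
#' @export
embed_distance <- function(d, method = c("mds", "nmds"), k = 2) {
  method <- match.arg(method)
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (k >= n)
    abort("usage error: k must be smaller than the number of subjects",
          class = "tda_usage_error")
  coords <- cmdscale(as.dist(m), k = k)
  if (method == "nmds") {
    fit <- MASS::isoMDS(as.dist(m), y = coords, k = k, trace = FALSE)
    coords <- fit$points
  }
  out <- as_tibble(coords, .name_repair = ~ paste0("X", seq_len(k)))
  out <- dplyr::bind_cols(tibble(subject = rownames(m)), out)
  attr(out, "method") <- method
  class(out) <- c("tda_embedding", class(tibble()))
  out
}

emb_coords <- function(emb) {
  as.matrix(emb[, grep("^X[0-9]+$", names(emb)), drop = FALSE])
}

#' Centroid of a representative cycle in an embedding
#'
#' The arithmetic mean of the embedded coordinates of the distinct subjects
#' appearing on the representative cycle (the "curve" of a loop, the
#' skeleton of a void) — not of all subjects near it.
#'
#' @param emb A [embed_distance()] result.
#' @param rep A representative cycle: a matrix of subject labels (rows =
#'   simplices) from [representative_cycle()], or a vector of labels.
#' @return A numeric vector of length k.
#' @export
loop_centroid <- function(emb, rep) {
  verts <- unique(as.vector(rep))
  if (!length(verts))
    abort("usage error: empty representative", class = "tda_usage_error")
  i <- match(verts, emb$subject)
  if (anyNA(i))
    abort("usage error: representative vertices missing from the embedding",
          class = "tda_usage_error")
  colMeans(emb_coords(emb)[i, , drop = FALSE])
}

#' Assign subjects to angular sectors around a centroid
#'
#' In a 2-D embedding, each subject's angle about the centroid
#' (`atan2`, mapped to \[0°, 360°)) is binned into sectors of `width`
#' degrees: sector index `floor(angle / width)`. Subjects exactly at the
#' centroid have no angle and are excluded with a warning (`NA` sector).
#'
#' @param emb A 2-D [embed_distance()] result.
#' @param centroid Length-2 numeric centre.
#' @param width Sector width in degrees; must divide 360 (default 20,
#'   giving 18 sectors).
#' @return A tibble with columns `subject`, `angle` (degrees) and `sector`
#'   (0-based index); attribute `"n_sectors"`.
#' @export
assign_sectors <- function(emb, centroid, width = 20) {
  xy <- emb_coords(emb)
  if (ncol(xy) != 2)
    abort("usage error: sector assignment needs a 2-D embedding",
          class = "tda_usage_error")
  if (360 %% width != 0)
    abort("usage error: sector width must divide 360 degrees",
          class = "tda_usage_error")
  dx <- xy[, 1] - centroid[1]
  dy <- xy[, 2] - centroid[2]
  at_centre <- dx == 0 & dy == 0
  if (any(at_centre))
    warn(paste0(sum(at_centre), " subject(s) at the exact centroid excluded",
                " from sector assignment"))
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  sector <- ifelse(at_centre, NA_integer_, as.integer(floor(ang / width)))
  out <- tibble(subject = emb$subject,
                angle = ifelse(at_centre, NA_real_, ang),
                sector = sector)
  attr(out, "n_sectors") <- as.integer(360 / width)
  attr(out, "width") <- width
  out
}

#' Per-sector means of a numeric feature
#'
#' Averages a numeric feature over the subjects falling in each angular
#' sector; missing values are dropped per sector, and sectors containing no
#' observed subject yield `NA`.
#'
#' @param values Numeric vector, one value per row of `sectors`.
#' @param sectors A [assign_sectors()] result (or an integer vector of
#'   0-based sector indices with `n_sectors` supplied).
#' @param n_sectors Number of sectors (taken from `sectors` if available).
#' @return Numeric vector of length `n_sectors`.
#' @export
sector_profile <- function(values, sectors, n_sectors = NULL) {
  idx <- if (is.data.frame(sectors)) sectors$sector else sectors
  n_sectors <- n_sectors %||% attr(sectors, "n_sectors")
  if (is.null(n_sectors))
    abort("usage error: n_sectors not supplied", class = "tda_usage_error")
  out <- rep(NA_real_, n_sectors)
  ok <- !is.na(idx) & !is.na(values)
  if (any(ok)) {
    agg <- tapply(values[ok], idx[ok], mean)
    out[as.integer(names(agg)) + 1L] <- agg
  }
  out
}

#' Sinusoidal fit of sector means and the kappa statistic
#'
#' Ordinary least squares of the sector means on
#' \eqn{(1, \sin\theta_s, \cos\theta_s)}, with \eqn{\theta_s} the
#' sector-centre angles \eqn{(s + 1/2) \cdot \mathrm{width}}. The
#' goodness-of-fit statistic is \eqn{\kappa = \mathrm{MSE} / \sigma^2},
#' where MSE = RSS / S and \eqn{\sigma^2} is the total sum of squares about
#' the mean divided by the same S (the number of non-missing sectors), so
#' \eqn{\kappa \in [0, 1]}: small values indicate circular (loop-explaining)
#' behaviour. The peak angle is \eqn{\mathrm{atan2}(\beta_1, \beta_2)}.
#'
#' Constant sector means make \eqn{\sigma^2 = 0}; the result is flagged and
#' \eqn{\kappa} is `NA` (such features are excluded from rankings).
#'
#' @param sector_means Numeric vector of per-sector means (`NA` for empty
#'   sectors); at least 4 non-missing.
#' @param width Sector width in degrees.
#' @return A one-row tibble: `b0`, `b1`, `b2`, `mse`, `sigma2`, `kappa`,
#'   `peak_angle` (degrees in \[0, 360)), `n_sectors_used`, `flag`.
#' @export
fit_sinusoid <- function(sector_means, width = 20) {
  s <- which(!is.na(sector_means)) - 1L
  y <- sector_means[!is.na(sector_means)]
  if (length(y) < 4)
    abort("usage error: need at least 4 non-missing sector means",
          class = "tda_usage_error")
  theta <- (s + 0.5) * width * pi / 180
  X <- cbind(1, sin(theta), cos(theta))
  beta <- qr.solve(X, y)
  resid <- y - X %*% beta
  S <- length(y)
  mse <- sum(resid^2) / S
  sigma2 <- sum((y - mean(y))^2) / S
  flag <- if (sigma2 == 0) "constant" else NA_character_
  tibble(
    b0 = beta[1], b1 = beta[2], b2 = beta[3],
    mse = mse, sigma2 = sigma2,
    kappa = if (sigma2 == 0) NA_real_ else mse / sigma2,
    peak_angle = (atan2(beta[2], beta[3]) * 180 / pi) %% 360,
    n_sectors_used = S, flag = flag
  )
}

#' Sector-averaged sinusoidal interpretation of a loop
#'
#' The complete loop-interpretation computation: locate the loop's centroid
#' in the embedding, bin subjects into angular sectors, average every
#' numeric-encoded feature per sector, and fit the sinusoidal model with its
#' \eqn{\kappa} statistic per feature. Nominal features with more than two
#' levels are excluded (the sinusoid needs an at-least-ordinal encoding);
#' dichotomize them (or continuous features, with [dichotomize_median()])
#' to include them.
#'
#' @param x A [cohort()].
#' @param emb A 2-D [embed_distance()] of the cohort's distance matrix.
#' @param rep A representative cycle from [representative_cycle()].
#' @param width Sector width in degrees (default 20).
#' @param features Features to profile (default: all but >2-level nominals).
#' @return An object of class `tda_loop_fit` with fields `centroid`,
#'   `sectors`, `profile` (feature x sector matrix of means) and `fits`;
#'   `tidy()` returns the per-feature fit table ranked by \eqn{\kappa}
#'   ascending.
#' @export
loop_fit <- function(x, emb, rep, width = 20, features = NULL) {
  sch <- schema_of(x)
  if (is.null(features)) {
    excl <- sch$feature[sch$type == "nominal" &
                          vapply(sch$levels, length, 1L) > 2]
    features <- setdiff(sch$feature, excl)
  }
  centroid <- loop_centroid(emb, rep)
  sectors <- assign_sectors(emb, centroid, width = width)
  num <- to_numeric(x)
  ord <- match(sectors$subject, num$subject)
  n_sec <- attr(sectors, "n_sectors")
  profile <- matrix(NA_real_, length(features), n_sec,
                    dimnames = list(features, paste0("sector_", seq_len(n_sec) - 1)))
  fits <- vector("list", length(features))
  for (i in seq_along(features)) {
    v <- num[[features[i]]][ord]
    profile[i, ] <- sector_profile(v, sectors)
    fits[[i]] <- dplyr::bind_cols(tibble(feature = features[i]),
                                  fit_sinusoid(profile[i, ], width = width))
  }
  fits <- dplyr::bind_rows(fits)
  fits <- fits[order(fits$kappa), ]
  structure(list(centroid = centroid, width = width, sectors = sectors,
                 profile = profile, fits = fits),
            class = "tda_loop_fit")
}

#' @export
print.tda_loop_fit <- function(x, ...) {
  cat("<tda_loop_fit> ", nrow(x$profile), " features x ",
      ncol(x$profile), " sectors (", x$width, " degrees)\n", sep = "")
  print(head(x$fits, 5))
  invisible(x)
}

#' @rdname loop_fit
#' @param ... Unused.
#' @method tidy tda_loop_fit
#' @export
tidy.tda_loop_fit <- function(x, ...) x$fits

#' @rdname loop_fit
#' @method glance tda_loop_fit
#' @export
glance.tda_loop_fit <- function(x, ...) {
  tibble(n_features = nrow(x$profile), n_sectors = ncol(x$profile),
         width = x$width,
         best_feature = x$fits$feature[1], best_kappa = x$fits$kappa[1])
}

#' Centroid separation of binary features
#'
#' For each binary feature, the Euclidean distance in the embedding between
#' the mean positions of the two patient groups it defines. Widely
#' separated groups define interpretable axes across a loop or void.
#' Continuous features must be median-dichotomized first to take part.
#'
#' @param x A [cohort()].
#' @param emb A [embed_distance()] result (any k).
#' @param features Binary features (default all).
#' @return A tibble: `feature`, `separation`, `level_1`, `level_2`, `n_1`,
#'   `n_2`, `flag` (`"one_level_empty"` when undefined).
#' @export
centroid_separation <- function(x, emb, features = NULL) {
  sch <- schema_of(x)
  if (is.null(features)) features <- binary_features(x)
  bad <- setdiff(features, binary_features(x))
  if (length(bad))
    abort(paste0("usage error: not binary: ", paste(bad, collapse = ", ")),
          class = "tda_usage_error")
  xy <- emb_coords(emb)
  ord <- match(emb$subject, x$subject)
  purrr::map_dfr(features, function(f) {
    lv <- sch$levels[[match(f, sch$feature)]]
    v <- as.character(x[[f]])[ord]
    n1 <- sum(v == lv[1], na.rm = TRUE)
    n2 <- sum(v == lv[2], na.rm = TRUE)
    if (n1 == 0 || n2 == 0)
      return(tibble(feature = f, separation = NA_real_, level_1 = lv[1],
                    level_2 = lv[2], n_1 = n1, n_2 = n2,
                    flag = "one_level_empty"))
    c1 <- colMeans(xy[which(v == lv[1]), , drop = FALSE])
    c2 <- colMeans(xy[which(v == lv[2]), , drop = FALSE])
    tibble(feature = f, separation = sqrt(sum((c1 - c2)^2)),
           level_1 = lv[1], level_2 = lv[2], n_1 = n1, n_2 = n2,
           flag = NA_character_)
  })
}

#' Feature-by-sector table for circular plots
#'
#' The sector-mean grid of a fitted loop, rows ordered by \eqn{\kappa}
#' ascending (most circular first) and min-max scaled to \[0, 1\] per row
#' for display. Constant rows scale to 0 and are flagged. Written as CSV,
#' the table is consumable by external circular-plot (circos) tools.
#'
#' @param lf A [loop_fit()] result.
#' @param features Optional subset/order of features; default all ranked
#'   (flagged-constant features last).
#' @return A matrix (features x sectors) with attribute `"flagged"`.
#' @export
circos_table <- function(lf, features = NULL) {
  stopifnot(inherits(lf, "tda_loop_fit"))
  if (is.null(features)) features <- lf$fits$feature
  if (!length(features)) {
    out <- lf$profile[integer(0), , drop = FALSE]
    attr(out, "flagged") <- character(0)
    return(out)
  }
  m <- lf$profile[features, , drop = FALSE]
  flagged <- character(0)
  for (i in seq_len(nrow(m))) {
    rng <- range(m[i, ], na.rm = TRUE)
    if (diff(rng) == 0) {
      m[i, ] <- ifelse(is.na(m[i, ]), NA_real_, 0)
      flagged <- c(flagged, rownames(m)[i])
    } else {
      m[i, ] <- (m[i, ] - rng[1]) / diff(rng)
    }
  }
  attr(m, "flagged") <- flagged
  m
}

#' @rdname circos_table
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_circos <- function(lf, path, features = NULL) {
  m <- circos_table(lf, features)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Binary axes of a void in a 3-D embedding
#'
#' For each of three binary features, the segment joining the embedded
#' centroids of its two groups. The three unit direction vectors form a
#' (generally skewed) coordinate system for the void; their 3x3 direction-
#' cosine matrix and its determinant diagnose linear independence —
#' statistically dependent features can still span independent directions.
#' An absolute determinant below `tol` flags (near-)collinear axes.
#'
#' @param x A [cohort()].
#' @param emb3 A 3-D [embed_distance()] result.
#' @param features Exactly three binary feature names.
#' @param tol Collinearity tolerance on the determinant (default 1e-6).
#' @return Object of class `tda_void_axes`: `segments` (tibble of endpoint
#'   coordinates), `directions` (3x3 matrix of unit rows), `determinant`,
#'   `collinear` flag. `tidy()` returns the segments.
#' @export
void_axes <- function(x, emb3, features, tol = 1e-6) {
  if (length(features) != 3)
    abort("usage error: exactly three binary features required",
          class = "tda_usage_error")
  if (ncol(emb_coords(emb3)) != 3)
    abort("usage error: void axes need a 3-D embedding",
          class = "tda_usage_error")
  sep <- centroid_separation(x, emb3, features)
  if (any(!is.na(sep$flag)))
    abort(paste0("usage error: feature(s) with an empty level: ",
                 paste(sep$feature[!is.na(sep$flag)], collapse = ", ")),
          class = "tda_usage_error")
  sch <- schema_of(x)
  xy <- emb_coords(emb3)
  ord <- match(emb3$subject, x$subject)
  seg <- purrr::map_dfr(features, function(f) {
    lv <- sch$levels[[match(f, sch$feature)]]
    v <- as.character(x[[f]])[ord]
    c1 <- colMeans(xy[which(v == lv[1]), , drop = FALSE])
    c2 <- colMeans(xy[which(v == lv[2]), , drop = FALSE])
    tibble(feature = f, level_1 = lv[1], level_2 = lv[2],
           x1 = c1[1], y1 = c1[2], z1 = c1[3],
           x2 = c2[1], y2 = c2[2], z2 = c2[3])
  })
  dirs <- t(vapply(seq_len(3), function(i) {
    v <- c(seg$x2[i] - seg$x1[i], seg$y2[i] - seg$y1[i], seg$z2[i] - seg$z1[i])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  rownames(dirs) <- features
  det3 <- det(dirs)
  structure(list(segments = seg, directions = dirs, determinant = det3,
                 collinear = abs(det3) < tol),
            class = "tda_void_axes")
}

#' @export
print.tda_void_axes <- function(x, ...) {
  cat("<tda_void_axes> determinant = ", signif(x$determinant, 5),
      if (x$collinear) "  [FLAG: collinear axes]", "\n", sep = "")
  print(x$segments)
  invisible(x)
}

#' @rdname void_axes
#' @param ... Unused.
#' @method tidy tda_void_axes
#' @export
tidy.tda_void_axes <- function(x, ...) x$segments

#' Project subjects onto a unit sphere around a void centroid
#'
#' Each subject's displacement from the centroid in the 3-D embedding,
#' normalized to unit length, so feature values can be painted on the
#' sphere surrounding the void. Subjects at the exact centroid are
#' excluded with a warning.
#'
#' @param emb3 A 3-D [embed_distance()] result.
#' @param centroid Length-3 centre (e.g. from [loop_centroid()] on the
#'   void's representative).
#' @param values Optional numeric feature values to carry along.
#' @return A tibble: `subject`, `U1`, `U2`, `U3` (unit coordinates), and
#'   `value` if supplied.
#' @export
sphere_projection <- function(emb3, centroid, values = NULL) {
  xy <- emb_coords(emb3)
  if (ncol(xy) != 3)
    abort("usage error: sphere projection needs a 3-D embedding",
          class = "tda_usage_error")
  disp <- sweep(xy, 2, centroid)
  nrm <- sqrt(rowSums(disp^2))
  at_centre <- nrm == 0
  if (any(at_centre))
    warn(paste0(sum(at_centre), " subject(s) at the centroid excluded from ",
                "the sphere projection"))
  u <- disp / nrm
  out <- tibble(subject = emb3$subject[!at_centre],
                U1 = u[!at_centre, 1], U2 = u[!at_centre, 2],
                U3 = u[!at_centre, 3])
  if (!is.null(values)) out$value <- values[!at_centre]
  out
}

#' Export a void skeleton as an OFF mesh
#'
#' Writes the triangles of a dimension-2 representative cycle, with vertex
#' positions taken from a 3-D embedding, in the plain-text OFF format
#' readable by standard mesh viewers.
#'
#' @param rep A triangle matrix from [representative_cycle()] (3 columns of
#'   subject labels).
#' @param emb3 A 3-D [embed_distance()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(rep, emb3, path) {
  if (!is.matrix(rep) || ncol(rep) != 3)
    abort("usage error: need a triangle (3-column) representative",
          class = "tda_usage_error")
  verts <- unique(as.vector(rep))
  i <- match(verts, emb3$subject)
  if (anyNA(i))
    abort("usage error: representative vertices missing from the embedding",
          class = "tda_usage_error")
  xyz <- emb_coords(emb3)[i, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(length(verts), nrow(rep), 0), con)
  for (r in seq_len(nrow(xyz)))
    writeLines(paste(sprintf("%.8f", xyz[r, ]), collapse = " "), con)
  for (r in seq_len(nrow(rep)))
    writeLines(paste(c(3, match(rep[r, ], verts) - 1L), collapse = " "), con)
  invisible(path)
}

#' Embedding scatter plot with optional group overlay
#' @param object A `tda_embedding`.
#' @param colour Optional vector (factor/numeric) to colour subjects by.
#' @param loop Optional edge matrix of subject labels (a dim-1
#'   representative) drawn as segments.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tda_embedding
#' @export
autoplot.tda_embedding <- function(object, colour = NULL, loop = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$X1, .data$X2))
  if (!is.null(colour)) {
    df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$X1, .data$X2,
                                          colour = .data$colour))
  }
  p <- p + ggplot2::geom_point(size = 1.2)
  if (!is.null(loop)) {
    i1 <- match(loop[, 1], object$subject)
    i2 <- match(loop[, 2], object$subject)
    segs <- data.frame(x = df$X1[i1], y = df$X2[i1],
                       xend = df$X1[i2], yend = df$X2[i2])
    p <- p + ggplot2::geom_segment(data = segs,
                                   ggplot2::aes(x = .data$x, y = .data$y,
                                                xend = .data$xend,
                                                yend = .data$yend),
                                   inherit.aes = FALSE, colour = "blue",
                                   linewidth = 0.5)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(title = paste0(toupper(attr(object, "method")),
                                 " embedding"))
}
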