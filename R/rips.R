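#' Simplex counts of a full Vietoris-Rips complex
#'
#' Number of k-simplices on n points when every tuple is admitted (the
#' worst case at large filtration scale): \eqn{\binom{n}{k+1}} per
#' dimension. These counts are what make higher-dimensional homology
#' infeasible on desktop hardware — e.g. on 266 points there are
#' 35,245 candidate edges, 3,101,560 candidate triangles and
#' 203,927,570 candidate tetrahedra.
#'
#' @param n Number of points.
#' @param max_dim Highest homology dimension sought (simplices up to
#'   dimension `max_dim + 1` are needed).
#' @return A tibble with columns `dim`, `simplex` and `count`.
#' @export
simplex_counts <- function(n, max_dim = 2) {
  k <- 0:(max_dim + 1)
  tibble(
    dim = k,
    simplex = c("vertex", "edge", "triangle", "tetrahedron")[k + 1],
    count = choose(n, k + 1)
  )
}

# Resource guard: projected simplex count for the filtration actually
# enumerated (edge fraction p under the effective threshold thins dimension-k
# counts roughly by p^{choose(k+1,2)}).
check_complex_size <- function(n, max_dim, edge_fraction, ceiling) {
  proj <- n + choose(n, 2) + choose(n, 3) * edge_fraction^3
  if (max_dim >= 2) proj <- proj + choose(n, 4) * edge_fraction^6
  if (proj > ceiling) {
    abort(paste0(
      "resource guard: projected simplex count ", format(proj, big.mark = ","),
      " exceeds the ceiling ", format(ceiling, big.mark = ","),
      ". The complex grows as choose(n, k): choose(", n, ", 2) = ",
      format(choose(n, 2), big.mark = ","), ", choose(", n, ", 3) = ",
      format(choose(n, 3), big.mark = ","), ", choose(", n, ", 4) = ",
      format(choose(n, 4), big.mark = ","),
      ". Reduce max_scale or max_dim, or raise size_ceiling."),
      class = "tda_resource_error")
  }
  invisible(proj)
}

as_distance_matrix <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12) || any(diag(m) != 0))
    abort("usage error: need a symmetric zero-diagonal distance matrix",
          class = "tda_usage_error")
  if (any(!is.finite(m)))
    abort("usage error: distances must be finite", class = "tda_usage_error")
  if (is.null(rownames(m))) {
    labs <- attr(d, "Labels") %||% paste0("S", seq_len(nrow(m)))
    dimnames(m) <- list(labs, labs)
  }
  m
}

#' Persistent homology of the Vietoris-Rips filtration
#'
#' Computes the persistence barcode of a finite metric space over the field
#' Z/2 in dimensions 0 to `max_dim`, together with a representative cycle
#' for every finite bar. Dimension 0 is computed by single-linkage
#' union-find; dimensions 1 and 2 by boundary-matrix reduction (persistent
#' cohomology with clearing for the pairing, then a homology pass restricted
#' to death columns for the representatives). Zero-persistence pairs are
#' discarded. With `max_scale` at its default (the maximum observed
#' distance) there is exactly one infinite bar, in dimension 0.
#'
#' Equal-diameter simplices are ordered by dimension and then by
#' lexicographic vertex order; the barcode does not depend on this
#' tie-break, but representative cycles do.
#'
#' @param d A [stats::dist] object or symmetric distance matrix.
#' @param max_dim Highest homology dimension, 1 or 2.
#' @param max_scale Filtration cutoff; defaults to the maximum distance.
#' @param representatives Attach representative cycles? (default `TRUE`).
#' @param size_ceiling Resource guard on the projected simplex count
#'   (default 5e7); exceeding it raises a `tda_resource_error`.
#' @return An object of class `tda_homology`: use [tidy()] for the bar
#'   table (`id`, `dimension`, `birth`, `death`, `duration`),
#'   [representative_cycle()] for cycles, [autoplot()] for the barcode.
#' @export
#' @examples
#' d <- sample_shapes("square_corners")
#' ph <- vietoris_rips(d, max_dim = 2)
#' tidy(ph)
vietoris_rips <- function(d, max_dim = 2, max_scale = NULL,
                          representatives = TRUE, size_ceiling = 5e7) {
  if (!max_dim %in% 1:2)
    abort("usage error: max_dim must be 1 or 2", class = "tda_usage_error")
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (is.null(max_scale)) max_scale <- max(m)
  if (max_scale <= 0)
    abort("usage error: max_scale must be positive", class = "tda_usage_error")
  r_enc <- min(apply(m, 1, max))
  thresh <- min(max_scale, r_enc)
  ut <- m[upper.tri(m)]
  check_complex_size(n, max_dim, mean(ut <= thresh), size_ceiling)

  res <- .rips_cpp(m, as.integer(max_dim), as.double(max_scale),
                   isTRUE(representatives))
  pairs <- tibble(
    id = seq_along(res$dimension),
    dimension = as.integer(res$dimension),
    birth = res$birth,
    death = res$death,
    duration = res$death - res$birth
  )
  structure(
    list(pairs = pairs, representatives = res$representatives,
         labels = rownames(m), n = n, max_dim = max_dim,
         max_scale = max_scale, enclosing_radius = res$enclosing_radius,
         threshold = res$threshold),
    class = "tda_homology")
}

#' @export
print.tda_homology <- function(x, ...) {
  tab <- table(factor(x$pairs$dimension, levels = 0:x$max_dim))
  cat("<tda_homology> ", x$n, " points, dims 0-", x$max_dim,
      ", max_scale ", signif(x$max_scale, 4), "\n  bars: ",
      paste(sprintf("dim %s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname vietoris_rips
#' @param x A `tda_homology` object.
#' @param ... Unused.
#' @method tidy tda_homology
#' @export
tidy.tda_homology <- function(x, ...) x$pairs

#' @rdname vietoris_rips
#' @method glance tda_homology
#' @export
glance.tda_homology <- function(x, ...) {
  p <- x$pairs
  tibble(
    n_points = x$n, max_dim = x$max_dim, max_scale = x$max_scale,
    enclosing_radius = x$enclosing_radius,
    n_bars_dim0 = sum(p$dimension == 0),
    n_bars_dim1 = sum(p$dimension == 1),
    n_bars_dim2 = sum(p$dimension == 2),
    n_infinite = sum(is.infinite(p$death))
  )
}

#' Representative cycle of a persistence pair
#'
#' For a finite bar in dimension 1 or 2, the representative is the reduced
#' boundary column at the death simplex: a chain of edges (dimension 1) or
#' triangles (dimension 2) whose boundary vanishes mod 2 and whose largest
#' simplex diameter equals the bar's birth (up to diameter ties). For finite
#' dimension-0 bars it is the vertex set of the component absorbed at the
#' death; the essential dimension-0 class returns all vertices of its
#' component.
#'
#' @param ph A [vietoris_rips()] result computed with
#'   `representatives = TRUE`.
#' @param id Bar id (row of `tidy(ph)`).
#' @return For dims ≥ 1 a character matrix of subject labels, one simplex
#'   per row; for dim 0 a character vector of labels.
#' @export
representative_cycle <- function(ph, id) {
  stopifnot(inherits(ph, "tda_homology"))
  if (!id %in% ph$pairs$id)
    abort("usage error: unknown bar id", class = "tda_usage_error")
  rep <- ph$representatives[[id]]
  if (is.null(rep))
    abort("no representative available for this bar (infinite bar in dim >= 1, or computed without representatives)",
          class = "tda_usage_error")
  if (is.matrix(rep)) {
    matrix(ph$labels[rep], nrow = nrow(rep))
  } else {
    ph$labels[rep]
  }
}

#' Distinct subjects on a representative cycle
#' @inheritParams representative_cycle
#' @return Character vector of subject labels.
#' @export
representative_vertices <- function(ph, id) {
  unique(as.vector(representative_cycle(ph, id)))
}

#' Most persistent bar in a dimension
#' @param ph A `tda_homology`.
#' @param dimension Homology dimension.
#' @return The bar id with the largest finite duration (NA if none).
#' @export
most_persistent <- function(ph, dimension) {
  p <- ph$pairs[ph$pairs$dimension == dimension & is.finite(ph$pairs$death), ]
  if (!nrow(p)) return(NA_integer_)
  p$id[which.max(p$duration)]
}

#' Barcode plot
#' @param object A `tda_homology`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tda_homology
#' @export
autoplot.tda_homology <- function(object, ...) {
  p <- object$pairs
  p$death_plot <- ifelse(is.finite(p$death), p$death, object$max_scale)
  p <- p[order(p$dimension, p$birth), ]
  p$y <- seq_len(nrow(p))
  ggplot2::ggplot(p, ggplot2::aes(x = .data$birth, xend = .data$death_plot,
                                  y = .data$y, yend = .data$y,
                                  colour = factor(.data$dimension))) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::labs(x = expression(tau), y = NULL, colour = "dimension",
                  title = "Persistence barcode") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Average-linkage clusters from a distance matrix
#'
#' Hierarchical clustering of the distance matrix cut to `k` clusters;
#' used to colour embeddings and silhouette plots.
#'
#' @param d A [stats::dist] or distance matrix.
#' @param k Number of clusters, between 1 and n.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(d, k) {
  m <- as_distance_matrix(d)
  if (k < 1 || k > nrow(m))
    abort("usage error: k must be in 1..n", class = "tda_usage_error")
  cutree(hclust(as.dist(m), method = "average"), k = k)
}

#' Enumerate the Vietoris-Rips filtration explicitly
#'
#' Lists every simplex of dimension at most `max_dim + 1` with diameter at
#' most `max_scale`, in filtration order: by diameter, then dimension, then
#' lexicographic vertex order. Intended for inspection and small examples;
#' the homology computation enumerates simplices internally.
#'
#' @inheritParams vietoris_rips
#' @return A tibble with columns `diameter`, `dim` and `vertices`
#'   (list column of integer vectors).
#' @export
build_filtration <- function(d, max_dim = 2, max_scale = NULL,
                             size_ceiling = 5e7) {
  m <- as_distance_matrix(d)
  n <- nrow(m)
  if (is.null(max_scale)) max_scale <- max(m)
  if (!max_dim %in% 1:2 || max_scale <= 0)
    abort("usage error: max_dim in {1,2} and max_scale > 0 required",
          class = "tda_usage_error")
  ut <- m[upper.tri(m)]
  check_complex_size(n, max_dim, mean(ut <= max_scale), size_ceiling)
  verts <- lapply(seq_len(n), identity)
  diam <- rep(0, n)
  for (k in 2:(max_dim + 2)) {
    if (k > n) break
    cmb <- combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      v <- cmb[, j]
      dd <- max(m[t(combn(v, 2))])
      if (dd <= max_scale) {
        verts[[length(verts) + 1]] <- v
        diam[length(diam) + 1] <- dd
      }
    }
  }
  dims <- lengths(verts) - 1L
  lex <- vapply(verts, function(v) paste(sprintf("%06d", v), collapse = ""), "")
  o <- order(diam, dims, lex)
  tibble(diameter = diam[o], dim = dims[o], vertices = verts[o])
}

#' Export a barcode as TSV
#'
#' Columns `dim`, `birth`, `death`, `duration`, `representative` (simplices
#' joined by semicolons, vertices within a simplex by commas). The dialect
#' is this package's own.
#'
#' @param ph A `tda_homology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(ph, path) {
  p <- ph$pairs
  rep_str <- vapply(seq_len(nrow(p)), function(i) {
    r <- ph$representatives[[i]]
    if (is.null(r)) return("")
    if (is.matrix(r))
      paste(apply(r, 1, function(v) paste(ph$labels[v], collapse = ",")),
            collapse = ";")
    else paste(ph$labels[r], collapse = ",")
  }, "")
  out <- data.frame(dim = p$dimension, birth = p$birth, death = p$death,
                    duration = p$duration, representative = rep_str)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
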