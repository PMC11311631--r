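#' Robust exponential null rate for bar durations
#'
#' Estimates the rate of the exponential null component from the full set of
#' observed durations by median matching: \eqn{\lambda = \ln 2 /
#' \mathrm{median}(x)}. The median is insensitive to the long right tail
#' contributed by real topological features, which is what makes the
#' estimator usable on the mixture.
#'
#' @param durations Positive bar durations.
#' @return The estimated rate (per duration unit).
#' @export
fit_null_rate <- function(durations) {
  if (!length(durations) || any(!is.finite(durations)) || any(durations <= 0))
    abort("usage error: durations must all be positive and finite",
          class = "tda_usage_error")
  if (length(durations) < 10)
    warn("fewer than 10 durations; the null rate estimate is unstable")
  log(2) / median(durations)
}

#' Conservative null prior for the duration mixture
#'
#' The prior probability that a random duration arises from the null
#' component, chosen as large as the data allow: the minimum over a grid of
#' central data quantiles \eqn{t} of
#' \deqn{\hat F(t) / F_0(t),}
#' the ratio of the empirical distribution function to the exponential null
#' CDF, capped at 1. Below every such \eqn{t} the data contain at most
#' \eqn{n \hat F(t)} durations while a pure null would supply
#' \eqn{n p_0 F_0(t)}; the smallest ratio is therefore the largest prior
#' consistent with the observed short-duration mass. Working at CDF level
#' keeps the estimate stable at \eqn{O(1/\sqrt n)}, where a pointwise
#' density ratio inherits the full variance of the density estimate and is
#' dragged down by its most extreme downward fluctuation.
#'
#' @param durations Positive bar durations.
#' @param rate Exponential null rate (default [fit_null_rate()] of the same
#'   durations).
#' @param probs Quantile grid over which the ratio is minimized (default
#'   `seq(0.5, 0.95, by = 0.05)`; the upper half of the data, where the
#'   empirical CDF is precise and alternative contamination shows up as a
#'   depressed ratio).
#' @return The prior null probability, in (0, 1].
#' @export
fit_conservative_prior <- function(durations, rate = fit_null_rate(durations),
                                   probs = seq(0.5, 0.95, by = 0.05)) {
  if (length(unique(durations)) < 3)
    abort("degenerate duration set: need at least 3 distinct durations",
          class = "tda_usage_error")
  ts <- quantile(durations, probs)
  min(1, min(ecdf(durations)(ts) / stats::pexp(ts, rate)))
}

#' Empirical Bayes mixture model for bar durations
#'
#' Models observed durations as a two-group mixture
#' \eqn{f(x) = p_0 f_0(x) + (1 - p_0) f_1(x)} with an exponential null
#' \eqn{f_0(x) = \lambda e^{-\lambda x}} (rate from [fit_null_rate()]) and
#' an unspecified alternative. The marginal density \eqn{\hat f} is a
#' Gaussian kernel estimate on the duration scale with reflection at zero
#' (durations are non-negative), bandwidth by Silverman's rule; beyond the
#' data range the estimate is held at its boundary value, so a duration far
#' outside everything observed scores as at least as alternative-like as
#' the longest observed bar. Alternatives behind `density_estimator`: a
#' log-scale kernel estimate back-transformed (`"logkde"`) and a histogram
#' estimator (`"hist"`). The null prior \eqn{p_0} comes from
#' [fit_conservative_prior()].
#'
#' The local false discovery rate \eqn{p_0 f_0(x)/\hat f(x)} is
#' monotonized (running minimum) beyond the mode of \eqn{\hat f}, so the
#' posterior never ranks a longer tail bar below a shorter one.
#'
#' @param durations Positive finite bar durations (at least 3 distinct).
#' @param bandwidth Optional kernel bandwidth (default Silverman's rule,
#'   [stats::bw.nrd0()], on the estimator's working scale).
#' @param density_estimator `"kde"` (default), `"logkde"` or `"hist"`.
#' @param dimension Optional homology dimension tag carried in summaries.
#' @return An object of class `tda_eb` with fields `rate`, `p0`, `fhat`
#'   (vectorized density function), `durations`, `dimension`.
#' @export
fit_eb_model <- function(durations, bandwidth = NULL,
                         density_estimator = c("kde", "logkde", "hist"),
                         dimension = NA_integer_) {
  density_estimator <- match.arg(density_estimator)
  rate <- fit_null_rate(durations)
  if (length(unique(durations)) < 3)
    abort("degenerate duration set: density estimate requires at least 3 distinct durations",
          class = "tda_usage_error")
  tiny <- .Machine$double.xmin
  if (density_estimator == "kde") {
    den <- density(durations, bw = bandwidth %||% stats::bw.nrd0(durations))
    f <- approxfun(den$x, den$y, rule = 2)
    fhat <- function(x) pmax(f(x) + f(-x), tiny)  # reflection at zero
    bw_used <- den$bw
  } else if (density_estimator == "logkde") {
    lx <- log(durations)
    den <- density(lx, bw = bandwidth %||% stats::bw.nrd0(lx))
    lf <- approxfun(den$x, den$y, rule = 2)
    fhat <- function(x) pmax(ifelse(x > 0, lf(log(pmax(x, tiny))) / x, NA_real_),
                             tiny)
    bw_used <- den$bw
  } else {
    lx <- log(durations)
    h <- graphics::hist(lx, breaks = "Sturges", plot = FALSE)
    sf <- stats::stepfun(h$breaks, c(tiny, h$density, tiny))
    fhat <- function(x) pmax(ifelse(x > 0, sf(log(pmax(x, tiny))) / x, NA_real_),
                             tiny)
    bw_used <- NA_real_
  }
  p0 <- fit_conservative_prior(durations, rate)
  f0 <- function(x) rate * exp(-rate * x)
  raw_fdr <- function(x) p0 * f0(x) / fhat(x)
  grid <- seq(0, max(durations) * 3, length.out = 512)
  mode_x <- grid[which.max(fhat(grid))]
  gx <- grid[grid >= mode_x]
  mono <- approxfun(gx, cummin(raw_fdr(gx)), rule = 2)
  fdr <- function(x) ifelse(x < mode_x, raw_fdr(x), pmin(raw_fdr(x), mono(x)))
  structure(list(rate = rate, p0 = p0, fhat = fhat, fdr = fdr,
                 durations = durations, dimension = dimension,
                 bandwidth = bw_used, density_estimator = density_estimator,
                 mode = mode_x),
            class = "tda_eb")
}

#' @export
print.tda_eb <- function(x, ...) {
  cat("<tda_eb> exponential-null mixture",
      if (!is.na(x$dimension)) paste0(" (dim ", x$dimension, ")"), "\n",
      "  rate = ", signif(x$rate, 5), ", p0 = ", signif(x$p0, 5),
      ", n = ", length(x$durations), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_eb_model
#' @param x A `tda_eb` model.
#' @param ... Unused.
#' @method glance tda_eb
#' @export
glance.tda_eb <- function(x, ...) {
  tibble(rate = x$rate, p0 = x$p0, n = length(x$durations),
         dimension = x$dimension,
         median_duration = median(x$durations))
}

#' Posterior probability that a duration is a real feature
#'
#' Under the fitted mixture, the posterior probability that a bar of
#' duration `x` arises from the alternative (non-null) component:
#' \deqn{P(\mathrm{alt} \mid x) = \mathrm{clamp}\left(1 - p_0 f_0(x) /
#' \hat f(x),\ 0,\ 1\right)}
#' with the tail-monotonized false discovery rate of [fit_eb_model()].
#'
#' @param model A [fit_eb_model()] result.
#' @param x Non-negative duration(s).
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_alternative <- function(model, x) {
  stopifnot(inherits(model, "tda_eb"))
  if (any(x < 0))
    abort("usage error: durations must be non-negative",
          class = "tda_usage_error")
  pmin(pmax(1 - model$fdr(x), 0), 1)
}

#' Score a barcode with the empirical Bayes mixture
#'
#' Fits one mixture model per homology dimension at least 1 on that
#' dimension's finite durations (dimensions may instead be pooled into a
#' single model with `pool_dimensions = TRUE`), and returns the bars with
#' their posterior probabilities of being real features, sorted by
#' posterior descending. Infinite bars are excluded from fitting and
#' scoring; a dimension with fewer than 10 bars is scored but flagged
#' unstable.
#'
#' @param ph A [vietoris_rips()] result (or its `tidy()` bar tibble).
#' @param pool_dimensions Fit one model across all dimensions ≥ 1?
#'   (default `FALSE`, one model per dimension).
#' @param bandwidth,density_estimator Passed to [fit_eb_model()].
#' @return A tibble of class `tda_scored` with columns `id`, `dimension`,
#'   `birth`, `death`, `duration`, `posterior`, `unstable`; fitted models
#'   are attached as attribute `"models"` (a named list by dimension, or
#'   `"pooled"`).
#' @export
score_barcodes <- function(ph, pool_dimensions = FALSE, bandwidth = NULL,
                           density_estimator = c("kde", "logkde", "hist")) {
  density_estimator <- match.arg(density_estimator)
  bars <- if (inherits(ph, "tda_homology")) ph$pairs else as_tibble(ph)
  bars <- bars[bars$dimension >= 1 & is.finite(bars$death) &
                 bars$duration > 0, , drop = FALSE]
  empty <- tibble(id = integer(), dimension = integer(), birth = double(),
                  death = double(), duration = double(), posterior = double(),
                  unstable = logical())
  if (!nrow(bars)) {
    attr(empty, "models") <- list()
    class(empty) <- c("tda_scored", class(empty))
    return(empty)
  }
  models <- list()
  scored <- list()
  groups <- if (pool_dimensions) list(pooled = bars) else
    split(bars, bars$dimension)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    unstable <- nrow(g) < 10
    if (unstable)
      warn(paste0("dimension group '", gname, "' has only ", nrow(g),
                  " bars; its mixture fit is flagged unstable"))
    if (length(unique(g$duration)) < 3) {
      warn(paste0("dimension group '", gname, "' has too few distinct ",
                  "durations to fit a mixture; posteriors are NA"))
      g$posterior <- NA_real_
      g$unstable <- TRUE
    } else {
      mod <- fit_eb_model(g$duration, bandwidth = bandwidth,
                          density_estimator = density_estimator,
                          dimension = if (pool_dimensions) NA_integer_ else
                            as.integer(gname))
      g$posterior <- posterior_alternative(mod, g$duration)
      g$unstable <- unstable
      models[[gname]] <- mod
    }
    scored[[gname]] <- g
  }
  out <- dplyr::bind_rows(scored)
  out <- out[order(-out$posterior, -out$duration), ]
  attr(out, "models") <- models
  class(out) <- c("tda_scored", class(empty))
  out
}

#' Posterior curve plot for a fitted mixture
#' @param object A `tda_eb` model.
#' @param ... Unused.
#' @return A ggplot of posterior probability against duration.
#' @method autoplot tda_eb
#' @export
autoplot.tda_eb <- function(object, ...) {
  xs <- seq(min(object$durations), max(object$durations), length.out = 200)
  df <- data.frame(duration = xs,
                   posterior = posterior_alternative(object, xs))
  ggplot2::ggplot(df, ggplot2::aes(.data$duration, .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = data.frame(duration = object$durations),
                      ggplot2::aes(x = .data$duration), inherit.aes = FALSE,
                      sides = "b", alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "duration", y = "P(real feature | duration)",
                  title = paste0("Empirical Bayes posterior",
                                 if (!is.na(object$dimension))
                                   paste0(" (dim ", object$dimension, ")"))) +
    ggplot2::theme_minimal()
}

#' Write scored barcodes as TSV and model summaries as JSON
#' @param scored A [score_barcodes()] result.
#' @param path TSV output path.
#' @param models_path Optional JSON path for the per-dimension model
#'   summaries (rate, p0, n).
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path, models_path = NULL) {
  utils::write.table(as.data.frame(scored), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(models_path)) {
    models <- attr(scored, "models")
    summ <- lapply(models, function(m)
      list(rate = m$rate, p0 = m$p0, n = length(m$durations),
           dimension = m$dimension))
    jsonlite::write_json(summ, models_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
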