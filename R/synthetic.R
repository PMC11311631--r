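#' Simulate a cohort with a planted latent loop
#'
#' Each subject receives a latent angle \eqn{\phi \sim U[0, 2\pi)} on a
#' circle of the given radius with Gaussian radial noise; the two noisy
#' coordinates enter the cohort as continuous features. Each planted binary
#' feature with phase \eqn{\psi} takes its positive level exactly on the
#' half-circle \eqn{\cos(\phi - \psi) > 0}, so each level covers a 180-degree
#' arc and the features' centroid axes point in distinct, phase-shifted
#' directions. Nuisance continuous features are standard normal, nuisance
#' binary features fair coin flips, and missingness is completely at random.
#'
#' The defaults emulate a mid-sized clinical cohort shaped by three
#' phase-shifted prognostic dichotomies: n = 300 subjects, phases 0, 120
#' and 240 degrees, 10% radial noise, three nuisance continuous features.
#' Under these defaults the planted loop dominates: its bar is typically
#' several times longer than the next dimension-1 bar. Binary nuisance
#' features and missing values blur the planted geometry much faster than
#' continuous nuisance does (a stray binary split moves every affected
#' Gower distance by a full 1/p step, and a missing informative coordinate
#' lets mirror-image subjects bridge the loop), so both default to off and
#' are available as parameters for stress runs.
#'
#' @param n Number of subjects (≥ 30).
#' @param radius Latent circle radius.
#' @param noise_sd Radial noise standard deviation.
#' @param phases_deg Phase angles (degrees, in \[0, 360)) of the planted
#'   binary features.
#' @param n_noise_continuous,n_noise_binary Nuisance feature counts.
#' @param missing_rate Probability a feature cell is missing (< 0.5).
#' @param seed Optional RNG seed for exact reproducibility.
#' @return A [cohort()] whose attribute `"truth"` holds the latent angles
#'   (tibble `subject`, `angle_deg`) and the planted phases.
#' @export
simulate_loop_cohort <- function(n = 300, radius = 1, noise_sd = 0.1,
                                 phases_deg = c(0, 120, 240),
                                 n_noise_continuous = 3, n_noise_binary = 0,
                                 missing_rate = 0, seed = NULL) {
  if (n < 30) abort("usage error: n must be at least 30",
                    class = "tda_usage_error")
  if (missing_rate < 0 || missing_rate >= 0.5)
    abort("usage error: missing_rate must lie in [0, 0.5)",
          class = "tda_usage_error")
  if (any(phases_deg < 0 | phases_deg >= 360))
    abort("usage error: phases must lie in [0, 360)",
          class = "tda_usage_error")
  if (!is.null(seed)) set.seed(seed)
  phi <- runif(n, 0, 2 * pi)
  r <- radius + rnorm(n, 0, noise_sd)
  dat <- tibble(subject = sprintf("P%03d", seq_len(n)),
                coord_x = r * cos(phi), coord_y = r * sin(phi))
  feats <- c("coord_x", "coord_y")
  types <- c("continuous", "continuous")
  lvls <- list(NULL, NULL)
  for (i in seq_along(phases_deg)) {
    nm <- paste0("loop_factor_", i)
    psi <- phases_deg[i] * pi / 180
    dat[[nm]] <- ifelse(cos(phi - psi) > 0, "Pos", "Neg")
    feats <- c(feats, nm); types <- c(types, "binary_symmetric")
    lvls <- c(lvls, list(c("Neg", "Pos")))
  }
  for (i in seq_len(n_noise_continuous)) {
    nm <- paste0("noise_num_", i)
    dat[[nm]] <- rnorm(n)
    feats <- c(feats, nm); types <- c(types, "continuous")
    lvls <- c(lvls, list(NULL))
  }
  for (i in seq_len(n_noise_binary)) {
    nm <- paste0("noise_bin_", i)
    dat[[nm]] <- ifelse(rbinom(n, 1, 0.5) == 1, "Yes", "No")
    feats <- c(feats, nm); types <- c(types, "binary_symmetric")
    lvls <- c(lvls, list(c("No", "Yes")))
  }
  dat <- sprinkle_missing(dat, missing_rate)
  out <- cohort(dat, cohort_schema(feats, types, lvls))
  attr(out, "truth") <- list(
    angles = tibble(subject = out$subject, angle_deg = phi * 180 / pi),
    phases_deg = phases_deg,
    planted = paste0("loop_factor_", seq_along(phases_deg)))
  out
}

#' Simulate a cohort with a planted void
#'
#' Subjects are assigned uniformly to the 8 vertices of a cube and jittered
#' with isotropic Gaussian noise; with probability `shell` each point is
#' then pushed radially onto the cube's circumscribed sphere, leaving the
#' interior empty — the configuration that carries dimension-2 homology (a
#' filled cube has none). The three planted binary features record the sign
#' of each coordinate of the assigned vertex, so they form three
#' near-independent axes. Nuisance features and missingness as in
#' [simulate_loop_cohort()].
#'
#' @param n Number of subjects (≥ 30).
#' @param sd Gaussian diffusion around the vertices.
#' @param shell Probability of pushing a point onto the sphere (default 1).
#' @param n_noise_continuous,n_noise_binary Nuisance feature counts.
#' @param missing_rate Missingness probability (< 0.5).
#' @param seed Optional RNG seed.
#' @return A [cohort()]; attribute `"truth"` holds the vertex assignment.
#' @export
simulate_void_cohort <- function(n = 120, sd = 0.15, shell = 1,
                                 n_noise_continuous = 3, n_noise_binary = 0,
                                 missing_rate = 0, seed = NULL) {
  if (n < 30) abort("usage error: n must be at least 30",
                    class = "tda_usage_error")
  if (missing_rate < 0 || missing_rate >= 0.5)
    abort("usage error: missing_rate must lie in [0, 0.5)",
          class = "tda_usage_error")
  if (!is.null(seed)) set.seed(seed)
  verts <- as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5), c(-0.5, 0.5)))
  vid <- sample.int(8, n, replace = TRUE)
  pos <- verts[vid, , drop = FALSE] + matrix(rnorm(3 * n, 0, sd), n, 3)
  push <- runif(n) < shell
  rad <- sqrt(3) / 2  # circumscribed sphere of the unit cube
  nrm <- sqrt(rowSums(pos^2))
  nz <- push & nrm > 0
  pos[nz, ] <- pos[nz, , drop = FALSE] * (rad / nrm[nz])
  dat <- tibble(subject = sprintf("P%03d", seq_len(n)),
                coord_x = pos[, 1], coord_y = pos[, 2], coord_z = pos[, 3])
  feats <- c("coord_x", "coord_y", "coord_z")
  types <- rep("continuous", 3)
  lvls <- list(NULL, NULL, NULL)
  for (i in 1:3) {
    nm <- paste0("axis_factor_", i)
    dat[[nm]] <- ifelse(verts[vid, i] > 0, "Pos", "Neg")
    feats <- c(feats, nm); types <- c(types, "binary_symmetric")
    lvls <- c(lvls, list(c("Neg", "Pos")))
  }
  for (i in seq_len(n_noise_continuous)) {
    nm <- paste0("noise_num_", i)
    dat[[nm]] <- rnorm(n)
    feats <- c(feats, nm); types <- c(types, "continuous")
    lvls <- c(lvls, list(NULL))
  }
  for (i in seq_len(n_noise_binary)) {
    nm <- paste0("noise_bin_", i)
    dat[[nm]] <- ifelse(rbinom(n, 1, 0.5) == 1, "Yes", "No")
    feats <- c(feats, nm); types <- c(types, "binary_symmetric")
    lvls <- c(lvls, list(c("No", "Yes")))
  }
  dat <- sprinkle_missing(dat, missing_rate)
  out <- cohort(dat, cohort_schema(feats, types, lvls))
  attr(out, "truth") <- list(
    vertices = tibble(subject = out$subject, vertex = vid),
    planted = paste0("axis_factor_", 1:3))
  out
}

#' Simulate an unstructured (null) cohort
#'
#' Independent standard normal continuous features — the null model under
#' which bar durations follow an approximately exponential law.
#'
#' @param n Subjects (≥ 20).
#' @param p Features (≥ 2).
#' @param seed Optional RNG seed.
#' @return A [cohort()] of `p` continuous features.
#' @export
simulate_null_cohort <- function(n = 100, p = 10, seed = NULL) {
  if (n < 20 || p < 2)
    abort("usage error: need n >= 20 and p >= 2", class = "tda_usage_error")
  if (!is.null(seed)) set.seed(seed)
  dat <- as_tibble(matrix(rnorm(n * p), n, p),
                   .name_repair = ~ paste0("V", seq_len(p)))
  dat <- dplyr::bind_cols(tibble(subject = sprintf("P%03d", seq_len(n))), dat)
  cohort(dat, cohort_schema(paste0("V", seq_len(p)),
                            rep("continuous", p)))
}

# missing-completely-at-random mask over feature cells (never the subject id)
sprinkle_missing <- function(dat, rate) {
  if (rate <= 0) return(dat)
  for (nm in setdiff(names(dat), "subject")) {
    hit <- runif(nrow(dat)) < rate
    dat[[nm]][hit] <- NA
  }
  dat
}

#' Euclidean distance matrices of benchmark point clouds
#'
#' Fixed geometric fixtures and sampled manifolds whose homology is known:
#' `square_corners` (4 points, one loop born at 1 dying at sqrt(2)),
#' `octahedron` (6 points, one void born at sqrt(2) dying at 2), `circle`
#' (n equally spaced points, one dominant loop), `sphere` (n uniform
#' points, one dominant void), `torus` (uniform angles on a ring torus).
#'
#' @param shape One of `"circle"`, `"sphere"`, `"torus"`,
#'   `"square_corners"`, `"octahedron"`.
#' @param n Number of points (ignored for the fixed fixtures).
#' @param noise Isotropic Gaussian noise sd added to the coordinates.
#' @param seed Optional RNG seed.
#' @param radius Manifold radius (major radius for the torus).
#' @param minor_radius Torus minor radius.
#' @return A [stats::dist] of Euclidean distances.
#' @export
sample_shapes <- function(shape = c("circle", "sphere", "torus",
                                    "square_corners", "octahedron"),
                          n = 40, noise = 0, seed = NULL, radius = 1,
                          minor_radius = 0.4) {
  shape <- match.arg(shape)
  if (!is.null(seed)) set.seed(seed)
  pts <- switch(shape,
    square_corners = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    octahedron = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
    circle = {
      th <- 2 * pi * (seq_len(n) - 1) / n
      radius * cbind(cos(th), sin(th))
    },
    sphere = {
      z <- matrix(rnorm(3 * n), n, 3)
      radius * z / sqrt(rowSums(z^2))
    },
    torus = {
      u <- runif(n, 0, 2 * pi); v <- runif(n, 0, 2 * pi)
      cbind((radius + minor_radius * cos(v)) * cos(u),
            (radius + minor_radius * cos(v)) * sin(u),
            minor_radius * sin(v))
    })
  if (noise > 0) pts <- pts + matrix(rnorm(length(pts), 0, noise),
                                     nrow(pts), ncol(pts))
  dist(pts)
}
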