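# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

# Naive persistent homology: enumerate every simplex up to dim max_dim + 1,
# sort by (diameter, dim, lexicographic vertices), reduce the full boundary
# matrix over GF(2) left to right. Returns the (dim, birth, death) table of
# positive-persistence pairs plus essential classes.
naive_rips <- function(dmat, max_dim = 2, max_scale = max(dmat)) {
  n <- nrow(dmat)
  simp <- list(); diam <- c(); dims <- c()
  for (k in 1:(max_dim + 2)) {
    if (k > n) break
    cmb <- combn(n, k)
    for (j in seq_len(ncol(cmb))) {
      v <- cmb[, j]
      d <- if (k == 1) 0 else max(dmat[t(combn(v, 2))])
      if (d <= max_scale) {
        simp[[length(simp) + 1]] <- v
        diam[length(diam) + 1] <- d
        dims[length(dims) + 1] <- k - 1L
      }
    }
  }
  lex <- vapply(simp, function(v) paste(sprintf("%05d", v), collapse = ""), "")
  o <- order(diam, dims, lex)
  simp <- simp[o]; diam <- diam[o]; dims <- dims[o]
  m <- length(simp)
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(m)) assign(paste(simp[[i]], collapse = ","), i, envir = idx)
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    v <- simp[[j]]
    cols[[j]] <- if (length(v) > 1)
      sort(vapply(seq_along(v), function(s)
        get(paste(v[-s], collapse = ","), envir = idx), 1L))
    else integer(0)
  }
  lowmap <- integer(m)
  pairs <- NULL
  for (j in seq_len(m)) {
    c_j <- cols[[j]]
    while (length(c_j)) {
      l <- max(c_j)
      k <- lowmap[l]
      if (k == 0) break
      c_j <- sort(c(setdiff(c_j, cols[[k]]), setdiff(cols[[k]], c_j)))
    }
    cols[[j]] <- c_j
    if (length(c_j)) {
      l <- max(c_j)
      lowmap[l] <- j
      pairs <- rbind(pairs, c(dims[l], diam[l], diam[j]))
    }
  }
  has_col <- vapply(seq_len(m), function(j) length(cols[[j]]) > 0, TRUE)
  ess <- setdiff(seq_len(m), c(which(lowmap > 0), which(has_col)))
  for (e in ess)
    if (dims[e] <= max_dim) pairs <- rbind(pairs, c(dims[e], diam[e], Inf))
  pairs <- pairs[pairs[, 3] > pairs[, 2], , drop = FALSE]
  pairs <- pairs[pairs[, 1] <= max_dim, , drop = FALSE]
  colnames(pairs) <- c("dimension", "birth", "death")
  pairs[order(pairs[, 1], pairs[, 2], pairs[, 3]), , drop = FALSE]
}

diagram_of <- function(ph) {
  p <- tidy(ph)
  m <- cbind(dimension = p$dimension, birth = p$birth, death = p$death)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Brute-force Gower dissimilarity: per-pair loop straight from the formula.
gower_oracle <- function(ch) {
  sch <- schema_of(ch)
  num <- as.matrix(to_numeric(ch)[, sch$feature, drop = FALSE])
  n <- nrow(ch)
  rng <- rep(NA_real_, nrow(sch))
  for (k in seq_len(nrow(sch)))
    if (sch$type[k] %in% c("continuous", "ordinal"))
      rng[k] <- diff(range(num[, k], na.rm = TRUE))
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num_sum <- den_sum <- 0
    for (k in seq_len(nrow(sch))) {
      xi <- num[i, k]; xj <- num[j, k]
      if (is.na(xi) || is.na(xj)) next
      tp <- sch$type[k]
      if (tp %in% c("continuous", "ordinal")) {
        if (rng[k] == 0) next  # uninformative feature
        num_sum <- num_sum + abs(xi - xj) / rng[k]
        den_sum <- den_sum + 1
      } else if (tp == "binary_asymmetric") {
        if (xi == 0 && xj == 0) next
        num_sum <- num_sum + as.numeric(xi != xj)
        den_sum <- den_sum + 1
      } else {
        num_sum <- num_sum + as.numeric(xi != xj)
        den_sum <- den_sum + 1
      }
    }
    out[i, j] <- out[j, i] <- if (den_sum == 0) NA_real_ else num_sum / den_sum
  }
  dimnames(out) <- list(ch$subject, ch$subject)
  out
}

# Random mixed-type cohort for oracle sweeps.
random_mixed_cohort <- function(n = 10, seed = 1, missing_rate = 0.1) {
  set.seed(seed)
  dat <- tibble::tibble(
    subject = paste0("s", seq_len(n)),
    cont_1 = rnorm(n), cont_2 = runif(n, 0, 10),
    ord_1 = sample(paste("Stage", 0:3), n, replace = TRUE),
    nom_1 = sample(c("A", "B", "C"), n, replace = TRUE),
    bsym_1 = sample(c("F", "M"), n, replace = TRUE),
    basym_1 = sample(c("Absent", "Present"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
  )
  for (nm in setdiff(names(dat), "subject")) {
    hit <- runif(n) < missing_rate
    dat[[nm]][hit] <- NA
  }
  sch <- cohort_schema(
    feature = c("cont_1", "cont_2", "ord_1", "nom_1", "bsym_1", "basym_1"),
    type = c("continuous", "continuous", "ordinal", "nominal",
             "binary_symmetric", "binary_asymmetric"),
    levels = list(NULL, NULL, paste("Stage", 0:3), c("A", "B", "C"),
                  c("F", "M"), c("Absent", "Present")),
    positive_level = c(NA, NA, NA, NA, NA, "Present")
  )
  cohort(dat, sch)
}

# Textbook silhouette: direct double loop over the definition.
silhouette_oracle <- function(dmat, labels) {
  n <- nrow(dmat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(dmat[i, labels == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Shared expensive simulations, computed once per test session.
.sim_cache <- new.env(parent = emptyenv())

cached_loop_run <- function(seed) {
  key <- paste0("loop_", seed)
  if (!exists(key, envir = .sim_cache)) {
    ch <- simulate_loop_cohort(seed = seed)
    d <- daisy_distance(ch)
    ph <- vietoris_rips(d, max_dim = 1)
    assign(key, list(cohort = ch, dist = d, ph = ph), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

cached_null_run <- function(seed) {
  key <- paste0("null_", seed)
  if (!exists(key, envir = .sim_cache)) {
    ch <- simulate_null_cohort(100, 10, seed = seed)
    ph <- vietoris_rips(daisy_distance(ch), max_dim = 2,
                        representatives = FALSE)
    assign(key, list(cohort = ch, ph = ph), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}
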