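test_that("classical MDS reproduces exact low-dimensional geometry", {
  # collinear points at mutual distances 1, 1, 2
  d <- as.dist(rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  emb <- embed_distance(d, "mds", k = 1)
  x <- sort(emb$X1)
  expect_equal(diff(x), c(1, 1), tolerance = 1e-8)
  # planar configurations are recovered up to rigid motion
  set.seed(14)
  P <- matrix(rnorm(20), 10, 2)
  emb2 <- embed_distance(dist(P), "mds", k = 2)
  expect_equal(as.matrix(dist(as.matrix(emb2[, c("X1", "X2")]))),
               as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # dimension bound
  expect_error(embed_distance(d, k = 3), class = "tda_usage_error")
})

test_that("embeddings are deterministic given identical input", {
  run <- cached_loop_run(1)
  e1 <- embed_distance(run$dist, "nmds", k = 2)
  e2 <- embed_distance(run$dist, "nmds", k = 2)
  expect_identical(e1, e2)
})

test_that("loop_centroid averages the distinct representative vertices", {
  emb <- structure(
    tibble::tibble(subject = c("a", "b", "c", "d"),
                   X1 = c(-1, 1, 1, -1), X2 = c(-1, -1, 1, 1)),
    class = c("tda_embedding", class(tibble::tibble())))
  rep <- rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))
  expect_equal(loop_centroid(emb, rep), c(X1 = 0, X2 = 0),
               ignore_attr = TRUE)
  # degenerate: one repeated vertex is its own centroid
  expect_equal(unname(loop_centroid(emb, c("b", "b"))), c(1, -1))
  # regular polygon centroid hits the centre to machine precision
  th <- 2 * pi * (0:11) / 12
  emb12 <- structure(
    tibble::tibble(subject = paste0("p", 1:12),
                   X1 = cos(th) + 2, X2 = sin(th) - 1),
    class = c("tda_embedding", class(tibble::tibble())))
  expect_equal(unname(loop_centroid(emb12, paste0("p", 1:12))), c(2, -1),
               tolerance = 1e-12)
  expect_error(loop_centroid(emb, character(0)), class = "tda_usage_error")
})

test_that("sector assignment bins angles and enforces divisibility", {
  emb <- structure(
    tibble::tibble(subject = c("a", "b", "c"),
                   X1 = c(1, cos(25 * pi / 180), 0),
                   X2 = c(0, sin(25 * pi / 180), 0)),
    class = c("tda_embedding", class(tibble::tibble())))
  expect_warning(s <- assign_sectors(emb, c(0, 0)), "centroid")
  expect_equal(s$sector[1], 0)   # angle 0 -> sector 0
  expect_equal(s$sector[2], 1)   # angle 25 -> sector 1
  expect_true(is.na(s$sector[3]))
  expect_equal(attr(s, "n_sectors"), 18)
  expect_error(assign_sectors(emb, c(0, 0), width = 25),
               class = "tda_usage_error")
  # all off-centroid subjects are partitioned
  set.seed(2)
  emb2 <- structure(
    tibble::tibble(subject = paste0("s", 1:50),
                   X1 = rnorm(50), X2 = rnorm(50)),
    class = c("tda_embedding", class(tibble::tibble())))
  s2 <- assign_sectors(emb2, c(0, 0))
  expect_equal(sum(table(s2$sector)), 50)
})

test_that("sector profiles average per sector with missing handling", {
  sectors <- structure(
    tibble::tibble(subject = paste0("s", 1:36),
                   angle = (0:35) * 10, sector = rep(0:17, each = 2)),
    n_sectors = 18L)
  expect_equal(sector_profile(rep(1, 36), sectors), rep(1, 18))
  # indicator of the upper half-plane
  upper <- as.numeric(sectors$angle < 180)
  prof <- sector_profile(upper, sectors)
  expect_equal(prof, c(rep(1, 9), rep(0, 9)))
  # empty sector yields NA
  s2 <- sectors; s2$sector[s2$sector == 5] <- 6
  expect_true(is.na(sector_profile(rep(1, 36), s2)[6]))
})

test_that("fit_sinusoid recovers exact coefficients and ranks noise high", {
  th <- ((0:17) + 0.5) * 20 * pi / 180
  fit <- fit_sinusoid(2 + sin(th))
  expect_equal(c(fit$b0, fit$b1, fit$b2), c(2, 1, 0), tolerance = 1e-10)
  expect_equal(fit$kappa, 0, tolerance = 1e-10)
  expect_equal(fit$peak_angle, 90, tolerance = 1e-6)
  # constant means are flagged with undefined kappa
  fitc <- fit_sinusoid(rep(3, 18))
  expect_equal(fitc$flag, "constant")
  expect_true(is.na(fitc$kappa))
  # agreement with a generic least-squares oracle (lm) on noisy means
  set.seed(77)
  for (i in 1:5) {
    y <- rnorm(18)
    got <- fit_sinusoid(y)
    orac <- lm(y ~ sin(th) + cos(th))
    expect_equal(unname(c(got$b0, got$b1, got$b2)), unname(coef(orac)),
                 tolerance = 1e-10)
    expect_equal(got$mse, sum(resid(orac)^2) / 18, tolerance = 1e-10)
  }
  # white-noise null: kappa concentrates near 1 (median >= 0.6)
  set.seed(42)
  ks <- replicate(300, fit_sinusoid(rnorm(18))$kappa)
  expect_gte(median(ks), 0.6)
  # contracts
  expect_error(fit_sinusoid(c(1, 2, 3, rep(NA, 15))),
               class = "tda_usage_error")
})

test_that("kappa is invariant under affine rescaling of the feature", {
  set.seed(13)
  y <- rnorm(18)
  expect_equal(fit_sinusoid(y)$kappa, fit_sinusoid(3.7 * y - 11)$kappa,
               tolerance = 1e-10)
})

test_that("centroid separation measures group displacement", {
  sch <- cohort_schema("grp", "binary_symmetric", list(c("A", "B")))
  n <- 4000
  set.seed(21)
  # perfectly separated groups at (0,0) and (1,0) with small jitter
  grp <- rep(c("A", "B"), each = n / 2)
  emb <- structure(
    tibble::tibble(subject = paste0("s", 1:n),
                   X1 = as.numeric(grp == "B") + rnorm(n, 0, 0.01),
                   X2 = rnorm(n, 0, 0.01)),
    class = c("tda_embedding", class(tibble::tibble())))
  ch <- cohort(data.frame(subject = paste0("s", 1:n), grp = grp), sch)
  sep <- centroid_separation(ch, emb)
  expect_equal(sep$separation, 1, tolerance = 0.01)
  expect_equal(sep$n_1 + sep$n_2, n)
  # a random feature separates by ~0 at large n
  ch2 <- cohort(data.frame(subject = paste0("s", 1:n),
                           grp = sample(c("A", "B"), n, TRUE)), sch)
  expect_lte(centroid_separation(ch2, emb)$separation, 0.05)
  # an empty level is flagged, not an error
  ch3 <- cohort(data.frame(subject = paste0("s", 1:n),
                           grp = rep("A", n)), sch)
  sep3 <- centroid_separation(ch3, emb)
  expect_true(is.na(sep3$separation))
  expect_equal(sep3$flag, "one_level_empty")
})

test_that("loop_fit ranks planted phase-shifted features by kappa", {
  run <- cached_loop_run(1)
  emb <- embed_distance(run$dist, "mds", k = 2)
  rep1 <- representative_cycle(run$ph, most_persistent(run$ph, 1))
  lf <- loop_fit(run$cohort, emb, rep1)
  expect_s3_class(lf, "tda_loop_fit")
  expect_equal(ncol(lf$profile), 18)
  fits <- tidy(lf)
  expect_false(is.unsorted(fits$kappa, na.rm = TRUE))
  # the latent coordinates are themselves perfect sinusoids around the loop
  expect_true(all(c("coord_x", "coord_y") %in% head(fits$feature, 4)))
  # planted binary factors carry phase-shifted signals: their peak angles
  # are mutually separated (phase differences are frame-invariant)
  pk <- fits$peak_angle[match(paste0("loop_factor_", 1:3), fits$feature)]
  gaps <- sort(diff(sort(pk)))
  expect_gte(min(c(gaps, 360 - sum(gaps))), 60)
})

test_that("circos tables are kappa-ordered and row-scaled to [0, 1]", {
  run <- cached_loop_run(1)
  emb <- embed_distance(run$dist, "mds", k = 2)
  lf <- loop_fit(run$cohort, emb,
                 representative_cycle(run$ph, most_persistent(run$ph, 1)))
  m <- circos_table(lf)
  expect_equal(rownames(m), tidy(lf)$feature)
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  rng <- apply(m, 1, function(r) range(r, na.rm = TRUE))
  expect_true(all(abs(rng[1, ] - 0) < 1e-12))
  expect_true(all(abs(rng[2, ] - 1) < 1e-12 |
                    rownames(m) %in% attr(m, "flagged")))
  # empty feature list gives an empty grid
  m0 <- circos_table(lf, features = character(0))
  expect_equal(nrow(m0), 0)
  # CSV export
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_circos(lf, tmp)
  expect_equal(nrow(utils::read.csv(tmp, row.names = 1)), nrow(m))
})

cube_cohort <- function(n = 80, seed = 5) {
  set.seed(seed)
  verts <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  vid <- sample.int(8, n, TRUE)
  pos <- verts[vid, ] + matrix(rnorm(3 * n, 0, 0.05), n, 3)
  dat <- data.frame(subject = paste0("s", 1:n),
                    fx = ifelse(verts[vid, 1] > 0, "Hi", "Lo"),
                    fy = ifelse(verts[vid, 2] > 0, "Hi", "Lo"),
                    fz = ifelse(verts[vid, 3] > 0, "Hi", "Lo"))
  sch <- cohort_schema(c("fx", "fy", "fz"), rep("binary_symmetric", 3),
                       list(c("Lo", "Hi"), c("Lo", "Hi"), c("Lo", "Hi")))
  emb <- structure(
    tibble::tibble(subject = dat$subject, X1 = pos[, 1], X2 = pos[, 2],
                   X3 = pos[, 3]),
    class = c("tda_embedding", class(tibble::tibble())))
  list(cohort = cohort(dat, sch), emb = emb)
}

test_that("void axes of a cube align with the coordinate directions", {
  cc <- cube_cohort()
  ax <- void_axes(cc$cohort, cc$emb, c("fx", "fy", "fz"))
  expect_equal(abs(ax$determinant), 1, tolerance = 0.02)
  expect_false(ax$collinear)
  # each unit axis is close to a coordinate direction
  expect_equal(abs(diag(ax$directions)), rep(1, 3), tolerance = 0.02,
               ignore_attr = TRUE)
  # two identical features give collinear axes, flagged not an error
  ax2 <- void_axes(cc$cohort, cc$emb, c("fx", "fx", "fy"))
  expect_equal(ax2$determinant, 0, tolerance = 1e-9)
  expect_true(ax2$collinear)
  expect_error(void_axes(cc$cohort, cc$emb, c("fx", "fy")),
               class = "tda_usage_error")
})

test_that("sphere projection normalizes displacements from the centroid", {
  cc <- cube_cohort(n = 40, seed = 9)
  sph <- sphere_projection(cc$emb, c(0, 0, 0))
  expect_equal(sqrt(sph$U1^2 + sph$U2^2 + sph$U3^2), rep(1, nrow(sph)),
               tolerance = 1e-12)
  # a subject at centroid + (2, 0, 0) projects to (1, 0, 0)
  emb <- structure(
    tibble::tibble(subject = c("a", "b"), X1 = c(2, -2), X2 = c(0, 0),
                   X3 = c(0, 0)),
    class = c("tda_embedding", class(tibble::tibble())))
  sph2 <- sphere_projection(emb, c(0, 0, 0))
  expect_equal(unname(unlist(sph2[1, c("U1", "U2", "U3")])), c(1, 0, 0))
  # antipodal subjects land antipodally
  expect_equal(unname(unlist(sph2[2, c("U1", "U2", "U3")])), c(-1, 0, 0))
})

test_that("void skeletons export as valid OFF meshes", {
  d <- sample_shapes("octahedron")
  ph <- vietoris_rips(d, max_dim = 2)
  emb3 <- embed_distance(d, "mds", k = 3)
  rep2 <- representative_cycle(ph, most_persistent(ph, 2))
  tmp <- withr::local_tempfile(fileext = ".off")
  write_mesh_off(rep2, emb3, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "OFF")
  expect_equal(scan(text = lines[2], quiet = TRUE), c(6, 8, 0))
})
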