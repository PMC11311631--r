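test_that("square corners yield exactly one loop bar [1, sqrt(2))", {
  d <- sample_shapes("square_corners")
  ph <- vietoris_rips(d, max_dim = 2)
  bars <- tidy(ph)
  loop <- bars[bars$dimension == 1, ]
  expect_equal(nrow(loop), 1)
  expect_identical(loop$birth, 1)
  expect_identical(loop$death, sqrt(2))
  expect_equal(sum(bars$dimension == 2), 0)
  # representative is the 4 square edges
  rep <- representative_cycle(ph, loop$id)
  expect_equal(nrow(rep), 4)
  expect_setequal(representative_vertices(ph, loop$id), ph$labels)
  # dim 0: n - 1 finite bars plus exactly one infinite bar
  d0 <- bars[bars$dimension == 0, ]
  expect_equal(sum(is.finite(d0$death)), 3)
  expect_equal(sum(is.infinite(d0$death)), 1)
})

test_that("octahedron yields exactly one void bar [sqrt(2), 2)", {
  d <- sample_shapes("octahedron")
  ph <- vietoris_rips(d, max_dim = 2)
  bars <- tidy(ph)
  void <- bars[bars$dimension == 2, ]
  expect_equal(nrow(void), 1)
  expect_equal(void$birth, sqrt(2))
  expect_identical(void$death, 2)
  # its representative is the 8 facet triangles of the hollow octahedron
  rep <- representative_cycle(ph, void$id)
  expect_equal(dim(rep), c(8, 3))
})

test_that("an equilateral simplex carries no positive-persistence loop", {
  d <- as.dist(matrix(1, 3, 3) - diag(3))
  ph <- vietoris_rips(d, max_dim = 2)
  expect_equal(sum(tidy(ph)$dimension >= 1), 0)
})

test_that("homology matches the naive reduction oracle on random spaces", {
  set.seed(20)
  for (trial in 1:15) {
    np <- sample(4:8, 1)
    X <- if (trial %% 3 == 0) matrix(sample(0:2, np * 2, TRUE), np)
         else matrix(rnorm(np * 3), np)
    dm <- as.matrix(dist(X))
    dimnames(dm) <- NULL
    got <- diagram_of(vietoris_rips(dm, max_dim = 2))
    want <- naive_rips(dm, max_dim = 2)
    expect_equal(unname(got), unname(want), tolerance = 1e-14,
                 label = paste("trial", trial))
  }
})

test_that("representatives are cycles with the right diameter", {
  set.seed(32)
  th <- 2 * pi * (0:9) / 10
  X <- cbind(cos(th), sin(th)) + matrix(rnorm(20, 0, 0.15), 10)
  dm <- as.matrix(dist(X)); dimnames(dm) <- NULL
  ph <- vietoris_rips(dm, max_dim = 2)
  bars <- tidy(ph)
  expect_gt(sum(bars$dimension >= 1 & is.finite(bars$death)), 0)
  for (i in bars$id[bars$dimension >= 1 & is.finite(bars$death)]) {
    rep <- ph$representatives[[i]]
    dd <- bars$dimension[bars$id == i]
    # boundary vanishes mod 2: every face appears an even number of times
    faces <- do.call(rbind, lapply(seq_len(nrow(rep)), function(r)
      t(combn(rep[r, ], dd))))
    counts <- table(apply(faces, 1, paste, collapse = ","))
    expect_true(all(counts %% 2 == 0))
    # max simplex diameter equals the birth (up to ties)
    mx <- max(apply(rep, 1, function(v) max(dm[t(combn(v, 2))])))
    expect_equal(mx, bars$birth[bars$id == i], tolerance = 1e-12)
  }
})

test_that("dim-0 deaths are the single-linkage merge heights", {
  set.seed(12)
  X <- matrix(rnorm(15 * 2), 15)
  dm <- as.matrix(dist(X))
  ph <- vietoris_rips(dm, max_dim = 1)
  d0 <- tidy(ph)
  d0 <- sort(d0$death[d0$dimension == 0 & is.finite(d0$death)])
  hc <- hclust(dist(X), method = "single")
  expect_equal(d0, sort(hc$height), tolerance = 1e-12)
})

test_that("points on a circle give one dominant loop visiting most points", {
  d <- sample_shapes("circle", n = 40)
  ph <- vietoris_rips(d, max_dim = 1)
  loops <- tidy(ph)
  loops <- loops[loops$dimension == 1, ]
  loops <- loops[order(-loops$duration), ]
  expect_gte(loops$duration[1],
             3 * if (nrow(loops) > 1) loops$duration[2] else 0)
  rep <- representative_cycle(ph, loops$id[1])
  verts <- unique(as.vector(rep))
  expect_gte(length(verts), 20)
  # a single closed cycle: every vertex meets exactly two edges
  deg <- table(as.vector(rep))
  expect_true(all(deg == 2))
})

test_that("duplicate points change no finite bar in dims >= 1", {
  set.seed(4)
  X <- matrix(rnorm(12 * 2), 12)
  X2 <- rbind(X, X[5, ])
  bars <- function(X) {
    b <- tidy(vietoris_rips(as.matrix(dist(X)), max_dim = 2))
    b <- b[b$dimension >= 1 & is.finite(b$death), c("dimension", "birth", "death")]
    b[order(b$dimension, b$birth, b$death), ]
  }
  expect_equal(bars(X), bars(X2), ignore_attr = TRUE)
})

test_that("raising max_scale never removes an already-dead pair", {
  set.seed(8)
  X <- matrix(rnorm(14 * 2), 14)
  dm <- as.matrix(dist(X))
  cut <- stats::median(dm)
  lo <- tidy(vietoris_rips(dm, max_dim = 1, max_scale = cut))
  hi <- tidy(vietoris_rips(dm, max_dim = 1))
  lo_dead <- lo[is.finite(lo$death) & lo$death < cut,
                c("dimension", "birth", "death")]
  hi_key <- paste(hi$dimension, signif(hi$birth, 12), signif(hi$death, 12))
  lo_key <- paste(lo_dead$dimension, signif(lo_dead$birth, 12),
                  signif(lo_dead$death, 12))
  expect_true(all(lo_key %in% hi_key))
})

test_that("build_filtration lists simplices in filtration order", {
  d <- as.dist(matrix(1, 3, 3) - diag(3))  # 3 points pairwise distance 1
  filt <- build_filtration(d, max_dim = 1, max_scale = 2)
  expect_equal(nrow(filt), 7)  # 3 vertices + 3 edges + 1 triangle
  expect_true(all(diff(filt$diameter) >= 0))
  expect_equal(filt$dim, c(0, 0, 0, 1, 1, 1, 2))
})

test_that("the resource guard trips on combinatorially infeasible requests", {
  expect_equal(simplex_counts(266)$count[2:3], c(35245, 3101560))
  expect_equal(simplex_counts(266, max_dim = 2)$count[4], 203927570)
  set.seed(1)
  dm <- as.matrix(dist(matrix(rnorm(600), 300)))
  expect_error(vietoris_rips(dm, max_dim = 2, size_ceiling = 5e7),
               class = "tda_resource_error")
  expect_error(vietoris_rips(dm, max_dim = 2, size_ceiling = 5e7),
               "choose")
})

test_that("cut_clusters recovers separated blobs and boundary cases", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20, 0, 0.2), 10), matrix(rnorm(20, 5, 0.2), 10))
  d <- dist(X)
  lab <- cut_clusters(d, 2)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_false(lab[1] == lab[11])
  expect_equal(length(unique(cut_clusters(d, 20))), 20)
  expect_equal(length(unique(cut_clusters(d, 1))), 1)
})

test_that("barcode TSV export carries representatives", {
  d <- sample_shapes("square_corners")
  ph <- vietoris_rips(d, max_dim = 2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_barcodes(ph, tmp)
  tab <- utils::read.delim(tmp)
  expect_equal(nrow(tab), nrow(tidy(ph)))
  expect_true(any(grepl(";", tab$representative)))
})
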