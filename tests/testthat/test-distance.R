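test_that("Gower dissimilarity matches the formula on hand-built cases", {
  sch <- cohort_schema(
    feature = c("x", "sex", "grp"),
    type = c("continuous", "binary_symmetric", "nominal"),
    levels = list(NULL, c("F", "M"), c("A", "B", "C"))
  )
  # continuous range 10 with |diff| 5, matching binary, mismatching nominal
  dat <- data.frame(subject = 1:3, x = c(0, 5, 10),
                    sex = c("F", "F", "M"), grp = c("A", "B", "A"))
  d <- as.matrix(daisy_distance(cohort(dat, sch)))
  expect_equal(d[1, 2], (0.5 + 0 + 1) / 3)
  # identical subjects on all shared features -> distance 0
  sch2 <- cohort_schema(c("x", "sex", "grp"),
                        c("continuous", "binary_symmetric", "nominal"),
                        list(NULL, c("F", "M"), c("A", "B", "C")))
  d2 <- suppressWarnings(as.matrix(daisy_distance(cohort(
    data.frame(subject = 1:3, x = c(3, 3, 9), sex = c("F", "F", "M"),
               grp = c("B", "B", "A")), sch2))))
  expect_equal(d2[1, 2], 0)
})

test_that("asymmetric binary joint absence yields an undefined pair", {
  sch <- cohort_schema("flag", "binary_asymmetric", list(c("No", "Yes")),
                       positive_level = "Yes")
  dat <- data.frame(subject = 1:2, flag = c("No", "No"))
  expect_error(daisy_distance(cohort(dat, sch)),
               class = "tda_distance_error")
  # the error names the offending pair
  expect_error(daisy_distance(cohort(dat, sch)), "share no usable feature")
})

test_that("zero-range continuous features are dropped with a warning", {
  sch <- cohort_schema(c("x", "y"), c("continuous", "continuous"))
  dat <- data.frame(subject = 1:3, x = c(1, 1, 1), y = c(0, 1, 2))
  expect_warning(d <- daisy_distance(cohort(dat, sch)), "zero observed range")
  expect_equal(as.matrix(d)[1, 3], 1)  # only y contributes, range-normalized
})

test_that("daisy_distance equals the brute-force Gower oracle", {
  for (seed in 1:8) {
    ch <- random_mixed_cohort(n = 10, seed = seed, missing_rate = 0.1)
    got <- try(as.matrix(daisy_distance(ch)), silent = TRUE)
    want <- gower_oracle(ch)
    if (inherits(got, "try-error")) {
      expect_true(anyNA(want))  # oracle agrees the pair is undefined
      next
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("removing a feature missing for a pair leaves that distance alone", {
  ch <- random_mixed_cohort(n = 8, seed = 3, missing_rate = 0)
  ch$cont_2[c(1, 2)] <- NA
  d_full <- as.matrix(daisy_distance(ch))
  sch <- schema_of(ch)
  keep <- setdiff(sch$feature, "cont_2")
  ch_red <- cohort(as.data.frame(ch)[, c("subject", keep)],
                   sch[sch$feature %in% keep, ])
  d_red <- as.matrix(daisy_distance(ch_red))
  expect_equal(d_full[1, 2], d_red[1, 2], tolerance = 1e-12)
})

test_that("all-continuous complete data reduce to scaled Manhattan distance", {
  set.seed(9)
  p <- 4
  dat <- as.data.frame(matrix(runif(12 * p), 12))
  names(dat) <- paste0("v", 1:p)
  dat$subject <- 1:12
  ch <- cohort(dat, cohort_schema(paste0("v", 1:p), rep("continuous", p)))
  d <- as.matrix(daisy_distance(ch))
  num <- as.matrix(dat[paste0("v", 1:p)])
  scl <- sweep(num, 2, apply(num, 2, min))
  scl <- sweep(scl, 2, apply(num, 2, function(x) diff(range(x))), "/")
  man <- as.matrix(dist(scl, method = "manhattan")) / p
  expect_equal(d, man, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("binary feature distances match hand computations", {
  sch <- cohort_schema(paste0("b", 1:3), rep("binary_symmetric", 3),
                       list(c("0", "1"), c("0", "1"), c("0", "1")))
  dat <- data.frame(subject = 1:4,
                    b1 = c("1", "1", "0", "0"),
                    b2 = c("1", "0", "1", "0"),
                    b3 = c("1", "1", "0", "0"))
  ch <- cohort(dat, sch)
  sm <- as.matrix(binary_feature_distance(ch, "sokal_michener"))
  pe <- as.matrix(binary_feature_distance(ch, "pearson"))
  expect_equal(sm["b1", "b2"], 0.5)   # 2 of 4 match
  expect_equal(pe["b1", "b2"], 0.5)   # r = 0
  expect_equal(sm["b1", "b3"], 0)     # identical vectors
  expect_equal(pe["b1", "b3"], 0)
  # complementary vectors: 0110 vs 1001
  dat2 <- data.frame(subject = 1:4, b1 = c("0", "1", "1", "0"),
                     b2 = c("1", "0", "0", "1"))
  ch2 <- cohort(dat2, cohort_schema(c("b1", "b2"),
                                    rep("binary_symmetric", 2),
                                    list(c("0", "1"), c("0", "1"))))
  expect_equal(as.matrix(binary_feature_distance(ch2, "sokal_michener"))[1, 2], 1)
  expect_equal(as.matrix(binary_feature_distance(ch2, "pearson"))[1, 2], 1)
  # alternative pearson transform
  expect_equal(as.matrix(binary_feature_distance(
    ch2, "pearson", pearson_transform = "one_minus"))[1, 2], 2)
})

test_that("constant binary features give NA Pearson entries with a warning", {
  dat <- data.frame(subject = 1:4, b1 = c("1", "1", "1", "1"),
                    b2 = c("1", "0", "1", "0"))
  ch <- cohort(dat, cohort_schema(c("b1", "b2"), rep("binary_symmetric", 2),
                                  list(c("0", "1"), c("0", "1"))))
  expect_warning(pe <- binary_feature_distance(ch, "pearson"), "constant")
  expect_true(is.na(as.matrix(pe)[1, 2]))
  # sokal-michener remains defined
  expect_equal(as.matrix(binary_feature_distance(ch, "sokal_michener"))[1, 2],
               0.5)
})

test_that("distance exports round-trip through CSV and PHYLIP text", {
  d <- sample_shapes("octahedron")
  tmp <- withr::local_tempdir()
  write_distance_csv(d, file.path(tmp, "d.csv"))
  back <- as.matrix(utils::read.csv(file.path(tmp, "d.csv"), row.names = 1))
  expect_equal(unname(back), unname(as.matrix(d)), tolerance = 1e-8)
  write_distance_phylip(d, file.path(tmp, "d.phy"))
  lines <- readLines(file.path(tmp, "d.phy"))
  expect_equal(as.integer(trimws(lines[1])), 6)
  expect_length(lines, 7)
})
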