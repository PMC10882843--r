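test_that("CSS factors follow the cumulative-sum-below-quantile rule", {
  # flat sample: median count 10, factor = 40, all values 1000 * 10/40 = 250
  flat <- make_count_table(matrix(c(10, 10, 10, 10), 1,
                                  dimnames = list("S1", letters[1:4])))
  out <- css_normalize(flat)
  expect_equal(unname(as.matrix(out[, -1])[1, ]), rep(250, 4))
  expect_equal(unname(attr(out, "scaling_factors")), 40)

  # single-taxon sample: factor n, normalized value = scale constant
  single <- make_count_table(matrix(17, 1, dimnames = list("S1", "a")))
  expect_equal(as.matrix(css_normalize(single)[, -1])[1, 1], 1000,
               ignore_attr = TRUE)

  # hand-computed 3 x 4 toy (q = 0.5, type-7 quantile over nonzero counts)
  m <- matrix(c(1, 2, 3, 4,
                10, 0, 10, 20,
                5, 5, 0, 0), 3, 4, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), letters[1:4]))
  # S1: median 2.5 -> 1 + 2 = 3; S2: median of (10,10,20)=10 -> 20; S3: 5 -> 10
  out2 <- css_normalize(make_count_table(m))
  expect_equal(unname(attr(out2, "scaling_factors")), c(3, 20, 10))
  expect_equal(unname(as.matrix(out2[, -1])[1, ]), c(1, 2, 3, 4) / 3 * 1000)

  # scale invariance: doubling a sample's counts leaves its values unchanged
  tbl <- random_count_table(4, 6, seed = 3)
  doubled <- tbl
  doubled[2, -1] <- doubled[2, -1] * 2
  expect_equal(as.matrix(css_normalize(doubled)[, -1]),
               as.matrix(css_normalize(tbl)[, -1]))

  zero <- make_count_table(matrix(c(1, 0, 2, 0), 2,
                                  dimnames = list(c("S1", "Szero"), c("a", "b"))))
  expect_error(css_normalize(zero), "Szero")
})

test_that("alpha diversity matches the direct formula", {
  tbl <- make_count_table(matrix(c(25, 25, 25, 25,
                                   100, 0, 0, 0,
                                   50, 30, 20, 0), 3, 4, byrow = TRUE,
                                 dimnames = list(NULL, letters[1:4])))
  a <- alpha_diversity(tbl)
  expect_equal(a$richness, c(4L, 1L, 3L))
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[2], 0)
  p <- c(50, 30, 20) / 100
  expect_equal(a$shannon[3], -sum(p * log(p)), tolerance = 1e-12)
  # invariants: shannon <= log(richness)
  rnd <- random_count_table(10, 8, seed = 5)
  ar <- alpha_diversity(rnd)
  expect_true(all(ar$shannon <= log(ar$richness) + 1e-12))
})

test_that("Bray-Curtis has the formula values and metric-like properties", {
  tbl <- make_count_table(matrix(c(1, 1, 0,
                                   0, 1, 1,
                                   1, 1, 0,
                                   0, 0, 5), 4, 3, byrow = TRUE,
                                 dimnames = list(NULL, letters[1:3])))
  d <- as.matrix(bray_curtis(tbl))
  expect_equal(d[1, 2], 0.5)        # (1+0+1)/(1+2+1)
  expect_equal(d[1, 3], 0)          # identical
  expect_equal(d[1, 4], 1)          # disjoint supports
  for (s in 1:3) {
    r <- random_count_table(8, 10, seed = s)
    dm <- as.matrix(bray_curtis(r))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0 & dm <= 1))
  }
  zeros <- make_count_table(matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE,
                                   dimnames = list(NULL, c("a", "b"))))
  expect_error(bray_curtis(zeros), "all-zero")
})

test_that("beta-dispersion equals direct distance-to-centroid on Euclidean input", {
  set.seed(7)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("S", 1:5), NULL))
  d <- dist(pts)
  bd <- beta_dispersion(d, rep("g", 5))
  direct <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  expect_equal(bd$distance_to_centroid, unname(direct), tolerance = 1e-8)

  # identical samples: zero dispersion; singleton group: zero
  tbl <- make_count_table(matrix(c(3, 4, 3, 4, 9, 1), 3, 2, byrow = TRUE,
                                 dimnames = list(paste0("S", 1:3), c("a", "b"))))
  d2 <- bray_curtis(tbl)
  bd2 <- beta_dispersion(d2, c("x", "x", "solo"))
  expect_equal(bd2$distance_to_centroid[1:2], c(0, 0), tolerance = 1e-12)
  expect_equal(bd2$distance_to_centroid[3], 0, tolerance = 1e-12)

  # four equidistant samples (regular simplex): equal dispersions
  simplex <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  attr(simplex, "Labels") <- paste0("S", 1:4)
  bs <- beta_dispersion(simplex, rep("g", 4))
  expect_equal(diff(range(bs$distance_to_centroid)), 0, tolerance = 1e-10)
})

test_that("shared features match brute-force set algebra", {
  # 3 groups x 6 features toy; presence computed per group then intersected
  m <- matrix(c(
    5, 0, 2, 0, 1, 0,   # g1 samples
    1, 0, 0, 0, 1, 0,
    0, 3, 2, 0, 1, 0,   # g2 samples
    0, 1, 0, 0, 0, 0,
    0, 0, 2, 4, 1, 0,   # g3 samples
    0, 0, 1, 1, 0, 0), 6, 6, byrow = TRUE,
    dimnames = list(paste0("S", 1:6), paste0("f", 1:6)))
  groups <- rep(c("g1", "g2", "g3"), each = 2)
  sf <- shared_features(make_count_table(m), groups)
  present <- list(g1 = c("f1", "f3", "f5"), g2 = c("f2", "f3", "f5"),
                  g3 = c("f3", "f4", "f5"))
  combos <- setNames(sf$combinations$n, sf$combinations$groups)
  # brute force every feature's presence signature
  sig <- vapply(paste0("f", 1:6), function(f) {
    paste(names(present)[vapply(present, function(g) f %in% g, logical(1))],
          collapse = "&")
  }, character(1))
  expected <- table(sig[sig != ""])
  expect_equal(combos[names(expected)], unclass(expected)[names(expected)],
               ignore_attr = TRUE)
  expect_equal(sf$all_groups_intersection, 2L)  # f3 and f5
  expect_equal(sf$totals$n[sf$totals$group == "g1"], 3L)

  # one group: unique count = number of present features
  one <- shared_features(make_count_table(m[1:2, ]), rep("g", 2))
  expect_equal(one$totals$n, 3L)
  # identical presence across two groups: all shared, no uniques
  two <- shared_features(make_count_table(m[c(1, 2, 1, 2), ],
                                          ids = paste0("T", 1:4)),
                         rep(c("a", "b"), each = 2))
  expect_equal(two$combinations$groups, "a&b")
  expect_equal(two$all_groups_intersection, 3L)
})

test_that("min_samples presence rule is honoured", {
  m <- matrix(c(2, 0,
                1, 0,
                0, 3), 3, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("a", "b")))
  sf <- shared_features(make_count_table(m), c("g", "g", "g"), min_samples = 2)
  expect_equal(sf$totals$n, 1L)  # only taxon a present in >= 2 samples
})
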