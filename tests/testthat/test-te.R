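test_that("sparse pattern counts match the dense full-scan oracle", {
  set.seed(101)
  for (rep in 1:40) {
    D <- sample(60:400, 1)
    k <- sample(1:5, 1)
    l <- sample(1:5, 1)
    d <- sample(1:min(30, D - l - 3), 1)
    if (D - max(k, d + l - 1) <= 1) next
    dens <- stats::runif(1, 0, 0.5)
    i <- rbin(D, dens)
    j <- rbin(D, dens)
    cp <- count_patterns(i, j, k, l, d)
    expect_equal(unname(cp$counts), unname(dense_counts(i, j, k, l, d)),
                 info = sprintf("D=%d k=%d l=%d d=%d", D, k, l, d))
    expect_equal(sum(cp$counts), cp$n_valid)
    expect_equal(cp$n_valid, D - max(k, d + l - 1))
  }
})

test_that("all-zero series yield a single all-zero pattern", {
  cp <- count_patterns(rep(0, 50), rep(0, 50), k = 2, l = 2, d = 3)
  expect_equal(cp$counts[1, 1, 1], cp$n_valid)
  expect_equal(sum(cp$counts), cp$n_valid)
})

test_that("alternating identical series occupy exactly two patterns", {
  x <- rep(c(0, 1), 30)
  cp <- count_patterns(x, x, k = 1, l = 1, d = 1)
  occ <- which(cp$counts > 0)
  expect_length(occ, 2)
  expect_equal(sort(unname(cp$counts[cp$counts > 0])),
               c(floor(cp$n_valid / 2), ceiling(cp$n_valid / 2)))
})

test_that("transfer entropy matches direct evaluation of the defining sum", {
  set.seed(102)
  for (rep in 1:20) {
    D <- sample(100:400, 1)
    k <- sample(1:3, 1)
    l <- sample(1:3, 1)
    d <- sample(1:5, 1)
    i <- rbin(D, 0.3)
    j <- rbin(D, 0.3)
    cp <- count_patterns(i, j, k, l, d)
    expect_equal(te_from_counts(cp), naive_te(cp$counts), tolerance = 1e-12)
  }
})

test_that("product-form counts give exactly zero transfer entropy", {
  # counts with p(i_next | i_word, j_word) independent of j_word
  r <- matrix(c(30, 10, 25, 15), 2, 2)  # (i_next, i_word)
  s <- c(3, 7)                          # j_word weights
  cnt <- array(0, c(2, 2, 2))
  for (a in 1:2) for (b in 1:2) for (g in 1:2)
    cnt[a, b, g] <- r[a, b] * s[g]
  expect_equal(te_from_counts(cnt), 0, tolerance = 1e-14)
})

test_that("a perfect one-bit copy channel carries one bit", {
  set.seed(103)
  D <- 4000
  j <- rbin(D, 0.5)
  i <- c(0, j[-D])  # i(t+1) = j(t)
  expect_equal(d1te(i, j), 1, tolerance = 5e-3)
})

test_that("TE estimates lie in [0, 1] bits for binary targets", {
  set.seed(104)
  for (rep in 1:25) {
    D <- sample(100:500, 1)
    i <- rbin(D, stats::runif(1, 0.02, 0.5))
    j <- rbin(D, stats::runif(1, 0.02, 0.5))
    v <- te_from_counts(count_patterns(i, j, sample(1:3, 1), sample(1:3, 1),
                                       sample(1:4, 1)))
    expect_gte(v, -1e-12)
    expect_lte(v, 1 + 1e-12)
  }
})

test_that("d1te equals delayed TE at delay one and hote reduces to delayed TE", {
  set.seed(105)
  i <- rbin(500, 0.2)
  j <- rbin(500, 0.2)
  prof <- delayed_te(i, j, delays = 1:10)
  expect_equal(d1te(i, j), prof$values[1])
  hot <- hote(i, j, k = 1, l = 1, delays = 1:10)
  expect_identical(hot$values, prof$values)
})

test_that("delayed TE localizes a pure transmission lag", {
  set.seed(106)
  D <- 30000
  j <- rbin(D, 0.03)
  i <- c(rep(0, 7), j[1:(D - 7)])  # i(t) = j(t - 7)
  prof <- delayed_te(i, j, delays = 1:30)
  expect_equal(prof$delays[which.max(prof$values)], 7)
})

test_that("burst-coded transmission is seen better at message length two", {
  # target responds only to two consecutive source spikes
  set.seed(107)
  D <- 60000
  j <- rbin(D, 0.15)
  pairs2 <- j == 1 & c(0, j[-D]) == 1
  i <- c(0, as.integer(pairs2[-D] & stats::runif(D - 1) < 0.9))
  pk1 <- max(hote(i, j, k = 1, l = 1, delays = 1:10)$values)
  pk2 <- max(hote(i, j, k = 1, l = 2, delays = 1:10)$values)
  expect_gt(pk2, pk1)
})

test_that("constant-zero source yields an all-zero TE profile", {
  i <- rbin(300, 0.2)
  prof <- delayed_te(i, rep(0, 300), delays = 1:10)
  expect_equal(prof$values, rep(0, 10))
})

test_that("dependence vanishes under source shuffling", {
  set.seed(108)
  D <- 20000
  j <- rbin(D, 0.05)
  i <- c(0, as.integer(j[-D] & stats::runif(D - 1) < 0.8))
  orig <- d1te(i, j)
  sh <- replicate(40, d1te(i, sample(j)))
  expect_gte(mean(orig > sh), 0.95)
})

test_that("independent series stay below a spike-jitter null across delays", {
  set.seed(109)
  D <- 200000
  i <- rbin(D, 0.004)
  j <- rbin(D, 0.03)
  prof <- delayed_te(i, j, delays = 1:30)
  jitter_null <- replicate(20, {
    tj <- which(j == 1) - 1
    tj <- unique(sort(pmin(pmax(tj + sample(-50:50, length(tj),
                                            replace = TRUE), 0), D - 1)))
    js <- integer(D)
    js[tj + 1] <- 1L
    max(delayed_te(i, js, delays = 1:30)$values)
  })
  expect_lt(max(prof$values), stats::quantile(jitter_null, 0.99) * 1.5)
})

test_that("the batch path agrees with the single-pair path", {
  set.seed(110)
  n <- 4
  D <- 3000
  mats <- lapply(1:n, function(q) rbin(D, 0.05))
  raster <- spike_raster(do.call(rbind, mats))
  for (ord in list(c(1, 1), c(2, 3))) {
    ps <- te_profiles(raster, k = ord[1], l = ord[2], delays = c(1, 4, 9))
    for (p in seq_len(nrow(ps$pairs))) {
      i <- mats[[ps$pairs$post[p]]]
      j <- mats[[ps$pairs$pre[p]]]
      ref <- hote(i, j, k = ord[1], l = ord[2], delays = c(1, 4, 9))
      expect_equal(ps$values[p, ], ref$values, tolerance = 1e-12)
    }
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(count_patterns(rbin(10, .5), rbin(10, .5), k = 1, l = 1,
                              d = 12), "valid time positions")
  expect_error(count_patterns(rbin(20, .5), rbin(20, .5), k = 6, l = 1,
                              d = 1), "k and l")
})

test_that("the optional Miller-Madow correction matches its closed form", {
  set.seed(111)
  for (rep in 1:8) {
    i <- rbin(800, 0.2)
    j <- rbin(800, 0.2)
    cp <- count_patterns(i, j, k = 2, l = 1, d = 2)
    raw <- te_from_counts(cp)
    corrected <- te_from_counts(cp, correction = "miller-madow")
    cnt <- cp$counts
    supp <- function(m) sum(m > 0)
    offset <- (supp(apply(cnt, c(1, 2), sum)) - supp(apply(cnt, 2, sum)) -
                 supp(cnt) + supp(apply(cnt, c(2, 3), sum))) /
      (2 * cp$n_valid * log(2))
    expect_equal(corrected, raw + offset, tolerance = 1e-12)
    # the full joint support dominates, so the correction lowers the bias
    expect_lte(corrected, raw + 1e-12)
  }
  # the correction is negligible for a long, strongly informative channel
  set.seed(112)
  j <- rbin(6000, 0.5)
  i <- c(0, j[-6000])
  expect_equal(te_from_counts(count_patterns(i, j, 1, 1, 1),
                              correction = "miller-madow"),
               1, tolerance = 5e-3)
})
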