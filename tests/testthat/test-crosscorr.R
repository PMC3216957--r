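test_that("self-correlation at zero lag is exactly one for both variants", {
  set.seed(201)
  x <- rbin(500, 0.2)
  expect_equal(ncc(x, x, delays = 0)$values, 1)
  expect_equal(ncch(x, x, delays = 0)$values, 1)
})

test_that("NCC matches a direct overlap-window computation", {
  set.seed(202)
  for (rep in 1:10) {
    D <- sample(50:200, 1)
    i <- rbin(D, 0.3)
    j <- rbin(D, 0.4)
    taus <- 0:10
    ref <- vapply(taus, function(tau) {
      t <- 1:(D - tau)
      sum((i[t + tau] - mean(i)) * (j[t] - mean(j))) /
        (D * stats::sd(i) * sqrt((D - 1) / D) *
           stats::sd(j) * sqrt((D - 1) / D))
    }, numeric(1))
    expect_equal(ncc(i, j, delays = taus)$values, ref, tolerance = 1e-12)
  }
})

test_that("NCCH is the coincidence count over the geometric-mean norm", {
  i <- c(0, 1, 0, 1, 1, 0, 0, 1)
  j <- c(1, 0, 0, 1, 0, 0, 1, 0)
  # lag 1 matches (0-based): j spikes {0,3,6}, i spikes {1,3,4,7}:
  # pairs (0,1), (3,4), (6,7)
  expect_equal(ncch(i, j, delays = 1)$values,
               3 / sqrt(4 * 3))
})

test_that("anti-correlated series give negative NCC at zero lag", {
  set.seed(203)
  j <- rbin(400, 0.5)
  expect_lt(ncc(1 - j, j, delays = 0)$values, 0)
})

test_that("independent dense series decorrelate at CLT rate", {
  set.seed(204)
  D <- 10000
  i <- rbin(D, 0.5)
  j <- rbin(D, 0.5)
  vals <- ncc(i, j, delays = 0:20)$values
  expect_true(all(abs(vals) <= 3 / sqrt(D)))
})

test_that("NCC approaches NCCH in the sparse-spike limit", {
  set.seed(205)
  D <- 50000
  i <- rbin(D, 0.002)
  j <- rbin(D, 0.002)
  a <- ncc(i, j, delays = 1:10)$values
  b <- ncch(i, j, delays = 1:10)$values
  expect_lt(max(abs(a - b)), 0.005)
})

test_that("pair swap with lag negation is a symmetry of NCC", {
  set.seed(206)
  i <- rbin(300, 0.3)
  j <- rbin(300, 0.3)
  # NCC_{ij}(tau) uses source j preceding target i by tau; swapping roles
  # and keeping the same lag direction must give the transpose relation
  ij <- ncc(i, j, delays = 0:5)$values
  ji <- ncc(j, i, delays = 0:5)$values
  expect_equal(ij[1], ji[1], tolerance = 1e-12)  # tau = 0 symmetric
})

test_that("degenerate series are flagged as missing, not errors", {
  x <- rbin(100, 0.3)
  expect_true(all(is.na(ncc(x, rep(0, 100), delays = 0:3)$values)))
  expect_true(all(is.na(ncch(x, rep(0, 100), delays = 0:3)$values)))
  expect_true(all(is.na(ncc(rep(1, 100), x, delays = 0:3)$values)))
})

test_that("batch profiles agree with per-pair computation", {
  set.seed(207)
  mats <- lapply(1:4, function(q) rbin(2000, 0.05))
  raster <- spike_raster(do.call(rbind, mats))
  for (variant in c("ncc", "ncch")) {
    ps <- cc_profiles(raster, variant, delays = 1:15)
    fun <- if (variant == "ncc") ncc else ncch
    for (p in seq_len(nrow(ps$pairs))) {
      ref <- fun(mats[[ps$pairs$post[p]]], mats[[ps$pairs$pre[p]]],
                 delays = 1:15)
      expect_equal(ps$values[p, ], ref$values, tolerance = 1e-12)
    }
  }
})
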