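test_that("positive_loss matches hand arithmetic and the scalar oracle", {
  expect_lt(positive_loss(c(1, 0), c(1 - 1e-7, 0.5)), 1e-6)
  expect_equal(positive_loss(c(1, 0, 0), c(0.8, 0.6, 0.1)), -log(0.8),
               tolerance = 1e-12)
  expect_equal(positive_loss(c(0, 0), c(0.3, 0.7)), 0)
  set.seed(5)
  y <- rbinom(50, 1, 0.3)
  p <- runif(50)
  expect_equal(positive_loss(y, p), oracle_cross_entropy(y, p)$pos,
               tolerance = 1e-12)
  expect_error(positive_loss(c(1, 0), c(0.5)), "length")
})

test_that("negative_loss matches hand arithmetic and scales linearly in lambda", {
  expect_equal(negative_loss(c(1, 0, 0), c(0.8, 0.6, 0.1), lambda_ = 0.6),
               -0.6 * (log(0.4) + log(0.9)), tolerance = 1e-12)
  set.seed(6)
  y <- rbinom(40, 1, 0.2)
  p <- runif(40)
  expect_equal(negative_loss(y, p, lambda_ = 0), 0)
  l1 <- negative_loss(y, p, lambda_ = 1)
  for (lam in c(0.1, 0.37, 0.6, 2)) {
    expect_identical(negative_loss(y, p, lambda_ = lam), lam * l1)
  }
  # lambda = 1 over all-negative labels equals the oracle's negative part.
  y0 <- rep(0, 40)
  expect_equal(negative_loss(y0, p, lambda_ = 1),
               oracle_cross_entropy(y0, p)$neg, tolerance = 1e-12)
  expect_error(negative_loss(y, p, lambda_ = -0.1), "nonnegative")
})

test_that("masked_loss matches hand arithmetic on the worked example", {
  lb <- masked_loss(c(1, 0, 0), c(0.8, 0.6, 0.1), lambda_ = 0.6,
                    mask = c(0, 1, 0))
  expect_equal(lb$l_m, -log(0.8) - 0.6 * log(0.4), tolerance = 1e-12)
  expect_equal(lb$l_ps, -log(0.8), tolerance = 1e-12)
  expect_equal(lb$n_pos, 1L)
  expect_equal(lb$n_neg_kept, 1L)
})

test_that("perfect predictions give (near-)zero masked loss", {
  y <- c(1, 1, 0, 0, 1)
  lb <- masked_loss(y, y, lambda_ = 1, mask = 1 - y)
  expect_lt(lb$l_m, 1e-5)
})

test_that("full mask at lambda 1 reduces to standard cross-entropy (oracle, many instances)", {
  set.seed(99)
  for (rep in seq_len(1000)) {
    n <- sample(3:40, 1)
    y <- rbinom(n, 1, 0.3)
    p <- runif(n)
    lb <- masked_loss(y, p, lambda_ = 1, mask = rep(1, n))
    o <- oracle_cross_entropy(y, p)
    expect_equal(lb$l_m, o$total, tolerance = 1e-12)
    expect_equal(lb$l_ps + lb$l_ns, lb$l_m, tolerance = 1e-9)
    expect_equal(lb$l_m,
                 positive_loss(y, p) + negative_loss(y, p, lambda_ = 1),
                 tolerance = 1e-12)
  }
})

test_that("flipping a mask bit from 1 to 0 never increases the loss", {
  set.seed(21)
  for (rep in seq_len(50)) {
    n <- sample(5:30, 1)
    y <- rbinom(n, 1, 0.3)
    p <- runif(n)
    m <- rbinom(n, 1, 0.7) * (1 - y)
    base <- masked_loss(y, p, lambda_ = 0.6, mask = m)$l_m
    on <- which(m == 1)
    if (length(on) == 0) next
    i <- sample(on, 1)
    m2 <- m; m2[i] <- 0
    expect_lte(masked_loss(y, p, lambda_ = 0.6, mask = m2)$l_m, base)
  }
})

test_that("per-term normalization divides by the positive and kept-negative counts", {
  y <- c(1, 1, 0, 0, 0)
  p <- c(0.7, 0.6, 0.3, 0.2, 0.4)
  m <- c(0, 0, 1, 1, 0)
  plain <- masked_loss(y, p, lambda_ = 0.5, mask = m)
  norm <- masked_loss(y, p, lambda_ = 0.5, mask = m, normalize = TRUE)
  expect_equal(norm$l_ps, plain$l_ps / 2, tolerance = 1e-12)
  expect_equal(norm$l_ns, plain$l_ns / 2, tolerance = 1e-12)
})

test_that("sample_negative_mask is a pure function of labels, fraction and seed", {
  lab <- structure(c(rep(0L, 50), rep(1L, 5), rep(NA_integer_, 5)),
                   class = "anchor_labels")
  m1 <- sample_negative_mask(lab, 0.4, seed = 77)
  m2 <- sample_negative_mask(lab, 0.4, seed = 77)
  expect_identical(unclass(m1), unclass(m2))
  m3 <- sample_negative_mask(lab, 0.4, seed = 78)
  expect_false(identical(unclass(m1), unclass(m3)))
  # Mask never touches positive or ignored positions.
  expect_true(all(unclass(m1)[51:60] == 0))
})

test_that("mask keep counts follow Binomial(n, kappa) within 3 sigma", {
  lab <- structure(rep(0L, 10000), class = "anchor_labels")
  for (kappa in c(0.1, 0.3, 0.6)) {
    m <- sample_negative_mask(lab, kappa, seed = 123)
    kept <- sum(unclass(m))
    expect_lt(abs(kept - 10000 * kappa), 3 * sqrt(10000 * kappa * (1 - kappa)))
  }
  expect_equal(sum(unclass(sample_negative_mask(lab, 1.0, seed = 1))), 10000)
})

test_that("mask edge cases behave: no negatives, bad fractions", {
  all_pos <- structure(rep(1L, 10), class = "anchor_labels")
  expect_equal(sum(unclass(sample_negative_mask(all_pos, 0.5, seed = 1))), 0)
  lab <- structure(rep(0L, 10), class = "anchor_labels")
  expect_error(sample_negative_mask(lab, 0), "keep_fraction")
  expect_error(sample_negative_mask(lab, 1.2), "keep_fraction")
})

test_that("loss breakdown serializes to a flat JSON record", {
  lb <- masked_loss(c(1, 0), c(0.9, 0.2), lambda_ = 0.6, mask = c(0, 1))
  js <- loss_record_json(lb)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$l_m, lb$l_m, tolerance = 1e-12)
  expect_equal(rec$lambda_, 0.6)
})
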