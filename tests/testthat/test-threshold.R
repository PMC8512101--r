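test_that("hard and soft thresholds match their closed forms", {
  expect_equal(threshold_hard(2, 1), 2)
  expect_equal(threshold_hard(0.5, 1), 0)
  expect_equal(threshold_hard(-1, 1), -1)    # boundary |w| = lambda is kept
  expect_equal(threshold_soft(2, 1), 1)
  expect_equal(threshold_soft(-2, 1), -1)
  expect_equal(threshold_soft(0.5, 1), 0)
  set.seed(10)
  for (lam in c(0, 0.3, 1.7)) {
    w <- rnorm(200, sd = 2)
    expect_equal(threshold_hard(w, lam), ifelse(abs(w) >= lam, w, 0))
    expect_equal(threshold_soft(w, lam),
                 ifelse(abs(w) >= lam, sign(w) * (abs(w) - lam), 0))
  }
  expect_error(threshold_hard(1, -0.1), ">= 0")
  expect_error(threshold_soft(1, -1), ">= 0")
})

test_that("improved threshold matches its printed formula and limits", {
  # value at the threshold equals (1 - m) * lambda from both sides
  for (lam in c(0.5, 1, 3)) for (m in c(0.2, 0.5, 0.8)) for (k in 1:3) {
    expect_equal(threshold_improved(lam, lam, k, m), (1 - m) * lam,
                 tolerance = 1e-12)
    eps <- 1e-8 * lam
    expect_lt(abs(threshold_improved(lam + eps, lam, k, m) - (1 - m) * lam),
              1e-6)
    expect_lt(abs(threshold_improved(lam - eps, lam, k, m) - (1 - m) * lam),
              1e-6)
  }
  expect_equal(threshold_improved(0, 2, 1, 0.5), 0)
  # frozen high-precision evaluation of the upper branch
  expect_equal(threshold_improved(1000, 1, 1, 0.5), 936.77093152731472,
               tolerance = 1e-12)
  # relative deviation bound m / (1 + log(|w| / lambda))
  expect_lt(abs(threshold_improved(1000, 1, 1, 0.5) - 1000) / 1000,
            0.5 / (1 + log(1000)) + 1e-12)
  # asymptotic approach to the identity
  w <- 1e6
  expect_lt(abs(threshold_improved(w, 1, 2, 0.5) - w) / w, 0.04)
  # lambda = 0 degenerates to the identity
  expect_equal(threshold_improved(c(-2, 0, 3), 0, 1, 0.5), c(-2, 0, 3))
  expect_error(threshold_improved(1, 1, 0, 0.5), "k")
  expect_error(threshold_improved(1, 1, 1, 1), "m")
  expect_error(threshold_improved(1, 1, 1, 0), "m")
})

test_that("all three threshold functions are odd and shrinking", {
  set.seed(11)
  w <- c(rnorm(100, sd = 3), 0, 1, -1, 0.999, 1.001)
  for (lam in c(0.5, 1, 2)) for (m in c(0.2, 0.8)) for (k in c(1, 3)) {
    fs <- list(hard = threshold_hard(w, lam),
               soft = threshold_soft(w, lam),
               improved = threshold_improved(w, lam, k, m))
    neg <- list(hard = threshold_hard(-w, lam),
                soft = threshold_soft(-w, lam),
                improved = threshold_improved(-w, lam, k, m))
    for (nm in names(fs)) {
      expect_equal(neg[[nm]], -fs[[nm]], tolerance = 1e-12)
      expect_true(all(abs(fs[[nm]]) <= abs(w) + 1e-12))
    }
  }
})

test_that("risk-selected threshold agrees with enumeration", {
  expect_equal(heursure_lambda(c(0, 0, 0)), 0)
  expect_equal(heursure_lambda(c(1, 2, 3)), 2)  # tie at i = 2, 3 -> smaller i
  for (trial in 1:200) {
    set.seed(trial + 400)
    W <- rnorm(sample(8:256, 1), sd = runif(1, 0.2, 5))
    lam <- heursure_lambda(W)
    expect_equal(lam, oracle_heursure(W))
    expect_true(any(abs(sort(W^2) - lam^2) < 1e-12))  # structural membership
  }
  expect_error(heursure_lambda(numeric(0)), "non-empty")
  expect_error(heursure_lambda(c(1, NA)), "finite")
})

test_that("SNR and RMSE follow their defining formulas", {
  expect_equal(snr_db(c(3, 4), c(0, 0)), 0)
  expect_equal(snr_db(c(1, 2), c(1, 2)), Inf)
  set.seed(12)
  x <- rnorm(50)
  y <- x + rnorm(50, sd = 0.3)
  expect_equal(snr_db(3 * x, 3 * y), snr_db(x, y), tolerance = 1e-10)
  expect_equal(rmse(c(3, 4), c(0, 0)), 3.5355339059327376, tolerance = 1e-12)
  expect_equal(rmse(x, x), 0)
  d <- 0.7
  n <- 100
  z <- numeric(n)
  z2 <- z
  z2[40] <- d
  expect_equal(rmse(z, z2), d / sqrt(n), tolerance = 1e-12)
  expect_error(snr_db(1:3, 1:4), "equal length")
  expect_error(snr_db(c(0, 0), c(1, 1)), "zero")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("SNR and RMSE are monotone in the same residual", {
  set.seed(13)
  ref <- rnorm(200)
  ests <- lapply(c(0.1, 0.3, 0.5, 1), function(s) ref + rnorm(200, sd = s))
  snrs <- vapply(ests, function(e) snr_db(ref, e), numeric(1))
  rmses <- vapply(ests, function(e) rmse(ref, e), numeric(1))
  expect_equal(order(snrs), rev(order(rmses)))
})

test_that("denoising pipeline preserves length, zeros, and smooth trends", {
  dz <- wp_denoise(signal_record(rep(0, 512), 1000), threshold_config(),
                   "db4", 3)
  expect_equal(max(abs(dz$signal$samples)), 0)
  set.seed(14)
  x <- rnorm(5000)
  dn <- wp_denoise(signal_record(x, 2000), threshold_config("soft"),
                   "db8", 4)
  expect_equal(length(dn$signal$samples), 5000)
  expect_true(all(!is.na(dn$per_node_lambda)))
  # a noiseless smooth trend passes nearly unchanged when the
  # energy-carrying approximation leaf is exempted from shrinkage
  t <- seq(0, 1, length.out = 4096)
  poly <- 5 + 10 * t - 8 * t^2 + 3 * t^3
  dp <- wp_denoise(signal_record(poly, 1000),
                   threshold_config("improved", threshold_approx = FALSE),
                   "db8", 4)
  expect_lt(sqrt(sum((dp$signal$samples - poly)^2) / sum(poly^2)), 0.05)
  expect_true(any(is.na(dp$per_node_lambda)))   # exempt leaf recorded as NA
})

test_that("fixed-lambda and level-pooled threshold configurations work", {
  set.seed(15)
  sig <- signal_record(rnorm(1024), 1000)
  d1 <- wp_denoise(sig, threshold_config("hard", lambda_rule = "fixed",
                                         fixed_lambda = 10), "db4", 3)
  expect_equal(max(abs(d1$signal$samples)), 0)  # everything below 10 killed
  d2 <- wp_denoise(sig, threshold_config("soft", pool = "level"), "db4", 3)
  lam <- d2$per_node_lambda
  lev <- as.integer(sub("\\..*", "", names(lam)))
  for (l in unique(lev)) {
    expect_equal(length(unique(lam[lev == l])), 1L)  # one lambda per level
  }
  expect_error(threshold_config(lambda_rule = "fixed", fixed_lambda = -1),
               ">= 0")
})
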