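test_that("shannon entropy matches closed forms and rejects bad input", {
  expect_equal(shannon_entropy(c(0, 0, 0)), 0)
  expect_equal(shannon_entropy(1), 0)
  expect_equal(shannon_entropy(c(1 / sqrt(2), 1 / sqrt(2))), log(2),
               tolerance = 1e-12)
  # direct term-by-term reference on a random vector
  set.seed(1)
  s <- rnorm(32)
  expect_equal(shannon_entropy(s), -sum(s^2 * log(s^2)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(1, NA)), "finite")
  expect_error(shannon_entropy(c(1, Inf)), "finite")
})

test_that("decomposition produces a complete entropy-annotated tree", {
  set.seed(2)
  sig <- signal_record(rnorm(512), 2000)
  tr <- wp_decompose(sig, "db4", 4)
  expect_s3_class(tr, "wp_tree")
  expect_equal(length(tr$nodes), sum(2^(0:4)))
  expect_equal(nrow(tr$best_leaves), 16)            # full depth-4 leaf set
  expect_true(all(tr$best_leaves[, "level"] == 4))
  # root holds the input
  expect_equal(tr$nodes[["0.0"]]$coefficients, sig$samples)
  # every node entropy agrees with a recomputation
  for (key in names(tr$nodes)) {
    expect_equal(tr$nodes[[key]]$entropy,
                 shannon_entropy(tr$nodes[[key]]$coefficients))
  }
  zt <- wp_decompose(signal_record(rep(0, 256), 1), "db4", 3)
  expect_true(all(vapply(zt$nodes, `[[`, numeric(1), "entropy") == 0))
})

test_that("too-deep decomposition errors name the feasible depth", {
  expect_error(wp_decompose(signal_record(rnorm(8), 1), "db2", 5),
               "maximum feasible level: 3")
})

test_that("transform is orthonormal: perfect reconstruction and Parseval", {
  for (n in c(1024, 4096)) {
    set.seed(n)
    x <- rnorm(n)
    tr <- wp_decompose(signal_record(x, 2000), "db45", 4)
    rec <- wp_reconstruct(tr)
    expect_lt(max(abs(rec$samples - x)), 1e-8 * max(abs(x)))
    # energy conservation across every single-level tiling
    ex <- sum(x^2)
    for (lev in 0:4) {
      e <- sum(vapply(0:(2^lev - 1), function(i) {
        sum(tr$nodes[[sprintf("%d.%d", lev, i)]]$coefficients^2)
      }, numeric(1)))
      expect_lt(abs(e - ex) / ex, 1e-6)
    }
  }
})

test_that("reconstruction is linear and zero coefficients give zero output", {
  set.seed(5)
  x <- rnorm(1024)
  tr <- wp_decompose(signal_record(x, 100), "db8", 3)
  tr <- wp_best_tree(tr)
  half <- tr
  for (r in seq_len(nrow(tr$best_leaves))) {
    key <- sprintf("%d.%d", tr$best_leaves[r, 1], tr$best_leaves[r, 2])
    half$nodes[[key]]$coefficients <- half$nodes[[key]]$coefficients / 2
  }
  expect_equal(wp_reconstruct(half)$samples, x / 2, tolerance = 1e-10)
  zero <- tr
  for (r in seq_len(nrow(tr$best_leaves))) {
    key <- sprintf("%d.%d", tr$best_leaves[r, 1], tr$best_leaves[r, 2])
    zero$nodes[[key]]$coefficients <- 0 * zero$nodes[[key]]$coefficients
  }
  expect_equal(max(abs(wp_reconstruct(zero)$samples)), 0)
})

test_that("reconstruction rejects an incomplete tiling", {
  tr <- wp_decompose(signal_record(rnorm(64), 1), "db2", 2)
  tr$best_leaves <- tr$best_leaves[-1, ]
  expect_error(wp_reconstruct(tr), "tile")
})

test_that("split rule follows the strict child-entropy comparison", {
  ent <- list("0.0" = 1.0, "1.0" = 0.3, "1.1" = 0.4)
  tr <- wp_best_tree(make_entropy_tree(1, ent))   # 0.3 + 0.4 < 1.0: split
  expect_equal(canonical_leaves(tr$best_leaves), "1.0;1.1")
  ent <- list("0.0" = 0.7, "1.0" = 0.3, "1.1" = 0.4)
  tr <- wp_best_tree(make_entropy_tree(1, ent))   # tie: keep parent
  expect_equal(canonical_leaves(tr$best_leaves), "0.0")
})

test_that("zero signal prunes to the root alone", {
  tr <- wp_best_tree(wp_decompose(signal_record(rep(0, 128), 1), "db4", 3))
  expect_equal(canonical_leaves(tr$best_leaves), "0.0")
})

test_that("best-tree selection matches exhaustive pruning enumeration", {
  for (trial in 1:100) {
    set.seed(trial)
    J <- sample(1:3, 1)
    ent <- list()
    for (lev in 0:J) for (idx in 0:(2^lev - 1)) {
      ent[[sprintf("%d.%d", lev, idx)]] <- runif(1, 0, 2)
    }
    tree <- make_entropy_tree(J, ent)
    got <- wp_best_tree(tree)$best_leaves
    want <- oracle_best_leaves(tree)
    expect_equal(canonical_leaves(got), canonical_leaves(want))
  }
})

test_that("best-tree cost never exceeds the full leaf set or the root", {
  set.seed(99)
  sig <- signal_record(rnorm(512) + sin(seq_len(512) / 5), 1000)
  tr <- wp_best_tree(wp_decompose(sig, "db8", 4))
  cost_of <- function(leaves) {
    sum(vapply(seq_len(nrow(leaves)), function(r) {
      tr$nodes[[sprintf("%d.%d", leaves[r, 1], leaves[r, 2])]]$entropy
    }, numeric(1)))
  }
  best <- cost_of(tr$best_leaves)
  full <- cost_of(cbind(4, 0:15))
  expect_lte(best, full + 1e-12)
  expect_lte(best, tr$nodes[["0.0"]]$entropy + 1e-12)
})

test_that("non-power-of-two lengths survive the pad-and-truncate round trip", {
  set.seed(7)
  x <- rnorm(5000)
  tr <- wp_decompose(signal_record(x, 2000), "db4", 4)
  expect_equal(length(wp_reconstruct(tr)$samples), 5000)
  expect_lt(max(abs(wp_reconstruct(tr)$samples - x)), 1e-8)
})

test_that("filter table is orthonormal for every tabulated order", {
  for (ord in c(1, 2, 4, 8, 20, 45)) {
    f <- wavelet_filters(paste0("db", ord))
    expect_equal(length(f$h), 2 * ord)
    expect_equal(sum(f$h^2), 1, tolerance = 1e-14)
    expect_equal(sum(f$h), sqrt(2), tolerance = 1e-14)
    for (k in seq_len(ord - 1)) {
      expect_lt(abs(sum(f$h[seq_len(2 * ord - 2 * k)] *
                          f$h[(2 * k + 1):(2 * ord)])), 1e-14)
    }
  }
  expect_error(wavelet_filters("db11"), "not tabulated")
  expect_error(wavelet_filters("sym4"), "unknown wavelet")
})
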