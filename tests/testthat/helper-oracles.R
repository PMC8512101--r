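# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive each quantity by direct enumeration or term-by-term
# summation, sharing no code with the implementation under test.

# Risk-minimising threshold by explicit per-candidate evaluation.
oracle_heursure <- function(W) {
  N <- length(W)
  Ws <- sort(W^2)
  risks <- vapply(seq_len(N), function(i) {
    (N - 2 * i + sum(Ws[seq_len(i)]) + (N - i + 1) * Ws[N - i + 1]) / N
  }, numeric(1))
  sqrt(Ws[which.min(risks)])
}

# A bare wavelet-packet tree skeleton carrying only entropies, for testing
# the pruning rule in isolation from any transform.
make_entropy_tree <- function(max_level, entropies) {
  nodes <- list()
  for (lev in 0:max_level) {
    for (idx in 0:(2^lev - 1)) {
      nodes[[sprintf("%d.%d", lev, idx)]] <-
        list(level = lev, index = idx,
             entropy = entropies[[sprintf("%d.%d", lev, idx)]])
    }
  }
  structure(list(wavelet = "db1", max_level = max_level, orig_n = 2^max_level,
                 padded_n = 2^max_level, sampling_rate = 1, label = "x",
                 nodes = nodes,
                 best_leaves = cbind(level = rep(max_level, 2^max_level),
                                     index = 0:(2^max_level - 1))),
            class = "wp_tree")
}

# All admissible prunings (leaf tilings) of a complete depth-J binary tree,
# each as a two-column level/index matrix.
enumerate_prunings <- function(max_level, lev = 0L, idx = 0L) {
  leaf_only <- list(matrix(c(lev, idx), ncol = 2))
  if (lev == max_level) return(leaf_only)
  left <- enumerate_prunings(max_level, lev + 1L, 2L * idx)
  right <- enumerate_prunings(max_level, lev + 1L, 2L * idx + 1L)
  combos <- list()
  for (l in left) for (r in right) {
    combos[[length(combos) + 1L]] <- rbind(l, r)
  }
  c(leaf_only, combos)
}

# Minimum-total-entropy pruning by exhaustive enumeration. Ties resolved
# toward fewer leaves (the unsplit parent), matching the strict-inequality
# split rule.
oracle_best_leaves <- function(tree) {
  prunings <- enumerate_prunings(tree$max_level)
  cost <- vapply(prunings, function(p) {
    sum(vapply(seq_len(nrow(p)), function(r) {
      tree$nodes[[sprintf("%d.%d", p[r, 1], p[r, 2])]]$entropy
    }, numeric(1)))
  }, numeric(1))
  nleaf <- vapply(prunings, nrow, integer(1))
  best <- which(cost <= min(cost) + 1e-12)
  best <- best[which.min(nleaf[best])]
  prunings[[best]]
}

canonical_leaves <- function(m) {
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  paste(m[, 1], m[, 2], sep = ".", collapse = ";")
}

# Tiny fatigue dataset + split + LSTM train helper shared by classifier
# tests.
quick_lstm_run <- function(seed, sep = 3, n = 120, epochs = 30,
                           fractions = c(0.7, 0.1, 0.2), permute = FALSE,
                           units = 100L, fc_units = 32L, patience = 10L,
                           seq_len = 5L) {
  ds <- generate_feature_dataset(n, sep, seed = seed, seq_len = seq_len)
  if (permute) {
    ds <- with_fixed_seed(seed + 5000L,
                          labeled_dataset(ds$x, sample(ds$y), ds$feature_names))
  }
  sp <- stratified_split(ds, split_spec(fractions[1], fractions[2],
                                        fractions[3], seed = seed))
  m <- train_lstm(sp$train, sp$val,
                  lstm_config(units = units, fc_units = fc_units,
                              epochs = epochs, patience = patience,
                              seed = seed))
  evaluate_model(m, sp$test)$acc
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
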