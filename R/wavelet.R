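#' Daubechies wavelet filter pair
#'
#' Returns the orthonormal analysis filter pair for a Daubechies wavelet.
#' Coefficients were computed by spectral factorization of the Daubechies
#' polynomial in 120-digit arithmetic and are stored as a plain-text table,
#' so even long filters (db45 has 90 taps) are accurate to double precision.
#'
#' @param wavelet Wavelet name, `"dbN"` for one of the tabulated orders
#'   (1--10, 12, 15, 20, 25, 30, 35, 40, 45).
#' @return A list with `h` (lowpass) and `g` (highpass) filter taps; `g` is
#'   the quadrature mirror of `h`.
#' @examples
#' f <- wavelet_filters("db4")
#' sum(f$h^2)  # orthonormal: 1
#' @export
wavelet_filters <- function(wavelet = "db45") {
  if (!is.character(wavelet) || length(wavelet) != 1L ||
      !grepl("^db[0-9]+$", wavelet)) {
    stop(sprintf("unknown wavelet '%s' (expected 'dbN')", wavelet),
         call. = FALSE)
  }
  order <- as.integer(sub("^db", "", wavelet))
  tab <- daubechies_table()
  h <- tab[[as.character(order)]]
  if (is.null(h)) {
    stop(sprintf("wavelet 'db%d' is not tabulated; available orders: %s",
                 order, paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g, name = wavelet, length = L)
}

# Cache the filter table in the package namespace on first use.
.wavelet_cache <- new.env(parent = emptyenv())

daubechies_table <- function() {
  if (!is.null(.wavelet_cache$tab)) return(.wavelet_cache$tab)
  path <- system.file("extdata", "daubechies_filters.csv",
                      package = "semgfatigue", mustWork = TRUE)
  df <- utils::read.csv(path)
  tab <- lapply(split(df, df$order), function(d) d$h[order(d$tap)])
  names(tab) <- names(split(df, df$order))
  .wavelet_cache$tab <- tab
  tab
}

#' Shannon entropy of a coefficient sequence
#'
#' The (non-normalized) Shannon entropy cost used to score wavelet-packet
#' nodes: `-sum(s^2 * log(s^2))` with natural logarithm and the convention
#' `0 * log(0) = 0`.
#'
#' @param coeffs Numeric vector of coefficients; must be finite.
#' @return A single number.
#' @examples
#' shannon_entropy(c(1 / sqrt(2), 1 / sqrt(2)))  # log(2)
#' @export
shannon_entropy <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (!all(is.finite(coeffs))) {
    stop("`coeffs` must be finite", call. = FALSE)
  }
  s2 <- coeffs^2
  nz <- s2 > 0
  -sum(s2[nz] * log(s2[nz]))
}

node_key <- function(level, index) sprintf("%d.%d", level, index)

# Periodized single-step analysis: circular correlation with the filter,
# downsampled by two. FFT-based so long filters (db45) stay cheap; the filter
# is wrapped modulo the node length, which keeps the step exact even when the
# filter is longer than the node.
wp_analysis_step <- function(v, filt) {
  n <- length(v)
  stopifnot(n %% 2L == 0L)
  wrap <- function(f) {
    fp <- numeric(n)
    idx <- ((seq_along(f) - 1) %% n) + 1
    for (i in seq_along(f)) fp[idx[i]] <- fp[idx[i]] + f[i]
    fp
  }
  V <- stats::fft(v)
  cc_h <- Re(stats::fft(V * Conj(stats::fft(wrap(filt$h))), inverse = TRUE)) / n
  cc_g <- Re(stats::fft(V * Conj(stats::fft(wrap(filt$g))), inverse = TRUE)) / n
  keep <- seq(1, n, by = 2)
  list(a = cc_h[keep], d = cc_g[keep])
}

# Adjoint of the analysis step: upsample both branches by two, circularly
# convolve with the filters and sum. Exact inverse for orthonormal filters.
wp_synthesis_step <- function(a, d, filt) {
  n <- 2L * length(a)
  wrap <- function(f) {
    fp <- numeric(n)
    idx <- ((seq_along(f) - 1) %% n) + 1
    for (i in seq_along(f)) fp[idx[i]] <- fp[idx[i]] + f[i]
    fp
  }
  up <- function(x) {
    u <- numeric(n)
    u[seq(1, n, by = 2)] <- x
    u
  }
  A <- stats::fft(up(a)) * stats::fft(wrap(filt$h))
  D <- stats::fft(up(d)) * stats::fft(wrap(filt$g))
  Re(stats::fft(A + D, inverse = TRUE)) / n
}

#' Wavelet packet decomposition
#'
#' Decomposes a signal into a complete wavelet-packet tree: at every level
#' both the lowpass (approximation) and highpass (detail) branches are split
#' again, down to `max_level`. Boundary handling is periodized, so the
#' transform is orthonormal: it reconstructs perfectly and conserves energy
#' across levels. Signals whose length is not a multiple of `2^max_level`
#' are zero-padded internally; the original length is restored by
#' [wp_reconstruct()].
#'
#' Each node stores its coefficient sequence and Shannon entropy. The
#' best-leaf set is initialised to the full set of depth-`max_level` leaves;
#' use [wp_best_tree()] to prune it.
#'
#' @param signal A `signal_record` (or numeric vector, taken at 1 Hz).
#' @param wavelet Wavelet name; default `"db45"`.
#' @param max_level Decomposition depth, an integer >= 1; default 4.
#' @return An object of class `wp_tree`.
#' @export
wp_decompose <- function(signal, wavelet = "db45", max_level = 4L) {
  if (!inherits(signal, "signal_record")) {
    signal <- signal_record(signal, 1, "x")
  }
  max_level <- as.integer(max_level)
  if (is.na(max_level) || max_level < 1L) {
    stop("`max_level` must be an integer >= 1", call. = FALSE)
  }
  n <- length(signal$samples)
  if (n < 2^max_level) {
    stop(sprintf(
      "signal of length %d is too short for %d decomposition levels (maximum feasible level: %d)",
      n, max_level, max(0L, floor(log2(n)))), call. = FALSE)
  }
  filt <- wavelet_filters(wavelet)
  block <- 2^max_level
  padded_n <- as.integer(block * ceiling(n / block))
  x <- c(signal$samples, numeric(padded_n - n))

  nodes <- list()
  nodes[[node_key(0L, 0L)]] <- list(level = 0L, index = 0L, coefficients = x,
                                    entropy = shannon_entropy(x))
  for (lev in seq_len(max_level)) {
    for (pidx in 0:(2^(lev - 1) - 1)) {
      parent <- nodes[[node_key(lev - 1L, pidx)]]
      br <- wp_analysis_step(parent$coefficients, filt)
      for (side in 0:1) {
        cidx <- 2L * pidx + side
        co <- if (side == 0) br$a else br$d
        nodes[[node_key(lev, cidx)]] <- list(level = lev, index = cidx,
                                             coefficients = co,
                                             entropy = shannon_entropy(co))
      }
    }
  }
  best <- cbind(level = rep(max_level, 2^max_level),
                index = 0:(2^max_level - 1))
  structure(
    list(wavelet = wavelet, max_level = max_level, orig_n = n,
         padded_n = padded_n, sampling_rate = signal$sampling_rate,
         label = signal$label, nodes = nodes, best_leaves = best),
    class = "wp_tree"
  )
}

#' @export
print.wp_tree <- function(x, ...) {
  cat(sprintf("<wp_tree> %s, %d level(s), %d nodes, %d best leaves (signal n = %d)\n",
              x$wavelet, x$max_level, length(x$nodes), nrow(x$best_leaves),
              x$orig_n))
  invisible(x)
}

#' Best-tree (best-basis) selection by entropy pruning
#'
#' Replaces the tree's best-leaf set by the minimum-entropy pruning: a node
#' is split into its two children if and only if the summed entropy of the
#' children's best subtrees is strictly lower than the node's own entropy
#' (ties keep the node unsplit). Applied bottom-up from `max_level` this
#' local rule yields the globally minimal-entropy admissible tiling.
#'
#' @param tree A `wp_tree` from [wp_decompose()].
#' @return The tree with `best_leaves` updated.
#' @export
wp_best_tree <- function(tree) {
  stopifnot(inherits(tree, "wp_tree"))
  J <- tree$max_level
  cost <- new.env(parent = emptyenv())
  split <- new.env(parent = emptyenv())
  for (idx in 0:(2^J - 1)) {
    assign(node_key(J, idx), tree$nodes[[node_key(J, idx)]]$entropy,
           envir = cost)
  }
  for (lev in rev(seq_len(J) - 1L)) {
    for (idx in 0:(2^lev - 1)) {
      key <- node_key(lev, idx)
      own <- tree$nodes[[key]]$entropy
      kids <- get(node_key(lev + 1L, 2L * idx), envir = cost) +
        get(node_key(lev + 1L, 2L * idx + 1L), envir = cost)
      if (kids < own) {
        assign(key, kids, envir = cost)
        assign(key, TRUE, envir = split)
      } else {
        assign(key, own, envir = cost)
        assign(key, FALSE, envir = split)
      }
    }
  }
  leaves <- list()
  walk <- function(lev, idx) {
    key <- node_key(lev, idx)
    is_split <- lev < J && get(key, envir = split)
    if (is_split) {
      walk(lev + 1L, 2L * idx)
      walk(lev + 1L, 2L * idx + 1L)
    } else {
      leaves[[length(leaves) + 1L]] <<- c(lev, idx)
    }
  }
  walk(0L, 0L)
  m <- do.call(rbind, leaves)
  colnames(m) <- c("level", "index")
  tree$best_leaves <- m
  tree
}

# TRUE if `leaves` (matrix level/index) tiles the root exactly once.
leaves_tile_root <- function(leaves, max_level) {
  if (is.null(dim(leaves))) leaves <- matrix(leaves, ncol = 2)
  cover <- integer(2^max_level)
  for (r in seq_len(nrow(leaves))) {
    lev <- leaves[r, 1]
    idx <- leaves[r, 2]
    if (lev < 0 || lev > max_level || idx < 0 || idx >= 2^lev) return(FALSE)
    span <- 2^(max_level - lev)
    pos <- idx * span + seq_len(span)
    cover[pos] <- cover[pos] + 1L
  }
  all(cover == 1L)
}

#' Inverse wavelet packet transform
#'
#' Reconstructs the signal from the coefficients stored at the tree's best
#' leaves, merging sibling nodes bottom-up with the synthesis filter bank.
#' With unmodified coefficients this is the exact inverse of
#' [wp_decompose()]; after thresholding it returns the denoised signal.
#'
#' @param tree A `wp_tree` whose `best_leaves` form a valid tiling.
#' @return A `signal_record` of the original signal length.
#' @export
wp_reconstruct <- function(tree) {
  stopifnot(inherits(tree, "wp_tree"))
  leaves <- tree$best_leaves
  if (!leaves_tile_root(leaves, tree$max_level)) {
    stop("`best_leaves` do not tile the frequency axis exactly once",
         call. = FALSE)
  }
  filt <- wavelet_filters(tree$wavelet)
  leaf_set <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(leaves))) {
    assign(node_key(leaves[r, 1], leaves[r, 2]), TRUE, envir = leaf_set)
  }
  value <- function(lev, idx) {
    key <- node_key(lev, idx)
    if (exists(key, envir = leaf_set)) {
      co <- tree$nodes[[key]]$coefficients
      if (is.null(co)) stop(sprintf("leaf %s has no coefficients", key),
                            call. = FALSE)
      return(co)
    }
    wp_synthesis_step(value(lev + 1L, 2L * idx), value(lev + 1L, 2L * idx + 1L),
                      filt)
  }
  x <- value(0L, 0L)[seq_len(tree$orig_n)]
  signal_record(x, tree$sampling_rate, tree$label)
}
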