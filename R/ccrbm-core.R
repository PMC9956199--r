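#' Define the CCRBM architecture
#'
#' A centered convolutional restricted Boltzmann machine over 1-D feature
#' vectors. A bank of `n_filters` shared filters of width `filter_width` is
#' correlated (valid mode) with the visible vector, giving a detection layer
#' of length `visible_length - filter_width + 1` per filter. Detection units
#' are grouped into consecutive pooling blocks of size `pool_block`; within
#' a block at most one unit may be active, and the pooled unit above the
#' block signals whether any is (probabilistic max-pooling). If the block
#' size does not divide the detection length, the final block is simply
#' smaller.
#'
#' @param visible_length Number of visible units (features); default 5.
#' @param n_filters Number of convolution filters; default 2.
#' @param filter_width Filter width; default 3.
#' @param pool_block Pooling block size; default 3.
#' @return An object of class `ccrbm_structure`.
#' @export
ccrbm_structure <- function(visible_length = 5L, n_filters = 2L,
                            filter_width = 3L, pool_block = 3L) {
  for (v in list(visible_length, n_filters, filter_width, pool_block))
    if (!is_count(v)) stopf("all structure fields must be positive integers")
  if (filter_width > visible_length)
    stopf("filter_width %d exceeds visible_length %d",
          filter_width, visible_length)
  d <- visible_length - filter_width + 1L
  blocks <- unname(split(seq_len(d), ceiling(seq_len(d) / pool_block)))
  structure(list(visible_length = as.integer(visible_length),
                 n_filters = as.integer(n_filters),
                 filter_width = as.integer(filter_width),
                 pool_block = as.integer(pool_block),
                 detection_length = d,
                 blocks = blocks,
                 n_blocks = length(blocks)),
            class = "ccrbm_structure")
}

#' Create (or initialise) CCRBM parameters
#'
#' Parameters are the filter bank (`n_filters x filter_width`), one hidden
#' bias per filter, a single visible bias, and the centering offsets: one
#' per hidden unit (`alpha_h`) and one per visible unit (`alpha_v`). At
#' initialisation the offsets are set to the sigmoid of the corresponding
#' biases, so that units start centred on their unconditional activations.
#'
#' @param structure A [ccrbm_structure()].
#' @param filters Optional `n_filters x filter_width` matrix; when `NULL`,
#'   filters are drawn N(0, `init_sd`) under `seed` (or zero if `seed` is
#'   `NULL`).
#' @param beta Hidden biases, length `n_filters`; default 0.
#' @param o Visible bias (scalar); default 0.
#' @param learning_rate Contrastive-divergence learning rate; default 0.1.
#' @param seed Seed for the random filter draw.
#' @param init_sd Standard deviation of random filter initialisation.
#' @return An object of class `ccrbm_params`.
#' @export
ccrbm_params <- function(structure, filters = NULL, beta = NULL, o = 0,
                         learning_rate = 0.1, seed = NULL, init_sd = 0.01) {
  stopifnot(inherits(structure, "ccrbm_structure"))
  l <- structure$n_filters; w <- structure$filter_width
  if (is.null(filters)) {
    filters <- if (is.null(seed)) matrix(0, l, w)
               else with_seed(seed, matrix(rnorm(l * w, sd = init_sd), l, w))
  }
  filters <- matrix(as.numeric(filters), l, w)
  if (is.null(beta)) beta <- rep(0, l)
  beta <- rep_len(as.numeric(beta), l)
  if (!is.numeric(o) || length(o) != 1L) stopf("o must be a scalar")
  if (!is.numeric(learning_rate) || learning_rate < 0)
    stopf("learning_rate must be nonnegative")
  p <- structure(list(structure = structure,
                      filters = filters, beta = beta, o = o,
                      alpha_h = matrix(plogis(beta), l,
                                       structure$detection_length),
                      alpha_v = rep(plogis(o), structure$visible_length),
                      learning_rate = learning_rate),
                 class = "ccrbm_params")
  validate_params(p)
}

#' @noRd
validate_params <- function(p) {
  if (!all(is.finite(p$filters)) || !all(is.finite(p$beta)) ||
      !is.finite(p$o))
    stopf("CCRBM parameters must be finite")
  if (any(p$alpha_h < 0 | p$alpha_h > 1) || any(p$alpha_v < 0 | p$alpha_v > 1))
    stopf("centering offsets must lie in [0, 1]")
  p
}

# Sparse-pattern weight matrix: column (l-1)*D + k holds filter l placed at
# offset k, so valid-mode correlation is a single matrix product and the
# visible conditional its transpose.
#' @noRd
conv_matrix <- function(params) {
  s <- params$structure
  m <- matrix(0, s$visible_length, s$n_filters * s$detection_length)
  for (l in seq_len(s$n_filters))
    for (k in seq_len(s$detection_length))
      m[k:(k + s$filter_width - 1L), (l - 1L) * s$detection_length + k] <-
        params$filters[l, ]
  m
}

#' @noRd
flat_alpha_h <- function(params) as.vector(t(params$alpha_h))

#' Bottom-up signal of the detection layer
#'
#' For filter l and position k, the signal is
#' `S[l, k] = beta_l + (omega_l * v)_k` (valid-mode correlation). The
#' centered variant correlates with `v - alpha_v` instead of `v`.
#'
#' @param v Visible vector (length `visible_length`).
#' @param params A [ccrbm_params()].
#' @param centered Use the centering offsets (default `TRUE`).
#' @return An `n_filters x detection_length` matrix.
#' @export
bottom_up_signal <- function(v, params, centered = TRUE) {
  s <- params$structure
  if (length(v) != s$visible_length)
    stopf("v has length %d, expected %d", length(v), s$visible_length)
  vc <- if (centered) v - params$alpha_v else v
  sig <- as.vector(vc %*% conv_matrix(params)) +
    rep(params$beta, each = s$detection_length)
  t(matrix(sig, s$detection_length, s$n_filters))
}

# Block softmax with an explicit "all off" outcome, log-sum-exp guarded.
# S is an n x (L*D) batch matrix of signals (columns filter-major).
#' @noRd
batch_block_softmax <- function(sig, structure) {
  if (any(is.na(sig))) stopf("NaN in bottom-up signal")
  n <- nrow(sig)
  p <- matrix(0, n, ncol(sig))
  p_off <- matrix(0, n, structure$n_filters * structure$n_blocks)
  for (l in seq_len(structure$n_filters)) {
    base <- (l - 1L) * structure$detection_length
    for (b in seq_len(structure$n_blocks)) {
      cols <- base + structure$blocks[[b]]
      sb <- sig[, cols, drop = FALSE]
      m <- 0
      for (j in seq_along(cols)) m <- pmax(m, sb[, j])
      e <- exp(sb - m)
      den <- exp(-m) + rowSums(e)
      p[, cols] <- e / den
      p_off[, (l - 1L) * structure$n_blocks + b] <- exp(-m) / den
    }
  }
  list(p = p, p_off = p_off)
}

#' Conditional distribution of the detection layer given the visible layer
#'
#' Within each pooling block the units and the "all off" outcome form a
#' softmax: `P(h = 1 | v) = exp(S) / (1 + sum_block exp(S))` and
#' `P(block off | v) = 1 / (1 + sum_block exp(S))`, so the block's
#' probabilities sum to one. The centered variant computes S from
#' `v - alpha_v`.
#'
#' @inheritParams bottom_up_signal
#' @return A list with `p` (`n_filters x detection_length` activation
#'   probabilities) and `p_off` (`n_filters x n_blocks` off-probabilities).
#' @export
hidden_conditional <- function(v, params, centered = TRUE) {
  s <- params$structure
  sig <- bottom_up_signal(v, params, centered)
  bs <- batch_block_softmax(matrix(as.vector(t(sig)), 1L), s)
  list(p = t(matrix(bs$p[1, ], s$detection_length, s$n_filters)),
       p_off = t(matrix(bs$p_off[1, ], s$n_blocks, s$n_filters)))
}

#' Conditional distribution of the visible layer given the detection layer
#'
#' `P(v_j = 1 | h) = sigmoid( sum_l (omega_l * (h_l - alpha_h))_j + o )`,
#' the full-mode correlation of each filter with its (centered) hidden map.
#'
#' @param h Binary `n_filters x detection_length` matrix satisfying the
#'   at-most-one-per-block constraint (activation probabilities are also
#'   accepted, for mean-field use).
#' @inheritParams bottom_up_signal
#' @return Vector of `visible_length` activation probabilities.
#' @export
visible_conditional <- function(h, params, centered = TRUE) {
  s <- params$structure
  h <- matrix(h, s$n_filters, s$detection_length)
  hc <- if (centered) h - params$alpha_h else h
  act <- as.vector(conv_matrix(params) %*% as.vector(t(hc))) + params$o
  plogis(act)
}

#' @noRd
check_block_constraint <- function(h, structure) {
  h <- matrix(h, structure$n_filters, structure$detection_length)
  if (!all(h %in% c(0, 1))) stopf("h must be binary")
  for (l in seq_len(structure$n_filters))
    for (b in structure$blocks)
      if (sum(h[l, b]) > 1)
        stopf("pooling-block constraint violated: more than one active unit")
  invisible(h)
}

#' Energy of a joint configuration
#'
#' Plain form: `F(v, h) = -sum_{l,k} h (omega_l * v)_k - sum beta_l h
#' - o sum_j v_j`. The centered form substitutes `h - alpha_h` and
#' `v - alpha_v` throughout; with zero offsets the two coincide.
#'
#' @param v Visible vector.
#' @param h Binary detection matrix satisfying the block constraint.
#' @inheritParams bottom_up_signal
#' @return The scalar energy.
#' @export
ccrbm_energy <- function(v, h, params, centered = TRUE) {
  s <- params$structure
  h <- check_block_constraint(h, s)
  av <- if (centered) params$alpha_v else rep(0, s$visible_length)
  ah <- if (centered) params$alpha_h else matrix(0, s$n_filters,
                                                 s$detection_length)
  vc <- v - av
  conv <- as.vector(vc %*% conv_matrix(params))  # (omega_l * vc)_k
  hc <- h - ah
  -sum(as.vector(t(hc)) * conv) -
    sum(params$beta * rowSums(hc)) -
    params$o * sum(vc)
}

# Draw one detection-layer configuration per block: categorical over the
# block's units plus the off outcome. p/p_off as from hidden_conditional.
#' @noRd
sample_blocks <- function(p, p_off, structure) {
  h <- matrix(0, structure$n_filters, structure$detection_length)
  for (l in seq_len(structure$n_filters)) {
    for (b in seq_len(structure$n_blocks)) {
      idx <- structure$blocks[[b]]
      probs <- c(p[l, idx], p_off[l, b])
      pick <- sample.int(length(probs), 1L, prob = probs)
      if (pick <= length(idx)) h[l, idx[pick]] <- 1
    }
  }
  h
}

#' Gibbs sampling of layer states
#'
#' `sample_hidden` draws a detection-layer configuration given `v` (one
#' categorical draw per pooling block, including the off outcome) and the
#' pooled layer it implies; `sample_visible` draws independent Bernoulli
#' visible units given `h`. Both use R's current RNG stream; seed the stream
#' for reproducible chains.
#'
#' @inheritParams visible_conditional
#' @param v Visible vector.
#' @return `sample_hidden`: a list (`v`, `h`, `z`) — the layer state, where
#'   `z` is the `n_filters x n_blocks` pooled indicator. `sample_visible`:
#'   a binary visible vector.
#' @export
sample_hidden <- function(v, params, centered = TRUE) {
  s <- params$structure
  hc <- hidden_conditional(v, params, centered)
  h <- sample_blocks(hc$p, hc$p_off, s)
  z <- vapply(seq_len(s$n_blocks),
              function(b) as.numeric(rowSums(h[, s$blocks[[b]],
                                               drop = FALSE]) > 0),
              numeric(s$n_filters))
  list(v = v, h = h, z = matrix(z, s$n_filters, s$n_blocks))
}

#' @rdname sample_hidden
#' @export
sample_visible <- function(h, params, centered = TRUE) {
  p <- visible_conditional(h, params, centered)
  rbinom(length(p), 1L, p)
}

#' Pooled feature extraction
#'
#' Maps a visible vector to the vector of pooled activation probabilities
#' `P(block on | v) = 1 - P(block off | v)`, one per (filter, block) pair,
#' filter-major. Deterministic given `v` and the parameters.
#'
#' @param v A visible vector, or an `n x visible_length` matrix of records.
#' @inheritParams bottom_up_signal
#' @return A feature vector of length `n_filters * n_blocks`, or the
#'   corresponding matrix for matrix input.
#' @export
extract_features <- function(v, params, centered = TRUE) {
  s <- params$structure
  single <- is.null(dim(v))
  v <- if (single) matrix(v, 1L) else as.matrix(v)
  if (ncol(v) != s$visible_length)
    stopf("feature matrix has %d columns, expected %d", ncol(v),
          s$visible_length)
  av <- if (centered) params$alpha_v else rep(0, s$visible_length)
  sig <- sweep(v, 2L, av) %*% conv_matrix(params)
  sig <- sweep(sig, 2L, rep(params$beta, each = s$detection_length), "+")
  bs <- batch_block_softmax(sig, s)
  feat <- 1 - bs$p_off
  if (single) as.vector(feat) else feat
}
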