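#' Exact joint distribution of a small CCRBM
#'
#' Enumerates every binary visible vector and every detection-layer
#' configuration satisfying the at-most-one-per-block constraint, assigns
#' each joint state the Boltzmann probability `exp(-F) / Z`, and returns the
#' full table. Intended as an exact oracle for conditionals, sampling and
#' gradients on toy models; refuses state spaces larger than 2^16.
#'
#' @param params A [ccrbm_params()].
#' @param centered Use the centered energy; default `TRUE`.
#' @return A list with `v_states` (matrix of visible states, one per row),
#'   `h_states` (list of detection matrices), `log_prob` (matrix
#'   `n_v x n_h`), `prob` (same shape, sums to 1), and `log_z`.
#' @export
enumerate_joint <- function(params, centered = TRUE) {
  s <- params$structure
  n_h_per_filter <- prod(lengths(s$blocks) + 1L)
  n_h <- n_h_per_filter^s$n_filters
  n_v <- 2^s$visible_length
  if (n_v * n_h > 2^16)
    stopf("state space %.0f x %.0f exceeds the enumeration limit", n_v, n_h)

  v_states <- as.matrix(expand.grid(rep(list(c(0, 1)), s$visible_length)))
  dimnames(v_states) <- NULL

  block_choices <- lapply(s$blocks, function(b) 0:length(b))
  per_filter <- as.matrix(expand.grid(block_choices))
  filter_rows <- function(choice) {
    h <- numeric(s$detection_length)
    for (b in seq_along(s$blocks))
      if (choice[b] > 0) h[s$blocks[[b]][choice[b]]] <- 1
    h
  }
  filter_configs <- t(apply(per_filter, 1, filter_rows))
  if (s$detection_length == 1L) filter_configs <- t(filter_configs)
  combo <- as.matrix(expand.grid(rep(list(seq_len(n_h_per_filter)),
                                     s$n_filters)))
  h_states <- lapply(seq_len(nrow(combo)), function(i) {
    h <- matrix(0, s$n_filters, s$detection_length)
    for (l in seq_len(s$n_filters)) h[l, ] <- filter_configs[combo[i, l], ]
    h
  })

  energy <- matrix(0, n_v, length(h_states))
  for (i in seq_len(n_v))
    for (j in seq_along(h_states))
      energy[i, j] <- ccrbm_energy(v_states[i, ], h_states[[j]], params,
                                   centered)
  mx <- max(-energy)
  log_z <- mx + log(sum(exp(-energy - mx)))
  log_prob <- -energy - log_z
  list(v_states = v_states, h_states = h_states,
       log_prob = log_prob, prob = exp(log_prob), log_z = log_z)
}

#' Exact log-likelihood gradient from enumeration (oracle)
#'
#' Computes the exact gradient of the mean log-likelihood of `v_batch`
#' under the (centered) CCRBM by enumerating the joint distribution:
#' data-expectation minus model-expectation of the centered sufficient
#' statistics. Used to validate the contrastive-divergence direction on toy
#' models.
#'
#' @param v_batch Binary visible vectors (rows).
#' @param params A [ccrbm_params()].
#' @param centered Use centered statistics.
#' @return A list with `filters`, `beta`, `o` gradient components.
#' @export
exact_gradient <- function(v_batch, params, centered = TRUE) {
  if (is.null(dim(v_batch))) v_batch <- matrix(v_batch, 1L)
  s <- params$structure
  joint <- enumerate_joint(params, centered)
  av <- if (centered) params$alpha_v else rep(0, s$visible_length)
  ah <- if (centered) params$alpha_h else matrix(0, s$n_filters,
                                                 s$detection_length)

  stats_of <- function(v, h) {
    vc <- v - av
    hc <- h - ah
    w <- matrix(0, s$n_filters, s$filter_width)
    for (l in seq_len(s$n_filters))
      for (k in seq_len(s$detection_length))
        w[l, ] <- w[l, ] + hc[l, k] * vc[k:(k + s$filter_width - 1L)]
    list(w = w, beta = rowSums(hc), o = sum(vc))
  }

  # model expectation over the full joint
  mw <- matrix(0, s$n_filters, s$filter_width); mb <- numeric(s$n_filters)
  mo <- 0
  for (i in seq_len(nrow(joint$v_states)))
    for (j in seq_along(joint$h_states)) {
      p <- joint$prob[i, j]
      if (p == 0) next
      st <- stats_of(joint$v_states[i, ], joint$h_states[[j]])
      mw <- mw + p * st$w; mb <- mb + p * st$beta; mo <- mo + p * st$o
    }

  # data expectation: exact P(h | v) per record via the block softmax
  dw <- matrix(0, s$n_filters, s$filter_width); db <- numeric(s$n_filters)
  dov <- 0
  for (r in seq_len(nrow(v_batch))) {
    v <- v_batch[r, ]
    hc <- hidden_conditional(v, params, centered)
    st <- stats_of(v, hc$p)
    dw <- dw + st$w / nrow(v_batch)
    db <- db + st$beta / nrow(v_batch)
    dov <- dov + st$o / nrow(v_batch)
  }
  list(filters = dw - mw, beta = db - mb, o = dov - mo)
}
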