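# Batch helpers: records as rows, detection columns filter-major
# ((l-1)*D + k), matching conv_matrix().

#' @noRd
batch_signal <- function(v, params, centered = TRUE, m = conv_matrix(params)) {
  s <- params$structure
  av <- if (centered) params$alpha_v else rep(0, s$visible_length)
  sig <- sweep(v, 2L, av) %*% m
  sweep(sig, 2L, rep(params$beta, each = s$detection_length), "+")
}

# one categorical draw per (record, filter, block), vectorised over records
#' @noRd
batch_sample_blocks <- function(p, p_off, structure) {
  n <- nrow(p)
  h <- matrix(0, n, ncol(p))
  for (l in seq_len(structure$n_filters)) {
    base <- (l - 1L) * structure$detection_length
    for (b in seq_len(structure$n_blocks)) {
      cols <- base + structure$blocks[[b]]
      cum <- p[, cols, drop = FALSE]
      if (length(cols) > 1L)
        for (j in 2:length(cols)) cum[, j] <- cum[, j] + cum[, j - 1L]
      u <- runif(n) * (cum[, length(cols)] +
                         p_off[, (l - 1L) * structure$n_blocks + b])
      pick <- rowSums(u > cum) + 1L  # length(cols)+1 means "off"
      on <- pick <= length(cols)
      h[cbind(which(on), cols[pick[on]])] <- 1
    }
  }
  h
}

#' Refresh the centering offsets
#'
#' Exponential-moving-average update of the hidden and visible centering
#' offsets toward the batch mean activations:
#' `alpha <- (1 - ema_rate) * alpha + ema_rate * batch_mean`. With
#' `ema_rate = 1` the offsets become the batch means outright.
#'
#' @param params A [ccrbm_params()].
#' @param mean_h Batch mean hidden activation, `n_filters x
#'   detection_length`.
#' @param mean_v Batch mean visible activation, length `visible_length`.
#' @param ema_rate Rate in (0, 1]; default 0.01.
#' @return Updated parameters.
#' @export
update_offsets <- function(params, mean_h, mean_v, ema_rate = 0.01) {
  if (!is.numeric(ema_rate) || length(ema_rate) != 1L ||
      ema_rate <= 0 || ema_rate > 1)
    stopf("ema_rate must lie in (0, 1]")
  s <- params$structure
  mean_h <- matrix(mean_h, s$n_filters, s$detection_length)
  params$alpha_h <- (1 - ema_rate) * params$alpha_h + ema_rate * mean_h
  params$alpha_v <- (1 - ema_rate) * params$alpha_v + ema_rate * mean_v
  validate_params(params)
}

#' One step of centered contrastive divergence
#'
#' CD-k on a batch of visible vectors: hidden probabilities are computed
#' from the data, a Gibbs chain of `k_steps` alternating draws provides the
#' model statistics, and the gradient is the centered data-minus-model
#' correlation: filters move along
#' `corr(v - alpha_v, p_h - alpha_h)_data - corr(...)_model`, hidden biases
#' along the data-minus-model hidden activation sums, the visible bias along
#' the data-minus-model visible sums. Offsets are then refreshed by
#' [update_offsets()] from the data-side batch means (disable with
#' `refresh_offsets = FALSE`; offsets are statistics of the data, not
#' gradient-trained parameters). Uses the current RNG stream.
#'
#' @param v_batch Matrix of records (rows) in \[0, 1\], or a single vector.
#' @param params A [ccrbm_params()].
#' @param k_steps Number of Gibbs steps (CD-k); default 1.
#' @param centered Use centering offsets; default `TRUE`.
#' @param refresh_offsets Refresh offsets after the gradient step.
#' @param ema_rate Offset EMA rate.
#' @return Updated parameters, with attribute `"recon_error"` holding the
#'   batch mean squared one-step reconstruction error.
#' @export
cd_update <- function(v_batch, params, k_steps = 1L, centered = TRUE,
                      refresh_offsets = TRUE, ema_rate = 0.01) {
  if (is.null(dim(v_batch))) v_batch <- matrix(v_batch, 1L)
  v_batch <- as.matrix(v_batch)
  if (nrow(v_batch) == 0L) stopf("empty batch")
  if (!is_count(k_steps)) stopf("k_steps must be a positive integer")
  s <- params$structure
  n <- nrow(v_batch)
  m <- conv_matrix(params)
  ah <- if (centered) flat_alpha_h(params) else rep(0, ncol(m))
  av <- if (centered) params$alpha_v else rep(0, s$visible_length)

  sig0 <- batch_signal(v_batch, params, centered, m)
  bs0 <- batch_block_softmax(sig0, s)
  h <- batch_sample_blocks(bs0$p, bs0$p_off, s)
  pv <- NULL
  for (step in seq_len(k_steps)) {
    hc <- sweep(h, 2L, ah)
    pv <- sigmoid(hc %*% t(m) + params$o)
    vs <- matrix(rbinom(length(pv), 1L, pv), n)
    sig <- batch_signal(vs, params, centered, m)
    bsk <- batch_block_softmax(sig, s)
    if (step < k_steps) h <- batch_sample_blocks(bsk$p, bsk$p_off, s)
  }
  recon <- mean((v_batch - pv)^2)

  vc0 <- sweep(v_batch, 2L, av)
  vck <- sweep(vs, 2L, av)
  pos <- crossprod(vc0, sweep(bs0$p, 2L, ah))
  neg <- crossprod(vck, sweep(bsk$p, 2L, ah))
  grad_flat <- (pos - neg) / n  # visible_length x (L*D)
  w_grad <- matrix(0, s$n_filters, s$filter_width)
  for (l in seq_len(s$n_filters))
    for (k in seq_len(s$detection_length)) {
      col <- (l - 1L) * s$detection_length + k
      w_grad[l, ] <- w_grad[l, ] + grad_flat[k:(k + s$filter_width - 1L), col]
    }
  dsum <- colSums(bs0$p) - colSums(bsk$p)
  beta_grad <- vapply(seq_len(s$n_filters), function(l)
    sum(dsum[(l - 1L) * s$detection_length + seq_len(s$detection_length)]),
    numeric(1)) / n
  o_grad <- sum(colMeans(v_batch) - colMeans(pv))

  if (!all(is.finite(w_grad)) || !all(is.finite(beta_grad)) ||
      !is.finite(o_grad))
    stopf("non-finite CD gradient (|w|max=%.3g, recon=%.3g)",
          max(abs(params$filters)), recon)

  lr <- params$learning_rate
  params$filters <- params$filters + lr * w_grad
  params$beta <- params$beta + lr * beta_grad
  params$o <- params$o + lr * o_grad
  if (refresh_offsets && centered)
    params <- update_offsets(params, colMeans(bs0$p), colMeans(v_batch),
                             ema_rate)
  params <- validate_params(params)
  attr(params, "recon_error") <- recon
  attr(params, "gradient") <- list(filters = w_grad, beta = beta_grad,
                                   o = o_grad)
  params
}

#' Mean-field reconstruction error of a batch
#'
#' Deterministic one-step reconstruction: hidden activation probabilities
#' from the data, then visible probabilities from those, then the batch mean
#' squared error against the data.
#'
#' @inheritParams cd_update
#' @return A scalar mean squared error.
#' @export
reconstruction_error <- function(v_batch, params, centered = TRUE) {
  if (is.null(dim(v_batch))) v_batch <- matrix(v_batch, 1L)
  s <- params$structure
  m <- conv_matrix(params)
  ah <- if (centered) flat_alpha_h(params) else rep(0, ncol(m))
  bs <- batch_block_softmax(batch_signal(v_batch, params, centered, m), s)
  pv <- sigmoid(sweep(bs$p, 2L, ah) %*% t(m) + params$o)
  mean((v_batch - pv)^2)
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

# Ridge-stabilised Newton (IRLS) fit of the logistic readout. Deterministic:
# zero init, fixed iteration count; the small ridge keeps the Hessian
# invertible and the weights bounded on separable features.
#' @noRd
train_readout <- function(features, labels, iters = 25L, ridge = 1e-4) {
  x <- cbind(1, as.matrix(features))
  y <- as.numeric(labels)
  w <- numeric(ncol(x))
  eye <- diag(ncol(x))
  for (i in seq_len(iters)) {
    p <- sigmoid(as.vector(x %*% w))
    g <- as.vector(crossprod(x, y - p)) - ridge * w
    h <- crossprod(x * (p * (1 - p) + 1e-10), x) + ridge * eye
    step <- solve(h, g)
    w <- w + step
    if (max(abs(step)) < 1e-10) break
  }
  w
}

#' Train a CCRBM classifier
#'
#' Runs `epochs` full-batch centered CD-k updates of the generative model on
#' the training features, then fits a logistic readout on the pooled
#' features by gradient descent. The per-epoch reconstruction error is
#' logged (epoch 0 is the error of the initial parameters).
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @param params Initial [ccrbm_params()]; when `NULL`, small random filters
#'   are drawn under `seed`.
#' @param structure Used only when `params` is `NULL`.
#' @param epochs CD training epochs; default 50.
#' @param cd_k Gibbs steps per update; default 1.
#' @param centered Use centering; default `TRUE`.
#' @param ema_rate Offset refresh rate; default 0.01.
#' @param readout_iters,readout_ridge Newton iteration cap and ridge
#'   stabiliser of the logistic readout fit.
#' @param seed Seed for the CD Gibbs chains (and the random init).
#' @param log_path Optional path; when given, one JSON line per epoch
#'   (`epoch`, `recon_error`, offset summaries) is appended.
#' @return A `ccrbm_model`: list with `params`, `readout` (weight vector,
#'   intercept first), and `history` (`epoch`, `recon_error`).
#' @export
ccrbm_fit <- function(cohort, params = NULL, structure = ccrbm_structure(),
                      epochs = 50L, cd_k = 1L, centered = TRUE,
                      ema_rate = 0.01, readout_iters = 25L,
                      readout_ridge = 1e-4, seed = 1L, log_path = NULL) {
  validate_cohort(cohort)
  v <- cohort_features(cohort)
  if (is.null(params))
    params <- ccrbm_params(structure, seed = derive_seed(seed, "init"))
  recon <- c(reconstruction_error(v, params, centered), numeric(epochs))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      params <- cd_update(v, params, k_steps = cd_k, centered = centered,
                          ema_rate = ema_rate)
      recon[ep + 1L] <- attr(params, "recon_error")
      if (!is.null(log_path))
        cat(jsonlite::toJSON(list(epoch = ep,
                                  recon_error = attr(params, "recon_error"),
                                  mean_alpha_h = mean(params$alpha_h),
                                  mean_alpha_v = mean(params$alpha_v)),
                             auto_unbox = TRUE, digits = NA),
            "\n", sep = "", file = log_path, append = TRUE)
    }
  })
  history <- data.frame(epoch = 0:epochs, recon_error = recon)
  feats <- extract_features(v, params, centered)
  readout <- train_readout(feats, cohort$label, readout_iters,
                           readout_ridge)
  structure(list(params = params, centered = centered, readout = readout,
                 history = history),
            class = "ccrbm_model")
}

#' Predict disease labels with a trained CCRBM
#'
#' Applies the logistic readout to the pooled features of each record. The
#' confidence is the readout's sigmoid output; the label is 1 when the
#' confidence is at least 0.5 (a tie at exactly 0.5 is assigned to class 1).
#'
#' @param object A `ccrbm_model` from [ccrbm_fit()].
#' @param newdata A cohort `data.frame` or a feature matrix.
#' @param ... Unused.
#' @return A `data.frame` with columns `label` and `confidence`.
#' @export
predict.ccrbm_model <- function(object, newdata, ...) {
  if (is.null(object$readout)) stopf("model has no trained readout")
  v <- if (is.data.frame(newdata)) cohort_features(newdata)
       else as.matrix(newdata)
  feats <- extract_features(v, object$params, object$centered)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = nrow(v))
  conf <- plogis(as.vector(cbind(1, feats) %*% object$readout))
  data.frame(label = as.integer(conf >= 0.5), confidence = conf)
}

#' Serialize a CCRBM model to JSON (and back)
#'
#' A single versioned JSON document holding the structure, all parameter
#' arrays and the readout weights at full precision; identical models
#' produce byte-identical files.
#'
#' @param model A `ccrbm_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  p <- model$params
  s <- p$structure
  doc <- list(format = "phecare-ccrbm-1",
              structure = list(visible_length = s$visible_length,
                               n_filters = s$n_filters,
                               filter_width = s$filter_width,
                               pool_block = s$pool_block),
              centered = model$centered,
              learning_rate = p$learning_rate,
              filters = format_full_precision(as.vector(t(p$filters))),
              beta = format_full_precision(p$beta),
              o = format_full_precision(p$o),
              alpha_h = format_full_precision(as.vector(t(p$alpha_h))),
              alpha_v = format_full_precision(p$alpha_v),
              readout = format_full_precision(model$readout))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "phecare-ccrbm-1"))
    stopf("unrecognised model format in %s", path)
  s <- ccrbm_structure(doc$structure$visible_length, doc$structure$n_filters,
                       doc$structure$filter_width, doc$structure$pool_block)
  filters <- matrix(as.numeric(doc$filters), s$n_filters, s$filter_width,
                    byrow = TRUE)
  p <- ccrbm_params(s, filters = filters, beta = as.numeric(doc$beta),
                    o = as.numeric(doc$o),
                    learning_rate = as.numeric(doc$learning_rate))
  p$alpha_h <- matrix(as.numeric(doc$alpha_h), s$n_filters,
                      s$detection_length, byrow = TRUE)
  p$alpha_v <- as.numeric(doc$alpha_v)
  structure(list(params = validate_params(p), centered = doc$centered,
                 readout = as.numeric(doc$readout), history = NULL),
            class = "ccrbm_model")
}
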