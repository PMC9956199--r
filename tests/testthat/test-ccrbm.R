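# Core CCRBM mechanics validated against hand arithmetic and the exact
# enumeration oracle on the 4-visible / 1-filter / width-2 toy model.

test_that("bottom-up signal reproduces hand convolutions", {
  s <- toy_structure()
  # zero filters: signal is the bias everywhere
  p0 <- ccrbm_params(s, beta = 0.5)
  expect_equal(bottom_up_signal(c(0.3, 0.9, 0.1, 0.7), p0, centered = FALSE),
               matrix(0.5, 1, 3))
  # single filter (2, 3) on a unit impulse
  p1 <- ccrbm_params(s, filters = matrix(c(2, 3), 1), beta = 0)
  expect_equal(bottom_up_signal(c(1, 0, 0, 0), p1, centered = FALSE),
               matrix(c(2, 0, 0), 1))
  # centering with alpha_v = v annihilates the input
  p2 <- random_toy_params(1)
  v <- p2$alpha_v
  expect_equal(bottom_up_signal(v, p2, centered = TRUE),
               matrix(p2$beta, 1, 3))
  expect_error(bottom_up_signal(c(1, 0), p1), "length")
})

test_that("block softmax normalizes and saturates correctly", {
  s <- toy_structure()
  p <- ccrbm_params(s)  # zero parameters: uniform case, block of 3
  hc <- hidden_conditional(c(0.5, 0.5, 0.5, 0.5), p, centered = FALSE)
  expect_equal(as.vector(hc$p), rep(0.25, 3))
  expect_equal(as.vector(hc$p_off), 0.25)
  # a dominant unit takes all the mass
  pbig <- ccrbm_params(s, filters = matrix(c(50, 0), 1))
  hcb <- hidden_conditional(c(1, 0, 0, 0), pbig, centered = FALSE)
  expect_gt(hcb$p[1, 1], 1 - 1e-10)
  expect_lt(max(hcb$p[1, 2:3], hcb$p_off), 1e-10)
})

test_that("block probabilities sum to one for random models", {
  for (seed in 1:200) {
    p <- random_toy_params(seed, sd = 3)
    v <- withr::with_seed(seed + 1000, runif(4))
    hc <- hidden_conditional(v, p)
    expect_lt(abs(sum(hc$p[1, ]) + hc$p_off[1, 1] - 1), 1e-10)
  }
  # a wider model with a partial final block (detection length 4, B = 3)
  s <- ccrbm_structure(6, 2, 3, 3)
  p <- ccrbm_params(s, seed = 3, init_sd = 2)
  hc <- hidden_conditional(runif(6), p)
  for (l in 1:2)
    for (b in seq_along(s$blocks))
      expect_lt(abs(sum(hc$p[l, s$blocks[[b]]]) + hc$p_off[l, b] - 1), 1e-10)
})

test_that("energy matches direct summation and reduces when uncentered", {
  s <- toy_structure()
  p <- random_toy_params(2)
  # zero hidden state, zero visible bias: plain energy is 0
  p0 <- ccrbm_params(s, filters = p$filters, beta = p$beta, o = 0)
  expect_equal(ccrbm_energy(c(1, 0, 1, 1), matrix(0, 1, 3), p0,
                            centered = FALSE), 0)
  # centered energy with zero offsets equals plain energy exactly
  pz <- p
  pz$alpha_h[] <- 0
  pz$alpha_v[] <- 0
  for (seed in 1:20) {
    st <- withr::with_seed(seed, {
      v <- rbinom(4, 1, 0.5)
      k <- sample.int(4, 1)  # position 4 = all off
      h <- matrix(0, 1, 3); if (k < 4) h[1, k] <- 1
      list(v = v, h = h)
    })
    expect_identical(ccrbm_energy(st$v, st$h, pz, centered = TRUE),
                     ccrbm_energy(st$v, st$h, pz, centered = FALSE))
  }
  # term-by-term oracle on one hand-set configuration
  ph <- ccrbm_params(s, filters = matrix(c(1, -2), 1), beta = 0.5, o = -0.3)
  v <- c(1, 0, 1, 1); h <- matrix(c(0, 1, 0), 1)
  conv2 <- 1 * v[2] + (-2) * v[3]  # filter at position 2
  expect_equal(ccrbm_energy(v, h, ph, centered = FALSE),
               -(conv2 + 0.5) - (-0.3) * sum(v))
  expect_error(ccrbm_energy(v, matrix(c(1, 1, 0), 1), ph), "block")
})

test_that("conditionals match the exact enumeration posterior", {
  for (seed in 1:10) {
    p <- random_toy_params(seed, sd = 1.5)
    joint <- enumerate_joint(p, centered = TRUE)
    expect_lt(abs(sum(joint$prob) - 1), 1e-12)
    for (v in list(c(0, 0, 0, 0), c(1, 0, 1, 0), c(1, 1, 1, 1))) {
      marg <- enum_hidden_marginal(joint, v)
      hc <- hidden_conditional(v, p, centered = TRUE)
      expect_lt(max(abs(marg - hc$p)), 1e-10)
    }
    for (h in list(matrix(c(0, 0, 0), 1), matrix(c(0, 1, 0), 1))) {
      marg_v <- enum_visible_marginal(joint, h)
      expect_lt(max(abs(marg_v - visible_conditional(h, p, centered = TRUE))),
                1e-10)
    }
  }
})

test_that("visible conditional saturates and centers as expected", {
  p <- random_toy_params(4)
  # h equal to alpha_h with zero visible bias: all probabilities 1/2
  p$o <- 0
  expect_equal(visible_conditional(p$alpha_h, p, centered = TRUE),
               rep(0.5, 4))
  p$o <- -50
  expect_lt(max(visible_conditional(p$alpha_h, p, centered = TRUE)), 1e-10)
})

test_that("joint enumeration is uniform at zero parameters", {
  p <- ccrbm_params(toy_structure())
  p$alpha_h[] <- 0
  p$alpha_v[] <- 0
  joint <- enumerate_joint(p)
  expect_equal(max(joint$prob), min(joint$prob))
  expect_equal(sum(joint$prob), 1, tolerance = 1e-12)
  expect_error(enumerate_joint(ccrbm_params(ccrbm_structure(12, 4, 3, 2))),
               "enumeration limit")
})

test_that("sampled states respect the block constraint and the seed", {
  p <- random_toy_params(5)
  withr::with_seed(1, {
    for (i in 1:50) {
      st <- sample_hidden(runif(4), p)
      expect_lte(sum(st$h), 1)  # one block of three
      expect_identical(st$z[1, 1], as.numeric(sum(st$h) > 0))
      vv <- sample_visible(st$h, p)
      expect_true(all(vv %in% c(0, 1)))
    }
  })
  s1 <- withr::with_seed(42, sample_hidden(c(0.2, 0.8, 0.4, 0.6), p))
  s2 <- withr::with_seed(42, sample_hidden(c(0.2, 0.8, 0.4, 0.6), p))
  expect_identical(s1, s2)
})

test_that("uniform-block sampling frequencies follow the law of large numbers", {
  p <- ccrbm_params(toy_structure())  # zero params, uniform 4-way choice
  counts <- withr::with_seed(7, {
    draws <- vapply(1:20000, function(i) {
      h <- sample_hidden(c(0.5, 0.5, 0.5, 0.5), p, centered = FALSE)$h
      if (sum(h) == 0) 4L else which(h[1, ] == 1)
    }, integer(1))
    tabulate(draws, 4)
  })
  expect_lt(max(abs(counts / 20000 - 0.25)), 0.01)
})

test_that("offset refresh is a clamped exponential moving average", {
  p <- random_toy_params(6)
  mh <- matrix(0.9, 1, 3); mv <- rep(0.2, 4)
  full <- update_offsets(p, mh, mv, ema_rate = 1)
  expect_equal(full$alpha_h, mh)
  expect_equal(full$alpha_v, mv)
  expect_error(update_offsets(p, mh, mv, ema_rate = 0), "ema_rate")
  # geometric convergence to a constant batch
  q <- p
  for (i in 1:5) q <- update_offsets(q, mh, mv, ema_rate = 0.5)
  expect_equal(max(abs(q$alpha_h - 0.9)), max(abs(p$alpha_h - 0.9)) * 0.5^5,
               tolerance = 1e-12)
})

test_that("zero learning rate leaves parameters unchanged", {
  p <- random_toy_params(7)
  p$learning_rate <- 0
  v <- withr::with_seed(8, matrix(runif(20), 5, 4))
  q <- withr::with_seed(9, cd_update(v, p, refresh_offsets = FALSE))
  expect_identical(q$filters, p$filters)
  expect_identical(q$beta, p$beta)
  expect_identical(q$o, p$o)
  expect_true(is.finite(attr(q, "recon_error")))
})

test_that("CD gradient points along the exact log-likelihood gradient", {
  cos_sims <- vapply(1:40, function(seed) {
    p <- random_toy_params(seed)
    v <- withr::with_seed(seed + 500, matrix(rbinom(40, 1, 0.5), 10, 4))
    g_cd <- withr::with_seed(seed + 900, {
      attr(cd_update(v, p, k_steps = 1, refresh_offsets = FALSE),
           "gradient")
    })
    g_ex <- exact_gradient(v, p)
    a <- flatten_gradient(g_cd); b <- flatten_gradient(g_ex)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_gt(mean(cos_sims), 0.9)
})

test_that("training reduces reconstruction error over epochs", {
  finals <- vapply(1:5, function(s) {
    cohort <- generate_cohort(synthetic_config(300, seed = s))
    m <- ccrbm_fit(cohort, epochs = 25, seed = s)
    m$history$recon_error[nrow(m$history)] / m$history$recon_error[1]
  }, numeric(1))
  expect_lt(median(finals), 1)
})

test_that("pooled features are probabilities with the right geometry", {
  p <- ccrbm_params(toy_structure())  # zero params: S = 0, block of 3
  f <- extract_features(c(0.5, 0.5, 0.5, 0.5), p, centered = FALSE)
  expect_equal(f, 0.75)  # 1 - 1/(1 + 3)
  q <- random_toy_params(9, sd = 3)
  vm <- withr::with_seed(10, matrix(runif(40), 10, 4))
  fm <- extract_features(vm, q)
  expect_equal(dim(fm), c(10, 1))
  expect_true(all(fm >= 0 & fm <= 1))
  expect_identical(fm, extract_features(vm, q))  # deterministic
})

test_that("readout predicts through a monotone sigmoid and fails untrained", {
  cohort <- generate_cohort(synthetic_config(200, seed = 12))
  m <- ccrbm_fit(cohort, epochs = 3, seed = 12)
  pr <- predict(m, cohort)
  expect_true(all(pr$label %in% c(0, 1)))
  expect_true(all(pr$confidence >= 0 & pr$confidence <= 1))
  expect_identical(pr$label, as.integer(pr$confidence >= 0.5))
  m0 <- m; m0$readout <- rep(0, length(m0$readout))
  expect_equal(unique(predict(m0, cohort)$confidence), 0.5)
  mna <- m; mna$readout <- NULL
  expect_error(predict(mna, cohort), "readout")
})

test_that("model JSON serialization roundtrips bit-exactly", {
  cohort <- generate_cohort(synthetic_config(100, seed = 13))
  m <- ccrbm_fit(cohort, epochs = 5, seed = 13)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_model(m, p1)
  m2 <- read_model(p1)
  expect_identical(m2$params$filters, m$params$filters)
  expect_identical(m2$params$alpha_h, m$params$alpha_h)
  expect_identical(m2$readout, m$readout)
  write_model(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  pred1 <- predict(m, cohort); pred2 <- predict(m2, cohort)
  expect_identical(pred1, pred2)
})
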