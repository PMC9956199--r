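# Small fixtures shared across tests: toy keys with hand-checkable moduli
# and a 4-visible / 1-filter / width-2 CCRBM whose joint distribution can
# be enumerated exactly.

# plain-R modular exponentiation on small integers: the independent oracle
# for the big-integer backend and the toy cryptosystems
modpow <- function(base, expo, mod) {
  r <- 1
  base <- base %% mod
  while (expo > 0) {
    if (expo %% 2 == 1) r <- (r * base) %% mod
    base <- (base * base) %% mod
    expo <- expo %/% 2
  }
  r
}

toy_paillier <- function() he_keygen("paillier", primes = c("5", "7"))
toy_rsa <- function() he_keygen("rsa", primes = c("3", "11"),
                                public_exponent = 7)

toy_structure <- function() ccrbm_structure(visible_length = 4L,
                                            n_filters = 1L,
                                            filter_width = 2L,
                                            pool_block = 3L)

random_toy_params <- function(seed, sd = 1) {
  s <- toy_structure()
  withr::with_seed(seed, {
    p <- ccrbm_params(s, filters = matrix(rnorm(2, sd = sd), 1),
                      beta = rnorm(1, sd = sd), o = rnorm(1, sd = sd))
    p$alpha_h[] <- runif(length(p$alpha_h))
    p$alpha_v <- runif(length(p$alpha_v))
    p
  })
}

# exact posteriors from the enumerated joint
enum_hidden_marginal <- function(joint, v) {
  iv <- which(apply(joint$v_states, 1, function(r) all(r == v)))
  post <- joint$prob[iv, ] / sum(joint$prob[iv, ])
  acc <- 0 * joint$h_states[[1]]
  for (j in seq_along(joint$h_states))
    acc <- acc + post[j] * joint$h_states[[j]]
  acc
}

enum_visible_marginal <- function(joint, h) {
  jh <- which(vapply(joint$h_states, function(hs) all(hs == h), logical(1)))
  post <- joint$prob[, jh] / sum(joint$prob[, jh])
  as.vector(post %*% joint$v_states)
}

flatten_gradient <- function(g) c(as.vector(g$filters), g$beta, g$o)
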