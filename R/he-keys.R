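#' Generate a key pair for partially homomorphic encryption
#'
#' Two schemes are provided behind one interface, because no single partially
#' homomorphic scheme supports both operations: `"paillier"` is additively
#' homomorphic (multiplying ciphertexts adds plaintexts) and `"rsa"` is
#' textbook, unpadded RSA, which is multiplicatively homomorphic and
#' demonstration-grade only. Prime search is driven by the supplied seed so
#' key generation is reproducible; candidates are drawn from R's RNG and
#' advanced to the next prime under a Miller-Rabin test.
#'
#' @param scheme `"paillier"` (additive) or `"rsa"` (multiplicative).
#' @param key_bits Modulus size in bits; at least 32 and even. 512 is quick
#'   enough for tests and experiments; use 2048 for realistic deployments.
#' @param seed Integer seed for the prime search.
#' @param primes Optional character vector of two decimal prime strings,
#'   bypassing the random search (a hook for tiny, hand-checkable keys).
#' @param public_exponent RSA public exponent; default 65537 (3 for toy keys
#'   whose Carmichael function it must be coprime to, if needed).
#' @return An object of class `phe_keypair` with fields `scheme`, `n`
#'   (decimal string), scheme-specific public and private components, a
#'   `fingerprint` identifying the key, `key_bits`, and `bt_ms`, the wall
#'   clock key-generation time in milliseconds.
#' @export
#' @examples
#' key <- he_keygen("paillier", key_bits = 128, seed = 42)
#' key$bt_ms >= 0
he_keygen <- function(scheme = c("paillier", "rsa"), key_bits = 512L,
                      seed = 1L, primes = NULL, public_exponent = 65537) {
  scheme <- match.arg(scheme)
  t0 <- now_ms()
  if (is.null(primes)) {
    if (!is_count(key_bits) || key_bits < 32L || key_bits %% 2L != 0L)
      stopf("key_bits must be an even integer >= 32, got %s", key_bits)
    half <- as.integer(key_bits / 2L)
    pq <- with_seed(seed, {
      p <- random_prime(half)
      q <- random_prime(half)
      tries <- 0L
      while (p == q) {
        q <- random_prime(half)
        tries <- tries + 1L
        if (tries > 50L)
          stopf("key_bits = %d too small to find distinct primes", key_bits)
      }
      c(p, q)
    })
    p <- pq[1]; q <- pq[2]
  } else {
    p <- as.character(primes[1]); q <- as.character(primes[2])
    if (!bn_is_prime(p) || !bn_is_prime(q) || p == q)
      stopf("supplied primes must be two distinct primes")
  }
  n <- bn_mul(p, q)
  p1 <- bn_sub(p, "1"); q1 <- bn_sub(q, "1")
  phi <- bn_mul(p1, q1)
  if (bn_gcd(n, phi) != "1")
    stopf("degenerate primes: gcd(n, (p-1)(q-1)) != 1; choose another seed")
  lambda <- bn_div(phi, bn_gcd(p1, q1))  # lcm(p-1, q-1)
  key <- switch(scheme,
    paillier = {
      n2 <- bn_mul(n, n)
      g <- bn_add(n, "1")
      # with g = n + 1, L(g^lambda mod n^2) = lambda mod n, so mu = lambda^-1,
      # but compute it by the general rule to keep the code honest
      u <- bn_mod_exp(g, lambda, n2)
      lu <- bn_div(bn_sub(u, "1"), n)
      mu <- bn_mod_inverse(lu, n)
      list(scheme = "paillier", n = n, n2 = n2, g = g,
           lambda = lambda, mu = mu)
    },
    rsa = {
      e <- format(public_exponent, scientific = FALSE)
      if (bn_gcd(e, lambda) != "1")
        stopf("public exponent %s not coprime to lambda(n); choose another seed",
              e)
      d <- bn_mod_inverse(e, lambda)
      list(scheme = "rsa", n = n, e = e, d = d)
    })
  key$key_bits <- bn_num_bits(n)
  key$fingerprint <- key_fingerprint(key)
  key$bt_ms <- now_ms() - t0
  structure(key, class = "phe_keypair")
}

#' @noRd
key_fingerprint <- function(key) {
  pub <- if (key$scheme == "paillier") key$g else key$e
  substr(sha256_hex(paste(key$scheme, key$n, pub, sep = ":")), 1L, 16L)
}

# Random odd candidate with the top two bits set (so p*q reaches the full
# modulus length), advanced to the next prime.
#' @noRd
random_prime <- function(bits) {
  n_bytes <- ceiling(bits / 8)
  bytes <- sample.int(256L, n_bytes, replace = TRUE) - 1L
  hex <- paste(sprintf("%02x", bytes), collapse = "")
  cand <- bn_from_hex(hex)
  # clamp to exactly `bits` bits, force top two and bottom bit
  two_b <- bn_pow2(bits)
  cand <- bn_mod(cand, two_b)
  cand <- bn_add(bn_mod(cand, bn_pow2(bits - 2L)),
                 bn_add(bn_pow2(bits - 1L), bn_pow2(bits - 2L)))
  if (bn_mod(cand, "2") == "0") cand <- bn_add(cand, "1")
  while (!bn_is_prime(cand)) cand <- bn_add(cand, "2")
  cand
}

# 2^k as a decimal string, built from its hex representation
#' @noRd
bn_pow2 <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  bn_from_hex(paste0(c("1", "2", "4", "8")[k %% 4L + 1L],
                     strrep("0", k %/% 4L)))
}

#' @export
print.phe_keypair <- function(x, ...) {
  cat(sprintf("<phe_keypair> scheme=%s bits=%d fingerprint=%s\n",
              x$scheme, x$key_bits, x$fingerprint))
  invisible(x)
}

#' Write or read key files
#'
#' Keys are serialized as JSON with the public and private halves in separate
#' files, big integers as decimal strings.
#'
#' @param key A `phe_keypair`.
#' @param public_path,private_path File paths; `private_path = NULL` writes
#'   only the public half.
#' @export
write_keys <- function(key, public_path, private_path = NULL) {
  if (!inherits(key, "phe_keypair")) stopf("not a phe_keypair")
  pub_fields <- switch(key$scheme,
                       paillier = c("scheme", "n", "n2", "g"),
                       rsa = c("scheme", "n", "e"))
  pub <- c(key[pub_fields], list(key_bits = key$key_bits,
                                 fingerprint = key$fingerprint))
  jsonlite::write_json(pub, public_path, auto_unbox = TRUE)
  if (!is.null(private_path)) {
    priv_fields <- switch(key$scheme,
                          paillier = c("scheme", "n", "n2", "g", "lambda", "mu"),
                          rsa = c("scheme", "n", "e", "d"))
    priv <- c(key[priv_fields], list(key_bits = key$key_bits,
                                     fingerprint = key$fingerprint))
    jsonlite::write_json(priv, private_path, auto_unbox = TRUE)
  }
  invisible(public_path)
}

#' @rdname write_keys
#' @param path Path of a key JSON file (public or private half).
#' @export
read_keys <- function(path) {
  k <- jsonlite::read_json(path, simplifyVector = TRUE)
  k$key_bits <- as.integer(k$key_bits)
  structure(k, class = "phe_keypair")
}
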