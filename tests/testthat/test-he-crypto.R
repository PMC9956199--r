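# Toy keys small enough to check every step against plain modular
# arithmetic, plus realistic 512-bit keys for the scheme properties.

test_that("toy Paillier key has the hand-computed components", {
  key <- toy_paillier()
  expect_equal(key$n, "35")
  expect_equal(key$g, "36")
  expect_equal(key$lambda, "12")  # lcm(4, 6)
  expect_equal(key$scheme, "paillier")
  expect_gte(key$bt_ms, 0)
})

test_that("toy Paillier encryption matches the modular-exponentiation oracle", {
  key <- toy_paillier()
  # c = g^m * r^n mod n^2 computed independently
  expected <- (modpow(36, 3, 1225) * modpow(2, 35, 1225)) %% 1225
  ct <- phe_encrypt("3", key, r = "2")
  expect_equal(ct$value, as.character(expected))
  expect_equal(phe_decrypt(ct, key), "3")
  # decryption inverts encryption over the whole message space
  for (m in as.character(c(0, 1, 17, 34)))
    expect_equal(phe_decrypt(phe_encrypt(m, key), key), m)
})

test_that("toy RSA encrypts and decrypts by the textbook rule", {
  key <- toy_rsa()
  expect_equal(key$n, "33")
  expect_equal(key$d, as.character(3))  # 7 * 3 = 21 = 1 mod lcm(2,10)
  ct <- phe_encrypt("4", key)
  expect_equal(ct$value, as.character(modpow(4, 7, 33)))
  expect_equal(phe_decrypt(ct, key), "4")
})

test_that("key generation is seed-deterministic and invariant-satisfying", {
  k1 <- he_keygen("paillier", key_bits = 128, seed = 9)
  k2 <- he_keygen("paillier", key_bits = 128, seed = 9)
  expect_identical(k1$n, k2$n)
  expect_identical(k1$mu, k2$mu)
  k3 <- he_keygen("paillier", key_bits = 128, seed = 10)
  expect_false(identical(k1$n, k3$n))
  expect_gte(k1$key_bits, 127)
  expect_error(he_keygen("paillier", key_bits = 30), "key_bits")
  expect_error(he_keygen("paillier", key_bits = 33), "key_bits")
})

test_that("homomorphic addition decrypts to exact sums", {
  key <- toy_paillier()
  s <- he_add(phe_encrypt("3", key), phe_encrypt("4", key), key)
  expect_equal(phe_decrypt(s, key), "7")
  # additive identity
  m <- phe_encrypt("19", key)
  expect_equal(phe_decrypt(he_add(m, phe_encrypt("0", key), key), key), "19")

  key512 <- he_keygen("paillier", 512, seed = 21)
  withr::with_seed(22, {
    for (i in 1:50) {
      a <- sample.int(1e8, 1); b <- sample.int(1e8, 1)
      ct <- he_add(phe_encrypt(as.character(a), key512),
                   phe_encrypt(as.character(b), key512), key512)
      expect_identical(phe_decrypt(ct, key512), as.character(a + b))
    }
  })
})

test_that("homomorphic multiplication decrypts to exact products", {
  key <- toy_rsa()
  pr <- he_multiply(phe_encrypt("4", key), phe_encrypt("2", key), key)
  expect_equal(phe_decrypt(pr, key), "8")
  expect_equal(phe_decrypt(he_multiply(phe_encrypt("7", key),
                                       phe_encrypt("1", key), key), key),
               "7")

  key512 <- he_keygen("rsa", 512, seed = 23)
  withr::with_seed(24, {
    for (i in 1:50) {
      a <- sample.int(1e7, 1); b <- sample.int(1e7, 1)
      ct <- he_multiply(phe_encrypt(as.character(a), key512),
                        phe_encrypt(as.character(b), key512), key512)
      expect_identical(phe_decrypt(ct, key512),
                       as.character(phecare:::bn_mul(as.character(a),
                                                     as.character(b))))
    }
  })
})

test_that("scheme and key mismatches are refused", {
  kp <- toy_paillier(); kr <- toy_rsa()
  cp <- phe_encrypt("2", kp); cr <- phe_encrypt("2", kr)
  expect_error(he_add(cp, cr, kp), "scheme")
  expect_error(he_multiply(cr, cp, kr), "scheme")
  expect_error(phe_decrypt(cp, kr), "fingerprint")
  expect_error(phe_encrypt("40", kp), "message space")
  kp2 <- he_keygen("paillier", primes = c("11", "13"))
  expect_error(he_add(cp, phe_encrypt("2", kp2), kp), "same key")
})

test_that("Paillier is randomized, textbook RSA is deterministic", {
  kp <- he_keygen("paillier", 128, seed = 31)
  withr::with_seed(32, {
    c1 <- phe_encrypt("5", kp)
    c2 <- phe_encrypt("5", kp)
  })
  expect_false(identical(c1$value, c2$value))
  expect_identical(phe_decrypt(c1, kp), phe_decrypt(c2, kp))
  kr <- he_keygen("rsa", 128, seed = 31)
  expect_identical(phe_encrypt("5", kr)$value, phe_encrypt("5", kr)$value)
})

test_that("fixed-point encoding roundtrips within the stated precision", {
  key <- he_keygen("paillier", 128, seed = 41)
  x <- c(0, 1, 0.123456, -0.654321, 0.999999, -1)
  enc <- phe_encode(x, key$n, digits = 6)
  expect_equal(phe_decode(enc$mantissa, key$n, 6), x)
  y <- c(0.1234567891, -0.987654321)
  enc2 <- phe_encode(y, key$n, digits = 6)
  expect_lt(max(abs(phe_decode(enc2$mantissa, key$n, 6) - y)), 1e-6)
  expect_error(phe_encode(NaN, key$n), "non-finite")
  expect_error(phe_encode(1e60, toy_paillier()$n), "fixed-point|message")
})

test_that("cohort encryption roundtrips exactly and records timings", {
  cohort <- generate_cohort(synthetic_config(60, seed = 5))
  key <- he_keygen("paillier", 128, seed = 6)
  store <- encrypt_cohort(cohort, key)
  expect_gte(store$meta$at_ms, 0)
  back <- decrypt_cohort(store, key)
  expect_gte(attr(back, "ct_ms"), 0)
  attr(back, "ct_ms") <- NULL
  expect_identical(back, cohort)

  # plaintext store (unprotected baseline) roundtrips too
  ps <- encrypt_cohort(cohort, key = NULL)
  backp <- decrypt_cohort(ps)
  attr(backp, "ct_ms") <- NULL
  expect_identical(backp, cohort)

  empty <- store; empty$records <- list()
  expect_error(decrypt_cohort(empty, key), "empty")
  broken <- store; broken$records[[3]]$values <- broken$records[[3]]$values[-1]
  expect_error(decrypt_cohort(broken, key), "incomplete record 3")
})

test_that("key files and ciphertext stores survive JSON serialization", {
  key <- he_keygen("paillier", 128, seed = 8)
  pub <- withr::local_tempfile(fileext = ".json")
  priv <- withr::local_tempfile(fileext = ".json")
  write_keys(key, pub, priv)
  kpub <- read_keys(pub)
  expect_null(kpub$lambda)
  expect_identical(kpub$fingerprint, key$fingerprint)
  kpriv <- read_keys(priv)
  expect_identical(kpriv$lambda, key$lambda)

  cohort <- generate_cohort(synthetic_config(10, seed = 9))
  store <- encrypt_cohort(cohort, key)
  sp <- withr::local_tempfile(fileext = ".json")
  write_store(store, sp)
  store2 <- read_store(sp)
  # ciphertext encrypted with the written public key decrypts with the
  # written private key
  back <- decrypt_cohort(store2, kpriv)
  attr(back, "ct_ms") <- NULL
  expect_identical(back, cohort)
})
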