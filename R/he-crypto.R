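#' Fixed-point encoding of real numbers into the message space
#'
#' Real features are mapped to residues by `mantissa = round(x * 10^digits)`,
#' with negative values represented as `n - |mantissa|` (decoded back by the
#' `n/2` threshold, the usual signed-residue convention). Decoding recovers
#' the value to within `10^-digits`.
#'
#' @param x Numeric vector to encode.
#' @param n Modulus (decimal string) defining the message space.
#' @param digits Decimal digits of fixed-point precision; default 6.
#' @return `phe_encode` returns a list with `mantissa` (character vector of
#'   decimal residues) and `exponent` (= `digits`); `phe_decode` returns the
#'   numeric values.
#' @export
phe_encode <- function(x, n, digits = 6L) {
  if (any(!is.finite(x))) stopf("cannot encode non-finite values")
  m <- round(x * 10^digits)
  if (any(abs(m) >= 2^53))
    stopf("value too large for fixed-point encoding at %d digits", digits)
  half <- bn_div(n, "2")
  ms <- character(length(m))
  for (i in seq_along(m)) {
    a <- format(abs(m[i]), scientific = FALSE)
    if (bn_cmp(a, half) >= 0)
      stopf("encoded magnitude %s exceeds message space n/2", a)
    ms[i] <- if (m[i] < 0) bn_sub(n, a) else a
  }
  list(mantissa = ms, exponent = as.integer(digits))
}

#' @rdname phe_encode
#' @param mantissa Character vector of decimal residues mod `n`.
#' @export
phe_decode <- function(mantissa, n, digits = 6L) {
  half <- bn_div(n, "2")
  vapply(mantissa, function(m) {
    neg <- bn_cmp(m, half) > 0
    if (neg) m <- bn_sub(n, m)
    v <- as.numeric(m)
    if (v >= 2^53) warnf("decoded mantissa exceeds double precision")
    (if (neg) -v else v) / 10^digits
  }, numeric(1), USE.NAMES = FALSE)
}

#' Encrypt and decrypt single residues
#'
#' Paillier encryption computes `c = g^m * r^n mod n^2` with fresh random
#' `r` coprime to `n` (so repeated encryptions of the same message differ);
#' textbook RSA computes the deterministic `c = m^e mod n`. Decryption
#' inverts exactly: Paillier via `m = L(c^lambda mod n^2) * mu mod n` with
#' `L(u) = (u - 1) / n`, RSA via `m = c^d mod n`.
#'
#' @param mantissa A decimal residue string (see [phe_encode()]).
#' @param key A `phe_keypair`.
#' @param exponent Fixed-point exponent carried on the ciphertext.
#' @param r Optional fixed Paillier randomizer (testing hook); by default a
#'   fresh random unit mod n is drawn from the current RNG stream.
#' @return `phe_encrypt` returns a `phe_ciphertext` (fields `value`,
#'   `scheme`, `fingerprint`, `exponent`); `phe_decrypt` returns the decimal
#'   mantissa string.
#' @export
phe_encrypt <- function(mantissa, key, exponent = 6L, r = NULL) {
  if (!inherits(key, "phe_keypair")) stopf("not a phe_keypair")
  if (bn_cmp(mantissa, key$n) >= 0 || substr(mantissa, 1, 1) == "-")
    stopf("mantissa outside message space [0, n)")
  value <- switch(key$scheme,
    paillier = {
      if (is.null(r)) r <- random_unit(key$n)
      gm <- bn_mod(bn_add(bn_mul(mantissa, key$n), "1"), key$n2)  # (1+n)^m
      bn_mod_mul(gm, bn_mod_exp(r, key$n, key$n2), key$n2)
    },
    rsa = bn_mod_exp(mantissa, key$e, key$n),
    stopf("unknown scheme %s", key$scheme))
  structure(list(value = value,
                 scheme = if (key$scheme == "paillier") "additive"
                          else "multiplicative",
                 fingerprint = key$fingerprint,
                 exponent = as.integer(exponent)),
            class = "phe_ciphertext")
}

#' @rdname phe_encrypt
#' @param ciphertext A `phe_ciphertext`.
#' @export
phe_decrypt <- function(ciphertext, key) {
  if (!inherits(ciphertext, "phe_ciphertext")) stopf("not a phe_ciphertext")
  if (!identical(ciphertext$fingerprint, key$fingerprint))
    stopf("ciphertext key fingerprint %s does not match key %s",
          ciphertext$fingerprint, key$fingerprint)
  switch(key$scheme,
    paillier = {
      if (is.null(key$lambda)) stopf("private Paillier components missing")
      u <- bn_mod_exp(ciphertext$value, key$lambda, key$n2)
      lu <- bn_div(bn_sub(u, "1"), key$n)
      bn_mod_mul(lu, key$mu, key$n)
    },
    rsa = {
      if (is.null(key$d)) stopf("private RSA exponent missing")
      bn_mod_exp(ciphertext$value, key$d, key$n)
    })
}

# fresh random unit mod n (coprime to n), from the current RNG stream
#' @noRd
random_unit <- function(n) {
  bits <- bn_num_bits(n)
  repeat {
    n_bytes <- ceiling(bits / 8)
    bytes <- sample.int(256L, n_bytes, replace = TRUE) - 1L
    r <- bn_mod(bn_from_hex(paste(sprintf("%02x", bytes), collapse = "")), n)
    if (r != "0" && bn_gcd(r, n) == "1") return(r)
  }
}

#' Homomorphic operations on ciphertexts
#'
#' `he_add` combines two additive (Paillier) ciphertexts so that the result
#' decrypts to the sum of the plaintexts mod n: implemented as ciphertext
#' multiplication mod n^2. `he_multiply` combines two multiplicative (RSA)
#' ciphertexts so that the result decrypts to the product mod n: ciphertext
#' multiplication mod n. Both require matching scheme, key fingerprint and
#' fixed-point exponent.
#'
#' @param c1,c2 `phe_ciphertext` objects under the same key.
#' @param key The (public half of the) `phe_keypair`.
#' @return A `phe_ciphertext`.
#' @export
he_add <- function(c1, c2, key) {
  check_pair(c1, c2, key, "additive")
  structure(list(value = bn_mod_mul(c1$value, c2$value, key$n2),
                 scheme = "additive", fingerprint = c1$fingerprint,
                 exponent = c1$exponent),
            class = "phe_ciphertext")
}

#' @rdname he_add
#' @export
he_multiply <- function(c1, c2, key) {
  check_pair(c1, c2, key, "multiplicative")
  structure(list(value = bn_mod_mul(c1$value, c2$value, key$n),
                 scheme = "multiplicative", fingerprint = c1$fingerprint,
                 exponent = c1$exponent),
            class = "phe_ciphertext")
}

#' @noRd
check_pair <- function(c1, c2, key, scheme) {
  for (ct in list(c1, c2)) {
    if (!inherits(ct, "phe_ciphertext")) stopf("not a phe_ciphertext")
    if (!identical(ct$scheme, scheme))
      stopf("ciphertext scheme %s incompatible with %s operation",
            ct$scheme, scheme)
  }
  if (!identical(c1$fingerprint, c2$fingerprint) ||
      !identical(c1$fingerprint, key$fingerprint))
    stopf("ciphertexts are not under the same key")
  if (!identical(c1$exponent, c2$exponent))
    stopf("fixed-point exponents differ: %d vs %d", c1$exponent, c2$exponent)
  invisible(TRUE)
}

#' Encrypt / decrypt a whole cohort
#'
#' Encrypts every feature value and the label of each record, producing a
#' ciphertext store with the encryption time AT recorded in milliseconds;
#' decryption reverses the store into a cohort and records the decryption
#' time CT. With `key = NULL` the "store" keeps plaintext mantissas
#' (scheme `"plaintext"`), which is useful as the unprotected baseline in
#' security analyses.
#'
#' @param cohort A cohort `data.frame`.
#' @param key A `phe_keypair`, or `NULL` for an unencrypted store.
#' @param digits Fixed-point precision (decimal digits); default 6.
#' @return `encrypt_cohort`: a `phe_store` list with `meta` (scheme,
#'   fingerprint, exponent, feature names, `at_ms`) and `records`.
#'   `decrypt_cohort`: the cohort, with `ct_ms` attached as attribute
#'   `"ct_ms"`.
#' @export
encrypt_cohort <- function(cohort, key, digits = 6L) {
  validate_cohort(cohort)
  t0 <- now_ms()
  feat_cols <- grep("^f[0-9]+$", names(cohort), value = TRUE)
  plaintext <- is.null(key)
  records <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    vals <- c(as.numeric(cohort[i, feat_cols]), cohort$label[i])
    if (plaintext) {
      m <- format(round(vals * 10^digits), scientific = FALSE)
      enc <- gsub(" ", "", m)
    } else {
      enc <- vapply(phe_encode(vals, key$n, digits)$mantissa,
                    function(m) phe_encrypt(m, key, digits)$value,
                    character(1), USE.NAMES = FALSE)
    }
    records[[i]] <- list(patient_id = cohort$patient_id[i], values = enc)
  }
  structure(list(
    meta = list(scheme = if (plaintext) "plaintext"
                         else if (key$scheme == "paillier") "additive"
                         else "multiplicative",
                base_scheme = if (plaintext) "plaintext" else key$scheme,
                fingerprint = if (plaintext) "plaintext" else key$fingerprint,
                exponent = as.integer(digits),
                features = feat_cols,
                at_ms = now_ms() - t0),
    records = records), class = "phe_store")
}

#' @rdname encrypt_cohort
#' @param store A `phe_store`.
#' @export
decrypt_cohort <- function(store, key = NULL, digits = NULL) {
  if (!inherits(store, "phe_store")) stopf("not a phe_store")
  if (length(store$records) == 0L) stopf("ciphertext store is empty")
  t0 <- now_ms()
  digits <- if (is.null(digits)) store$meta$exponent else as.integer(digits)
  feat_cols <- store$meta$features
  plaintext <- identical(store$meta$scheme, "plaintext")
  if (!plaintext && !identical(store$meta$fingerprint, key$fingerprint))
    stopf("store fingerprint %s does not match key %s",
          store$meta$fingerprint, key$fingerprint)
  n <- length(store$records)
  mat <- matrix(NA_real_, n, length(feat_cols) + 1L)
  ids <- character(n)
  for (i in seq_len(n)) {
    rec <- store$records[[i]]
    if (is.null(rec$patient_id) || is.null(rec$values) ||
        length(rec$values) != length(feat_cols) + 1L)
      stopf("incomplete record %d in ciphertext store", i)
    ids[i] <- rec$patient_id
    ms <- if (plaintext) {
      vapply(unlist(rec$values), function(m)
        if (substr(m, 1, 1) == "-") m else m, character(1), USE.NAMES = FALSE)
    } else {
      vapply(unlist(rec$values), function(v) {
        ct <- structure(list(value = v, scheme = store$meta$scheme,
                             fingerprint = store$meta$fingerprint,
                             exponent = digits), class = "phe_ciphertext")
        phe_decrypt(ct, key)
      }, character(1), USE.NAMES = FALSE)
    }
    mat[i, ] <- if (plaintext) as.numeric(ms) / 10^digits
                else phe_decode(ms, key$n, digits)
  }
  cohort <- data.frame(patient_id = ids, mat[, seq_along(feat_cols),
                                            drop = FALSE],
                       label = as.integer(round(mat[, length(feat_cols) + 1L])),
                       stringsAsFactors = FALSE)
  names(cohort) <- c("patient_id", feat_cols, "label")
  cohort <- validate_cohort(cohort)
  attr(cohort, "ct_ms") <- now_ms() - t0
  cohort
}

#' Write / read a ciphertext store as JSON
#'
#' Ciphertext values are decimal strings; the file carries scheme,
#' fingerprint and fixed-point exponent so stores are self-describing.
#'
#' @param store A `phe_store`.
#' @param path File path.
#' @export
write_store <- function(store, path) {
  if (!inherits(store, "phe_store")) stopf("not a phe_store")
  jsonlite::write_json(list(meta = store$meta, records = store$records),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = FALSE)
  s$meta <- lapply(s$meta, function(x) if (is.list(x)) unlist(x) else x)
  s$meta$exponent <- as.integer(s$meta$exponent)
  s$records <- lapply(s$records, function(r)
    list(patient_id = r$patient_id, values = unlist(r$values)))
  structure(list(meta = s$meta, records = s$records), class = "phe_store")
}
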