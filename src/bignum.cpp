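// Arbitrary-precision modular arithmetic over decimal strings, backed by
// OpenSSL's BIGNUM. All values cross the R boundary as decimal strings so
// that 512-bit (and larger) moduli survive R's 53-bit doubles.
#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/evp.h>
#include <string>

using namespace Rcpp;

namespace {

struct Bn {
  BIGNUM *p;
  Bn() : p(BN_new()) {
    if (!p) stop("BN_new failed");
  }
  explicit Bn(const std::string &dec) : p(NULL) {
    if (BN_dec2bn(&p, dec.c_str()) == 0) {
      if (p) BN_free(p);
      stop("invalid decimal big integer: '%s'", dec.c_str());
    }
  }
  ~Bn() { BN_free(p); }
  std::string dec() const {
    char *s = BN_bn2dec(p);
    std::string out(s);
    OPENSSL_free(s);
    return out;
  }
};

struct Ctx {
  BN_CTX *p;
  Ctx() : p(BN_CTX_new()) {
    if (!p) stop("BN_CTX_new failed");
  }
  ~Ctx() { BN_CTX_free(p); }
};

}  // namespace

// [[Rcpp::export]]
std::string bn_add(std::string a, std::string b) {
  Bn x(a), y(b), r;
  BN_add(r.p, x.p, y.p);
  return r.dec();
}

// [[Rcpp::export]]
std::string bn_sub(std::string a, std::string b) {
  Bn x(a), y(b), r;
  BN_sub(r.p, x.p, y.p);
  return r.dec();
}

// [[Rcpp::export]]
std::string bn_mul(std::string a, std::string b) {
  Bn x(a), y(b), r;
  Ctx ctx;
  BN_mul(r.p, x.p, y.p, ctx.p);
  return r.dec();
}

// Integer quotient, truncated toward zero (OpenSSL convention).
// [[Rcpp::export]]
std::string bn_div(std::string a, std::string b) {
  Bn x(a), y(b), q, r;
  if (BN_is_zero(y.p)) stop("division by zero");
  Ctx ctx;
  BN_div(q.p, r.p, x.p, y.p, ctx.p);
  return q.dec();
}

// Non-negative residue a mod m.
// [[Rcpp::export]]
std::string bn_mod(std::string a, std::string m) {
  Bn x(a), y(m), r;
  if (BN_is_zero(y.p)) stop("modulus is zero");
  Ctx ctx;
  if (!BN_nnmod(r.p, x.p, y.p, ctx.p)) stop("bn_mod failed");
  return r.dec();
}

// [[Rcpp::export]]
std::string bn_mod_mul(std::string a, std::string b, std::string m) {
  Bn x(a), y(b), n(m), r;
  Ctx ctx;
  if (!BN_mod_mul(r.p, x.p, y.p, n.p, ctx.p)) stop("bn_mod_mul failed");
  return r.dec();
}

// [[Rcpp::export]]
std::string bn_mod_exp(std::string a, std::string e, std::string m) {
  Bn x(a), y(e), n(m), r;
  Ctx ctx;
  if (BN_is_negative(y.p)) stop("negative exponent");
  if (!BN_mod_exp(r.p, x.p, y.p, n.p, ctx.p)) stop("bn_mod_exp failed");
  return r.dec();
}

// Modular inverse; errors if gcd(a, m) != 1.
// [[Rcpp::export]]
std::string bn_mod_inverse(std::string a, std::string m) {
  Bn x(a), n(m), r;
  Ctx ctx;
  if (!BN_mod_inverse(r.p, x.p, n.p, ctx.p))
    stop("no modular inverse: argument not coprime to modulus");
  return r.dec();
}

// [[Rcpp::export]]
std::string bn_gcd(std::string a, std::string b) {
  Bn x(a), y(b), r;
  Ctx ctx;
  if (!BN_gcd(r.p, x.p, y.p, ctx.p)) stop("bn_gcd failed");
  return r.dec();
}

// -1, 0, 1 as sign of a - b.
// [[Rcpp::export]]
int bn_cmp(std::string a, std::string b) {
  Bn x(a), y(b);
  return BN_cmp(x.p, y.p);
}

// Miller-Rabin with OpenSSL's default number of rounds for the size.
// [[Rcpp::export]]
bool bn_is_prime(std::string a) {
  Bn x(a);
  Ctx ctx;
  int r = BN_check_prime(x.p, ctx.p, NULL);
  if (r < 0) stop("primality test failed");
  return r == 1;
}

// [[Rcpp::export]]
int bn_num_bits(std::string a) {
  Bn x(a);
  return BN_num_bits(x.p);
}

// [[Rcpp::export]]
std::string bn_from_hex(std::string h) {
  BIGNUM *p = NULL;
  if (BN_hex2bn(&p, h.c_str()) == 0) {
    if (p) BN_free(p);
    stop("invalid hex big integer");
  }
  char *s = BN_bn2dec(p);
  std::string out(s);
  OPENSSL_free(s);
  BN_free(p);
  return out;
}

// SHA-256 of a character string, hex-encoded (key fingerprints).
// [[Rcpp::export]]
std::string sha256_hex(std::string s) {
  unsigned char md[EVP_MAX_MD_SIZE];
  unsigned int len = 0;
  if (!EVP_Digest(s.data(), s.size(), md, &len, EVP_sha256(), NULL))
    stop("sha256 failed");
  static const char *hex = "0123456789abcdef";
  std::string out;
  out.reserve(2 * len);
  for (unsigned int i = 0; i < len; ++i) {
    out.push_back(hex[md[i] >> 4]);
    out.push_back(hex[md[i] & 0xf]);
  }
  return out;
}
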