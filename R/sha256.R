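# SHA-256 (FIPS 180-4) in pure R, used for structural tree digests.
# Words are doubles in [0, 2^32); bitwise ops work on 16-bit halves so that
# R's signed 32-bit integer bit operators never see values >= 2^31.

.sha256_k <- c(
  0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
  0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
  0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
  0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
  0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
  0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
  0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
  0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
  0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
  0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
  0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2)

.sha256_h0 <- c(0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
                0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19)

.bw <- function(f, a, b) {
  f(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
    f(as.integer(a %% 65536), as.integer(b %% 65536))
}
.bxor <- function(a, b) .bw(bitwXor, a, b)
.band <- function(a, b) .bw(bitwAnd, a, b)
.bnot <- function(a) 4294967295 - a
.rotr <- function(x, n) (x %/% 2^n) + (x %% 2^n) * 2^(32 - n)
.shr  <- function(x, n) x %/% 2^n

sha256_raw <- function(msg) {
  stopifnot(is.raw(msg))
  n <- length(msg)
  padlen <- (55 - n) %% 64
  bits <- as.numeric(n) * 8
  lenbytes <- as.raw((bits %/% 2^(8 * (7:0))) %% 256)
  m <- c(msg, as.raw(0x80), raw(padlen), lenbytes)
  words <- as.numeric(m)
  dim(words) <- c(4, length(words) / 4)
  w_all <- words[1, ] * 16777216 + words[2, ] * 65536 + words[3, ] * 256 + words[4, ]
  h <- .sha256_h0
  k <- .sha256_k
  for (blk in seq_len(length(w_all) / 16)) {
    w <- numeric(64)
    w[1:16] <- w_all[(blk - 1) * 16 + 1:16]
    for (t in 17:64) {
      s0 <- .bxor(.bxor(.rotr(w[t - 15], 7), .rotr(w[t - 15], 18)), .shr(w[t - 15], 3))
      s1 <- .bxor(.bxor(.rotr(w[t - 2], 17), .rotr(w[t - 2], 19)), .shr(w[t - 2], 10))
      w[t] <- (w[t - 16] + s0 + w[t - 7] + s1) %% 4294967296
    }
    a <- h[1]; b <- h[2]; cc <- h[3]; d <- h[4]
    e <- h[5]; f <- h[6]; g <- h[7]; hh <- h[8]
    for (t in 1:64) {
      S1 <- .bxor(.bxor(.rotr(e, 6), .rotr(e, 11)), .rotr(e, 25))
      ch <- .bxor(.band(e, f), .band(.bnot(e), g))
      t1 <- (hh + S1 + ch + k[t] + w[t]) %% 4294967296
      S0 <- .bxor(.bxor(.rotr(a, 2), .rotr(a, 13)), .rotr(a, 22))
      maj <- .bxor(.bxor(.band(a, b), .band(a, cc)), .band(b, cc))
      t2 <- (S0 + maj) %% 4294967296
      hh <- g; g <- f; f <- e
      e <- (d + t1) %% 4294967296
      d <- cc; cc <- b; b <- a
      a <- (t1 + t2) %% 4294967296
    }
    h <- (h + c(a, b, cc, d, e, f, g, hh)) %% 4294967296
  }
  paste(sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536)),
        collapse = "")
}

sha256_hex <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
  sha256_raw(x)
}
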