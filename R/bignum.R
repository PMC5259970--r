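# Minimal exact non-negative integer arithmetic on base-1e7 limb vectors
# (little-endian numeric vectors). Only what find_alpha_m() needs to report
# the worst-case memory score n^2 * (2^a + 2^(n-a)) exactly for large n:
# power of two, addition, multiplication by a small integer, decimal printing.

BIG_BASE <- 1e7

big_norm <- function(d) {
  repeat {
    carry <- d %/% BIG_BASE
    if (!any(carry > 0)) break
    d <- d %% BIG_BASE
    d <- c(d, 0)
    d <- d + c(0, carry)
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_pow2 <- function(k) {
  d <- 1
  if (k == 0) return(d)
  # square-free ladder: bulk-double in chunks of 23 (2^23 * base < 2^53)
  left <- k
  while (left > 0) {
    step <- min(left, 23L)
    d <- big_norm(d * 2^step)
    left <- left - step
  }
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

# m must satisfy m * (BIG_BASE - 1) < 2^53, i.e. m up to ~9e8
big_mul_small <- function(a, m) big_norm(a * m)

big_to_string <- function(d) {
  n <- length(d)
  paste0(sprintf("%.0f", d[n]),
         paste(rev(sprintf("%07.0f", d[-n])), collapse = ""))
}
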