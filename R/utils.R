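# internal helpers shared across modules

# half-up integer rounding (R's round() is banker's); x must be >= 0
round_half_up <- function(x) as.integer(floor(x + 0.5))

# stable 31-bit polynomial string hash; independent of R's RNG and locale
str_hash31 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

# derive a per-stream seed from a root seed and a string key; always < 2^31
derive_seed <- function(root_seed, key) {
  (as.numeric(root_seed) %% 2147483647 + str_hash31(key)) %% 2147483647
}

cs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "consensim_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
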