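# Internal helpers: seed derivation and canonical member-set keys.

# Derive a child seed from (seed, index) with a Lehmer-style mixing step.
# Keeps results in [1, 2^31 - 2] so they are valid 32-bit R seeds.
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.double(seed) %% m) * 48271 + as.double(index) * 104729 + 12345
  as.integer(x %% (m - 1)) + 1L
}

# Canonical key for a reaction member set (order-insensitive, duplicate-free).
member_key <- function(members) {
  paste(sort(unique(as.character(members))), collapse = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rxngap <- function(..., class) {
  stop(structure(
    class = c(class, "rxngap_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
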