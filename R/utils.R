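# Internal helpers shared across modules.

# Round half away from zero, so 86.5 -> 87 and -86.5 -> -87 (base round()
# rounds half to even, which would break integer-percent display values).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single non-missing number.", class = "probdnf_config_error")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number in %s%s, %s%s.",
                  name,
                  if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"),
          class = "probdnf_config_error")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x >= min && x == trunc(x)
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "probdnf_config_error")
  }
  invisible(as.integer(x))
}

# Uppercase a nucleotide string and reject characters outside ACGTN.
clean_dna <- function(x, name = "sequence") {
  if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0) {
    abort(sprintf("`%s` must be a single non-empty string.", name),
          class = "probdnf_sequence_error")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    abort(sprintf("`%s` contains characters outside ACGTN.", name),
          class = "probdnf_sequence_error")
  }
  x
}
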