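# Internal helpers: deterministic seeding without disturbing the caller's RNG
# stream, and a few small validators shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically fold integers and strings into a single 31-bit seed.
mix_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "|")) else as.integer(x)
  }), use.names = FALSE)
  h <- 17
  for (p in parts) {
    p <- abs(as.double(p)) %% 2147483647
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  as.integer(h)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0
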