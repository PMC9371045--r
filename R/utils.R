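# Internal helpers shared across modules.

# Deterministic 31-bit hash of a seed plus arbitrary string/number tags.
# Used to derive independent sub-seeds (per set-up, pool, fold, model) from one
# top-level seed so that any subset of the protocol is reproducible on its own.
deriveSeed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid 32-bit R integers
  h <- as.numeric(seed) %% m
  tags <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (tag in tags) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 31 + 7) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (the global .Random.seed is restored on exit).
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# First invalid UTF-8 byte offset (1-based) in a raw vector, or 0L if valid.
# Small DFA over the byte stream; files checked this way are desk-scale.
utf8InvalidOffset <- function(bytes) {
  i <- 1L
  n <- length(bytes)
  b <- as.integer(bytes)
  while (i <= n) {
    x <- b[i]
    if (x < 0x80) {
      i <- i + 1L
    } else if (x >= 0xC2 && x <= 0xDF) {
      if (i + 1L > n || b[i + 1L] < 0x80 || b[i + 1L] > 0xBF) return(i)
      i <- i + 2L
    } else if (x >= 0xE0 && x <= 0xEF) {
      if (i + 2L > n) return(i)
      lo <- if (x == 0xE0) 0xA0 else 0x80
      hi <- if (x == 0xED) 0x9F else 0xBF
      if (b[i + 1L] < lo || b[i + 1L] > hi) return(i)
      if (b[i + 2L] < 0x80 || b[i + 2L] > 0xBF) return(i)
      i <- i + 3L
    } else if (x >= 0xF0 && x <= 0xF4) {
      if (i + 3L > n) return(i)
      lo <- if (x == 0xF0) 0x90 else 0x80
      hi <- if (x == 0xF4) 0x8F else 0xBF
      if (b[i + 1L] < lo || b[i + 1L] > hi) return(i)
      if (any(b[i + 2L:3L] < 0x80 | b[i + 2L:3L] > 0xBF)) return(i)
      i <- i + 4L
    } else {
      return(i)
    }
  }
  0L
}

fmtNum <- function(x, digits = 9L) {
  sprintf(paste0("%.", digits, "g"), x)
}
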