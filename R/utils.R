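# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded from `seed` (and an optional
# stream index), restoring the caller's .Random.seed afterwards. All
# randomness in the package flows through this helper so results are
# reproducible given (seed, stream).
with_seed <- function(seed, expr, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # Knuth-style mix keeps derived seeds within 32-bit integer range.
  sub <- (abs(seed) * 2654435761 + stream * 40503 + 12345) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(sub))
  expr
}

# Order chromosome labels 1..22, X, Y, MT, then anything else alphabetically.
chrom_rank <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(ch))
  r <- ifelse(!is.na(num), num,
    ifelse(toupper(ch) == "X", 23,
      ifelse(toupper(ch) == "Y", 24,
        ifelse(toupper(ch) %in% c("M", "MT"), 25, 26))))
  r + match(ch, sort(unique(ch))) * 1e-6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
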