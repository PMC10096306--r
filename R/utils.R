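## Internal helpers.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards: generators stay reproducible from their own
## seeds without clobbering the session RNG.
withRNG <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

clamp01 <- function(x) {   # keeps dim attributes, unlike pmin/pmax(scalar, x)
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
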