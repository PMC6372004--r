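# Deterministic per-purpose child streams derived from one root seed, so
# that e.g. the frozen pattern is reproducible independently of how much
# background noise or jitter was drawn before it.

child_seed <- function(seed, purpose) {
  codes <- utf8ToInt(purpose)
  h <- sum(codes * seq_along(codes)) %% 65521L
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h * 31) %% 2147483647L
}

with_child_seed <- function(seed, purpose, code) {
  if (is.null(seed)) {
    return(force(code))
  }
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
  set.seed(child_seed(seed, purpose))
  force(code)
}
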