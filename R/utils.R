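# Run code under a temporary RNG seed, restoring the caller's RNG state.
# With seed = NULL the current stream is used unchanged.
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dirichlet draws via normalized gamma variates; rows sum to 1.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}
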