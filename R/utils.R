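# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
# seed = NULL means: use the current stream as-is.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rank-based permutation p-values with the +1 correction, so the smallest
# attainable p is 1/(R+1).
perm_p_geq <- function(obs, perms) (1 + sum(perms >= obs)) / (length(perms) + 1)
perm_p_leq <- function(obs, perms) (1 + sum(perms <= obs)) / (length(perms) + 1)
perm_p_two <- function(obs, perms) {
  min(1, 2 * min(perm_p_geq(obs, perms), perm_p_leq(obs, perms)))
}

# Upper-triangle (i < j) linear indices of an n x n matrix.
upper_pairs <- function(n) which(upper.tri(matrix(0, n, n)))
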