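# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps user-level RNG untouched by seeded helpers.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Numerically stable binomial negative log-likelihood at linear predictor f:
# sum over i of log(1 + exp(f_i)) - y_i * f_i.
binomial_nll <- function(y, f) {
  sum(pmax(f, 0) + log1p(exp(-abs(f))) - y * f)
}

gaussian_risk <- function(y, f) 0.5 * sum((y - f)^2)

risk_fun <- function(family) {
  switch(family, binomial = binomial_nll, gaussian = gaussian_risk,
         stop("unknown family: ", family))
}

check_binary_outcome <- function(y) {
  if (anyNA(y)) stop("outcome contains missing values")
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  as.numeric(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
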