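# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log(sum(exp(x))) without overflow
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# symmetric log-determinant via Cholesky
logdet <- function(S) {
  2 * sum(log(diag(chol((S + t(S)) / 2))))
}

# inverse of a symmetric positive-definite matrix, with escalating jitter
# if numerically singular
robust_inv <- function(S) {
  S <- (S + t(S)) / 2
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    out <- tryCatch(chol2inv(chol(S + j * mean(diag(S)) * diag(nrow(S)))),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("matrix inversion failed even with jitter")
}
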