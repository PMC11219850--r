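#' @keywords internal
"_PACKAGE"

# clamp to the open unit interval at machine-safe bounds; used before logit
clamp01 <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

# unaffected fraction of a two-parameter log-logistic concentration-response
# q(c) = 1 / (1 + (c/ec50)^beta); q(0) = 1 by continuity
loglogistic_unaffected <- function(dose, ec50, beta) {
  q <- rep(1, length(dose))
  pos <- dose > 0
  q[pos] <- 1 / (1 + (dose[pos] / ec50)^beta)
  q
}

stop_epfmix <- function(msg, class, data = NULL) {
  cond <- structure(
    class = c(class, "epfmix_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

# numeric covariance from an optim hessian, with a pseudo-inverse fallback
# for near-singular information matrices
solve_cov <- function(hess) {
  cov <- try(solve(hess), silent = TRUE)
  if (inherits(cov, "try-error") || any(!is.finite(cov))) {
    sv <- svd(hess)
    pos <- sv$d > max(sv$d) * 1e-10
    cov <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  cov
}
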