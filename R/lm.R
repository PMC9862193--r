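# Small dense Levenberg-Marquardt least-squares solver with box bounds via
# projection. No external optimizer dependency is available offline, and the
# estimation problems here are low-dimensional (<= ~12 free constants), so a
# plain LM with finite-difference Jacobians is adequate.

#' Levenberg-Marquardt nonlinear least squares (box-constrained)
#'
#' Minimizes `sum(fn(x)^2)` over `lower <= x <= upper`. The Jacobian is
#' forward-difference; iterates are projected onto the box. Intended for the
#' log10-parameter estimation problems of this package.
#'
#' @param fn function returning the residual vector
#' @param x0 start point
#' @param lower,upper bounds (finite)
#' @param max_iter iteration budget
#' @param ftol relative cost-decrease tolerance
#' @param diag_step finite-difference step
#' @return list with `par`, `cost`, `residuals`, `converged`, `iterations`,
#'   `n_eval`
#' @export
lm_least_squares <- function(fn, x0, lower = rep(-Inf, length(x0)),
                             upper = rep(Inf, length(x0)), max_iter = 50,
                             ftol = 1e-8, diag_step = 1e-3) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  x <- clamp(x0)
  n_eval <- 0L
  eval_fn <- function(x) { n_eval <<- n_eval + 1L; fn(x) }
  r <- eval_fn(x)
  cost <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- matrix(0, length(r), length(x))
    for (j in seq_along(x)) {
      dx <- diag_step * max(abs(x[j]), 1)
      # difference inward at the upper bound so the probe stays feasible
      if (x[j] + dx > upper[j]) dx <- -dx
      xp <- x; xp[j] <- xp[j] + dx
      J[, j] <- (eval_fn(xp) - r) / dx
    }
    g <- crossprod(J, r)
    A <- crossprod(J)
    improved <- FALSE
    for (tries in 1:12) {
      M <- A + lambda * diag(diag(A) + 1e-12, length(x))
      step <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(step)) {
        xn <- clamp(x + as.numeric(step))
        rn <- eval_fn(xn)
        cn <- sum(rn^2)
        if (is.finite(cn) && cn < cost) {
          if (cost - cn < ftol * (cost + 1e-30)) converged <- TRUE
          x <- xn; r <- rn; cost <- cn
          lambda <- max(lambda / 4, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 8
    }
    if (!improved) { converged <- max(abs(g)) < 1e-6; break }
    if (converged) break
  }
  list(par = x, cost = cost, residuals = r, converged = converged,
       iterations = it, n_eval = n_eval)
}
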