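# Shared ML engine for the two-timepoint variance-decomposition models.
#
# All models in this package (single-group constrained, multigroup with any
# across-group equality pattern) minimise the same pooled discrepancy
#   sum_g w_g [ log|Sigma_g| + tr(S_g Sigma_g^-1) - log|S_g| - 2 ],
# w_g = n_g - 1, where Sigma_g = [[b+e, b], [b, b+e]] is built from the
# parameter vector through per-group index maps (b_idx, e_idx). A quasi-Newton
# start is polished with full Newton steps using the analytic gradient and
# Hessian, so stationary points are located to machine precision (the
# acceptance contract for agreement with closed forms is 1e-8).

iced_objective <- function(theta, s11, s22, s12, w, b_idx, e_idx) {
  f <- 0
  for (g in seq_along(w)) {
    b <- theta[b_idx[g]]; e <- theta[e_idx[g]]
    fg <- fml_discrepancy(s11[g], s22[g], s12[g], b + e, b + e, b)
    if (!is.finite(fg)) return(Inf)
    f <- f + w[g] * fg
  }
  f
}

iced_grad_hess <- function(theta, s11, s22, s12, w, b_idx, e_idx) {
  P <- length(theta)
  grad <- numeric(P)
  H <- matrix(0, P, P)
  J <- matrix(1, 2, 2); I2 <- diag(2)
  for (g in seq_along(w)) {
    b <- theta[b_idx[g]]; e <- theta[e_idx[g]]
    det_m <- (b + e)^2 - b^2
    if (det_m <= 0 || b + e <= 0) return(NULL)
    inv <- matrix(c(b + e, -b, -b, b + e), 2, 2) / det_m
    Sg <- matrix(c(s11[g], s12[g], s12[g], s22[g]), 2, 2)
    A <- inv %*% Sg %*% inv
    core <- inv - A
    gb <- sum(core)                 # tr(core %*% J)
    ge <- core[1, 1] + core[2, 2]   # tr(core %*% I)
    bi <- b_idx[g]; ei <- e_idx[g]
    grad[bi] <- grad[bi] + w[g] * gb
    grad[ei] <- grad[ei] + w[g] * ge
    h <- function(Di, Dj) {
      sum(diag(-inv %*% Dj %*% inv %*% Di +
                 inv %*% Dj %*% A %*% Di +
                 A %*% Dj %*% inv %*% Di))
    }
    hbb <- h(J, J); hbe <- h(J, I2); hee <- h(I2, I2)
    H[bi, bi] <- H[bi, bi] + w[g] * hbb
    H[bi, ei] <- H[bi, ei] + w[g] * hbe
    H[ei, bi] <- H[ei, bi] + w[g] * hbe
    H[ei, ei] <- H[ei, ei] + w[g] * hee
  }
  list(grad = grad, hess = H)
}

# Minimise the pooled discrepancy. `starts` is a list of candidate starting
# vectors; the best quasi-Newton solution is polished with damped Newton steps
# until the step is negligible. Returns list(theta, value, converged).
solve_iced_ml <- function(s11, s22, s12, w, b_idx, e_idx, starts,
                          lower = NULL) {
  obj <- function(p) iced_objective(p, s11, s22, s12, w, b_idx, e_idx)
  gr <- function(p) {
    gh <- iced_grad_hess(p, s11, s22, s12, w, b_idx, e_idx)
    if (is.null(gh)) rep(0, length(p)) else gh$grad
  }
  best <- NULL
  for (st in starts) {
    o <- if (is.null(lower)) {
      stats::optim(st, obj, gr = gr, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14))
    } else {
      stats::optim(pmax(st, lower + 1e-10), obj, gr = gr, method = "L-BFGS-B",
                   lower = lower, control = list(maxit = 1000, factr = 10))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- best$par
  f0 <- best$value
  if (!is.finite(f0)) {
    return(list(theta = theta, value = f0, converged = FALSE))
  }
  at_boundary <- !is.null(lower) && any(theta <= lower + 1e-9)
  if (!at_boundary) {
    scale <- max(abs(theta), 1e-12)
    for (it in seq_len(60)) {
      gh <- iced_grad_hess(theta, s11, s22, s12, w, b_idx, e_idx)
      if (is.null(gh)) break
      step <- tryCatch(solve(gh$hess, gh$grad), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) break
      t <- 1
      improved <- FALSE
      while (t >= 1e-10) {
        cand <- theta - t * step
        fc <- obj(cand)
        if (is.finite(fc) && fc <= f0 + 1e-13 * (1 + abs(f0))) {
          theta <- cand; f0 <- fc; improved <- TRUE
          break
        }
        t <- t / 2
      }
      if (!improved) break
      if (max(abs(t * step)) < 1e-12 * scale) break
    }
  }
  list(theta = theta, value = f0,
       converged = is.finite(f0) && best$convergence == 0)
}
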