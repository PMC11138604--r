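# Pure-R reference implementation of the cross-validated ratio fit, built
# from the exported primitive operations. Used to cross-check the compiled
# fitting path on small problems.
ref_cv_fit <- function(yp, yq, centers, alpha, sigmas, lambdas, n_folds, seed) {
  np <- nrow(yp); nq <- nrow(yq)
  nf <- min(n_folds, np, nq)
  fold_p <- plsbd:::assign_folds(np, nf, plsbd:::derive_seed(seed, 1L))
  fold_q <- plsbd:::assign_folds(nq, nf, plsbd:::derive_seed(seed, 2L))
  cv <- matrix(NA_real_, length(sigmas), length(lambdas))
  best <- list(J = Inf, si = 1L, li = 1L)
  for (si in seq_along(sigmas)) {
    for (li in seq_along(lambdas)) {
      Js <- numeric(0)
      for (f in seq_len(nf)) {
        Kp_tr <- kernel_matrix(yp[fold_p != f, , drop = FALSE], centers, sigmas[si])
        Kq_tr <- kernel_matrix(yq[fold_q != f, , drop = FALSE], centers, sigmas[si])
        th <- solve_theta(build_H_hat(Kp_tr, Kq_tr, alpha), build_h_hat(Kp_tr),
                          lambdas[li])
        Kp_va <- kernel_matrix(yp[fold_p == f, , drop = FALSE], centers, sigmas[si])
        Kq_va <- kernel_matrix(yq[fold_q == f, , drop = FALSE], centers, sigmas[si])
        Js <- c(Js, cv_objective(th, build_H_hat(Kp_va, Kq_va, alpha),
                                 build_h_hat(Kp_va)))
      }
      cv[si, li] <- mean(Js)
      if (cv[si, li] < best$J) best <- list(J = cv[si, li], si = si, li = li)
    }
  }
  sigma <- sigmas[best$si]; lambda <- lambdas[best$li]
  Kp <- kernel_matrix(yp, centers, sigma)
  Kq <- kernel_matrix(yq, centers, sigma)
  theta <- solve_theta(build_H_hat(Kp, Kq, alpha), build_h_hat(Kp), lambda)
  list(sigma = sigma, lambda = lambda, theta = theta,
       rp = drop(Kp %*% theta), rq = drop(Kq %*% theta), cv = cv)
}

# Random ratio-value draws for algebraic identity checks.
random_ratios <- function(n_cases, seed = 42L) {
  plsbd:::with_seed(seed, {
    lapply(seq_len(n_cases), function(i) {
      list(rp = rnorm(sample(1:20, 1), mean = 1, sd = 2),
           rq = rnorm(sample(1:20, 1), mean = 1, sd = 2),
           alpha = runif(1, 0, 0.95))
    })
  })
}
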