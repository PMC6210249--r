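# Maximum-likelihood covariance-structure estimation.
#
# The discrepancy minimized is
#   F(theta) = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p ,
# the normal-theory ML fit function; chi-square = (N-1) F. Estimation runs
# on the correlation scale (the sample covariance is rescaled to unit
# variances, which keeps the optimization well conditioned when indicators
# mix fractions and meters) and estimates are mapped back to the input
# scale afterwards -- ML estimates are equivariant under diagonal scaling,
# so the fit value and all fit indices are unaffected.

# Low-rank representation of dSigma/dtheta_k = a b' + b a' for every free
# parameter; gradient and expected information then reduce to inner
# products.
sem_deriv_pairs <- function(mod, mm, C, Phi) {
  p <- length(mod$obs)
  pt <- mod$param_table
  q <- nrow(pt)
  LC <- mm$Lambda %*% C      # p x m
  LPhi <- mm$Lambda %*% Phi  # p x m
  A <- matrix(0, p, q); B <- matrix(0, p, q)
  for (k in seq_len(q)) {
    i <- pt$i[k]; j <- pt$j[k]
    switch(pt$matrix[k],
           lambda = { A[i, k] <- 1; B[, k] <- LPhi[, j] },
           b = { A[, k] <- LC[, i]; B[, k] <- LPhi[, j] },
           psi = if (i == j) { A[, k] <- LC[, i]; B[, k] <- LC[, i] / 2 }
                 else { A[, k] <- LC[, i]; B[, k] <- LC[, j] },
           theta = if (i == j) { A[i, k] <- 1; B[i, k] <- 0.5 }
                   else { A[i, k] <- 1; B[j, k] <- 1 })
  }
  list(A = A, B = B)
}

sem_start_values <- function(mod) {
  pt <- mod$param_table
  ifelse(pt$type == "loading", 1.0,
  ifelse(pt$type == "path", 0.1,
  ifelse(pt$type == "latent_variance", 0.4,
  ifelse(pt$type == "latent_covariance", 0.05,
  ifelse(pt$type == "error_variance", 0.5, 0.0)))))
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory discrepancy between the sample covariance
#' and the model-implied covariance by quasi-Newton (BFGS) with analytic
#' gradients, restarting until the gradient norm falls below `grad_tol`.
#' Standard errors come from the inverse expected-information matrix;
#' critical ratios are estimate / SE with two-sided normal p-values.
#'
#' @param S sample covariance matrix with row/column names covering the
#'   model's indicators (order is taken from the model).
#' @param N number of observations behind `S`.
#' @param model a [sem_model()].
#' @param grad_tol convergence tolerance on the max absolute gradient of F.
#' @param max_restarts BFGS restarts before giving up.
#' @return an object of class `sem_fit`: parameter table (`estimates`),
#'   discrepancy `F`, degrees of freedom, implied covariance, standardized
#'   path matrix `B_std` with matching `path_p` p-values, latent
#'   correlation matrix, and convergence diagnostics.
#' @export
ml_fit <- function(S, N, model, grad_tol = 1e-6, max_restarts = 4) {
  obs <- model$obs
  if (is.null(rownames(S)) || !all(obs %in% rownames(S)))
    stop("S must carry dimnames covering the model indicators", call. = FALSE)
  S <- as.matrix(S)[obs, obs]
  p <- length(obs)
  if (N <= p) stop("N must exceed the number of indicators", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S)))
    stop("sample covariance is not symmetric", call. = FALSE)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite", call. = FALSE))

  D <- sqrt(diag(S))
  R <- stats::cov2cor(S)
  ldR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)

  build <- function(th) {
    mm <- sem_matrices(model, th)
    C <- solve(diag(length(model$latents)) - mm$B)
    Phi <- C %*% mm$Psi %*% t(C)
    Sg <- mm$Lambda %*% Phi %*% t(mm$Lambda) + mm$Theta
    list(mm = mm, C = C, Phi = Phi, Sigma = (Sg + t(Sg)) / 2)
  }
  fn <- function(th) {
    bd <- build(th)
    ch <- tryCatch(chol(bd$Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e8 + sum(th^2))
    W <- chol2inv(ch)
    2 * sum(log(diag(ch))) + sum(W * R) - ldR - p
  }
  gr <- function(th) {
    bd <- build(th)
    ev <- eigen(bd$Sigma, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-10)
    W <- ev$vectors %*% (t(ev$vectors) / vals)
    Amat <- W - W %*% R %*% W
    dp <- sem_deriv_pairs(model, bd$mm, bd$C, bd$Phi)
    2 * colSums(dp$A * (Amat %*% dp$B))
  }

  th <- sem_start_values(model)
  conv <- FALSE; gnorm <- Inf
  for (tries in seq_len(max_restarts)) {
    opt <- stats::optim(th, fn, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    th <- opt$par
    gnorm <- max(abs(gr(th)))
    if (gnorm < grad_tol) { conv <- TRUE; break }
  }
  Fval <- fn(th)
  if (Fval > 1e7)
    stop("ML fit did not reach a positive-definite solution", call. = FALSE)

  bd <- build(th)
  ch <- chol(bd$Sigma)
  W <- chol2inv(ch)
  dp <- sem_deriv_pairs(model, bd$mm, bd$C, bd$Phi)
  WA <- W %*% dp$A; WB <- W %*% dp$B
  info <- (N - 1) * ((crossprod(dp$A, WA)) * (crossprod(dp$B, WB)) +
                     (crossprod(dp$A, WB)) * (crossprod(dp$B, WA)))
  acov <- tryCatch(solve(info), error = function(e) {
    warning("expected information is near-singular; SEs use a ridge inverse")
    solve(info + diag(1e-8 * max(diag(info)), nrow(info)))
  })
  se_R <- sqrt(pmax(diag(acov), 0))

  # map estimates from the correlation scale back to the input scale
  pt <- model$param_table
  anchor <- vapply(model$latents, function(l) {
    which(model$obs == model$indicators[[l]][1])
  }, integer(1))
  f <- vapply(seq_len(nrow(pt)), function(k) {
    i <- pt$i[k]; j <- pt$j[k]
    switch(pt$matrix[k],
           lambda = D[i] / D[anchor[j]],
           b = D[anchor[i]] / D[anchor[j]],
           psi = D[anchor[i]] * D[anchor[j]],
           theta = D[i] * D[j])
  }, numeric(1))

  # standardized solution from the correlation-scale fit
  sd_lat <- sqrt(diag(bd$Phi))
  sd_obs <- sqrt(diag(bd$Sigma))
  std <- vapply(seq_len(nrow(pt)), function(k) {
    i <- pt$i[k]; j <- pt$j[k]; v <- th[k]
    switch(pt$matrix[k],
           lambda = v * sd_lat[j] / sd_obs[i],
           b = v * sd_lat[j] / sd_lat[i],
           psi = v / (sd_lat[i] * sd_lat[j]),
           theta = v / (sd_obs[i] * sd_obs[j]))
  }, numeric(1))

  est <- pt
  est$est <- th * f
  est$se <- se_R * f
  est$cr <- ifelse(est$se > 0, est$est / est$se, NA_real_)
  est$p_value <- 2 * stats::pnorm(-abs(est$cr))
  est$std <- std

  m <- length(model$latents)
  B_std <- matrix(0, m, m, dimnames = list(model$latents, model$latents))
  path_p <- matrix(NA_real_, m, m, dimnames = dimnames(B_std))
  sel <- which(pt$matrix == "b")
  for (k in sel) {
    B_std[pt$i[k], pt$j[k]] <- std[k]
    path_p[pt$i[k], pt$j[k]] <- est$p_value[k]
  }

  structure(list(model = model, S = S, N = N, p = p, df = model$df,
                 theta = th, estimates = est, F = Fval,
                 Sigma_hat = diag(D) %*% bd$Sigma %*% diag(D),
                 Sigma_cor = bd$Sigma, R = R,
                 Phi = bd$Phi, sd_lat = sd_lat,
                 B_std = B_std, path_p = path_p,
                 converged = conv, grad_norm = gnorm),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem fit: F = %.5f, chi2 = %.2f, df = %d, N = %d (%s)\n",
              x$F, (x$N - 1) * x$F, x$df, x$N,
              if (x$converged) "converged" else "NOT converged"))
  paths <- x$estimates[x$estimates$type == "path", ]
  if (nrow(paths) > 0) {
    cat("structural paths (standardized):\n")
    for (k in seq_len(nrow(paths)))
      cat(sprintf("  %-10s %6.3f  (C.R. %6.2f, p %.4g)\n",
                  paths$label[k], paths$std[k], paths$cr[k], paths$p_value[k]))
  }
  invisible(x)
}

#' Independence (null) model fit
#'
#' Baseline model with a diagonal implied covariance; its ML solution is
#' the sample variances, so F = -ln|R| with df = p(p-1)/2. Used by the
#' incremental fit indices.
#'
#' @param S sample covariance matrix.
#' @param N observation count.
#' @return list with `F`, `df`, `N`, `p`.
#' @export
null_fit <- function(S, N) {
  R <- stats::cov2cor(as.matrix(S))
  p <- nrow(R)
  list(F = -as.numeric(determinant(R, logarithm = TRUE)$modulus),
       df = p * (p - 1) / 2, N = N, p = p)
}

#' Goodness-of-fit indices
#'
#' The index battery of covariance-structure software: CMIN (the ML
#' chi-square (N-1)F) and CMIN/DF, GFI and AGFI, RMR, RMSEA, and the
#' incremental/parsimony set NFI, PNFI, CFI, PCFI computed against the
#' independence model. RMR is computed on the correlation metric so that
#' it — like every other index here — is invariant to indicator rescaling.
#'
#' @param fit a `sem_fit`.
#' @param null optional [null_fit()] on the same data; computed when `NULL`.
#' @return named list of indices (plus `chisq`, `df`, `chisq_null`,
#'   `df_null`, `NFI`, `CFI`).
#' @export
fit_indices <- function(fit, null = NULL) {
  if (fit$df < 0) stop("fit indices need nonnegative degrees of freedom", call. = FALSE)
  if (is.null(null)) null <- null_fit(fit$S, fit$N)
  N <- fit$N; p <- fit$p; df <- fit$df
  chisq <- (N - 1) * fit$F
  chisq0 <- (null$N - 1) * null$F
  df0 <- null$df

  W <- solve(fit$Sigma_cor)
  M <- W %*% fit$R
  gfi <- 1 - sum(diag((M - diag(p)) %*% (M - diag(p)))) / sum(diag(M %*% M))
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  res <- fit$R - fit$Sigma_cor
  rmr <- sqrt(2 * sum(res[upper.tri(res, diag = TRUE)]^2) / (p * (p + 1)))
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (N - 1))) else 0
  nfi <- if (chisq0 > 0) (chisq0 - chisq) / chisq0 else NA_real_
  pnfi <- (df / df0) * nfi
  d <- max(chisq - df, 0); d0 <- max(chisq0 - df0, chisq - df, 0)
  cfi <- if (d0 > 0) 1 - d / d0 else 1
  pcfi <- (df / df0) * cfi

  list(CMIN = chisq, DF = df,
       CMIN_DF = if (df > 0) chisq / df else NA_real_,
       GFI = gfi, RMR = rmr, RMSEA = rmsea, AGFI = agfi,
       NFI = nfi, PNFI = pnfi, CFI = cfi, PCFI = pcfi,
       chisq_null = chisq0, df_null = df0)
}
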