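# Independent oracles, written from the model definition directly (not via the
# package's internals), for auditing the REML optimizer and small formulas.

# Restricted log-likelihood of the intercept-only bivariate model at fixed
# variance components, evaluated naively with solve()/determinant() on full
# 2x2 matrices. Used for spot checks only (slow).
oracle_reml_loglik_naive <- function(tr, tau1, tau2, rho) {
  Sigma <- matrix(c(tau1^2, rho * tau1 * tau2, rho * tau1 * tau2, tau2^2), 2, 2)
  k <- nrow(tr)
  Ws <- vector("list", k)
  A <- matrix(0, 2, 2); b <- c(0, 0); sld <- 0
  for (i in seq_len(k)) {
    V <- Sigma + diag(c(tr$v1[i], tr$v2[i]))
    Ws[[i]] <- solve(V)
    sld <- sld + determinant(V, logarithm = TRUE)$modulus
    A <- A + Ws[[i]]
    b <- b + Ws[[i]] %*% c(tr$y1[i], tr$y2[i])
  }
  beta <- solve(A, b)
  quad <- 0
  for (i in seq_len(k)) {
    r <- c(tr$y1[i], tr$y2[i]) - beta
    quad <- quad + t(r) %*% Ws[[i]] %*% r
  }
  ldA <- determinant(A, logarithm = TRUE)$modulus
  as.numeric(-0.5 * ((2 * k - 2) * log(2 * pi) + sld + ldA + quad))
}

# Exhaustive grid search over (tau1, tau2, rho). Vectorized over the
# (tau2, rho) plane with closed-form 2x2 algebra, looping tau1 and studies;
# independent of the package's optimizer and evaluator code.
oracle_reml_grid <- function(tr, tau1s, tau2s, rhos) {
  y1 <- tr$y1; y2 <- tr$y2; v1 <- tr$v1; v2 <- tr$v2
  k <- length(y1)
  g <- expand.grid(tau2 = tau2s, rho = rhos)
  s22 <- g$tau2^2
  best <- -Inf; best_par <- c(NA, NA, NA)
  for (t1 in tau1s) {
    s11 <- t1^2
    s12 <- g$rho * t1 * g$tau2
    A11 <- A12 <- A22 <- b1 <- b2 <- sld <- 0
    w11s <- w12s <- w22s <- vector("list", k)
    ok <- TRUE
    for (i in seq_len(k)) {
      a <- s11 + v1[i]; d <- s22 + v2[i]
      det_i <- a * d - s12^2
      det_i[det_i <= 0] <- NA
      w11 <- d / det_i; w22 <- a / det_i; w12 <- -s12 / det_i
      w11s[[i]] <- w11; w12s[[i]] <- w12; w22s[[i]] <- w22
      sld <- sld + log(det_i)
      A11 <- A11 + w11; A12 <- A12 + w12; A22 <- A22 + w22
      b1 <- b1 + w11 * y1[i] + w12 * y2[i]
      b2 <- b2 + w12 * y1[i] + w22 * y2[i]
    }
    detA <- A11 * A22 - A12^2
    beta1 <- (A22 * b1 - A12 * b2) / detA
    beta2 <- (A11 * b2 - A12 * b1) / detA
    quad <- 0
    for (i in seq_len(k)) {
      r1 <- y1[i] - beta1; r2 <- y2[i] - beta2
      quad <- quad + w11s[[i]] * r1^2 + 2 * w12s[[i]] * r1 * r2 + w22s[[i]] * r2^2
    }
    ll <- -0.5 * ((2 * k - 2) * log(2 * pi) + sld + log(detA) + quad)
    m <- suppressWarnings(max(ll, na.rm = TRUE))
    if (is.finite(m) && m > best) {
      j <- which.max(ll)
      best <- m
      best_par <- c(t1, g$tau2[j], g$rho[j])
    }
  }
  list(loglik = best, par = best_par)
}
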