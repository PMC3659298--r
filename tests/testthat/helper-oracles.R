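# brute-force dense-matrix oracles for the mixed-model engine

dense_gls <- function(y, X, subject, var_u, var_e) {
  Z <- outer(subject, unique(subject), "==") * 1
  V <- var_u * tcrossprod(Z) + var_e * diag(length(y))
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
}

dense_ml_loglik <- function(y, X, subject, gamma) {
  K <- length(y)
  Z <- outer(subject, unique(subject), "==") * 1
  Vt <- gamma * tcrossprod(Z) + diag(K)
  Vi <- solve(Vt)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q <- drop(t(r) %*% Vi %*% r)
  s2 <- q / K
  -0.5 * (K * log(2 * pi) + K * log(s2) + determinant(Vt)$modulus[1] + K)
}

rand_instance <- function(seed) {
  set.seed(seed)
  n <- sample(5:10, 1)
  k <- sample(1:5, n, replace = TRUE)
  if (sum(k) < 8) k <- k + 1
  subject <- rep(seq_len(n), k)
  K <- length(subject)
  p <- sample(2:4, 1)
  X <- cbind(1, matrix(rnorm(K * (p - 1)), K))
  colnames(X) <- paste0("b", seq_len(p))
  u <- rnorm(n, 0, runif(1, 0.5, 2))
  y <- drop(X %*% runif(p, -2, 2)) + u[subject] + rnorm(K)
  list(y = y, X = X, subject = subject)
}
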