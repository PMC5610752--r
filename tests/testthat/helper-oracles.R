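# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (closed forms, SMO) wherever they check one.

# leave-one-out PRESS by explicit one-at-a-time OLS refits via stats::lm
loo_press_oracle <- function(x, y) {
  n <- nrow(x)
  press <- 0
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], x[-i, , drop = FALSE], check.names = FALSE)
    fit <- stats::lm(y ~ ., data = df)
    nd <- data.frame(x[i, , drop = FALSE], check.names = FALSE)
    press <- press + (y[i] - stats::predict(fit, nd))^2
  }
  unname(press)
}

# eps-SVR dual solved by accelerated projected gradient on the full
# 2n-variable QP: min 1/2 z'Qz + p'z, s'z = 0, 0 <= z <= C. The projection
# onto the box/hyperplane intersection is found by bisection on the
# hyperplane multiplier. Returns the prediction function values on `xq`.
svr_qp_oracle <- function(x_scaled, y_scaled, C, epsilon, gamma,
                          xq_scaled = x_scaled, iters = 6000) {
  n <- length(y_scaled)
  d2 <- as.matrix(stats::dist(x_scaled))^2
  K <- exp(-gamma * d2)
  Q <- rbind(cbind(K, -K), cbind(-K, K))
  p <- c(epsilon - y_scaled, epsilon + y_scaled)
  s <- rep(c(1, -1), each = n)
  proj <- function(v) {
    lo <- -(max(abs(v)) + C + 1); hi <- -lo
    for (b in 1:60) {
      mid <- (lo + hi) / 2
      if (sum(pmin(pmax(v - mid * s, 0), C) * s) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(v - ((lo + hi) / 2) * s, 0), C)
  }
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  z <- zp <- rep(0, 2 * n)
  for (t in seq_len(iters)) {           # Nesterov-accelerated PGD
    w <- z + (t - 1) / (t + 2) * (z - zp)
    zp <- z
    z <- proj(w - (drop(Q %*% w) + p) / L)
  }
  beta <- z[seq_len(n)] - z[n + seq_len(n)]
  # bias from KKT at free dual variables
  f0 <- drop(K %*% beta)
  tol <- C * 1e-5
  free_a <- which(z[seq_len(n)] > tol & z[seq_len(n)] < C - tol)
  free_as <- which(z[n + seq_len(n)] > tol & z[n + seq_len(n)] < C - tol)
  bs <- c(y_scaled[free_a] - f0[free_a] - epsilon,
          y_scaled[free_as] - f0[free_as] + epsilon)
  b <- if (length(bs)) mean(bs) else {
    up <- c(y_scaled - f0 - epsilon, y_scaled - f0 + epsilon)
    mean(range(up))
  }
  Kq <- exp(-gamma * (outer(rowSums(xq_scaled^2), rowSums(x_scaled^2), "+") -
                        2 * tcrossprod(xq_scaled, x_scaled)))
  drop(Kq %*% beta) + b
}

# best fixed-size subset by exhaustive enumeration of all combinations,
# scored with the package's LOO-Q2 fitness (the oracle checks the search)
exhaustive_best_subset <- function(data, k) {
  combos <- utils::combn(ncol(data$x), k)
  scores <- apply(combos, 2, function(cols)
    q2_loo(data, colnames(data$x)[cols])$q2)
  best <- which.max(scores)
  list(subset = sort(colnames(data$x)[combos[, best]]),
       fitness = scores[best])
}
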