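# Independent brute-force oracles, written from the textbook definitions.

# Kaplan-Meier product-limit, single group, by explicit product.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Two-group log-rank chi-square from the observed/expected table.
logrank_oracle <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t0 in ut) {
    n <- sum(time >= t0)
    n1 <- sum(time >= t0 & group == g[1])
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up from its definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  so <- p[o] * n / seq_len(n)
  qo <- rev(cummin(rev(so)))
  q <- numeric(n)
  q[o] <- pmin(qo, 1)
  q
}

# TMM factors recomputed step by step from the definition.
tmm_oracle <- function(counts, ltrim = 0.3, atrim = 0.05) {
  lib <- colSums(counts)
  ref <- which.min(abs(log(lib) - mean(log(lib))))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    keep <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[keep, j]; r <- counts[keep, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    n <- length(M)
    loM <- floor(n * ltrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * atrim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f / exp(mean(log(f)))
}

# Cox partial likelihood maximized by Newton-Raphson (distinct event times,
# so Efron and Breslow coincide with the exact partial likelihood).
cox_oracle <- function(time, event, X, max_iter = 100) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    grad <- rep(0, ncol(X))
    hess <- matrix(0, ncol(X), ncol(X))
    for (i in which(event == 1)) {
      R <- which(time >= time[i])
      w <- as.vector(exp(X[R, , drop = FALSE] %*% beta))
      xbar <- colSums(X[R, , drop = FALSE] * w) / sum(w)
      grad <- grad + X[i, ] - xbar
      xx <- t(X[R, , drop = FALSE]) %*% (X[R, , drop = FALSE] * w) / sum(w)
      hess <- hess + xx - outer(xbar, xbar)
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# AUC as the Mann-Whitney U statistic over positive/negative score pairs.
auc_u_oracle <- function(scores, labels) {
  np <- sum(labels); nn <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# Pearson correlation from the raw sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
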