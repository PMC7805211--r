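# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# fixed-effect beta regression by direct likelihood maximisation (BFGS on
# the dbeta log-likelihood) -- oracle for the GLMM's sigma -> 0 limit
oracle_betareg <- function(y, X) {
  n <- length(y)
  if (any(y == 0 | y == 1)) y <- (y * (n - 1) + 0.5) / n
  # optimise on a unit-scaled design (conditioning only; the likelihood
  # is reparameterisation-invariant) and map coefficients back
  sc <- apply(X, 2, function(cl) if (sd(cl) > 0) sd(cl) else 1)
  Xs <- sweep(X, 2, sc, "/")
  nll <- function(par) {
    b <- par[seq_len(ncol(X))]
    phi <- exp(par[ncol(X) + 1])
    mu <- plogis(as.vector(Xs %*% b))
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(qr.solve(Xs, qlogis(pmin(pmax(y, 0.01), 0.99))), log(10))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  list(coef = opt$par[seq_len(ncol(X))] / sc,
       phi = exp(opt$par[ncol(X) + 1]), loglik = -opt$value)
}

# brute-force BH: scan all ranks for each element
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_of <- integer(m)
  rank_of[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / rank_of[j] else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# O(n^2) pair-enumeration Kendall tau-b
oracle_kendall <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1
    if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# one-sided Fisher (central hypergeometric upper tail)
oracle_fisher_upper <- function(x, m1, m2, n) {
  phyper(x - 1, m1, m2, n, lower.tail = FALSE)
}

# interval Jaccard on bp spans
jaccard_interval <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  if (inter == 0) return(0)
  inter / (max(a2, b2) - min(a1, b1))
}
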