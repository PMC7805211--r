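#' Benjamini-Hochberg adjusted p-values
#'
#' `q_i = min_{j: p_j >= p_i} m * p_j / rank_j`, capped at 1. `NA`
#' entries (skipped fits) are excluded from the ranking and reinserted as
#' `NA`; output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @return numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_param("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  ord <- ok[order(p[ok])]          # stable: ties keep input order
  qs <- pmin(1, m * p[ord] / seq_len(m))
  qs <- rev(cummin(rev(qs)))
  q[ord] <- qs
  q
}

#' Kendall rank correlation with tie correction (tau-b)
#'
#' `tau = (concordant - discordant) / sqrt((n0 - n1)(n0 - n2))` with the
#' usual tie terms. The p-value is two-sided: exact by full permutation
#' enumeration when `n <= 8` and there are no ties, otherwise from the
#' normal approximation with tie-corrected variance.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return list with `tau`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_param("x and y lengths differ")
  if (n < 3) stop_param("need at least 3 observations")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; n <- length(x)
  if (n < 3) stop_param("need at least 3 complete observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop_param("tau undefined: an input vector is constant")

  stat <- function(x, y) {
    C <- D <- 0
    for (i in seq_len(n - 1)) {
      dx <- x[(i + 1):n] - x[i]
      dy <- y[(i + 1):n] - y[i]
      s <- sign(dx) * sign(dy)
      C <- C + sum(s > 0)
      D <- D + sum(s < 0)
    }
    c(C = C, D = D)
  }
  s <- stat(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- (s["C"] - s["D"]) / sqrt((n0 - n1) * (n0 - n2))
  ties <- n1 > 0 || n2 > 0

  if (n <= 8 && !ties) {
    # exact null distribution of C - D over all n! orderings of y
    perms <- all_perms(n)
    obs <- abs(s["C"] - s["D"])
    cnt <- 0L
    for (k in seq_len(nrow(perms))) {
      sp <- stat(x, y[perms[k, ]])
      if (abs(sp["C"] - sp["D"]) >= obs - 1e-9) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact"
  } else {
    # tie-corrected normal approximation for S = C - D
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- (s["C"] - s["D"]) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(tau = unname(tau), p = unname(min(1, p)), method = method)
}

# all permutations of 1..n as a matrix (n <= 8 only; 8! = 40320 rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Normality-gated correlation
#'
#' Assesses each vector with a Shapiro-Wilk test; if both pass at
#' `p > alpha` the Pearson product-moment correlation is used, otherwise
#' Spearman's rank correlation. The method actually used is reported.
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @param method `"auto"` (the gate), `"pearson"` or `"spearman"`.
#' @param alpha Shapiro-Wilk gate level, default 0.05.
#' @return list with `coefficient`, `p` and `method`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_param("x and y lengths differ")
  if (length(x) < 4) stop_param("need at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop_param("correlation undefined: an input vector is constant")
  if (method == "auto") {
    sw <- min(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
    method <- if (sw > alpha) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p = ct$p.value, method = method)
}
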