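#' Fit a beta-regression mixed model to one probe
#'
#' Maximum-likelihood beta regression on the natural-logit scale with up
#' to two Gaussian random-intercept factors, the random-effect integral
#' handled by a Laplace approximation (inner Newton mode search, outer
#' quasi-Newton over fixed effects, log random-effect SDs and log
#' precision phi). This is the per-probe model used for group contrasts
#' (random intercepts for slide and for patient nested within slide) and
#' for tumour-size association (patient intercept only).
#'
#' @param y numeric response vector of methylation fractions; boundary
#'   values are squeezed with [squeeze_beta()] before fitting; `NA`
#'   entries are dropped together with their design rows.
#' @param X fixed-effect design matrix (including intercept), one row per
#'   element of `y`.
#' @param random named list of factors (one per random intercept), each
#'   the same length as `y`; e.g. `list(slide = ..., patient = ...)`.
#' @param tol gradient/parameter tolerance of the outer optimiser.
#' @param max_iter outer iteration cap; exceeding it flags
#'   non-convergence (a recorded state, never an exception).
#' @return object of class `probe_fit`: coefficients, `se`, `loglik`,
#'   `sigma` (random-intercept SDs), `phi`, `converged`, `skipped`,
#'   `n_used`, `ranef`.
#' @export
fit_probe_glmm <- function(y, X, random = list(), tol = 1e-8,
                           max_iter = 200) {
  X <- as.matrix(X)
  keep <- is.finite(y) & complete.cases(X)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  random <- lapply(random, function(f) factor(f[keep]))
  n <- length(y)
  p <- ncol(X)
  n_par <- p + length(random) + 1
  skip <- function(reason) {
    structure(list(coefficients = setNames(rep(NA_real_, p), colnames(X)),
                   se = rep(NA_real_, p), loglik = NA_real_,
                   sigma = rep(NA_real_, length(random)), phi = NA_real_,
                   converged = FALSE, skipped = TRUE, reason = reason,
                   n_used = n, ranef = NULL),
              class = "probe_fit")
  }
  if (any(y < 0 | y > 1)) stop_param("y values must lie in [0, 1]")
  if (n < n_par + 2) return(skip("too few observations"))
  if (qr(X)$rank < p) return(skip("singular design"))
  if (any(y == 0 | y == 1)) y <- squeeze_beta(y, n)

  # standardize non-constant design columns (conditioning); the fit is
  # mapped back to the original scale below, so estimates are unchanged
  cmean <- colMeans(X)
  csd <- apply(X, 2, sd)
  const_col <- csd == 0
  int_idx <- which(const_col)[1]
  std <- !const_col
  Xs <- X
  if (any(std)) {
    ctr <- if (!is.na(int_idx)) cmean else setNames(rep(0, p), colnames(X))
    Xs[, std] <- sweep(sweep(X[, std, drop = FALSE], 2, ctr[std]), 2,
                       csd[std], "/")
  }
  Tm <- diag(p)
  diag(Tm)[std] <- 1 / csd[std]
  if (!is.na(int_idx) && any(std))
    Tm[int_idx, std] <- -cmean[std] / csd[std]

  g1 <- if (length(random) >= 1) as.integer(random[[1]]) - 1L else integer(0)
  g2 <- if (length(random) >= 2) as.integer(random[[2]]) - 1L else integer(0)
  n1 <- if (length(random) >= 1) nlevels(random[[1]]) else 0L
  n2 <- if (length(random) >= 2) nlevels(random[[2]]) else 0L
  if (length(random) > 2)
    stop_param("at most two random-intercept factors are supported")
  handle <- .glmm_make(y, Xs, g1, g2, n1, n2)

  # starting values: logit-scale least squares, moment estimate of phi
  eta0 <- qlogis(pmin(pmax(y, 0.01), 0.99))
  beta0 <- qr.solve(Xs, eta0)
  mu0 <- plogis(as.vector(Xs %*% beta0))
  rvar <- max(mean((y - mu0)^2), 1e-6)
  phi0 <- min(max(mean(mu0 * (1 - mu0)) / rvar - 1, 2), 500)
  start <- c(beta0, rep(log(0.1), length(random)), log(phi0))
  lower <- c(rep(-20, p), rep(-6, length(random)), log(0.5))
  upper <- c(rep(20, p), rep(2, length(random)), log(5e4))

  obj <- function(par) .glmm_nll(handle, par)
  gr <- function(par) as.numeric(.glmm_grad(handle, par))
  run_opt <- function(par0) tryCatch(
    nlminb(par0, obj, gradient = gr, lower = lower, upper = upper,
           control = list(iter.max = max_iter, eval.max = 4 * max_iter,
                          rel.tol = tol)),
    error = function(e) NULL)
  # certification: KKT check on the analytic gradient (a coordinate at an
  # active box bound may point outward)
  grad_ok <- function(o) {
    g <- gr(o$par)
    at_lo <- o$par <= lower + 1e-8
    at_hi <- o$par >= upper - 1e-8
    g[at_lo & g > 0] <- 0
    g[at_hi & g < 0] <- 0
    all(is.finite(g)) && max(abs(g)) < 1e-2
  }
  opt <- run_opt(start)
  certified <- !is.null(opt) && (opt$convergence == 0 || grad_ok(opt))
  if (!is.null(opt) && !certified) {           # one warm restart
    opt2 <- run_opt(opt$par)
    if (!is.null(opt2) && opt2$objective <= opt$objective) opt <- opt2
    certified <- opt$convergence == 0 || grad_ok(opt)
  }
  if (is.null(opt) || !is.finite(opt$objective) || opt$objective >= 1e10)
    return(skip("optimizer failure"))
  par <- opt$par
  cov <- tryCatch(.glmm_beta_cov(handle, par), error = function(e) NULL)
  coefs <- as.vector(Tm %*% par[seq_len(p)])
  se <- if (is.null(cov)) rep(NA_real_, p) else
    sqrt(pmax(diag(Tm %*% cov %*% t(Tm)), 0))
  structure(list(
    coefficients = setNames(coefs, colnames(X)),
    se = setNames(se, colnames(X)),
    loglik = -opt$objective,
    sigma = exp(par[p + seq_along(random)]),
    phi = exp(par[p + length(random) + 1]),
    converged = certified && !is.null(cov),
    skipped = FALSE, reason = NULL, n_used = n,
    ranef = .glmm_ranef(handle)), class = "probe_fit")
}

#' @export
print.probe_fit <- function(x, ...) {
  if (x$skipped) {
    cat("<probe_fit> skipped:", x$reason, "\n")
  } else {
    cat(sprintf("<probe_fit> logLik %.3f, phi %.1f, converged %s\n",
                x$loglik, x$phi, x$converged))
    print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested probe fits
#'
#' @param full,reduced `probe_fit` objects; every fixed-effect term of
#'   `reduced` must appear in `full`.
#' @return list with `stat` (twice the log-likelihood difference, clamped
#'   at zero), `df` (difference in fixed-effect parameter counts) and
#'   `p` (upper chi-square tail).
#' @export
lrt_group <- function(full, reduced) {
  stopifnot(inherits(full, "probe_fit"), inherits(reduced, "probe_fit"))
  if (full$skipped || reduced$skipped || !full$converged || !reduced$converged)
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_))
  if (!all(names(reduced$coefficients) %in% names(full$coefficients)))
    stop_param("models are not nested: reduced terms missing from full")
  df <- length(full$coefficients) - length(reduced$coefficients)
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  if (stat == 0) p <- 1
  list(stat = stat, df = df, p = p)
}

#' Per-probe differential methylation between two groups
#'
#' Fits, probe by probe, the hierarchical beta GLMM
#' `logit(mu) = group + covariates + (1 | slide) + (1 | patient)` and the
#' matching no-group reduced model, tests the group term by LRT (df = 1),
#' and applies Benjamini-Hochberg adjustment across probes. Masked
#' (failed) entries are dropped pairwise per probe.
#'
#' @param bm a QC-filtered [beta_matrix()].
#' @param samples sample sheet with columns `sample_id`, `patient_id`,
#'   `slide_id`, `group` and any covariates used.
#' @param contrast length-2 character; samples of other groups are
#'   excluded, and the estimate is the logit effect of the second level
#'   relative to the first.
#' @param covariates covariate column names entering both full and
#'   reduced models (default age and sex).
#' @param random character names of the random-intercept columns, outer
#'   factor first; default slide then patient (nested).
#' @param manifest optional probe manifest; adds `chrom`/`pos` columns.
#' @param verbose print a progress note every 500 probes.
#' @return data frame (one row per probe): `probe_id`, `estimate`
#'   (natural-logit scale), `odds_ratio`, `se`, `wald`, `lrt_stat`, `p`,
#'   `q`, `converged`, `n_used`.
#' @export
dmp_fit <- function(bm, samples, contrast = c("CNF", "PNF"),
                    covariates = c("age", "sex"),
                    random = c("slide_id", "patient_id"),
                    manifest = NULL, verbose = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"))
  missing_g <- setdiff(contrast, unique(samples$group))
  if (length(missing_g) > 0)
    stop_param("contrast group absent from sample sheet: ",
               paste(missing_g, collapse = ", "))
  samples <- samples[match(bm$sample_ids, samples$sample_id), ]
  sel <- samples$group %in% contrast
  samples <- samples[sel, ]
  samples$group <- factor(samples$group, levels = contrast)
  bm <- subset_bm(bm, samples = which(bm$sample_ids %in% samples$sample_id))

  fml <- paste(c("~ group", covariates), collapse = " + ")
  X_full <- stats::model.matrix(stats::as.formula(fml), samples)
  fml_red <- if (length(covariates) > 0)
    paste("~", paste(covariates, collapse = " + ")) else "~ 1"
  X_red <- stats::model.matrix(stats::as.formula(fml_red), samples)
  gcol <- grep("^group", colnames(X_full))[1]
  rf <- lapply(random, function(cn) samples[[cn]])
  names(rf) <- random

  np <- nrow(bm$beta)
  out <- data.frame(probe_id = bm$probe_ids,
                    estimate = NA_real_, odds_ratio = NA_real_,
                    se = NA_real_, wald = NA_real_, lrt_stat = NA_real_,
                    p = NA_real_, q = NA_real_, converged = FALSE,
                    n_used = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    y <- bm$beta[i, ]
    y[bm$mask[i, ]] <- NA
    full <- fit_probe_glmm(y, X_full, rf)
    red <- fit_probe_glmm(y, X_red, rf)
    lrt <- lrt_group(full, red)
    out$n_used[i] <- full$n_used
    out$converged[i] <- isTRUE(full$converged) && isTRUE(red$converged)
    if (!full$skipped) {
      out$estimate[i] <- full$coefficients[gcol]
      out$odds_ratio[i] <- exp(full$coefficients[gcol])
      out$se[i] <- full$se[gcol]
      out$wald[i] <- full$coefficients[gcol] / full$se[gcol]
      out$lrt_stat[i] <- lrt$stat
      out$p[i] <- lrt$p
    }
    if (verbose && i %% 500 == 0)
      message(sprintf("dmp_fit: %d/%d probes", i, np))
  }
  out$p[!out$converged] <- NA
  out$q <- bh_adjust(out$p)
  if (!is.null(manifest)) {
    idx <- match(out$probe_id, manifest$probe_id)
    out$chrom <- manifest$chrom[idx]
    out$pos <- manifest$pos[idx]
  }
  out
}

#' Select significant differentially methylated probes
#'
#' Non-converged fits are dropped first, then probes with `q` strictly
#' below the threshold are returned.
#'
#' @param fits data frame from [dmp_fit()].
#' @param q_threshold FDR cutoff (strict `<`), default 0.05.
#' @return the selected rows of `fits`.
#' @export
select_dmps <- function(fits, q_threshold = 0.05) {
  fits[!is.na(fits$q) & fits$converged & fits$q < q_threshold, ,
       drop = FALSE]
}

#' Select high-effect probes by odds ratio
#'
#' The default symmetric-log rule keeps probes with `odds_ratio >
#' or_threshold` or `< 1 / or_threshold` (hyper- and hypomethylation
#' treated alike); `rule = "raw"` applies the one-sided `>` only.
#'
#' @param fits data frame with an `odds_ratio` column.
#' @param or_threshold threshold, must exceed 1; default 4.
#' @param rule `"symmetric_log"` (default) or `"raw"`.
#' @return the selected rows of `fits`.
#' @export
select_high_effect <- function(fits, or_threshold = 4,
                               rule = c("symmetric_log", "raw")) {
  rule <- match.arg(rule)
  if (!is.numeric(or_threshold) || or_threshold <= 1)
    stop_param("or_threshold must be > 1")
  keep <- if (rule == "symmetric_log")
    abs(log(fits$odds_ratio)) > log(or_threshold)
  else fits$odds_ratio > or_threshold
  fits[!is.na(keep) & keep, , drop = FALSE]
}
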