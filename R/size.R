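#' Per-probe tumour-size association model
#'
#' Beta GLMM with logit link: `logit(mu) = size_mm + age + sex +
#' (1 | patient)`. Size enters linearly in millimetres; the random
#' intercept absorbs partially repeated sampling of the same patient
#' (deliberately patient-only, not slide-nested). Significance of the
#' size term is by LRT against the no-size model.
#'
#' @param y methylation fractions for one probe (CNF samples).
#' @param size_mm tumour sizes in mm, same length.
#' @param age,sex covariates.
#' @param patient patient identifiers (random-intercept factor).
#' @return list with `fit` (`probe_fit`), `estimate` (logit per mm),
#'   `lrt_stat`, `p`, `converged`.
#' @export
fit_size_glmm <- function(y, size_mm, age, sex, patient) {
  if (length(unique(size_mm[is.finite(size_mm)])) < 2) {
    return(list(fit = NULL, estimate = NA_real_, lrt_stat = NA_real_,
                p = NA_real_, converged = FALSE,
                reason = "constant size vector"))
  }
  df <- data.frame(size_mm = size_mm, age = age, sex = factor(sex))
  X_full <- stats::model.matrix(~ size_mm + age + sex, df)
  X_red <- stats::model.matrix(~ age + sex, df)
  rf <- list(patient = patient)
  full <- fit_probe_glmm(y, X_full, rf)
  red <- fit_probe_glmm(y, X_red, rf)
  lrt <- lrt_group(full, red)
  list(fit = full,
       estimate = if (full$skipped) NA_real_ else
         full$coefficients[["size_mm"]],
       lrt_stat = lrt$stat, p = lrt$p,
       converged = isTRUE(full$converged) && isTRUE(red$converged))
}

#' Delta-beta effect filter
#'
#' `delta_beta` is the per-probe range of beta values (maximum minus
#' minimum across samples); probes pass only when it strictly exceeds
#' `min_delta`.
#'
#' @param beta_rows probes x samples matrix of beta values.
#' @param min_delta threshold (strict `>`), default 0.2.
#' @return data frame `probe_id`, `delta_beta`, `pass`.
#' @export
delta_beta_filter <- function(beta_rows, min_delta = 0.2) {
  beta_rows <- as.matrix(beta_rows)
  db <- apply(beta_rows, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) NA_real_ else max(r) - min(r)
  })
  data.frame(probe_id = rownames(beta_rows), delta_beta = db,
             pass = !is.na(db) & db > min_delta,
             stringsAsFactors = FALSE)
}

#' Tumour-size association pipeline for one group
#'
#' Per probe: covariate-adjusted size GLMM with BH-adjusted LRT q; on
#' probes with model q below `q_threshold`, Kendall's tau-b between beta
#' and size with BH-adjusted q; finally the delta-beta filter. Every
#' stage's values are recorded per probe so the composition is
#' auditable; `passes_filter` requires model q < threshold, tau q <
#' threshold and delta-beta strictly above `min_delta`.
#'
#' @param bm QC-filtered [beta_matrix()].
#' @param samples sample sheet (needs `size_mm`, `age`, `sex`,
#'   `patient_id`).
#' @param group group whose samples carry sizes, default `"CNF"`.
#' @param q_threshold FDR cutoff for both model and tau stages.
#' @param min_delta delta-beta cutoff (strict `>`), default 0.2.
#' @param verbose progress notes.
#' @return data frame: `probe_id`, `estimate`, `p_model`, `q_model`,
#'   `tau`, `p_tau`, `q_tau`, `delta_beta`, `passes_filter`.
#' @export
size_association <- function(bm, samples, group = "CNF",
                             q_threshold = 0.05, min_delta = 0.2,
                             verbose = FALSE) {
  samples <- samples[match(bm$sample_ids, samples$sample_id), ]
  sel <- samples$group == group & is.finite(samples$size_mm)
  if (sum(sel) < 6) stop_param("too few sized samples in group ", group)
  ss <- samples[sel, ]
  np <- nrow(bm$beta)
  out <- data.frame(probe_id = bm$probe_ids, estimate = NA_real_,
                    p_model = NA_real_, q_model = NA_real_,
                    tau = NA_real_, p_tau = NA_real_, q_tau = NA_real_,
                    delta_beta = NA_real_, passes_filter = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    y <- bm$beta[i, sel]
    y[bm$mask[i, sel]] <- NA
    fit <- fit_size_glmm(y, ss$size_mm, ss$age, ss$sex, ss$patient_id)
    out$estimate[i] <- fit$estimate
    out$p_model[i] <- if (fit$converged) fit$p else NA_real_
    if (verbose && i %% 500 == 0)
      message(sprintf("size_association: %d/%d probes", i, np))
  }
  out$q_model <- bh_adjust(out$p_model)
  hit <- which(!is.na(out$q_model) & out$q_model < q_threshold)
  for (i in hit) {
    y <- bm$beta[i, sel]
    y[bm$mask[i, sel]] <- NA
    ok <- is.finite(y)
    kt <- tryCatch(kendall_tau(y[ok], ss$size_mm[ok]),
                   error = function(e) NULL)
    if (!is.null(kt)) {
      out$tau[i] <- kt$tau
      out$p_tau[i] <- kt$p
    }
  }
  out$q_tau <- bh_adjust(out$p_tau)
  beta_sel <- bm$beta[, sel, drop = FALSE]
  beta_sel[bm$mask[, sel, drop = FALSE]] <- NA
  db <- delta_beta_filter(beta_sel, min_delta)
  out$delta_beta <- db$delta_beta
  out$passes_filter <- !is.na(out$q_model) & out$q_model < q_threshold &
    !is.na(out$q_tau) & out$q_tau < q_threshold &
    !is.na(out$delta_beta) & out$delta_beta > min_delta
  out
}
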