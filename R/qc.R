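#' Construct a beta-value matrix container
#'
#' Bundles the probes x samples methylation fractions with their detection
#' p-values and a missingness mask. This is the universal input object of
#' the pipeline.
#'
#' @param beta numeric matrix of methylation fractions in `[0, 1]`, probes
#'   in rows (rownames = probe ids), samples in columns (colnames =
#'   sample ids).
#' @param detection_p numeric matrix of per-entry detection p-values, same
#'   shape as `beta`.
#' @param mask optional logical matrix marking entries to treat as
#'   missing; defaults to all `FALSE`.
#' @return an object of class `beta_matrix` with elements `beta`,
#'   `detection_p`, `mask`, `probe_ids`, `sample_ids`.
#' @export
beta_matrix <- function(beta, detection_p, mask = NULL) {
  beta <- as.matrix(beta)
  detection_p <- as.matrix(detection_p)
  if (!all(dim(beta) == dim(detection_p)))
    stop_param("beta and detection_p shapes differ")
  if (is.null(mask)) mask <- matrix(FALSE, nrow(beta), ncol(beta))
  if (!all(dim(mask) == dim(beta)))
    stop_param("mask shape differs from beta")
  if (is.null(rownames(beta)) && nrow(beta) > 0)
    rownames(beta) <- paste0("p", seq_len(nrow(beta)))
  if (is.null(colnames(beta)) && ncol(beta) > 0)
    colnames(beta) <- paste0("s", seq_len(ncol(beta)))
  bad <- !mask & (!is.finite(beta) | beta < 0 | beta > 1)
  if (any(bad)) stop_param("beta values outside [0, 1] at unmasked entries")
  structure(list(beta = beta, detection_p = detection_p,
                 mask = mask, probe_ids = rownames(beta),
                 sample_ids = colnames(beta)),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples (%.2f%% masked)\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

subset_bm <- function(bm, probes = NULL, samples = NULL) {
  pi <- if (is.null(probes)) seq_len(nrow(bm$beta)) else probes
  si <- if (is.null(samples)) seq_len(ncol(bm$beta)) else samples
  beta_matrix(bm$beta[pi, si, drop = FALSE],
              bm$detection_p[pi, si, drop = FALSE],
              bm$mask[pi, si, drop = FALSE])
}

#' Flag failed measurements from detection p-values
#'
#' An entry passes only when its detection p-value is strictly below the
#' threshold; entries at or above it are flagged failed.
#'
#' @param detection_p numeric matrix of detection p-values in `[0, 1]`.
#' @param p_threshold failure threshold, default 0.01.
#' @return logical matrix of the same shape, `TRUE` where failed.
#' @export
mark_failed <- function(detection_p, p_threshold = 0.01) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold >= 1)
    stop_param("p_threshold must lie in (0, 1)")
  m <- as.matrix(detection_p)
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop_param("detection p-values must lie in [0, 1]")
  res <- m >= p_threshold
  res[is.na(res)] <- TRUE
  res
}

#' Drop samples with too many failed probes
#'
#' Removes any sample whose fraction of failed probes strictly exceeds
#' `max_fail_frac`; surviving samples keep their order. Failed entries of
#' retained samples are recorded in the missingness mask.
#'
#' @param bm a [beta_matrix()].
#' @param max_fail_frac maximum tolerated failed-probe fraction per
#'   sample (strict inequality), default 0.10.
#' @param p_threshold detection p-value threshold passed to
#'   [mark_failed()].
#' @return list with the filtered `beta_matrix` and `dropped`, the ids of
#'   removed samples.
#' @export
drop_failed_samples <- function(bm, max_fail_frac = 0.10, p_threshold = 0.01) {
  stopifnot(inherits(bm, "beta_matrix"))
  failed <- mark_failed(bm$detection_p, p_threshold)
  frac <- colMeans(failed)
  keep <- frac <= max_fail_frac
  if (!any(keep)) stop_param("all samples dropped: empty cohort")
  out <- subset_bm(bm, samples = which(keep))
  out$mask <- out$mask | failed[, keep, drop = FALSE]
  list(matrix = out, dropped = bm$sample_ids[!keep])
}

#' Remove blacklisted probes
#'
#' Drops probes carrying the manifest blacklist flag (SNP-overlapping,
#' cross-reactive, CpH and sex-chromosome probes in real manifests).
#'
#' @param bm a [beta_matrix()].
#' @param manifest probe manifest data frame with columns `probe_id` and
#'   `blacklist`.
#' @return the filtered `beta_matrix`.
#' @export
drop_blacklisted <- function(bm, manifest) {
  stopifnot(inherits(bm, "beta_matrix"))
  idx <- match(bm$probe_ids, manifest$probe_id)
  if (anyNA(idx)) {
    miss <- bm$probe_ids[is.na(idx)][1]
    stop_param("probe missing from manifest: ", miss)
  }
  keep <- !as.logical(manifest$blacklist[idx])
  subset_bm(bm, probes = which(keep))
}

#' Convert beta values to M-values and back
#'
#' `beta_to_m` is the base-2 logit `log2(beta / (1 - beta))`; `m_to_beta`
#' is its inverse. Boundary inputs should be squeezed first with
#' [squeeze_beta()].
#'
#' @param beta methylation fractions in the open interval `(0, 1)`.
#' @param m M-values (any real).
#' @return numeric vector/matrix of the transformed values.
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop_param("beta values must lie in [0, 1]")
  if (any(beta == 0 | beta == 1, na.rm = TRUE))
    stop_param("boundary beta values: squeeze first (see squeeze_beta)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  z <- 2^m
  z / (1 + z)
}

#' Run the full QC filter chain
#'
#' Applies, in this fixed order: sample-level failure filtering (drop
#' samples with more than `max_fail_frac` failed probes, mask remaining
#' failed entries) then blacklist probe removal.
#'
#' @inheritParams drop_failed_samples
#' @inheritParams drop_blacklisted
#' @return list with `matrix` (filtered `beta_matrix`), `dropped_samples`,
#'   `n_blacklisted`.
#' @export
qc_filter <- function(bm, manifest, p_threshold = 0.01, max_fail_frac = 0.10) {
  st <- drop_failed_samples(bm, max_fail_frac, p_threshold)
  n_before <- nrow(st$matrix$beta)
  out <- drop_blacklisted(st$matrix, manifest)
  list(matrix = out, dropped_samples = st$dropped,
       n_blacklisted = n_before - nrow(out$beta))
}
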