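#' Gaussian-kernel smoothing of per-probe statistics
#'
#' For each probe `i`, the squared statistics of nearby probes are
#' averaged with Gaussian weights `w_ij = exp(-(pos_i - pos_j)^2 /
#' (2 sigma^2))`, `sigma = lambda / C`. The smoothed value is treated as
#' a weighted mean of chi-square(1) variables, and an effective degrees
#' of freedom per probe is obtained by Satterthwaite moment matching:
#' `df_i = (sum w)^2 / sum w^2`, so that `df_i * smoothed_i` is
#' approximately chi-square with `df_i` degrees of freedom.
#'
#' @param positions sorted bp positions within one chromosome.
#' @param stats per-probe statistics (Wald z-scores).
#' @param lambda kernel bandwidth in bp, default 1000.
#' @param C bandwidth scaling factor, default 2 (so sigma = 500 bp).
#' @return data frame with `smoothed`, `df` and `p` (upper chi-square
#'   tail of `df * smoothed` on `df` degrees of freedom).
#' @export
kernel_smooth <- function(positions, stats, lambda = 1000, C = 2) {
  n <- length(positions)
  if (length(stats) != n) stop_param("positions and stats lengths differ")
  if (n == 0)
    return(data.frame(smoothed = numeric(0), df = numeric(0), p = numeric(0)))
  if (is.unsorted(positions)) stop_param("positions must be sorted")
  if (any(!is.finite(stats))) stop_param("stats must be finite")
  sigma <- lambda / C
  cut <- 5 * sigma                       # beyond 5 sigma the weight is ~0
  smoothed <- df <- numeric(n)
  lo <- 1L
  for (i in seq_len(n)) {
    while (positions[i] - positions[lo] > cut) lo <- lo + 1L
    hi <- i
    while (hi < n && positions[hi + 1] - positions[i] <= cut) hi <- hi + 1L
    idx <- lo:hi
    w <- exp(-(positions[i] - positions[idx])^2 / (2 * sigma^2))
    sw <- sum(w)
    smoothed[i] <- sum(w * stats[idx]^2) / sw
    df[i] <- sw^2 / sum(w^2)
  }
  p <- pchisq(df * smoothed, df, lower.tail = FALSE)
  data.frame(smoothed = smoothed, df = df, p = p)
}

#' Call differentially methylated regions from smoothed statistics
#'
#' Probes significant after BH adjustment of the smoothed chi-square
#' p-values are chained into maximal runs whose consecutive members are
#' at most `gap` bp apart; runs with fewer than `min_cpgs` probes are
#' discarded. The region q is the minimum member q (alternatives:
#' Stouffer or harmonic-mean combination of member p-values, BH-adjusted
#' per region afterwards, selected via `combine`).
#'
#' @param probes data frame with columns `chrom`, `pos`, `stat` (Wald)
#'   and `fc` (per-probe quasi-beta fold-change, i.e. exponentiated model
#'   estimate); rows may be unsorted.
#' @param lambda,C kernel parameters passed to [kernel_smooth()].
#' @param fdr region FDR cutoff (strict `<`), default 0.05.
#' @param gap maximum intra-region probe gap in bp, default `lambda`.
#' @param min_cpgs minimum probes per region, default 2.
#' @param combine region significance summary, default `"min_q"`.
#' @return data frame of regions: `chrom`, `start`, `end`, `n_probes`,
#'   `region_q`, `max_fc` (member fold-change furthest from 1 on the log
#'   scale), plus member probe ids in attribute `"members"`.
#' @export
call_regions <- function(probes, lambda = 1000, C = 2, fdr = 0.05,
                         gap = lambda, min_cpgs = 2,
                         combine = c("min_q", "stouffer", "harmonic")) {
  combine <- match.arg(combine)
  ord <- order(probes$chrom, probes$pos)
  probes <- probes[ord, , drop = FALSE]
  # split() orders chromosomes alphabetically, matching the sort above
  sm <- do.call(rbind, lapply(split(probes, probes$chrom), function(pc) {
    kernel_smooth(pc$pos, pc$stat, lambda, C)
  }))
  probes$p_sm <- sm$p
  probes$q_sm <- bh_adjust(probes$p_sm)

  regions <- list()
  members <- list()
  for (ch in unique(probes$chrom)) {
    pc <- probes[probes$chrom == ch, , drop = FALSE]
    sig <- which(pc$q_sm < fdr)
    if (length(sig) == 0) next
    brk <- c(0, which(diff(pc$pos[sig]) > gap), length(sig))
    for (k in seq_len(length(brk) - 1)) {
      run <- sig[(brk[k] + 1):brk[k + 1]]
      if (length(run) < min_cpgs) next
      rq <- switch(combine,
        min_q = min(pc$q_sm[run]),
        stouffer = {
          z <- qnorm(pmax(pc$p_sm[run], 1e-300), lower.tail = FALSE)
          stats::pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
        },
        harmonic = length(run) / sum(1 / pmax(pc$p_sm[run], 1e-300)))
      fc <- pc$fc[run]
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = min(pc$pos[run]), end = max(pc$pos[run]),
        n_probes = length(run), region_q = rq,
        max_fc = fc[which.max(abs(log(fc)))])
      members[[length(members) + 1]] <-
        if ("probe_id" %in% names(pc)) pc$probe_id[run] else run
    }
  }
  out <- if (length(regions) > 0) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_probes = integer(0), region_q = numeric(0),
               max_fc = numeric(0))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Filter regions on quasi-beta fold-change
#'
#' Symmetric on the log scale: keeps regions whose extremal member
#' fold-change exceeds `min_fc` or falls below `1 / min_fc`.
#'
#' @param dmrs region data frame from [call_regions()].
#' @param min_fc fold-change threshold (> 1), default 2.
#' @return the surviving rows (with the `"members"` attribute subset).
#' @export
filter_fold_change <- function(dmrs, min_fc = 2) {
  if (min_fc <= 1) stop_param("min_fc must be > 1")
  keep <- abs(log(dmrs$max_fc)) > log(min_fc)
  out <- dmrs[keep, , drop = FALSE]
  attr(out, "members") <- attr(dmrs, "members")[keep]
  rownames(out) <- NULL
  out
}

#' Annotate regions with genomic context
#'
#' A region carries a context flag (island, shore, shelf, promoter,
#' enhancer) if any member probe carries it. Also tabulates the context
#' distribution over all regions and per-chromosome region counts with
#' mean and SD across autosomes.
#'
#' @param dmrs region data frame from [call_regions()] (needs the
#'   `"members"` attribute with probe ids).
#' @param manifest probe manifest covering all member probes.
#' @return list with `dmrs` (flag columns added), `context_counts`
#'   (named vector over the five categories), `chrom_counts`,
#'   `autosome_mean`, `autosome_sd`.
#' @export
annotate_context <- function(dmrs, manifest) {
  members <- attr(dmrs, "members")
  cats <- c("island", "shore", "shelf", "promoter", "enhancer")
  flags <- matrix(FALSE, nrow(dmrs), length(cats),
                  dimnames = list(NULL, cats))
  for (k in seq_len(nrow(dmrs))) {
    idx <- match(members[[k]], manifest$probe_id)
    if (anyNA(idx)) stop_param("member probe missing from manifest")
    rel <- manifest$relation[idx]
    flags[k, "island"] <- any(rel == "island")
    flags[k, "shore"] <- any(rel == "shore")
    flags[k, "shelf"] <- any(rel == "shelf")
    flags[k, "promoter"] <- any(as.logical(manifest$promoter[idx]))
    flags[k, "enhancer"] <- any(as.logical(manifest$enhancer[idx]))
  }
  out <- cbind(dmrs, as.data.frame(flags))
  attr(out, "members") <- members
  context_counts <- colSums(flags)
  chrom_counts <- table(factor(dmrs$chrom))
  auto <- chrom_counts[!grepl("chr[XY]$", names(chrom_counts))]
  list(dmrs = out, context_counts = context_counts,
       chrom_counts = chrom_counts,
       autosome_mean = if (length(auto)) mean(auto) else NA_real_,
       autosome_sd = if (length(auto) > 1) sd(auto) else NA_real_)
}

#' Rank regions by fold-change
#'
#' Orders by `|log max_fc|` descending, ties broken by `region_q`
#' ascending, and returns the top `n`.
#'
#' @param dmrs annotated or raw region data frame.
#' @param n how many regions to keep, default 250.
#' @return the top rows in rank order.
#' @export
top_dmrs <- function(dmrs, n = 250) {
  ord <- order(-abs(log(dmrs$max_fc)), dmrs$region_q)
  out <- dmrs[head(ord, n), , drop = FALSE]
  attr(out, "members") <- attr(dmrs, "members")[head(ord, n)]
  out
}

#' Write regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. The score column is `-10 log10(region_q)` capped at 1000.
#'
#' @param dmrs region data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(chrom = dmrs$chrom, start = dmrs$start - 1,
                    end = dmrs$end,
                    name = sprintf("DMR_%04d", seq_len(nrow(dmrs))),
                    score = round(pmin(1000,
                      -10 * log10(pmax(dmrs$region_q, 1e-100)))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
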