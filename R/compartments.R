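#' Select open-sea probes
#'
#' Open-sea probes lie at least 4 kb from any annotated CpG island; the
#' manifest's `relation` column encodes this (a manifest with no islands
#' classifies every probe open sea).
#'
#' @param manifest probe manifest with a `relation` column.
#' @return character vector of open-sea probe ids.
#' @export
select_open_sea <- function(manifest) {
  manifest$probe_id[manifest$relation == "open_sea"]
}

#' k-nearest-neighbour imputation of a probes x samples matrix
#'
#' Probes observed in at least `1 - max_missing_frac` of samples have
#' their missing entries replaced by the mean of the `k` nearest probes
#' (Euclidean distance over shared observed columns, scaled to a
#' per-column average) that carry a value in the target column; probes
#' missing in more than `max_missing_frac` of samples are dropped.
#'
#' @param m numeric matrix (rows = probes) with `NA` for missing.
#' @param k number of neighbours, default 10; reduced with a warning if
#'   fewer candidate rows exist.
#' @param max_missing_frac drop threshold on the per-probe missing
#'   fraction (strict `>`), default 0.5.
#' @return complete matrix containing only the retained rows.
#' @export
knn_impute <- function(m, k = 10, max_missing_frac = 0.5) {
  m <- as.matrix(m)
  miss_frac <- rowMeans(is.na(m))
  m <- m[miss_frac <= max_missing_frac, , drop = FALSE]
  need <- which(rowSums(is.na(m)) > 0)
  if (length(need) == 0) return(m)
  obs <- !is.na(m)
  for (i in need) {
    cand <- which(seq_len(nrow(m)) != i)
    for (j in which(is.na(m[i, ]))) {
      cj <- cand[obs[cand, j]]
      if (length(cj) == 0) next
      kk <- min(k, length(cj))
      if (kk < k && i == need[1] && j == which(is.na(m[i, ]))[1])
        warning("k reduced to ", kk, ": too few candidate rows")
      shared <- obs[cj, , drop = FALSE] &
        matrix(obs[i, ], length(cj), ncol(m), byrow = TRUE)
      d <- vapply(seq_along(cj), function(r) {
        sc <- shared[r, ]
        if (!any(sc)) return(Inf)
        mean((m[i, sc] - m[cj[r], sc])^2)
      }, numeric(1))
      nb <- cj[order(d)][seq_len(kk)]
      m[i, j] <- mean(m[nb, j])
    }
  }
  m
}

#' Median-summarise probe values into genomic bins
#'
#' Bins are genome-anchored half-open 100 kb intervals; a probe at
#' position `pos` (1-based) falls in bin `pos %/% bin_size + 1` when
#' `pos` is not an exact bin multiple, and opens the next bin when it is
#' (so position 100,000 belongs to the second bin).
#'
#' @param m probes x samples matrix of M-values.
#' @param positions bp positions parallel to the rows of `m`.
#' @param bin_size bin width in bp, default 100,000.
#' @return list with `binned` (bins x samples matrix of medians, `NA`
#'   for empty bins), `bin_start` (0-based starts), `n_probes` per bin.
#' @export
bin_median <- function(m, positions, bin_size = 1e5) {
  m <- as.matrix(m)
  if (length(positions) != nrow(m))
    stop_param("positions length must match rows of m")
  n_bins <- if (length(positions) == 0) 0 else
    max(positions %/% bin_size) + 1L
  binned <- matrix(NA_real_, n_bins, ncol(m))
  colnames(binned) <- colnames(m)
  n_probes <- integer(n_bins)
  idx <- positions %/% bin_size + 1L
  for (b in unique(idx)) {
    rows <- which(idx == b)
    n_probes[b] <- length(rows)
    binned[b, ] <- apply(m[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  }
  list(binned = binned, bin_start = (seq_len(n_bins) - 1L) * bin_size,
       n_probes = n_probes)
}

#' Infer an A/B compartment track for one group on one chromosome
#'
#' Computes the bin-by-bin Pearson correlation matrix across the group's
#' samples and takes the first eigenvector (unit norm) of that matrix as
#' the compartment eigenvalue track: positive entries are labelled A
#' (open), negative B (closed). Sign orientation is arbitrary in the
#' eigendecomposition; the track is oriented so the eigenvector
#' correlates positively with per-bin probe density, falling back to a
#' positive first informative bin when that correlation is negligible
#' (|r| < 0.1) - the fallback anchors both groups to the same reference
#' so cross-group sign comparison is meaningful.
#'
#' @param binned bins x samples matrix for one chromosome restricted to
#'   one group's samples (`NA` rows = empty bins).
#' @param chrom chromosome name carried through to the output.
#' @param group group label carried through.
#' @param n_probes per-bin probe counts (used by the orientation anchor).
#' @param min_bins minimum usable bins, default 10.
#' @return data frame of class `compartment_track`: `group`, `chrom`,
#'   `bin`, `start` (0-based), `eigen`, `label` (`"A"`/`"B"`/`NA`),
#'   `n_probes`.
#' @export
infer_track <- function(binned, chrom, group, n_probes = NULL,
                        min_bins = 10) {
  binned <- as.matrix(binned)
  if (ncol(binned) < 3) stop_param("need at least 3 samples in group")
  usable <- rowSums(is.na(binned)) == 0 &
    apply(binned, 1, function(r) stats::var(r) > 0)
  if (sum(usable) < min_bins)
    stop_param("fewer than ", min_bins, " informative bins on ", chrom)
  bu <- binned[usable, , drop = FALSE]
  # remove per-sample global offsets (array/patient level shifts) so the
  # leading eigenvector reflects spatial structure, not sample effects
  bu <- sweep(bu, 2, colMeans(bu))
  cm <- cor(t(bu))
  if (all(abs(cm - 1) < 1e-12))
    stop_param("degenerate correlation matrix: no structure on ", chrom)
  ev <- eigen(cm, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  # orientation: probe-density anchor, first-bin fallback
  flip <- FALSE
  if (!is.null(n_probes)) {
    dens <- n_probes[usable]
    r <- if (stats::sd(dens) > 0) cor(v, dens) else 0
    if (abs(r) >= 0.1) flip <- r < 0 else flip <- v[1] < 0
  } else flip <- v[1] < 0
  if (flip) v <- -v
  eig <- rep(NA_real_, nrow(binned))
  eig[usable] <- v
  out <- data.frame(group = group, chrom = chrom,
                    bin = seq_len(nrow(binned)),
                    start = (seq_len(nrow(binned)) - 1L) * 1L,
                    eigen = eig,
                    label = ifelse(is.na(eig), NA,
                                   ifelse(eig > 0, "A", "B")),
                    n_probes = if (is.null(n_probes)) NA_integer_ else
                      n_probes,
                    stringsAsFactors = FALSE)
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Call cross-group compartment discordance
#'
#' Bins where either group's eigenvalue magnitude falls below `min_abs`
#' (or is missing) are `filtered`; among the rest, bins with opposite
#' signs are `discordant`, same signs `concordant`. The concordance
#' fraction is `concordant / (concordant + discordant)`.
#'
#' @param track_a,track_b `compartment_track` data frames on identical
#'   bin grids (same chromosome(s) and bin indices).
#' @param min_abs minimum absolute eigenvalue retained in both groups,
#'   default 0.02.
#' @return list with `calls` (data frame `chrom`, `bin`, `eigen_a`,
#'   `eigen_b`, `status`), `concordance` and `counts`.
#' @export
call_discordance <- function(track_a, track_b, min_abs = 0.02) {
  key_a <- paste(track_a$chrom, track_a$bin)
  key_b <- paste(track_b$chrom, track_b$bin)
  if (!identical(key_a, key_b))
    stop_param("tracks are not on identical bin grids")
  ea <- track_a$eigen
  eb <- track_b$eigen
  status <- rep("filtered", length(ea))
  pass <- !is.na(ea) & !is.na(eb) & abs(ea) >= min_abs & abs(eb) >= min_abs
  status[pass & sign(ea) != sign(eb)] <- "discordant"
  status[pass & sign(ea) == sign(eb)] <- "concordant"
  counts <- c(concordant = sum(status == "concordant"),
              discordant = sum(status == "discordant"),
              filtered = sum(status == "filtered"))
  conc <- if (sum(counts[1:2]) > 0)
    counts[["concordant"]] / sum(counts[1:2]) else NA_real_
  list(calls = data.frame(chrom = track_a$chrom, bin = track_a$bin,
                          eigen_a = ea, eigen_b = eb, status = status,
                          stringsAsFactors = FALSE),
       concordance = conc, counts = counts)
}

#' Full compartment analysis for a two-group cohort
#'
#' Subsets to open-sea probes, converts to M-values, drops/imputes
#' missing entries by kNN, median-bins at `bin_size`, infers a per-group
#' track per chromosome (X and Y excluded) and calls discordance.
#'
#' @param bm QC-filtered [beta_matrix()].
#' @param samples sample sheet.
#' @param manifest probe manifest.
#' @param groups length-2 character, groups to compare.
#' @param bin_size bin width, default 100,000 bp.
#' @param min_abs discordance eigenvalue filter, default 0.02.
#' @param k kNN neighbours for imputation.
#' @return list with `tracks` (per group, rbind-ed over chromosomes),
#'   `calls`, `concordance`, `counts`.
#' @export
compartment_analysis <- function(bm, samples, manifest,
                                 groups = c("CNF", "PNF"),
                                 bin_size = 1e5, min_abs = 0.02, k = 10) {
  open_ids <- select_open_sea(manifest)
  keep <- bm$probe_ids %in% open_ids
  man <- manifest[match(bm$probe_ids[keep], manifest$probe_id), ]
  man <- man[!grepl("chr[XY]$", man$chrom), ]
  beta <- bm$beta[match(man$probe_id, bm$probe_ids), , drop = FALSE]
  mask <- bm$mask[match(man$probe_id, bm$probe_ids), , drop = FALSE]
  mv <- beta_to_m(squeeze_beta(beta, ncol(beta)))
  mv[mask] <- NA
  tracks <- list()
  calls <- list()
  for (ch in unique(man$chrom)) {
    rows <- which(man$chrom == ch)
    mi <- knn_impute(mv[rows, , drop = FALSE], k = k)
    pos <- man$pos[rows][match(rownames(mi), man$probe_id[rows])]
    bb <- bin_median(mi, pos, bin_size)
    tr <- list()
    for (g in groups) {
      cols <- samples$sample_id[samples$group == g]
      tr[[g]] <- infer_track(bb$binned[, colnames(bb$binned) %in% cols,
                                       drop = FALSE],
                             chrom = ch, group = g,
                             n_probes = bb$n_probes)
      tr[[g]]$start <- bb$bin_start
      tracks[[paste(g, ch)]] <- tr[[g]]
    }
    calls[[ch]] <- call_discordance(tr[[groups[1]]], tr[[groups[2]]],
                                    min_abs)$calls
  }
  all_calls <- do.call(rbind, calls)
  rownames(all_calls) <- NULL
  counts <- c(concordant = sum(all_calls$status == "concordant"),
              discordant = sum(all_calls$status == "discordant"),
              filtered = sum(all_calls$status == "filtered"))
  list(tracks = do.call(rbind, tracks),
       calls = all_calls,
       concordance = counts[["concordant"]] /
         max(1, sum(counts[1:2])),
       counts = counts)
}

#' Write a compartment track as bedGraph plus an A/B BED
#'
#' @param track `compartment_track` data frame (single or multiple
#'   chromosomes).
#' @param path_bedgraph,path_bed output files.
#' @param bin_size bin width used to reconstruct interval ends.
#' @return invisible `NULL`.
#' @export
write_track_bedgraph <- function(track, path_bedgraph, path_bed,
                                 bin_size = 1e5) {
  ok <- !is.na(track$eigen)
  bg <- data.frame(chrom = track$chrom[ok],
                   start = (track$bin[ok] - 1L) * bin_size,
                   end = track$bin[ok] * bin_size,
                   value = fmt_full(track$eigen[ok]))
  write.table(bg, path_bedgraph, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bed <- data.frame(chrom = track$chrom[ok],
                    start = (track$bin[ok] - 1L) * bin_size,
                    end = track$bin[ok] * bin_size,
                    name = track$label[ok])
  write.table(bed, path_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
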