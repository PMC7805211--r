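# Probe-density-bias-aware gene-set enrichment.
#
# Arrays cover genes with very different probe counts, so a gene with
# many probes is more likely to contain a significant probe by chance.
# Following the goseq/gometh idea, the selection bias is modelled with a
# Wallenius noncentral hypergeometric urn: genes in the tested set draw
# with odds proportional to their mean probe count relative to genes
# outside the set.

# Wallenius noncentral hypergeometric pmf over the full support.
# The distribution is exactly that of the number of white balls in n
# sequential weighted draws without replacement (white odds w), so a
# dynamic program over draws gives the pmf to machine precision and
# reduces to the central hypergeometric when w = 1.
wallenius_pmf <- function(m1, m2, n, w) {
  if (n > m1 + m2) stop_param("n exceeds population size")
  xmax_all <- min(n, m1)
  p <- c(1, rep(0, xmax_all))            # index = x + 1, after 0 draws
  for (t in seq_len(n)) {
    x <- 0:xmax_all
    # arrive at x by drawing white from state x-1 (after t-1 draws)
    wr1 <- m1 - (x - 1)
    br1 <- m2 - (t - 1) + (x - 1)
    pa <- c(0, p[-length(p)])            # p_prev at x-1
    da <- w * wr1 + br1
    termA <- ifelse(x >= 1 & wr1 > 0 & br1 >= 0 & da > 0,
                    pa * w * wr1 / ifelse(da > 0, da, 1), 0)
    # arrive at x by drawing black from state x
    wr2 <- m1 - x
    br2 <- m2 - (t - 1) + x
    db <- w * wr2 + br2
    termB <- ifelse(br2 > 0 & x <= t - 1 & db > 0,
                    p * br2 / ifelse(db > 0, db, 1), 0)
    p <- termA + termB
  }
  p / sum(p)
}

# upper-tail P(X >= x)
pwallenius_upper <- function(x, m1, m2, n, w) {
  pmf <- wallenius_pmf(m1, m2, n, w)
  if (x + 1 > length(pmf)) return(0)
  sum(pmf[seq.int(x + 1, length(pmf))])
}

#' Gene-set over-representation with probe-count bias correction
#'
#' Maps significant and background probes to genes, then tests each gene
#' set for over-representation among the significant genes with a
#' Wallenius noncentral hypergeometric model whose odds parameter is the
#' ratio of mean per-gene probe counts inside versus outside the set
#' (equal probe coverage reduces exactly to the one-sided Fisher /
#' central hypergeometric test). P-values are BH-adjusted across sets.
#'
#' @param sig_probes character vector of significant probe ids (must be
#'   a subset of `background_probes`).
#' @param background_probes all analysable probe ids after QC.
#' @param gene_sets named list of character vectors of gene symbols.
#' @param probe_to_gene data frame with columns `probe_id` and `gene`.
#' @return data frame: `set`, `n_set` (background genes in set),
#'   `n_sig` (significant genes in set), `odds` (bias odds used), `p`,
#'   `q`; attribute `"n_excluded"` counts set genes with zero probes in
#'   the background.
#' @export
enrich_gene_sets <- function(sig_probes, background_probes, gene_sets,
                             probe_to_gene) {
  if (!all(sig_probes %in% background_probes))
    stop_param("sig_probes must be a subset of background_probes")
  if (any(lengths(gene_sets) == 0)) stop_param("empty gene set supplied")
  p2g <- probe_to_gene[probe_to_gene$probe_id %in% background_probes, ]
  counts <- table(p2g$gene)                    # probes per gene (the bias)
  genes <- names(counts)
  sig_genes <- unique(p2g$gene[p2g$probe_id %in% sig_probes])
  N <- length(genes)
  n <- length(sig_genes)
  n_excluded <- 0L
  res <- lapply(names(gene_sets), function(nm) {
    gs <- unique(gene_sets[[nm]])
    absent <- sum(!gs %in% genes)
    if (absent > 0) n_excluded <<- n_excluded + absent
    gs <- gs[gs %in% genes]
    m1 <- length(gs)
    if (m1 == 0 || m1 == N)
      return(data.frame(set = nm, n_set = m1, n_sig = NA_integer_,
                        odds = NA_real_, p = NA_real_))
    x <- sum(sig_genes %in% gs)
    w_in <- mean(counts[gs])
    w_out <- mean(counts[setdiff(genes, gs)])
    w <- w_in / w_out
    p <- pwallenius_upper(x, m1, N - m1, n, w)
    data.frame(set = nm, n_set = m1, n_sig = x, odds = w, p = p)
  })
  out <- do.call(rbind, res)
  if (n_excluded > 0)
    warning(n_excluded, " gene-set genes had no probes in the background")
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}
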