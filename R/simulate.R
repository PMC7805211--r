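#' Configuration for the synthetic EPIC-like cohort generator
#'
#' Collects every knob of the simulator with validated defaults. The
#' defaults emulate a two-group neurofibroma-style cohort: tens of
#' patients per group with partially repeated tumour sampling, samples
#' laid out on a small number of array slides, beta-distributed probe
#' noise, planted group effects on the logit scale, planted DMR
#' intervals, alternating A/B compartment blocks with a fraction flipped
#' between the groups, and size-associated probes within the CNF group.
#'
#' @param n_probes total probe count across all chromosomes.
#' @param n_patients_per_group patients per group (groups are CNF, PNF).
#' @param tumors_per_patient repeated samples per patient (partially
#'   repeated sampling).
#' @param n_slides number of array slides; every sample of a patient sits
#'   on that patient's slide, so patient is nested within slide.
#' @param chrom_layout named numeric vector of chromosome lengths in bp.
#' @param mean_gap mean inter-probe gap in bp; `NULL` derives it from the
#'   genome length and probe count.
#' @param island_spacing,island_len spacing and length (bp) of the planted
#'   CpG islands used to compute island/shore/shelf/open-sea relations.
#' @param frac_island_probes fraction of probes packed densely inside
#'   islands (EPIC-like coverage: islands carry tight probe clusters,
#'   open sea is sparse); the rest follow exponential gaps genome-wide.
#' @param baseline_logit_mean,baseline_logit_sd per-probe baseline
#'   methylation drawn on the logit scale.
#' @param sigma_slide,sigma_patient random-intercept SDs (logit scale);
#'   intercepts are drawn independently per probe, matching the
#'   data-generating process the per-probe model assumes.
#' @param phi beta-distribution precision (> 0), shared across probes.
#' @param group_effect_delta logit-scale group effect applied (with random
#'   sign) to planted DMP probes.
#' @param frac_dmp fraction of probes planted as DMPs.
#' @param dmr_blocks list of planted regions, each
#'   `list(chrom=, start=, end=, delta=)`; every member probe receives
#'   `delta` on the logit scale in the PNF group.
#' @param compartment_block_len length (bp) of alternating A/B blocks;
#'   should be a multiple of the 100 kb analysis bin.
#' @param frac_discordant_blocks fraction of blocks (never the first block
#'   of a chromosome, which anchors eigenvector orientation) whose sign is
#'   flipped in the PNF group.
#' @param comp_amp,block_amp logit-scale amplitudes of the shared
#'   compartment latent and the per-block latent on open-sea probes.
#' @param size_effect_slope logit change per mm of CNF tumour size on
#'   planted size probes.
#' @param frac_size_probes fraction of probes planted as size-associated.
#' @param detection_fail_rate per-entry probability of a failed
#'   measurement (detection p-value above 0.01).
#' @param frac_blacklist fraction of probes flagged as blacklisted.
#' @param seed integer seed; identical `(config, seed)` regenerates
#'   byte-identical cohorts.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 2000,
                       n_patients_per_group = 15,
                       tumors_per_patient = 2,
                       n_slides = 8,
                       chrom_layout = c(chr1 = 3e6, chr2 = 3e6),
                       mean_gap = NULL,
                       island_spacing = 50000,
                       island_len = 1000,
                       frac_island_probes = 0.3,
                       baseline_logit_mean = 0,
                       baseline_logit_sd = 1,
                       sigma_slide = 0.3,
                       sigma_patient = 0.3,
                       phi = 50,
                       group_effect_delta = 1.5,
                       frac_dmp = 0.05,
                       dmr_blocks = list(),
                       compartment_block_len = 5e5,
                       frac_discordant_blocks = 0.15,
                       comp_amp = 0.4,
                       block_amp = 0.5,
                       size_effect_slope = 0.05,
                       frac_size_probes = 0,
                       detection_fail_rate = 0.005,
                       frac_blacklist = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  chk_frac <- function(nm) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_param("sim_config: field '", nm, "' must be a fraction in [0, 1]")
  }
  for (nm in c("frac_dmp", "frac_discordant_blocks", "frac_size_probes",
               "detection_fail_rate", "frac_blacklist",
               "frac_island_probes")) chk_frac(nm)
  if (phi <= 0) stop_param("sim_config: field 'phi' must be > 0")
  for (nm in c("sigma_slide", "sigma_patient"))
    if (cfg[[nm]] < 0) stop_param("sim_config: field '", nm, "' must be >= 0")
  if (any(chrom_layout <= 0) || is.null(names(chrom_layout)))
    stop_param("sim_config: field 'chrom_layout' needs named positive lengths")
  for (nm in c("n_probes", "n_patients_per_group", "tumors_per_patient",
               "n_slides"))
    if (cfg[[nm]] < 0 || cfg[[nm]] != round(cfg[[nm]]))
      stop_param("sim_config: field '", nm, "' must be a nonnegative count")
  for (b in dmr_blocks)
    if (!all(c("chrom", "start", "end", "delta") %in% names(b)))
      stop_param("sim_config: field 'dmr_blocks' entries need chrom/start/end/delta")
  structure(cfg, class = "sim_config")
}

# strictly increasing positions from cumulative exponential gaps,
# rescaled into [1, len]
draw_positions <- function(n, len, mean_gap) {
  if (n == 0) return(integer(0))
  raw <- cumsum(rexp(n, rate = 1 / mean_gap))
  # scale into [1, len - 1] keeping order strict (len itself would open a
  # new genomic bin under the half-open convention)
  pos <- round(raw / max(raw) * max(len - n - 1, 0)) + seq_len(n)
  as.integer(pos)
}

# island relation from distance to nearest planted island segment
island_relation <- function(pos, island_starts, island_len) {
  if (length(island_starts) == 0)
    return(list(relation = rep("open_sea", length(pos)),
                dist = rep(Inf, length(pos))))
  dist <- vapply(pos, function(p) {
    d <- pmax(island_starts - p, p - (island_starts + island_len - 1), 0)
    min(d)
  }, numeric(1))
  relation <- ifelse(dist == 0, "island",
              ifelse(dist <= 2000, "shore",
              ifelse(dist <= 4000, "shelf", "open_sea")))
  list(relation = relation, dist = dist)
}

#' Simulate an EPIC-like cohort with planted truth
#'
#' Draws beta values as `Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = baseline + group effect + slide intercept + patient
#' intercept + size slope * size + compartment latents`, injects random
#' detection failures, and returns the full planted-truth record needed
#' for parameter-recovery testing.
#'
#' @param config a [sim_config()].
#' @return list with elements `matrix` (a [beta_matrix()]), `samples`
#'   (sample sheet data frame), `manifest` (probe manifest data frame)
#'   and `truth` (planted-effect record).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  chroms <- names(cfg$chrom_layout)
  total_len <- sum(cfg$chrom_layout)
  mean_gap <- if (is.null(cfg$mean_gap))
    total_len / (cfg$n_probes + length(chroms)) else cfg$mean_gap

  ## ---- manifest ----
  n_per <- floor(cfg$n_probes * cfg$chrom_layout / total_len)
  rem <- cfg$n_probes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
  empty_man <- data.frame(chrom = character(0), pos = integer(0),
                          relation = character(0), gene = character(0),
                          promoter = logical(0), enhancer = logical(0),
                          stringsAsFactors = FALSE)
  man_list <- lapply(chroms, function(ch) {
    len <- cfg$chrom_layout[[ch]]
    n <- n_per[[ch]]
    if (n == 0) return(empty_man)
    isl <- if (cfg$island_spacing > 0 && cfg$island_spacing < len)
      seq(cfg$island_spacing, max(cfg$island_spacing, len - cfg$island_len),
          by = cfg$island_spacing) else numeric(0)
    # EPIC-like coverage: dense probe clusters inside islands, sparse
    # exponential-gap probes elsewhere
    n_isl <- if (length(isl) > 0) round(cfg$frac_island_probes * n) else 0L
    isl_pos <- integer(0)
    if (n_isl > 0) {
      cnt <- as.vector(stats::rmultinom(1, n_isl,
                                        rep(1 / length(isl), length(isl))))
      isl_pos <- unlist(lapply(seq_along(isl), function(k) {
        if (cnt[k] == 0) return(integer(0))
        isl[k] + sort(sample.int(cfg$island_len, cnt[k], replace = TRUE)) - 1L
      }))
    }
    pos <- sort(c(draw_positions(n - n_isl, len, mean_gap), isl_pos))
    rel <- island_relation(pos, isl, cfg$island_len)
    tss <- seq(12500, len, by = 25000)
    gidx <- vapply(pos, function(p) which.min(abs(tss - p)), integer(1))
    gene <- sprintf("G_%s_%03d", ch, gidx)
    promoter <- pos >= tss[gidx] - 1500 & pos <= tss[gidx] + 500
    enh_starts <- seq(20000, len, by = 40000)
    eidx <- findInterval(pos, enh_starts)
    enhancer <- eidx >= 1 & (pos - enh_starts[pmax(eidx, 1)]) < 500
    data.frame(chrom = ch, pos = pos, relation = rel$relation,
               gene = gene, promoter = promoter, enhancer = enhancer,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, man_list)
  np <- nrow(manifest)
  manifest$probe_id <- sprintf("cg%06d", seq_len(np))
  manifest$blacklist <- logical(np)
  if (np > 0 && cfg$frac_blacklist > 0)
    manifest$blacklist[sample.int(np, floor(cfg$frac_blacklist * np))] <- TRUE
  manifest <- manifest[, c("probe_id", "chrom", "pos", "relation", "gene",
                           "promoter", "enhancer", "blacklist")]
  rownames(manifest) <- NULL

  ## ---- sample sheet ----
  npat <- 2 * cfg$n_patients_per_group
  pat <- data.frame(
    patient_id = sprintf("P%03d", seq_len(npat)),
    group = rep(c("CNF", "PNF"), each = cfg$n_patients_per_group),
    stringsAsFactors = FALSE)
  ord <- sample.int(npat)
  pat$slide_id <- NA_character_
  pat$slide_id[ord] <- sprintf("S%02d", rep(seq_len(cfg$n_slides),
                                            length.out = npat))
  pat$age <- round(runif(npat, 20, 70))
  pat$sex <- sample(c("F", "M"), npat, replace = TRUE)
  samples <- pat[rep(seq_len(npat), each = cfg$tumors_per_patient), ]
  ns <- nrow(samples)
  samples$sample_id <- sprintf("%s_T%d", samples$patient_id,
                               rep(seq_len(cfg$tumors_per_patient), npat))
  samples$size_mm <- ifelse(samples$group == "CNF",
                            round(runif(ns, 2, 20), 1), NA_real_)
  samples <- samples[, c("sample_id", "patient_id", "slide_id", "group",
                         "age", "sex", "size_mm")]
  rownames(samples) <- NULL

  ## ---- planted effects ----
  baseline <- rnorm(np, cfg$baseline_logit_mean, cfg$baseline_logit_sd)
  effect <- numeric(np)
  in_dmr <- rep(FALSE, np)
  dmr_intervals <- data.frame(chrom = character(0), start = integer(0),
                              end = integer(0), delta = numeric(0),
                              stringsAsFactors = FALSE)
  for (b in cfg$dmr_blocks) {
    sel <- manifest$chrom == b$chrom & manifest$pos >= b$start &
      manifest$pos <= b$end
    if (sum(sel) < 2)
      stop_param("sim_config: dmr_blocks interval on ", b$chrom,
                 " contains fewer than 2 probes")
    effect[sel] <- b$delta
    in_dmr <- in_dmr | sel
    dmr_intervals <- rbind(dmr_intervals, data.frame(
      chrom = b$chrom, start = min(manifest$pos[sel]),
      end = max(manifest$pos[sel]), delta = b$delta))
  }
  free <- which(!in_dmr)
  n_dmp <- floor(cfg$frac_dmp * np)
  dmp_idx <- if (n_dmp > 0) sort(sample(free, n_dmp)) else integer(0)
  effect[dmp_idx] <- cfg$group_effect_delta *
    sample(c(-1, 1), length(dmp_idx), replace = TRUE)
  free <- setdiff(free, dmp_idx)
  n_size <- floor(cfg$frac_size_probes * np)
  size_idx <- if (n_size > 0) sort(sample(free, n_size)) else integer(0)
  size_slope <- numeric(np)
  size_slope[size_idx] <- cfg$size_effect_slope *
    sample(c(-1, 1), length(size_idx), replace = TRUE)

  # random intercepts are drawn independently PER PROBE (the exact
  # data-generating process of the fitted per-probe model); sample-level
  # global structure is carried by the compartment latents instead
  slide_levels <- sort(unique(samples$slide_id))
  slide_int <- matrix(rnorm(np * length(slide_levels), 0, cfg$sigma_slide),
                      np, length(slide_levels),
                      dimnames = list(NULL, slide_levels))
  pat_int <- matrix(rnorm(np * npat, 0, cfg$sigma_patient),
                    np, npat, dimnames = list(NULL, pat$patient_id))

  ## ---- compartment block structure on open-sea probes ----
  open_sea <- manifest$relation == "open_sea"
  comp_labels <- data.frame(group = character(0), chrom = character(0),
                            bin = integer(0), sign = integer(0),
                            stringsAsFactors = FALSE)
  discordant <- data.frame(chrom = character(0), bin = integer(0),
                           stringsAsFactors = FALSE)
  comp_eta <- matrix(0, np, ns)
  bin_size <- 1e5
  for (ch in chroms) {
    len <- cfg$chrom_layout[[ch]]
    nb <- max(1L, ceiling(len / cfg$compartment_block_len))
    sign_cnf <- rep_len(c(1L, -1L), nb)
    flip <- rep(FALSE, nb)
    if (nb > 1 && cfg$frac_discordant_blocks > 0) {
      k <- round(cfg$frac_discordant_blocks * nb)
      if (k > 0) flip[sample(2:nb, min(k, nb - 1))] <- TRUE
    }
    sign_pnf <- ifelse(flip, -sign_cnf, sign_cnf)
    pr <- which(manifest$chrom == ch & open_sea)
    blk <- pmin(nb, (manifest$pos[pr] %/% cfg$compartment_block_len) + 1L)
    if (length(pr) > 0) {
      z_blk <- matrix(rnorm(nb * ns), nb, ns)       # per-block latent
      c_lat <- rnorm(ns)                             # shared A/B latent
      for (j in seq_len(ns)) {
        s_here <- if (samples$group[j] == "PNF") sign_pnf else sign_cnf
        comp_eta[pr, j] <- cfg$block_amp * z_blk[blk, j] +
          cfg$comp_amp * s_here[blk] * c_lat[j]
      }
    }
    # record truth at the 100 kb analysis grid
    n_bins_100k <- ceiling(len / bin_size)
    bin_block <- pmin(nb, (((seq_len(n_bins_100k) - 1) * bin_size) %/%
                             cfg$compartment_block_len) + 1L)
    comp_labels <- rbind(comp_labels,
      data.frame(group = "CNF", chrom = ch, bin = seq_len(n_bins_100k),
                 sign = sign_cnf[bin_block]),
      data.frame(group = "PNF", chrom = ch, bin = seq_len(n_bins_100k),
                 sign = sign_pnf[bin_block]))
    db <- which(sign_cnf[bin_block] != sign_pnf[bin_block])
    if (length(db) > 0)
      discordant <- rbind(discordant, data.frame(chrom = ch, bin = db))
  }

  ## ---- linear predictor and beta draws ----
  is_pnf <- as.numeric(samples$group == "PNF")
  size_c <- ifelse(is.na(samples$size_mm), 0,
                   samples$size_mm - mean(samples$size_mm, na.rm = TRUE))
  size_c[samples$group != "CNF"] <- 0
  eta <- matrix(baseline, np, ns) +
    outer(effect, is_pnf) +
    outer(size_slope, size_c) +
    comp_eta
  if (ns > 0 && np > 0) {
    eta <- eta + slide_int[, samples$slide_id, drop = FALSE] +
      pat_int[, samples$patient_id, drop = FALSE]
  }
  mu <- plogis(eta)
  beta <- matrix(rbeta(np * ns, mu * cfg$phi, (1 - mu) * cfg$phi), np, ns)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

  detp <- matrix(runif(np * ns, 0, 0.009), np, ns)
  fail <- matrix(runif(np * ns) < cfg$detection_fail_rate, np, ns)
  detp[fail] <- runif(sum(fail), 0.011, 1)
  dimnames(beta) <- dimnames(detp) <- list(manifest$probe_id,
                                           samples$sample_id)
  bm <- beta_matrix(beta, detp, mask = detp >= 0.01)

  truth <- list(
    dmp_probe_ids = manifest$probe_id[dmp_idx],
    dmr_intervals = dmr_intervals,
    dmr_probe_ids = manifest$probe_id[in_dmr],
    compartment_labels = comp_labels,
    discordant_bins = discordant,
    size_probe_ids = manifest$probe_id[size_idx],
    size_slopes = setNames(size_slope[size_idx], manifest$probe_id[size_idx]),
    probe_effects = setNames(effect, manifest$probe_id),
    probe_baseline = setNames(baseline, manifest$probe_id))
  list(matrix = bm, samples = samples, manifest = manifest, truth = truth)
}

write_mat_tsv <- function(m, path, key = "probe_id") {
  df <- data.frame(rownames(m), apply(m, 2, fmt_full),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(m) == 0) df <- data.frame(matrix(character(0), 0, ncol(m) + 1))
  colnames(df) <- c(key, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_mat_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = NA, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Write a cohort to a fixture directory
#'
#' Emits `beta.tsv`, `detp.tsv`, `samples.csv`, `manifest.tsv` and
#' `truth.json`; all matrices are written with full float precision so
#' the round trip through [read_fixture()] is lossless.
#'
#' @param dir_path output directory (created if absent).
#' @param cohort result of [simulate_cohort()] (the `truth` element is
#'   optional).
#' @return `dir_path`, invisibly.
#' @export
write_fixture <- function(dir_path, cohort) {
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stop_param("cannot create fixture directory: ", dir_path)
  write_mat_tsv(cohort$matrix$beta, file.path(dir_path, "beta.tsv"))
  write_mat_tsv(cohort$matrix$detection_p, file.path(dir_path, "detp.tsv"))
  write.csv(cohort$samples, file.path(dir_path, "samples.csv"),
            row.names = FALSE, quote = FALSE)
  write.table(cohort$manifest, file.path(dir_path, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    for (nm in c("probe_effects", "probe_baseline", "size_slopes"))
      tr[[nm]] <- as.list(tr[[nm]])
    jsonlite::write_json(tr, file.path(dir_path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir_path)
}

#' Read a cohort fixture directory
#'
#' @param dir_path directory produced by [write_fixture()] (or
#'   hand-assembled in the same layout; `truth.json` is optional).
#' @return list with `matrix`, `samples`, `manifest` and (if present)
#'   `truth`.
#' @export
read_fixture <- function(dir_path) {
  beta <- read_mat_tsv(file.path(dir_path, "beta.tsv"))
  detp <- read_mat_tsv(file.path(dir_path, "detp.tsv"))
  samples <- read.csv(file.path(dir_path, "samples.csv"),
                      stringsAsFactors = FALSE)
  manifest <- read.table(file.path(dir_path, "manifest.tsv"), sep = "\t",
                         header = TRUE, stringsAsFactors = FALSE)
  out <- list(matrix = beta_matrix(beta, detp, mask = detp >= 0.01),
              samples = samples, manifest = manifest)
  tj <- file.path(dir_path, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    for (nm in c("probe_effects", "probe_baseline", "size_slopes"))
      tr[[nm]] <- unlist(tr[[nm]])
    out$truth <- tr
  }
  out
}
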