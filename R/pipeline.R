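#' Pipeline configuration
#'
#' Validated bundle of input paths and thresholds for [run_pipeline()].
#' Serialises to a flat `key: value` text file (YAML-compatible subset)
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param input_dir fixture directory (see [write_fixture()] layout).
#' @param out_dir output directory.
#' @param contrast length-2 group contrast, default `c("CNF", "PNF")`.
#' @param p_threshold detection p-value threshold.
#' @param max_fail_frac sample failure fraction cutoff.
#' @param q_dmp,q_dmr,q_size FDR cutoffs per stage.
#' @param or_threshold high-effect odds-ratio cutoff.
#' @param lambda,C kernel parameters for region calling.
#' @param bin_size compartment bin width (bp).
#' @param min_abs_eigen compartment discordance filter.
#' @param min_delta_beta size-hit delta-beta cutoff.
#' @param min_fc region fold-change cutoff.
#' @param size_group group carrying tumour sizes.
#' @param seed integer seed recorded in the run log.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            contrast = c("CNF", "PNF"),
                            p_threshold = 0.01, max_fail_frac = 0.10,
                            q_dmp = 0.05, q_dmr = 0.05, q_size = 0.05,
                            or_threshold = 4, lambda = 1000, C = 2,
                            bin_size = 1e5, min_abs_eigen = 0.02,
                            min_delta_beta = 0.2, min_fc = 2,
                            size_group = "CNF", seed = 1) {
  cfg <- as.list(environment())
  chk <- function(nm, lo, hi) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < lo || v > hi)
      stop_param("pipeline_config: '", nm, "' outside [", lo, ", ", hi, "]")
  }
  chk("p_threshold", 1e-12, 1 - 1e-12)
  chk("max_fail_frac", 0, 1)
  for (nm in c("q_dmp", "q_dmr", "q_size")) chk(nm, 0, 1)
  if (or_threshold <= 1) stop_param("pipeline_config: 'or_threshold' must be > 1")
  if (min_fc <= 1) stop_param("pipeline_config: 'min_fc' must be > 1")
  for (nm in c("lambda", "C", "bin_size")) if (cfg[[nm]] <= 0)
    stop_param("pipeline_config: '", nm, "' must be positive")
  if (length(contrast) != 2) stop_param("pipeline_config: contrast needs 2 groups")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s: %s", nm, paste(as.character(v), collapse = ","))
  }, character(1))
  writeLines(ser, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  args <- list()
  for (m in kv) {
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- strsplit(val, ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!anyNA(num)) num else parts
  }
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes qc -> differential methylation -> DMR calling -> compartment
#' analysis -> size association -> gene-set enrichment on a fixture
#' directory, writing `dmps.tsv`, `dmrs.tsv`, `dmrs.bed`,
#' `enrichment.tsv`, per-group compartment bedGraph/BED tracks,
#' `discordance.bed`, `size_hits.tsv` and a machine-readable
#' `run_log.json` with the seed, thresholds and record counts of every
#' stage. Output is deterministic: the same config and seed yield
#' byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @param gene_sets optional named list of gene sets for the enrichment
#'   stage; `NULL` derives consecutive 20-gene sets from the manifest
#'   (useful for smoke testing, not biology).
#' @return invisible list with all stage results and the run log.
#' @export
run_pipeline <- function(config, gene_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed,
              thresholds = config[!(names(config) %in%
                                      c("input_dir", "out_dir"))],
              stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  fx <- stage("read", read_fixture(config$input_dir))
  if (!all(config$contrast %in% fx$samples$group))
    stop("pipeline stage 'qc' failed: contrast group absent from sample sheet",
         call. = FALSE)

  qc <- stage("qc", qc_filter(fx$matrix, fx$manifest,
                              config$p_threshold, config$max_fail_frac))
  bm <- qc$matrix
  log$stages$qc <- list(n_probes_in = nrow(fx$matrix$beta),
                        n_samples_in = ncol(fx$matrix$beta),
                        dropped_samples = length(qc$dropped_samples),
                        blacklisted = qc$n_blacklisted,
                        n_probes_out = nrow(bm$beta),
                        n_samples_out = ncol(bm$beta))

  fits <- stage("dmp", dmp_fit(bm, fx$samples, contrast = config$contrast,
                               manifest = fx$manifest))
  dmps <- select_dmps(fits, config$q_dmp)
  high <- select_high_effect(dmps, config$or_threshold)
  write.table(fits, file.path(config$out_dir, "dmps.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log$stages$dmp <- list(n_fit = nrow(fits),
                         n_converged = sum(fits$converged),
                         n_significant = nrow(dmps),
                         n_high_effect = nrow(high))

  pr <- data.frame(probe_id = fits$probe_id, chrom = fits$chrom,
                   pos = fits$pos, stat = fits$wald,
                   fc = fits$odds_ratio)
  pr <- pr[fits$converged & is.finite(pr$stat), ]
  dmrs <- stage("dmr", call_regions(pr, lambda = config$lambda,
                                    C = config$C, fdr = config$q_dmr))
  dmrs_fc <- filter_fold_change(dmrs, config$min_fc)
  ann <- annotate_context(dmrs, fx$manifest)
  write.table(ann$dmrs, file.path(config$out_dir, "dmrs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_dmr_bed(dmrs, file.path(config$out_dir, "dmrs.bed"))
  log$stages$dmr <- list(n_regions = nrow(dmrs),
                         n_fold_change = nrow(dmrs_fc),
                         context_counts = as.list(ann$context_counts))

  comp <- stage("compartments",
                compartment_analysis(bm, fx$samples, fx$manifest,
                                     groups = config$contrast,
                                     bin_size = config$bin_size,
                                     min_abs = config$min_abs_eigen))
  for (g in config$contrast) {
    tr <- comp$tracks[comp$tracks$group == g, ]
    write_track_bedgraph(tr,
      file.path(config$out_dir, paste0("compartments_", g, ".bedgraph")),
      file.path(config$out_dir, paste0("compartments_", g, ".bed")),
      bin_size = config$bin_size)
  }
  disc <- comp$calls
  bed <- data.frame(chrom = disc$chrom,
                    start = (disc$bin - 1) * config$bin_size,
                    end = disc$bin * config$bin_size,
                    status = disc$status)
  write.table(bed, file.path(config$out_dir, "discordance.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  log$stages$compartments <- c(as.list(comp$counts),
                               concordance = comp$concordance)

  sz <- stage("size", size_association(bm, fx$samples,
                                       group = config$size_group,
                                       q_threshold = config$q_size,
                                       min_delta = config$min_delta_beta))
  write.table(sz, file.path(config$out_dir, "size_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log$stages$size <- list(n_model_sig = sum(!is.na(sz$q_model) &
                                              sz$q_model < config$q_size),
                          n_pass = sum(sz$passes_filter))

  if (is.null(gene_sets)) {
    genes <- sort(unique(fx$manifest$gene))
    gene_sets <- split(genes, ceiling(seq_along(genes) / 20))
    names(gene_sets) <- sprintf("SET_%03d", seq_along(gene_sets))
  }
  enr <- stage("enrich",
               enrich_gene_sets(dmps$probe_id, fits$probe_id, gene_sets,
                                fx$manifest[, c("probe_id", "gene")]))
  write.table(enr, file.path(config$out_dir, "enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log$stages$enrich <- list(n_sets = nrow(enr),
                            n_significant = sum(!is.na(enr$q) &
                                                  enr$q < 0.05))

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, dmps = dmps, high_effect = high,
                 dmrs = dmrs, dmrs_fold_change = dmrs_fc,
                 context = ann, compartments = comp, size = sz,
                 enrichment = enr, log = log))
}
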