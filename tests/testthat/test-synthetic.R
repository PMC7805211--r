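test_that("identical (config, seed) regenerates identical cohorts", {
  cfg <- sim_config(n_probes = 150, seed = 4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$matrix$beta, b$matrix$beta)
  expect_identical(a$matrix$detection_p, b$matrix$detection_p)
  expect_identical(a$samples, b$samples)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$truth$dmp_probe_ids, b$truth$dmp_probe_ids)
})

test_that("no planted effect means empty DMP truth and null group contrast", {
  co <- simulate_cohort(sim_config(n_probes = 200, frac_dmp = 0,
                                   comp_amp = 0, block_amp = 0,
                                   sigma_slide = 0, sigma_patient = 0,
                                   detection_fail_rate = 0, seed = 8))
  expect_length(co$truth$dmp_probe_ids, 0)
  expect_true(all(co$truth$probe_effects == 0))
  g <- co$samples$group
  diffs <- rowMeans(co$matrix$beta[, g == "PNF"]) -
    rowMeans(co$matrix$beta[, g == "CNF"])
  # pure sampling noise: per-probe beta noise sd ~ sqrt(v/(1+phi)) / sqrt(30)
  expect_lt(mean(abs(diffs)), 0.03)
  expect_lt(abs(mean(diffs)), 0.01)
})

test_that("emitted beta values are strictly inside (0,1) with no NaN", {
  co <- simulate_cohort(sim_config(n_probes = 300, seed = 3))
  expect_true(all(is.finite(co$matrix$beta)))
  expect_true(all(co$matrix$beta > 0 & co$matrix$beta < 1))
})

test_that("per-probe mean beta converges to inverse-logit(baseline)", {
  # 500 samples, no planted effects or random intercepts
  co <- simulate_cohort(sim_config(n_probes = 50,
                                   n_patients_per_group = 125,
                                   tumors_per_patient = 2,
                                   frac_dmp = 0, comp_amp = 0,
                                   block_amp = 0, sigma_slide = 0,
                                   sigma_patient = 0,
                                   detection_fail_rate = 0, seed = 15))
  expect_equal(ncol(co$matrix$beta), 500)
  mu <- plogis(co$truth$probe_baseline)
  expect_lt(max(abs(rowMeans(co$matrix$beta) - mu)), 0.02)
})

test_that("random-intercept variances recovered from the generator", {
  skip_if_not_installed("lme4")
  # intercepts are drawn per probe, so each probe is an independent
  # replicate; per-probe REML components averaged over probes (see
  # methods vignette for why this replaces raw level means)
  co <- simulate_cohort(sim_config(n_probes = 40,
                                   n_patients_per_group = 100,
                                   tumors_per_patient = 2, n_slides = 20,
                                   sigma_slide = 0.5, sigma_patient = 0.5,
                                   frac_dmp = 0, comp_amp = 0,
                                   block_amp = 0, detection_fail_rate = 0,
                                   seed = 11))
  s <- co$samples
  est <- vapply(seq_len(40), function(i) {
    d <- data.frame(y = qlogis(co$matrix$beta[i, ]),
                    slide = s$slide_id, patient = s$patient_id)
    fm <- suppressMessages(
      lme4::lmer(y ~ 1 + (1 | slide) + (1 | patient), data = d))
    vc <- as.data.frame(lme4::VarCorr(fm))
    c(patient = vc$vcov[vc$grp == "patient"],
      slide = vc$vcov[vc$grp == "slide"])
  }, numeric(2))
  expect_lt(abs(mean(est["patient", ]) - 0.25), 0.15 * 0.25)
  expect_lt(abs(mean(est["slide", ]) - 0.25), 0.15 * 0.25)
})

test_that("planted compartment blocks shape open-sea correlations", {
  co <- simulate_cohort(sim_config(n_probes = 1200,
                                   n_patients_per_group = 15,
                                   tumors_per_patient = 2,
                                   chrom_layout = c(chr1 = 5e6),
                                   frac_dmp = 0,
                                   frac_discordant_blocks = 0, seed = 6))
  man <- co$manifest[co$manifest$relation == "open_sea", ]
  sel <- co$samples$group == "CNF"
  expect_gte(sum(sel), 25)
  mv <- qlogis(co$matrix$beta[man$probe_id, sel])
  mv <- sweep(mv, 2, colMeans(mv))       # remove global sample offsets
  blk <- man$pos %/% 5e5 + 1
  tr <- co$truth$compartment_labels
  sg_by_blk <- tr$sign[tr$group == "CNF" & tr$chrom == "chr1"][seq(1, 50, 5)]
  # average probe-probe correlation within vs across blocks
  cm <- cor(t(mv))
  same_blk <- outer(blk, blk, "==") & row(cm) != col(cm)
  opp_sign <- outer(sg_by_blk[blk], sg_by_blk[blk], "!=")
  within <- mean(cm[same_blk])
  across_opp <- mean(cm[!same_blk & opp_sign])
  across_same <- mean(cm[!same_blk & !opp_sign & row(cm) != col(cm)])
  expect_gt(within, 0.15)
  expect_lt(across_opp, 0)          # anticorrelated A vs B
  expect_lt(abs(across_same), within)
})

test_that("fixture round-trips losslessly and truth counts match", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_probes = 1000, frac_dmp = 0.057,
                                   seed = 12))
  write_fixture(dir, co)
  back <- read_fixture(dir)
  expect_identical(back$matrix$beta, co$matrix$beta)
  expect_identical(back$matrix$detection_p, co$matrix$detection_p)
  expect_equal(back$samples, co$samples)
  expect_equal(back$manifest, co$manifest)
  # floor(frac_dmp * n_probes) planted probes listed in the truth record
  expect_length(back$truth$dmp_probe_ids, floor(0.057 * 1000))
  expect_true(all(back$truth$dmp_probe_ids %in% co$manifest$probe_id))
})

test_that("degenerate empty cohort writes and reads valid empty files", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_probes = 0, seed = 1))
  expect_equal(nrow(co$matrix$beta), 0)
  write_fixture(dir, co)
  back <- read_fixture(dir)
  expect_equal(nrow(back$matrix$beta), 0)
  expect_equal(nrow(back$manifest), 0)
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(frac_dmp = 1.2), "frac_dmp")
  expect_error(sim_config(phi = -1), "phi")
  expect_error(sim_config(sigma_slide = -0.1), "sigma_slide")
  expect_error(sim_config(chrom_layout = c(chr1 = -5)), "chrom_layout")
  expect_error(sim_config(dmr_blocks = list(list(chrom = "chr1"))),
               "dmr_blocks")
})

test_that("manifest island relations match a brute-force distance oracle", {
  co <- simulate_cohort(sim_config(n_probes = 400,
                                   chrom_layout = c(chr1 = 2e6), seed = 19))
  isl <- seq(50000, 2e6 - 1000, by = 50000)
  man <- co$manifest
  dist <- vapply(man$pos, function(p)
    min(pmax(isl - p, p - (isl + 999), 0)), numeric(1))
  expected <- ifelse(dist == 0, "island",
              ifelse(dist <= 2000, "shore",
              ifelse(dist <= 4000, "shelf", "open_sea")))
  expect_identical(man$relation, expected)
  # spec boundary semantics: >= 4 kb is open sea
  expect_true(all(dist[man$relation == "open_sea"] >= 4000))
  expect_true(all(dist[man$relation == "shelf"] < 4000))
})
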