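test_that("Kendall tau matches hand-enumerated and oracle values", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, c(3, 1, 2))$tau, -1 / 3)
  expect_equal(kendall_tau(3:1, 1:3)$tau, -1)
  set.seed(8)
  for (rep in 1:5) {                      # no ties: exact agreement
    n <- sample(10:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(kendall_tau(x, y)$tau, oracle_kendall(x, y))
  }
  for (rep in 1:5) {                      # ties: tau-b within 1e-12
    n <- sample(10:40, 1)
    x <- sample(1:5, n, TRUE); y <- sample(1:6, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_lt(abs(kendall_tau(x, y)$tau - oracle_kendall(x, y)), 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("tau is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(25); y <- rnorm(25)
  t0 <- kendall_tau(x, y)$tau
  expect_equal(kendall_tau(exp(x), y)$tau, t0)
  expect_equal(kendall_tau(x, y^3 + 5 * y)$tau, t0)
})

test_that("exact small-n p agrees with the permutation null", {
  # perfect concordance at n = 3: only 1 of 6 orderings as extreme both
  # ways -> two-sided exact p = 2/6
  r <- kendall_tau(1:3, 1:3)
  expect_equal(r$method, "exact")
  expect_equal(r$p, 2 / 6)
  r9 <- kendall_tau(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))
  expect_equal(r9$method, "normal")
})

test_that("delta-beta filter uses a strict 0.2 boundary", {
  rows <- rbind(a = c(0.10, 0.20, 0.35), b = c(0.40, 0.55, 0.45),
                c = c(0.10, 0.30, NA))
  out <- delta_beta_filter(rows)
  expect_equal(out$delta_beta, c(0.25, 0.15, 0.20), ignore_attr = TRUE)
  expect_identical(out$pass, c(TRUE, FALSE, FALSE))  # 0.20 is not > 0.2
})

test_that("constant size vectors yield a skipped record", {
  f <- fit_size_glmm(runif(12, 0.3, 0.6), rep(7, 12), age = rep(30, 12),
                     sex = rep(c("F", "M"), 6), patient = rep(1:6, 2))
  expect_false(f$converged)
  expect_match(f$reason, "constant size")
})

test_that("planted size slopes are recovered without material bias", {
  co <- simulate_cohort(sim_config(n_probes = 60,
                                   n_patients_per_group = 23,
                                   tumors_per_patient = 2,
                                   frac_size_probes = 1, frac_dmp = 0,
                                   size_effect_slope = 0.05,
                                   comp_amp = 0, block_amp = 0,
                                   detection_fail_rate = 0, seed = 27))
  s <- co$samples
  sel <- s$group == "CNF"
  est <- vapply(seq_len(60), function(i) {
    fit_size_glmm(co$matrix$beta[i, sel], s$size_mm[sel], s$age[sel],
                  s$sex[sel], s$patient_id[sel])$estimate
  }, numeric(1))
  truth_slopes <- co$truth$size_slopes[co$matrix$probe_ids]
  ok <- is.finite(est)
  bias <- mean(est[ok] * sign(truth_slopes[ok])) - 0.05
  expect_lt(abs(bias), 0.1 * 0.05)
})

test_that("shuffled sizes give a near-zero q < 0.05 hit rate", {
  co <- simulate_cohort(sim_config(n_probes = 150,
                                   n_patients_per_group = 15,
                                   tumors_per_patient = 2,
                                   frac_size_probes = 0, frac_dmp = 0,
                                   comp_amp = 0, block_amp = 0,
                                   detection_fail_rate = 0, seed = 28))
  res <- size_association(co$matrix, co$samples)
  hit <- mean(!is.na(res$q_model) & res$q_model < 0.05)
  expect_lte(hit, 0.07)
  expect_equal(sum(res$passes_filter), 0)
})

test_that("the size pipeline recovers planted probes and is order-stable", {
  co <- simulate_cohort(sim_config(n_probes = 120,
                                   n_patients_per_group = 23,
                                   tumors_per_patient = 2,
                                   frac_size_probes = 0.15, frac_dmp = 0,
                                   size_effect_slope = 0.06,
                                   comp_amp = 0, block_amp = 0,
                                   detection_fail_rate = 0, seed = 29))
  res <- size_association(co$matrix, co$samples)
  planted <- co$truth$size_probe_ids
  hits <- res$probe_id[res$passes_filter]
  expect_gte(mean(planted %in% hits), 0.7)
  expect_lte(sum(!(hits %in% planted)), 3)
  # composed filters are consistent with their recorded per-probe values
  expect_true(all(res$q_model[res$passes_filter] < 0.05))
  expect_true(all(res$q_tau[res$passes_filter] < 0.05))
  expect_true(all(res$delta_beta[res$passes_filter] > 0.2))
  # reordering probes never changes the surviving set
  perm <- rev(seq_len(nrow(co$matrix$beta)))
  bmp <- beta_matrix(co$matrix$beta[perm, ], co$matrix$detection_p[perm, ],
                     co$matrix$mask[perm, ])
  res2 <- size_association(bmp, co$samples)
  expect_setequal(res2$probe_id[res2$passes_filter], hits)
})
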