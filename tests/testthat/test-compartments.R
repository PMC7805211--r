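test_that("open-sea selection follows the manifest relation", {
  man <- data.frame(probe_id = c("a", "b", "c", "d"),
                    relation = c("open_sea", "shore", "island", "open_sea"))
  expect_identical(select_open_sea(man), c("a", "d"))
  # manifest with no islands: everything open sea, everything kept
  man2 <- data.frame(probe_id = c("x", "y"),
                     relation = c("open_sea", "open_sea"))
  expect_identical(select_open_sea(man2), c("x", "y"))
})

test_that("kNN imputation honours the 50% rule and neighbour averaging", {
  set.seed(6)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("p", 1:5), NULL))
  m[1, 1:6] <- NA                 # missing in 60% -> dropped
  m[3, 1] <- NA                   # imputable
  m[3, -1] <- m[2, -1]            # identical profile to p2 where shared
  out <- knn_impute(m, k = 1)
  expect_false("p1" %in% rownames(out))
  expect_false(anyNA(out))
  # k = 1 with an identical-profile neighbour copies its value
  expect_equal(unname(out["p3", 1]), unname(m[2, 1]))
  # no missing entries: identity
  full <- matrix(1:20, 4, 5)
  expect_equal(knn_impute(full), full)
})

test_that("bin medians follow the stated half-open convention", {
  m <- matrix(c(1, 2, 9), 3, 1)
  b <- bin_median(m, positions = c(10, 20, 30))
  expect_equal(b$binned[1, 1], 2)
  # single probe in a bin: its own value
  b2 <- bin_median(matrix(5, 1, 1), positions = 42)
  expect_equal(b2$binned[1, 1], 5)
  # position 100,000 opens the second bin; 99,999 stays in the first
  b3 <- bin_median(matrix(c(1, 3), 2, 1), positions = c(99999, 100000))
  expect_equal(nrow(b3$binned), 2)
  expect_equal(b3$binned[, 1], c(1, 3))
  expect_equal(b3$bin_start, c(0, 100000))
  expect_error(bin_median(matrix(1, 1, 1), positions = c(1, 2)), "length")
})

test_that("two-block structure is recovered by the track eigenvector", {
  set.seed(9)
  truth_sign <- rep(c(1, -1), each = 20)
  lat <- rnorm(30)
  binned <- outer(truth_sign, lat) + matrix(rnorm(40 * 30, 0, 0.6), 40, 30)
  tr <- infer_track(binned, "chr1", "CNF", n_probes = rep(5L, 40))
  acc <- mean(sign(tr$eigen) == truth_sign)
  expect_gte(acc, 0.95)
  # permuting samples leaves the track unchanged
  tr2 <- infer_track(binned[, sample(30)], "chr1", "CNF",
                     n_probes = rep(5L, 40))
  expect_equal(tr2$eigen, tr$eigen)
  # identical input for a second group: identical track, zero discordance
  trb <- infer_track(binned, "chr1", "PNF", n_probes = rep(5L, 40))
  dc <- call_discordance(tr, trb)
  expect_equal(dc$counts[["discordant"]], 0)
  expect_equal(dc$concordance, 1)
})

test_that("degenerate track inputs raise informative errors", {
  expect_error(infer_track(matrix(1, 20, 2), "chr1", "CNF"), "3 samples")
  expect_error(infer_track(matrix(rnorm(10), 5, 10), "chr1", "CNF"),
               "informative bins")
  # zero-variance bins are excluded and reported missing
  set.seed(2)
  b <- matrix(rnorm(20 * 12), 20, 12)
  b[7, ] <- 3
  tr <- infer_track(b, "chr1", "CNF")
  expect_true(is.na(tr$eigen[7]))
  expect_true(is.na(tr$label[7]))
})

test_that("discordance boundary semantics follow the 0.02 retention rule", {
  mk <- function(e, g) {
    d <- data.frame(group = g, chrom = "chr1", bin = seq_along(e),
                    start = 0, eigen = e,
                    label = ifelse(e > 0, "A", "B"), n_probes = 5L)
    class(d) <- c("compartment_track", "data.frame")
    d
  }
  a <- mk(c(0.05, 0.01, 0.05, 0.02, NA), "CNF")
  b <- mk(c(-0.05, -0.30, 0.30, -0.02, 0.5), "PNF")
  dc <- call_discordance(a, b)
  expect_identical(dc$calls$status,
                   c("discordant",   # opposite signs, both pass
                     "filtered",     # |0.01| < 0.02 in one group
                     "concordant",
                     "discordant",   # exactly 0.02 is retained (>=)
                     "filtered"))    # missing bin
  expect_equal(sum(dc$counts), nrow(dc$calls))   # exact partition
  expect_equal(dc$concordance, 1 / 3)
  expect_error(call_discordance(a, mk(0.1, "PNF")), "bin grids")
})

test_that("full compartment analysis recovers planted discordance", {
  co <- simulate_cohort(sim_config(n_probes = 1600,
                                   n_patients_per_group = 15,
                                   tumors_per_patient = 2,
                                   chrom_layout = c(chr1 = 4e6, chr2 = 3e6),
                                   frac_dmp = 0,
                                   frac_discordant_blocks = 0.2,
                                   seed = 44))
  res <- compartment_analysis(co$matrix, co$samples, co$manifest)
  expect_equal(sum(res$counts), nrow(res$calls))
  td <- paste(co$truth$discordant_bins$chrom, co$truth$discordant_bins$bin)
  called <- with(res$calls, paste(chrom, bin)[status == "discordant"])
  expect_gte(mean(td %in% called), 0.8)
  # per-chromosome independence: analysis restricted to chr1 probes
  # reproduces the chr1 portion of the genome-wide run
  sel <- which(co$matrix$probe_ids %in%
                 co$manifest$probe_id[co$manifest$chrom == "chr1"])
  bm1 <- beta_matrix(co$matrix$beta[sel, ], co$matrix$detection_p[sel, ],
                     co$matrix$mask[sel, ])
  res1 <- compartment_analysis(bm1, co$samples,
                               co$manifest[co$manifest$chrom == "chr1", ])
  full_chr1 <- res$tracks[res$tracks$chrom == "chr1", ]
  rownames(full_chr1) <- NULL
  rownames(res1$tracks) <- NULL
  expect_equal(res1$tracks, full_chr1)
})
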