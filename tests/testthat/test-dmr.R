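test_that("kernel smoothing matches hand-evaluated weight formulas", {
  # isolated probe: all neighbours far outside the kernel support
  r <- kernel_smooth(c(1000, 50000), c(3, 1), lambda = 1000, C = 2)
  expect_equal(r$smoothed[1], 9)
  expect_equal(r$df[1], 1)
  # two probes at the same position: smoothed = (a^2 + b^2) / 2, df = 2
  r2 <- kernel_smooth(c(500, 500), c(2, 4), lambda = 1000, C = 2)
  expect_equal(r2$smoothed, c(10, 10))
  expect_equal(r2$df, c(2, 2))
  # constant stats: weighted mean of a constant is the constant squared
  pos <- sort(sample(1:10000, 20))
  rc <- kernel_smooth(pos, rep(3, 20))
  expect_equal(rc$smoothed, rep(9, 20))
  # single probe
  r1 <- kernel_smooth(5000, 2.5)
  expect_equal(r1$smoothed, 6.25)
  expect_equal(r1$df, 1)
  expect_error(kernel_smooth(c(5, 1), c(1, 1)), "sorted")
  expect_error(kernel_smooth(c(1, 2), c(1, NA)), "finite")
})

test_that("kernel smoothing is shift-invariant and df stays in range", {
  set.seed(7)
  pos <- sort(sample(1:50000, 60))
  st <- rnorm(60)
  a <- kernel_smooth(pos, st)
  b <- kernel_smooth(pos + 123456, st)
  expect_equal(a, b)
  expect_true(all(a$df >= 1 - 1e-9))
  expect_true(all(a$df <= 60))
})

test_that("region chaining respects gap and min_cpgs rules", {
  mk <- function(pos, stat) data.frame(
    probe_id = sprintf("p%02d", seq_along(pos)), chrom = "chr1",
    pos = pos, stat = stat, fc = 3)
  # background of null probes plus 3 significant at 1 kb spacing
  bg <- mk(seq(100000, 395000, by = 5000), rep(0.1, 60))
  sig <- mk(c(50000, 51000, 52000), c(10, 10, 10))
  r <- call_regions(rbind(sig, bg), lambda = 1000, C = 2, gap = 1000)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_probes, 3)
  expect_equal(c(r$start, r$end), c(50000, 52000))
  # two significant probes 5 kb apart: runs of one probe, discarded
  sig2 <- mk(c(50000, 55000), c(10, 10))
  r2 <- call_regions(rbind(sig2, bg), gap = 1000)
  expect_equal(nrow(r2), 0)
  # input order never matters
  shuf <- rbind(sig, bg)[sample(63), ]
  expect_equal(call_regions(shuf, gap = 1000), r)
})

test_that("fold-change filter is two-sided on the log scale", {
  dmrs <- data.frame(chrom = "chr1", start = 1:3 * 10, end = 1:3 * 10 + 5,
                     n_probes = 2, region_q = 0.01,
                     max_fc = c(2.5, 1.0, 0.4))
  attr(dmrs, "members") <- list("a", "b", "c")
  out <- filter_fold_change(dmrs)
  expect_equal(out$max_fc, c(2.5, 0.4))
  expect_identical(attr(out, "members"), list("a", "c"))
  expect_error(filter_fold_change(dmrs, min_fc = 1), "min_fc")
})

test_that("context annotation equals a brute-force recount", {
  man <- data.frame(
    probe_id = sprintf("p%02d", 1:8),
    chrom = rep(c("chr1", "chr2"), each = 4),
    relation = c("island", "open_sea", "shore", "open_sea",
                 "shelf", "open_sea", "open_sea", "island"),
    promoter = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    enhancer = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  dmrs <- data.frame(chrom = c("chr1", "chr2"), start = c(1, 1),
                     end = c(100, 100), n_probes = c(4, 4),
                     region_q = 0.01, max_fc = 3)
  attr(dmrs, "members") <- list(sprintf("p%02d", 1:4), sprintf("p%02d", 5:8))
  ann <- annotate_context(dmrs, man)
  # independent recount: category hit iff any member probe carries it
  for (k in 1:2) {
    ids <- attr(dmrs, "members")[[k]]
    rel <- man$relation[man$probe_id %in% ids]
    expect_equal(ann$dmrs$island[k], "island" %in% rel)
    expect_equal(ann$dmrs$shore[k], "shore" %in% rel)
    expect_equal(ann$dmrs$shelf[k], "shelf" %in% rel)
    expect_equal(ann$dmrs$promoter[k],
                 any(man$promoter[man$probe_id %in% ids]))
    expect_equal(ann$dmrs$enhancer[k],
                 any(man$enhancer[man$probe_id %in% ids]))
  }
  expect_equal(unname(ann$context_counts),
               c(2, 1, 1, 2, 1))       # island, shore, shelf, prom, enh
  # a DMR of open-sea promoter probes flags promoter only
  d1 <- dmrs[1, ]; attr(d1, "members") <- list("p02")
  a1 <- annotate_context(d1, man)
  expect_true(a1$dmrs$promoter)
  expect_false(any(a1$dmrs$island, a1$dmrs$shore, a1$dmrs$shelf,
                   a1$dmrs$enhancer))
  # empty region list gives an all-zero distribution
  e <- annotate_context(dmrs[0, ], man)
  expect_true(all(e$context_counts == 0))
})

test_that("top-DMR ranking orders by |log fc| then region_q", {
  dmrs <- data.frame(chrom = "chr1", start = 1:4, end = 2:5, n_probes = 2,
                     region_q = c(0.04, 0.01, 0.02, 0.03),
                     max_fc = c(3, 0.25, 4, 4))
  attr(dmrs, "members") <- as.list(letters[1:4])
  top <- top_dmrs(dmrs, 3)
  # |log 0.25| = |log 4|: tie broken by q -> b before c ties? q(b)=.01 < q(c)=.02
  expect_equal(top$start, c(2, 3, 4))
})

test_that("BED export converts to 0-based half-open coordinates", {
  dir <- withr::local_tempdir()
  dmrs <- data.frame(chrom = "chr1", start = 101, end = 200, n_probes = 3,
                     region_q = 1e-3, max_fc = 3)
  p <- file.path(dir, "d.bed")
  write_dmr_bed(dmrs, p)
  bed <- read.table(p, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
  expect_equal(bed$V5, 30)           # -10 log10(1e-3)
})
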