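library(data.table)

test_that("STARR calls use the summit fold change with pseudocounts", {
  sig <- signal_track(data.table(chrom = "chr1", start = 0L, end = 2000L,
                                 value = 12))
  inp <- signal_track(data.table(chrom = "chr1", start = 0L, end = 2000L,
                                 value = 3))
  dhs <- data.table(id = "d1", chrom = "chr1", start = 900L, end = 1100L)
  call <- starr_call(dhs, sig, inp)
  expect_equal(call$lfc, log2(13 / 4))           # ~1.700
  expect_true(call$active)
  # signal == input everywhere -> lfc 0, inactive
  call0 <- starr_call(dhs, sig, sig)
  expect_equal(call0$lfc, 0)
  expect_false(call0$active)

  # summit equals a brute-force argmax over the 401-bp window
  set.seed(17)
  for (rep in 1:10) {
    vals <- rpois(40, 5)
    spans <- data.table(chrom = "chr1", start = seq(800L, 1190L, 10L),
                        end = seq(810L, 1200L, 10L), value = vals)
    tr <- signal_track(spans)
    cl <- starr_call(dhs, tr, inp)
    base <- track_value(tr, "chr1", 800:1200)
    mid <- 1000; half <- 200
    w <- (mid - half):(mid + half)
    v <- track_value(tr, "chr1", w)
    expect_equal(cl$summit, w[which.max(v)])
    expect_equal(cl$lfc, log2((max(v) + 1) /
                                (track_value(inp, "chr1",
                                             w[which.max(v)]) + 1)))
  }
  # monotonicity: raising the summit signal never lowers the lfc
  hi <- signal_track(data.table(chrom = "chr1", start = 0L, end = 2000L,
                                value = 20))
  expect_gt(starr_call(dhs, hi, inp)$lfc, call$lfc)
})

test_that("class-STARR crosstab recovers planted coupling; Fisher matches brute force", {
  # 2x2 Fisher: sample odds ratio and hypergeometric p by hand
  m <- matrix(c(10, 90, 50, 850), 2, byrow = TRUE)
  f <- fisher.test(m)
  expect_equal((10 * 850) / (90 * 50), 1.889, tolerance = 1e-3)
  # brute-force two-sided hypergeometric p
  probs <- dhyper(0:60, 60, 940, 100)
  p_bf <- sum(probs[probs <= dhyper(10, 60, 940, 100) * (1 + 1e-7)])
  expect_equal(f$p.value, p_bf, tolerance = 1e-9)

  # planted coupling: stable classes hkCP-active, unstable dCP-active
  set.seed(3)
  n <- 300
  classes <- data.table(id = sprintf("d%03d", 1:n),
                        class = sample(tre_classes(), n, replace = TRUE))
  stable <- classes$class %in% tre_classes()[1:3]
  hk <- data.table(id = classes$id, summit = 0L, lfc = 0,
                   active = stable & runif(n) < 0.8)
  dcp <- data.table(id = classes$id, summit = 0L, lfc = 0,
                    active = !stable & runif(n) < 0.8)
  enr <- class_starr_enrichment(classes, hk, dcp)
  pr <- enr$proportions
  expect_gt(mean(pr[tre_classes()[1:3], "hkCP_only"]),
            mean(pr[tre_classes()[4:6], "hkCP_only"]))
  expect_gt(mean(pr[tre_classes()[4:6], "dCP_only"]),
            mean(pr[tre_classes()[1:3], "dCP_only"]))
  expect_true(all(enr$fisher_dcp[tre_classes()[4:6], "p"] < 0.01))
  # all calls inactive -> everything in the inactive column
  none <- copy(hk)[, active := FALSE]
  enr0 <- class_starr_enrichment(classes, none, copy(none))
  expect_true(all(enr0$table[, "inactive"] == table(classes$class)))
})

test_that("binned association reports Spearman rho with average-rank ties", {
  x <- seq(0, 10, length.out = 100)
  ba <- binned_association(x, x)
  expect_equal(ba$rho, 1)
  # independent pairs: |rho| small
  set.seed(20)
  ba0 <- binned_association(rnorm(1000), rnorm(1000))
  expect_lt(abs(ba0$rho), 0.1)
  # ties fixture: rho equals rank-then-Pearson with average ranks
  xt <- c(1, 1, 2, 2, 2, 3, 4, 4, 5, 6, 6, 6, 7, 8, 8, 9, 10, 10, 11, 12)
  set.seed(21)
  yt <- round(xt + rnorm(20, 0, 2))
  bat <- binned_association(xt, yt, n_bins = 4)
  expect_equal(bat$rho, cor(rank(xt), rank(yt)))
  # per-bin summaries partition the truncated range
  expect_equal(sum(bat$bins$n), sum(xt >= quantile(xt, 0.01) &
                                      xt <= quantile(xt, 0.99)))
  # constant x -> NA sentinel
  expect_true(is.na(binned_association(rep(1, 50), rnorm(50))$rho))
  expect_error(binned_association(1:5, 1:5), "at least 10")
})

test_that("mark proportions use the +/-100 bp summit window inclusively", {
  summits <- data.table(id = c("a", "b"), chrom = "chr1",
                        pos = c(1000L, 5000L))
  classes <- data.table(id = c("a", "b"), class = c("X", "Y"))
  marks <- list(
    covering = data.table(chrom = "chr1", start = 990L, end = 1010L),
    adjacent = data.table(chrom = "chr1", start = 1101L, end = 1151L))
  mp <- mark_proportions(classes, summits, marks, flank = 100L)
  expect_true(mp$presence[id == "a", covering])
  expect_false(mp$presence[id == "a", adjacent])   # 101 bp away: absent
  expect_false(mp$presence[id == "b", covering])
  # boundary: a mark ending exactly at summit - 100 overlaps base -100
  edge <- list(m = data.table(chrom = "chr1", start = 850L, end = 901L))
  expect_true(mark_proportions(classes, summits, edge)$presence[
    id == "a", m])

  # hand-counted 12-DHS fixture
  set.seed(2)
  su <- data.table(id = sprintf("s%02d", 1:12), chrom = "chr1",
                   pos = seq(1000L, 12000L, 1000L))
  cl <- data.table(id = su$id, class = rep(c("P", "Q"), 6))
  mk <- list(h = data.table(chrom = "chr1",
                            start = c(980L, 2950L, 5080L, 11990L),
                            end = c(1020L, 2990L, 5120L, 12030L)))
  got <- mark_proportions(cl, su, mk)$proportions
  # hits: s01 (P), s03 (P), s05 (P), s12 (Q) -> P: 3/6, Q: 1/6
  expect_equal(unname(got["P", "h"]), 3 / 6)
  expect_equal(unname(got["Q", "h"]), 1 / 6)
})

test_that("footprint profiles mask neighboring DHSs and estimate background", {
  genome <- c(chr1 = 100000)
  su <- data.table(id = "d1", chrom = "chr1", pos = 50000L)
  dhs_all <- data.table(id = c("d1", "d2"), chrom = "chr1",
                        start = c(49900L, 50110L), end = c(50100L, 50160L))
  # marks everywhere -> observed presence 1 in all unmasked bins
  dense <- data.table(chrom = "chr1",
                      start = seq(0L, 99950L, 50L),
                      end = seq(50L, 100000L, 50L))
  fp <- footprint_profile(su, dense, dhs_all, genome, bin = 50L,
                          max_dist = 1000L, n_randomizations = 3,
                          seed = 2)
  expect_true(all(fp$mean_presence == 1))
  # bins overlapping the neighbor DHS (d2 at +110..+160) are excluded
  expect_false(100 %in% fp$bin_start)
  expect_false(150 %in% fp$bin_start)
  expect_true(-1000 %in% fp$bin_start)
  # no marks -> all-zero profile and (near-)zero background
  none <- data.table(chrom = "chr1", start = 10L, end = 11L)
  fp0 <- footprint_profile(su, none, dhs_all, genome, bin = 50L,
                           max_dist = 500L, n_randomizations = 5,
                           seed = 2)
  expect_true(all(fp0$mean_presence == 0))
  expect_lt(max(fp0$bg_mean), 0.05)
  # background converges to the global mark density
  half <- data.table(chrom = "chr1",
                     start = seq(0L, 99900L, 100L),
                     end = seq(50L, 99950L, 100L))  # 50% coverage
  fph <- footprint_profile(su, half, dhs_all, genome, bin = 50L,
                           max_dist = 500L, n_randomizations = 10,
                           seed = 3)
  expect_lt(abs(mean(fph$bg_mean) - mean(fph$mean_presence)), 0.15)
})
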