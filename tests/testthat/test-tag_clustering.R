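library(data.table)

test_that("tag cluster calling trims and splits as specified", {
  # single position -> width-1 TC
  tc <- call_tag_clusters(make_pooled(100, 5))
  expect_equal(tc[, .(start, end, summit, count)],
               data.table(start = 100L, end = 101L, summit = 100L,
                          count = 5))

  # [1, 10, 1] with trim_fraction 0.1: edges equal the threshold
  # (strict <), so the TC stays width 3
  tc <- call_tag_clusters(make_pooled(100:102, c(1, 10, 1)),
                          trim_fraction = 0.1)
  expect_equal(tc$start, 100L)
  expect_equal(tc$end, 103L)
  expect_equal(tc$summit, 101L)
  # but a lower edge is trimmed
  tc <- call_tag_clusters(make_pooled(100:102, c(0.9, 10, 1)),
                          trim_fraction = 0.1)
  expect_equal(tc$start, 101L)

  # [8, 1, 0, 0, 9]: valley below 0.2 * min(8, 9) -> two single-summit TCs
  tc <- call_tag_clusters(make_pooled(c(100, 101, 104), c(8, 1, 9)),
                          valley_fraction = 0.2)
  expect_equal(nrow(tc), 2L)
  expect_equal(tc$summit, c(100L, 104L))
  expect_equal(sum(tc$count), 18)

  # empty and non-pooled input
  expect_equal(nrow(call_tag_clusters(make_pooled(integer(), numeric()))),
               0L)
  expect_error(call_tag_clusters(data.table(chrom = "c", pos = 1L,
                                            strand = "+", c1 = 2L)),
               "pooled")
})

test_that("merging matches an exhaustive single-linkage oracle and splitting partitions counts", {
  # naive O(n^2) single-linkage grouping oracle
  naive_groups <- function(pos, merge_dist) {
    n <- length(pos)
    g <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n))
        if (abs(pos[i] - pos[j]) <= merge_dist && g[i] != g[j]) {
          g[g == g[j]] <- g[i]; changed <- TRUE
        }
      if (!changed) break
    }
    match(g, unique(g[order(pos)]))
  }
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample(1:2000, sample(20:200, 1)))
    cnt <- rpois(length(pos), 6) + 1
    md <- sample(c(5L, 20L, 50L), 1)
    # zero fractions: no trimming or splitting, pure merge behavior
    tcs <- call_tag_clusters(make_pooled(pos, cnt), merge_dist = md,
                             trim_fraction = 0, valley_fraction = 0)
    g <- naive_groups(pos, md)
    expect_equal(nrow(tcs), length(unique(g)))
    expect_equal(tcs$count, as.numeric(tapply(cnt, g, sum)))
    expect_equal(tcs$start, as.integer(tapply(pos, g, min)))
  }

  # split partitions the trimmed parent and is idempotent
  set.seed(7)
  for (rep in 1:20) {
    pos <- sort(sample(1:300, 40))
    cnt <- rpois(40, 4) + 1
    parent_kept <- call_tag_clusters(make_pooled(pos, cnt),
                                     merge_dist = 400L,
                                     trim_fraction = 0,
                                     valley_fraction = 0.3)
    expect_equal(sum(parent_kept$count), sum(cnt))   # partition
    expect_true(all(diff(parent_kept$start) > 0))    # ordered
    expect_true(all(head(parent_kept$end, -1) <=
                      tail(parent_kept$start, -1)))  # disjoint
    # idempotence: re-clustering each TC's own CTSS subset is a no-op
    for (i in seq_len(nrow(parent_kept))) {
      sub <- pos >= parent_kept$start[i] & pos < parent_kept$end[i]
      again <- call_tag_clusters(make_pooled(pos[sub], cnt[sub]),
                                 merge_dist = 400L,
                                 trim_fraction = 0,
                                 valley_fraction = 0.3)
      expect_equal(nrow(again), 1L)
      expect_equal(again$summit, parent_kept$summit[i])
      expect_equal(again$count, parent_kept$count[i])
    }
  }
})

test_that("quantification counts strand-matched tags and normalizes to TPM", {
  libs <- libraries(c("c1", "k1"), c("control", "exosomeKD"), c(1, 1),
                    total_mapped_tags = c(1e6, 2e6))
  ctss <- data.table(chrom = "chr1", pos = c(100L, 101L, 150L),
                     strand = c("+", "+", "-"),
                     c1 = c(3L, 4L, 9L), k1 = c(1L, 0L, 2L))
  tcs <- data.table(chrom = "chr1", strand = "+", start = 100L,
                    end = 102L, summit = 101L, count = 8)
  q <- quantify_and_normalize(tcs, ctss, libs)
  expect_equal(q$count_c1, 7)          # {3, 4} summed; minus tag ignored
  expect_equal(q$tpm_c1, 7)            # total 1e6
  expect_equal(q$tpm_k1, 0.5)          # total 2e6
  bad <- copy(libs)[1, total_mapped_tags := 0]
  expect_error(quantify_and_normalize(tcs, ctss, bad), "total_mapped")
  expect_error(quantify_and_normalize(tcs, ctss[, .(chrom, pos, strand, c1)],
                                      libs), "missing")
})

test_that("annotation follows sense distance, PROMPT geometry and tie-breaks", {
  tss <- data.table(chrom = "chr1", pos = c(300L, 400L, 850L, 1100L),
                    strand = c("+", "+", "+", "+"),
                    id = c("g1", "g2", "g3", "g4"),
                    biotype = c("mRNA", "mRNA", "mRNA", "ncRNA"))
  tcs <- data.table(chrom = "chr1", strand = c("+", "-", "+"),
                    start = c(99L, 99L, 2000L), end = c(102L, 102L, 2002L),
                    summit = c(100L, 100L, 2001L), count = 1)
  ann <- annotate_tcs(tcs, tss)
  expect_equal(ann$annotation[1], "mRNA_TSS")   # |100-300| = 200 <= 250
  expect_equal(ann$annotation[2], "PROMPT")     # antisense, 300 <= 500
  expect_equal(ann$annotation[3], "distal")

  # equidistant mRNA/ncRNA at 250 -> smaller-coordinate TSS wins
  tie_tss <- data.table(chrom = "chr1", pos = c(850L, 1350L),
                        strand = "+", id = c("gm", "gn"),
                        biotype = c("mRNA", "ncRNA"))
  tie <- data.table(chrom = "chr1", strand = "+", start = 1099L,
                    end = 1102L, summit = 1100L, count = 1)
  ann2 <- annotate_tcs(tie, tie_tss)
  expect_equal(ann2$annotation, "mRNA_TSS")
  # same geometry with the ncRNA upstream -> ncRNA wins the tie
  tie_tss2 <- copy(tie_tss)[, biotype := rev(biotype)]
  expect_equal(annotate_tcs(tie, tie_tss2)$annotation, "ncRNA_TSS")
})

test_that("divergence distances and head-to-head search are strand-aware", {
  tcs <- data.table(
    chrom = "chr1",
    strand = c("-", "+", "+", "+", "-", "-"),
    start = c(795L, 995L, 2000L, 3000L, 1600L, 2100L),
    end = c(805L, 1005L, 2005L, 3005L, 1610L, 2110L),
    summit = c(800L, 1000L, 2002L, 3002L, 1602L, 2102L), count = 1)
  dp <- divergence_profile(tcs, threshold = 500)
  # plus TC at 1000: nearest non-overlapping upstream minus summit 800
  expect_equal(dp$distances[1], 200)
  expect_true(dp$divergent[1])
  # plus TC at 2002: minus TC at 1602 -> 400; at 3002: minus 2102 -> 900
  expect_equal(dp$distances[2:3], c(400, 900))
  expect_equal(dp$divergent[2:3], c(TRUE, FALSE))
  # cumulative fraction at 500 bp counts 2 of 3 plus TCs
  cf <- dp$curve[distance <= 500][.N, cum_fraction]
  expect_equal(cf, 2 / 3)
  expect_true(all(diff(dp$curve$cum_fraction) >= 0))
  # no upstream minus TC -> unidirectional
  solo <- data.table(chrom = "chr9", strand = "+", start = 10L, end = 12L,
                     summit = 11L, count = 1)
  expect_true(is.na(divergence_profile(rbind(tcs, solo))$distances[4]))

  tssx <- data.table(chrom = "chr1", pos = c(4000L, 9000L),
                     strand = c("-", "+"), id = c("gA", "gB"),
                     biotype = "mRNA")
  d <- head_to_head_distance(
    data.table(chrom = "chr1", pos = c(5000L, 100L), strand = c("+", "+")),
    tssx)
  expect_equal(d[1], 1000)   # + summit 5000, upstream antisense TSS 4000
  expect_equal(d[2], Inf)    # nothing upstream
})
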