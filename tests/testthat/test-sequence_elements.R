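library(data.table)

# exhaustive enumeration oracle: p-values over all 4^L words, using the
# same score-equality tolerance convention as the DP (tol/2 in bits)
enum_pvalue <- function(motif, s, tol = 1e-7) {
  L <- ncol(motif$mat)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- apply(words, 1, function(w)
    sum(motif$score_mat[cbind(w, seq_len(L))]))
  pr <- apply(words, 1, function(w) prod(motif$background[w]))
  vapply(s, function(x) sum(pr[sc >= x - tol / 2]), 0)
}

test_that("exact motif p-values match exhaustive enumeration", {
  mots <- builtin_motifs()
  set.seed(8)
  rnd <- matrix(rexp(4 * 5), 4, 5)
  rnd <- sweep(rnd, 2, colSums(rnd), "/")
  cases <- list(mots$polyA, mots$Inr,
                motif_model("rnd", rnd, c(0.3, 0.2, 0.2, 0.3)))
  for (m in cases) {
    ptab <- motif_pvalue_table(m)
    # query at every attainable score, at midpoints between adjacent
    # attainable scores, and beyond the maximum
    sup <- ptab$support
    qs <- c(sup, (sup[-1] + head(sup, -1)) / 2, max(sup) + 1)
    expect_lt(max(abs(ptab$pvalue(qs) - enum_pvalue(m, qs))), 1e-9)
    # minimum attainable score has p-value 1
    expect_equal(ptab$pvalue(min(ptab$support)), 1)
  }
  # length-1 motif, uniform background: p of the best base = 0.25
  m1 <- motif_from_consensus("one", "A")
  expect_equal(motif_pvalue_table(m1)$pvalue(max(m1$score_mat[, 1])),
               0.25)
  expect_error(motif_model("bad", matrix(0.3, 4, 2)), "sum to 1")
  expect_error(motif_model("bg", matrix(0.25, 4, 2),
                           background = c(0.5, 0.5, 0.5, 0.5)),
               "not normalized")
})

test_that("motif models survive a minimal-MEME round trip", {
  dir <- withr_local_tempdir()
  mots <- builtin_motifs()[c("TATA", "polyA", "donor5SS")]
  p <- file.path(dir, "m.meme")
  write_meme(mots, p)
  back <- read_meme(p)
  expect_equal(names(back), names(mots))
  for (nm in names(mots))
    expect_lt(max(abs(back[[nm]]$mat - mots[[nm]]$mat)), 1e-4)
})

test_that("window scans find planted elements and respect strand orientation", {
  len <- c(chrA = 4000L)
  genome <- random_genome(len, seed = 5)
  mots <- builtin_motifs()[c("TATA", "Inr")]
  # plant a TATA instance starting at offset -30 from a plus summit
  seqs <- as.character(genome)
  seqs <- divtx:::write_instance(seqs[["chrA"]], "CTATAAATA", 2000L, "+",
                                 -30L)
  genome <- Biostrings::DNAStringSet(c(chrA = seqs))
  summits <- data.table(id = "d1", strand_role = "major", chrom = "chrA",
                        pos = 2000L, strand = "+")
  hits <- scan_windows(genome, summits, mots)
  th <- hits[motif == "TATA"]
  expect_true(th$significant)
  expect_equal(th$offset, -30L)
  expect_lt(th$p_value, 0.001)
  # at most one (max-score) hit per motif and window
  expect_equal(nrow(hits), 2L)

  # strand symmetry: the same instance on the minus strand of the
  # reverse-complemented genome gives the identical hit
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- names(genome)
  rc_pos <- len[["chrA"]] - 1L - 2000L
  hits_rc <- scan_windows(rc, data.table(id = "d1", strand_role = "major",
                                         chrom = "chrA", pos = rc_pos,
                                         strand = "-"), mots)
  expect_equal(hits_rc[motif == "TATA", .(offset, score)],
               th[, .(offset, score)])

  # stringent threshold on random sequence: no significant hits
  rnd_summits <- data.table(id = paste0("r", 1:5), strand_role = "major",
                            chrom = "chrA",
                            pos = c(500L, 900L, 1300L, 2900L, 3300L),
                            strand = "+")
  h0 <- scan_windows(genome, rnd_summits, mots, p_threshold = 1e-9)
  expect_true(!any(h0$significant))

  # positional profile: planted offset recovered as a point mass
  prof <- positional_profile(hits, n_elements = 1)
  expect_equal(prof[motif == "TATA", .(offset, fraction)],
               data.table(offset = -30L, fraction = 1))
  expect_equal(nrow(positional_profile(h0, 5)), 0L)
})

test_that("core-promoter composition clustering separates planted regimes", {
  # two planted regimes in score space -> k = 2 separates them
  set.seed(12)
  n <- 60
  hits <- rbindlist(lapply(1:n, function(i) {
    strong_tata <- i <= n / 2
    data.table(id = sprintf("d%03d", i), strand_role = "major",
               motif = c("TATA", "DRE"),
               offset = 0L,
               score = c(ifelse(strong_tata, 8, -20) + rnorm(1, 0, 0.5),
                         ifelse(strong_tata, -20, 7) + rnorm(1, 0, 0.5)),
               p_value = 1e-4, significant = TRUE, truncated = FALSE)
  }))
  mots <- builtin_motifs()[c("TATA", "DRE")]
  classes <- data.table(id = sprintf("d%03d", 1:n),
                        class = rep(c("A", "B"), each = n / 2))
  cc <- cluster_core_promoters(hits, mots, classes, k = 2)
  split_tab <- table(cc$cluster$cluster,
                     rep(c("A", "B"), each = n / 2))
  expect_true(all(apply(split_tab, 1,
                        function(r) max(r) / sum(r)) == 1))  # pure clusters
  # enrichment of a class identical to the whole set is 0 everywhere
  one <- copy(classes)[, class := "same"]
  cc1 <- cluster_core_promoters(hits, mots, one, k = 2)
  expect_true(all(abs(cc1$enrichment) < 1e-12))
  # constant score matrix -> degenerate scaling error
  hc <- copy(hits)[, score := 1][, significant := TRUE]
  expect_error(cluster_core_promoters(hc, mots, k = 2), "degenerate")
})

test_that("downstream processing profiles match a naive string-match oracle", {
  len <- c(chrB = 60000L)
  genome <- random_genome(len, seed = 9)
  set.seed(13)
  summits <- data.table(chrom = "chrB",
                        pos = sort(sample(1000:28000, 40)),
                        strand = sample(c("+", "-"), 40, replace = TRUE))
  bg <- data.table(chrom = "chrB", pos = sort(sample(30000:58000, 40)),
                   strand = sample(c("+", "-"), 40, replace = TRUE))
  prof <- downstream_processing_profile(genome, summits, bg, "polyA",
                                        max_window = 600, step = 100)
  # oracle: AWTAAA match starts from Biostrings::matchPattern (counts
  # overlapping occurrences), same start-in-window convention
  oracle_rate <- function(pts, w) {
    counts <- vapply(seq_len(nrow(pts)), function(i) {
      s <- divtx:::oriented_window(genome, pts$chrom[i], pts$pos[i],
                                   pts$strand[i], up = 0L, down = 599L)
      st <- Biostrings::start(Biostrings::matchPattern(
        "AWTAAA", Biostrings::DNAString(s$seq), fixed = FALSE))
      sum(st - 1L < w)
    }, 0)
    mean(counts / w)
  }
  for (wq in c(100, 400, 600)) {
    expect_equal(prof$signal_rate[prof$w == wq],
                 oracle_rate(summits, wq), tolerance = 1e-12)
  }
  expect_equal(prof$excess, prof$signal_rate - prof$bg_rate)

  # all-C downstream sequence: profile equals minus the background rate
  cg <- Biostrings::DNAStringSet(c(chrC = paste(rep("C", 5000),
                                                collapse = "")))
  pc <- downstream_processing_profile(
    cg, data.table(chrom = "chrC", pos = 100L, strand = "+"),
    data.table(chrom = "chrC", pos = 3000L, strand = "+"),
    "polyA", max_window = 500, step = 100)
  expect_true(all(pc$signal_rate == 0))
  expect_equal(pc$excess, -pc$bg_rate)

  # 5'SS profile detects planted donors above background
  seqs <- as.character(genome)[["chrB"]]
  for (i in seq_len(nrow(summits)))
    seqs <- divtx:::write_instance(seqs, "CAGGTAAGT", summits$pos[i],
                                   summits$strand[i], 60L)
  g2 <- Biostrings::DNAStringSet(c(chrB = seqs))
  p5 <- downstream_processing_profile(g2, summits, bg, "five_prime_SS",
                                      max_window = 300, step = 100)
  expect_gt(p5[w == 100, excess], 0)
})
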