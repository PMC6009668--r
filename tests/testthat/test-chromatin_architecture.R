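library(data.table)

mk_windows <- function(ids, centers, chrom = "chr1")
  data.table(id = ids, chrom = chrom, start = centers - 200L,
             end = centers + 201L)

test_that("TAD allocation respects the minimum-overlap rule and boundary distances", {
  tads <- data.table(id = c("t1", "t2"), chrom = "chr1",
                     start = c(0L, 10000L), end = c(9000L, 20000L))
  w <- mk_windows(c("a", "b", "c"), c(5000L, 9050L, 9700L))
  # a: fully inside t1; b: 150 bp overlap with t1 only -> BETWEEN;
  # c: [9500, 9901) overlaps neither
  ta <- assign_tads(w, tads)
  expect_equal(ta[id == "a", tad], "t1")
  expect_equal(ta[id == "a", dist_boundary], 4000)
  expect_equal(ta[id == "b", tad], "BETWEEN")   # 150 < 200 bp overlap
  expect_equal(ta[id == "c", tad], "BETWEEN")
  expect_true(ta[id == "c", near_boundary])     # 300 bp from 10000
  # straddling two TADs: larger overlap wins and the case is flagged
  tads2 <- data.table(id = c("t1", "t2"), chrom = "chr1",
                      start = c(0L, 5001L), end = c(5001L, 9000L))
  ta2 <- assign_tads(mk_windows("x", 5000L), tads2)
  expect_equal(ta2$tad, "t1")                   # 201 vs 200 bp overlap
  expect_true(ta2$ambiguous)
  expect_error(assign_tads(w, data.table(id = c("u", "v"), chrom = "chr1",
                                         start = c(0L, 500L),
                                         end = c(1000L, 1500L))),
               "overlapping")

  # inside/between fractions on an 8-DHS hand fixture
  w8 <- mk_windows(sprintf("h%d", 1:8),
                   c(1000L, 2000L, 3000L, 9050L, 12000L, 15000L, 9040L,
                     18000L))
  cl8 <- data.table(id = sprintf("h%d", 1:8),
                    class = rep(c("A", "B"), each = 4))
  s8 <- tad_class_summary(assign_tads(w8, tads), cl8)
  expect_equal(s8$fractions[class == "A", inside], 3 / 4)
  expect_equal(s8$fractions[class == "B", inside], 3 / 4)
})

test_that("pair enumeration matches brute force in count, distance and same-TAD flags", {
  # 3 collinear DHSs within 1 Mb -> C(3,2) pairs; boundary at 1 Mb + 1
  d3 <- data.table(id = c("p", "q", "r"), chrom = "chr1",
                   center = c(0L, 500000L, 1000001L))
  a3 <- data.table(id = d3$id, tad = "t")
  c3 <- data.table(id = d3$id, class = "A")
  pr3 <- enumerate_pairs(d3, a3, c3)
  expect_equal(nrow(pr3), 2L)   # p-q and q-r; p-r at 1000001 excluded
  expect_true(!any(pr3$id_i == "p" & pr3$id_j == "r"))

  set.seed(30)
  n <- 120
  d <- data.table(id = sprintf("d%03d", 1:n),
                  chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                  center = sample.int(3e6, n))
  a <- data.table(id = d$id, tad = sample(c(paste0("t", 1:6), "BETWEEN"),
                                          n, replace = TRUE))
  cl <- data.table(id = d$id, class = sample(c("A", "B", "C"), n,
                                             replace = TRUE))
  pairs <- enumerate_pairs(d, a, cl, max_dist = 1e6)
  # O(n^2) brute force
  bf <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_chrom <- d$chrom[i] == d$chrom[j]
    dist <- abs(d$center[i] - d$center[j])
    if (same_chrom && dist <= 1e6) {
      bf <- bf + 1L
      ii <- if (d$center[i] <= d$center[j]) c(i, j) else c(j, i)
      row <- pairs[(id_i == d$id[ii[1]] & id_j == d$id[ii[2]])]
      expect_equal(nrow(row), 1L)
      expect_equal(row$distance, dist)
      ti <- a$tad[i]; tj <- a$tad[j]
      expect_equal(row$same_tad, ti == tj && ti != "BETWEEN")
    }
  }
  expect_equal(nrow(pairs), bf)
})

test_that("co-occurrence GLM agrees with a hand-rolled IRLS fit", {
  set.seed(33)
  n <- 240
  partner <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  logd <- runif(n, 3, 6)
  eta <- 0.8 * (partner == "A") - 0.5 * (partner == "B") - 1.2 * logd + 5
  y <- rbinom(n, 1, plogis(eta))
  pairs <- data.table(id_i = "f", id_j = sprintf("x%03d", 1:n),
                      distance = 10^logd, same_tad = y == 1,
                      class_i = "F", class_j = as.character(partner))
  fit <- cooccurrence_glm(pairs, focal = "F")
  # independent IRLS with the same deviation coding
  X <- cbind(1, (partner == "A") - (partner == "C"),
             (partner == "B") - (partner == "C"), logd)
  beta <- rep(0, 4)
  for (it in 1:50) {
    mu <- plogis(X %*% beta)
    W <- as.vector(mu * (1 - mu))
    z <- X %*% beta + (y - mu) / W
    beta <- solve(t(X) %*% (X * W), t(X) %*% (z * W))
  }
  expect_equal(fit[partner_class == "A", estimate], beta[2],
               tolerance = 1e-6)
  expect_equal(fit[partner_class == "B", estimate], beta[3],
               tolerance = 1e-6)
  expect_equal(fit[partner_class == "C", estimate],
               -beta[2] - beta[3], tolerance = 1e-6)
  expect_equal(fit[partner_class == "log10_distance", estimate],
               beta[4], tolerance = 1e-6)

  # single partner class: deviation coding degenerates to coefficient 0
  p1 <- pairs[class_j == "A"]
  f1 <- cooccurrence_glm(p1, focal = "F")
  expect_equal(f1$estimate, 0)
  # all-one response -> separation flag
  psep <- copy(pairs)[, same_tad := TRUE]
  fsep <- cooccurrence_glm(psep, focal = "F")
  expect_true(attr(fsep, "separation"))
})

test_that("TAD composition clustering separates planted archetypes deterministically", {
  set.seed(35)
  n_tad <- 30
  mk_tad <- function(t, cls) data.table(
    id = sprintf("%s_d%d", t, 1:5), tad = t,
    class = sample(cls, 5, replace = TRUE))
  stable_tads <- rbindlist(lapply(paste0("s", 1:15), mk_tad,
                                  cls = tre_classes()[1:3]))
  unstable_tads <- rbindlist(lapply(paste0("u", 1:15), mk_tad,
                                    cls = tre_classes()[4:6]))
  all_t <- rbind(stable_tads, unstable_tads)
  asg <- all_t[, .(id, tad)]
  cls <- all_t[, .(id, class)]
  tc <- tad_composition_clusters(asg, cls, min_elements = 3, k = 2,
                                 seed = 7)
  grp <- merge(tc$clusters,
               data.table(tad = c(paste0("s", 1:15), paste0("u", 1:15)),
                          truth = rep(c("S", "U"), each = 15)), by = "tad")
  expect_equal(length(unique(grp[truth == "S", cluster])), 1L)
  expect_equal(length(unique(grp[truth == "U", cluster])), 1L)
  expect_true(grp[truth == "S", cluster][1] != grp[truth == "U", cluster][1])
  # determinism and size-enrichment bookkeeping
  tc2 <- tad_composition_clusters(asg, cls, min_elements = 3, k = 2,
                                  seed = 7)
  expect_identical(tc$clusters, tc2$clusters)
  expect_error(tad_composition_clusters(asg, cls, min_elements = 6,
                                        k = 40, seed = 1), "fewer")
})

test_that("interaction-target models recover planted preferences and flag degeneracy", {
  set.seed(36)
  n <- 300
  focal_class <- sample(c("stable", "unstable"), n, replace = TRUE)
  # planted: stable focals interact with hk-active targets
  hk_active <- runif(n) < ifelse(focal_class == "stable", 0.8, 0.3)
  pairs <- data.table(id_i = sprintf("f%03d", 1:n),
                      id_j = sprintf("t%03d", 1:n),
                      distance = sample.int(9e5, n), same_tad = TRUE,
                      class_i = focal_class, class_j = focal_class,
                      overlaps_interaction = TRUE)
  hk <- data.table(id = c(pairs$id_i, pairs$id_j), summit = 0L, lfc = 0,
                   active = c(rep(FALSE, n), hk_active))
  dcp <- copy(hk)[, active := FALSE]
  m <- interaction_target_model(pairs, hk, dcp, "hkCP")
  expect_gt(m[partner_class == "stable", estimate], 0)
  expect_lt(m[partner_class == "stable", p], 0.01)
  # no interactions -> NULL with a message
  p0 <- copy(pairs)[, overlaps_interaction := FALSE]
  expect_message(m0 <- interaction_target_model(p0, hk, dcp), "empty")
  expect_null(m0)
  # background-only targets -> separation flag
  hk0 <- copy(hk)[, active := FALSE]
  msep <- interaction_target_model(pairs, hk0, dcp, "hkCP")
  expect_true(attr(msep, "separation"))
})
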