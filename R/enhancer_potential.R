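# STARR-seq enhancer potential and chromatin marks at DHSs: summit
# log2 fold-change calls, class crosstabs, binned quantitative
# associations, binary-mark proportions and distance footprints.

#' Call STARR-seq enhancer potential at DHSs
#'
#' For each DHS the STARR summit is the leftmost position of maximal
#' signal within a `window`-bp region centered on the DHS midpoint; the
#' call is `log2((signal + pseudo) / (input + pseudo))` at the summit,
#' active when the fold change reaches `threshold`.
#'
#' @param dhs `data.table` with `id`, `chrom`, `start`, `end`.
#' @param signal,input [signal_track()]s (0 outside covered spans).
#' @param window summit search window (bp, centered on the midpoint).
#' @param threshold log2 fold-change activity threshold.
#' @param pseudo pseudocount guarding zero coverage.
#' @return `data.table`: `id`, `summit`, `lfc`, `active`.
#' @export
starr_call <- function(dhs, signal, input, window = 401L, threshold = 1.5,
                       pseudo = 1) {
  dhs <- as.data.table(dhs)
  half <- (window - 1L) %/% 2L
  res <- rbindlist(lapply(seq_len(nrow(dhs)), function(i) {
    mid <- as.integer(floor((dhs$start[i] + dhs$end[i]) / 2))
    mx <- track_max(signal, dhs$chrom[i], mid - half, mid + half + 1L)
    inp <- track_value(input, dhs$chrom[i], mx$pos)
    lfc <- log2((mx$max + pseudo) / (inp + pseudo))
    data.table(id = dhs$id[i], summit = mx$pos, lfc = lfc)
  }))
  res[, active := lfc >= threshold]
  res[]
}

#' STARR enhancer-class crosstab by DHS class
#'
#' Cross-tabulates DHS classes against combined housekeeping (hkCP) and
#' developmental (dCP) calls: `both`, `hkCP_only`, `dCP_only`,
#' `inactive`.  Per class, a chi-squared test against all other classes
#' and a Fisher test of the dCP overlap are reported.
#'
#' @param classes `data.table` with `id`, `class`.
#' @param hk,dcp call tables from [starr_call()] on the hkCP and dCP
#'   tracks.
#' @return list with `table`, `proportions`, `chisq_p`, `fisher_dcp`.
#' @export
class_starr_enrichment <- function(classes, hk, dcp) {
  cc <- merge(merge(as.data.table(classes),
                    as.data.table(hk)[, .(id, hk_active = active)],
                    by = "id"),
              as.data.table(dcp)[, .(id, dcp_active = active)], by = "id")
  cc[, category := fifelse(hk_active & dcp_active, "both",
                   fifelse(hk_active, "hkCP_only",
                   fifelse(dcp_active, "dCP_only", "inactive")))]
  tab <- table(cc$class, factor(cc$category,
                                levels = c("hkCP_only", "dCP_only",
                                           "both", "inactive")))
  if (any(rowSums(tab) == 0)) stopf("empty DHS class in STARR crosstab")
  chisq_p <- vapply(rownames(tab), function(cl) {
    m <- rbind(tab[cl, ], colSums(tab) - tab[cl, ])
    suppressWarnings(stats::chisq.test(m)$p.value)
  }, 0)
  fisher_dcp <- vapply(rownames(tab), function(cl) {
    inc <- cc$class == cl
    f <- stats::fisher.test(matrix(c(
      sum(inc & cc$dcp_active), sum(inc & !cc$dcp_active),
      sum(!inc & cc$dcp_active), sum(!inc & !cc$dcp_active)),
      2, byrow = TRUE))
    c(odds_ratio = unname(f$estimate), p = f$p.value)
  }, c(odds_ratio = 0, p = 0))
  list(table = tab, proportions = prop.table(tab, 1),
       chisq_p = chisq_p, fisher_dcp = t(fisher_dcp))
}

#' Binned association between two per-DHS quantities
#'
#' `x` is truncated to its `[pct_lo, pct_hi]` percentile range and cut
#' into `n_bins` equal-width bins; per-bin summaries of `y` are reported
#' together with Spearman's rho computed on the untruncated pairs.
#'
#' @param x,y paired per-DHS values (>= 10 complete pairs).
#' @param pct_lo,pct_hi truncation percentiles.
#' @param n_bins number of equal-width bins.
#' @return list with `bins` (`data.table`: bin center, n, median,
#'   quartiles, mean of `y`), `rho`, `p` (`NA` sentinels when `x` is
#'   constant).
#' @export
binned_association <- function(x, y, pct_lo = 1, pct_hi = 99,
                               n_bins = 10L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stopf("need at least 10 paired observations")
  if (stats::sd(x) == 0)
    return(list(bins = NULL, rho = NA_real_, p = NA_real_))
  qs <- stats::quantile(x, c(pct_lo, pct_hi) / 100, names = FALSE)
  keep <- x >= qs[1] & x <= qs[2]
  br <- seq(qs[1], qs[2], length.out = n_bins + 1L)
  bin <- cut(x[keep], br, include.lowest = TRUE, labels = FALSE)
  bins <- data.table(bin = bin, x = x[keep], y = y[keep])[, .(
    x_mid = (br[bin[1]] + br[bin[1] + 1L]) / 2, n = .N,
    y_median = stats::median(y), y_q1 = stats::quantile(y, .25, names = FALSE),
    y_q3 = stats::quantile(y, .75, names = FALSE), y_mean = mean(y)),
    by = bin][order(bin)]
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value)
}

#' Binary-mark proportions per DHS class
#'
#' A mark is present at a DHS iff at least one mark interval overlaps
#' `[summit - flank, summit + flank]` around the major-strand CAGE
#' summit.
#'
#' @param classes `data.table` with `id`, `class`.
#' @param summits `data.table` with `id`, `chrom`, `pos` (major summit).
#' @param marks named list of interval `data.table`s
#'   (`chrom`, `start`, `end`), one per mark.
#' @param flank half-window (bp).
#' @return list with `presence` (`data.table`: id x mark logical) and
#'   `proportions` (class x mark matrix).
#' @export
mark_proportions <- function(classes, summits, marks, flank = 100L) {
  su <- as.data.table(summits)
  pres <- data.table(id = su$id)
  for (mk in names(marks)) {
    mv <- as.data.table(marks[[mk]])[, .(chrom, start, end1 = end - 1L)]
    setkey(mv, chrom, start, end1)
    q <- su[, .(id, chrom, start = pos - flank, end1 = pos + flank)]
    ov <- foverlaps(q, mv, by.x = c("chrom", "start", "end1"),
                    nomatch = NULL)
    pres[, (mk) := id %in% ov$id]
  }
  cc <- merge(pres, as.data.table(classes), by = "id")
  prop <- vapply(names(marks), function(mk)
    tapply(cc[[mk]], cc$class, mean), numeric(length(unique(cc$class))))
  list(presence = pres, proportions = prop)
}

#' Distance footprint of a binary mark around summits
#'
#' Mean presence of the mark in `bin`-bp distance bins from each summit,
#' up to `max_dist` bp on both sides; bins overlapping another DHS are
#' excluded for that site.  A background band is obtained by uniformly
#' relocating the mark intervals `n_randomizations` times (deterministic
#' under `seed`).
#'
#' @param summits `data.table` with `id`, `chrom`, `pos`.
#' @param mark interval `data.table` (`chrom`, `start`, `end`).
#' @param other_dhs interval `data.table` of all DHSs (for the exclusion
#'   mask); the site's own interval is ignored.
#' @param genome genome (sizes) for the randomization.
#' @param bin bin width (bp).
#' @param max_dist maximal distance (bp).
#' @param n_randomizations number of uniform relocations.
#' @param seed RNG seed.
#' @return `data.table`: `bin_start` (signed), `mean_presence`,
#'   `bg_mean`, `bg_sd`, `n_sites`.
#' @export
footprint_profile <- function(summits, mark, other_dhs, genome,
                              bin = 50L, max_dist = 5000L,
                              n_randomizations = 10L, seed = 1L) {
  su <- as.data.table(summits)
  sizes <- chrom_sizes(genome)
  edges <- seq(-max_dist, max_dist, by = bin)
  starts <- head(edges, -1L)
  grid <- rbindlist(lapply(seq_len(nrow(su)), function(i)
    data.table(site = i, id = su$id[i], chrom = su$chrom[i],
               bs = su$pos[i] + starts, bin_start = starts)))
  grid[, be1 := bs + bin - 1L]
  # mask bins overlapping another DHS
  od <- as.data.table(other_dhs)[, .(id_dhs = id, chrom, start,
                                     end1 = end - 1L)]
  setkey(od, chrom, start, end1)
  ovm <- foverlaps(grid[, .(site, id, chrom, start = bs, end1 = be1)],
                   od, by.x = c("chrom", "start", "end1"), nomatch = NULL)
  mskd <- unique(ovm[id_dhs != id, .(site, bs = i.start)])
  grid[, masked := FALSE]
  if (nrow(mskd))
    grid[mskd, on = c("site", "bs"), masked := TRUE]
  presence_of <- function(mk) {
    mv <- as.data.table(mk)[, .(chrom, start, end1 = end - 1L)]
    setkey(mv, chrom, start, end1)
    ov <- foverlaps(grid[, .(site, bin_start, chrom, start = bs, end1 = be1)],
                    mv, by.x = c("chrom", "start", "end1"), nomatch = NULL)
    hit <- unique(ov[, .(site, bin_start)])[, present := TRUE]
    g <- merge(grid[, .(site, bin_start, masked)], hit,
               by = c("site", "bin_start"), all.x = TRUE)
    g[is.na(present), present := FALSE]
    g[masked == FALSE,
      .(mean_presence = mean(present), n_sites = .N), by = bin_start]
  }
  obs <- presence_of(mark)
  set.seed(seed)
  mk <- as.data.table(mark)
  widths <- mk$end - mk$start
  bgs <- lapply(seq_len(n_randomizations), function(r) {
    ch <- sample(names(sizes), nrow(mk), replace = TRUE,
                 prob = sizes / sum(sizes))
    st <- floor(runif(nrow(mk)) * pmax(1, sizes[ch] - widths))
    presence_of(data.table(chrom = ch, start = as.integer(st),
                           end = as.integer(st + widths)))
  })
  bgm <- rbindlist(bgs)[, .(bg_mean = mean(mean_presence),
                            bg_sd = stats::sd(mean_presence)),
                        by = bin_start]
  out <- merge(obs, bgm, by = "bin_start", all.x = TRUE)
  setorder(out, bin_start)
  out[]
}
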