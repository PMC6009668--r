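# CAGE genomic background noise: thresholds estimated from TSS-unlikely
# loci, and condition-wise replicate-support filtering.

#' Estimate per-library background noise thresholds
#'
#' Places `n_windows` random strand-specific windows of `window_width` bp
#' uniformly outside the exclusion regions (TSS-unlikely loci: outside
#' DNase hypersensitive sites and annotated TSSs, both padded) and takes,
#' per library, the empirical `quantile` of the summed CTSS counts per
#' window.  The threshold convention is the order statistic
#' `x[floor(q * n) + 1]`, the smallest count with strictly more than `q`
#' of the windows at or below it.  Deterministic under `seed`.
#'
#' @param ctss per-library CTSS table.
#' @param exclusion interval `data.table` (`chrom`, `start`, `end`) of
#'   TSS-likely regions to avoid; must be non-empty.
#' @param genome `DNAStringSet` or named vector of chromosome sizes.
#' @param libs library table (for totals used in the TPM conversion).
#' @param n_windows number of windows (>= 1000).
#' @param window_width window width in bp (default 200, matching the DHS
#'   quantification window so thresholds are in like-for-like units).
#' @param quantile quantile in (0, 1).
#' @param seed RNG seed.
#' @return `data.table` with `lib`, `count_threshold`, `tpm_threshold`.
#' @export
estimate_noise_threshold <- function(ctss, exclusion, genome, libs,
                                     n_windows = 10000L, window_width = 200L,
                                     quantile = 0.999, seed = 1L) {
  stopifnot(n_windows >= 1000L)
  if (is.null(exclusion) || nrow(exclusion) == 0L)
    stopf("exclusion set must be non-empty")
  sizes <- chrom_sizes(genome)
  allowed <- allowed_segments(exclusion, sizes, window_width)
  if (nrow(allowed) == 0L)
    stopf("genome too small to place background windows")
  set.seed(seed)
  seg <- sample.int(nrow(allowed), n_windows, replace = TRUE,
                    prob = allowed$end - allowed$start - window_width + 1)
  off <- floor(runif(n_windows) *
                 (allowed$end[seg] - allowed$start[seg] - window_width + 1))
  win <- data.table(chrom = allowed$chrom[seg],
                    start = allowed$start[seg] + off,
                    strand = sample(c("+", "-"), n_windows, replace = TRUE))
  win[, `:=`(end1 = start + window_width - 1L, wid = .I)]
  cx <- as.data.table(ctss)
  cx[, pos2 := pos]
  setkey(cx, chrom, strand, pos, pos2)
  ov <- foverlaps(win, cx, by.x = c("chrom", "strand", "start", "end1"),
                  by.y = c("chrom", "strand", "pos", "pos2"), nomatch = NULL)
  res <- rbindlist(lapply(libs$id, function(id) {
    sums <- numeric(n_windows)
    if (nrow(ov)) {
      agg <- ov[, sum(get(id)), by = wid]
      sums[agg$wid] <- agg$V1
    }
    thr <- empirical_threshold(sums, quantile)
    tot <- libs$total_mapped_tags[libs$id == id]
    data.table(lib = id, count_threshold = thr,
               tpm_threshold = thr / tot * 1e6)
  }))
  res[]
}

# complement of (merged) exclusion intervals, restricted to segments that
# can hold a window
allowed_segments <- function(exclusion, sizes, window_width) {
  ex <- as.data.table(exclusion)[, .(chrom, start = pmax(0L, start), end)]
  setorder(ex, chrom, start)
  merged <- ex[, {
    s <- start; e <- end
    ms <- s[1L]; me <- e[1L]; out_s <- integer(); out_e <- integer()
    if (.N > 1L) for (i in 2L:.N) {
      if (s[i] <= me) me <- max(me, e[i])
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
    }
    .(start = c(out_s, ms), end = c(out_e, me))
  }, by = chrom]
  rbindlist(lapply(names(sizes), function(ch) {
    m <- merged[chrom == ch]
    bounds <- c(0L, rbind(m$start, m$end), sizes[[ch]])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- (ends - starts) >= window_width
    data.table(chrom = ch, start = starts[keep], end = ends[keep])
  }))
}

#' Filter elements by noise support across replicates
#'
#' An element is kept in a condition iff its expression exceeds the
#' library threshold (strictly) in at least `min_replicates` replicates of
#' that condition.  With a replicate count other than 4 a warning is
#' emitted and the proportional rule `ceiling(min_replicates / 4 * n)` is
#' applied.
#'
#' @param expr numeric matrix/`data.table`, one column per library id
#'   (TPM scale).
#' @param thresholds threshold table from [estimate_noise_threshold()].
#' @param libs library table.
#' @param min_replicates required passing replicates per condition.
#' @return `data.table` with logical `kept_control`, `kept_kd`,
#'   `kept_any`, `kept_both`.
#' @export
filter_by_noise <- function(expr, thresholds, libs, min_replicates = 2L) {
  expr <- as.matrix(as.data.table(expr)[, libs$id, with = FALSE])
  thr <- stats::setNames(thresholds$tpm_threshold, thresholds$lib)
  pass <- sweep(expr, 2, thr[colnames(expr)], FUN = ">")
  res <- data.table(row = seq_len(nrow(expr)))
  for (cond in c("control", "exosomeKD")) {
    ids <- libs$id[libs$condition == cond]
    need <- min_replicates
    if (length(ids) != 4L) {
      warnf("%d replicates in condition %s; using proportional rule",
            length(ids), cond)
      need <- ceiling(min_replicates / 4 * length(ids))
    }
    res[, (ifelse(cond == "control", "kept_control", "kept_kd")) :=
          rowSums(pass[, ids, drop = FALSE]) >= need]
  }
  res[, `:=`(kept_any = kept_control | kept_kd,
             kept_both = kept_control & kept_kd, row = NULL)]
  res[]
}

#' Call a DHS transcribed from strand-wise expression
#'
#' A DHS is transcribed iff any strand passes the noise filter in at least
#' `min_replicates` libraries of either condition.
#'
#' @param expr_plus,expr_minus per-strand expression tables (columns per
#'   library id, TPM).
#' @inheritParams filter_by_noise
#' @return logical vector per DHS.
#' @export
dhs_transcribed <- function(expr_plus, expr_minus, thresholds, libs,
                            min_replicates = 2L) {
  p <- filter_by_noise(expr_plus, thresholds, libs, min_replicates)
  m <- filter_by_noise(expr_minus, thresholds, libs, min_replicates)
  p$kept_any | m$kept_any
}
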