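# CAGE tag clustering: single-linkage merging of CTSS positions, summit-
# fraction trimming of wide clusters, valley splitting of multi-modal
# clusters, quantification, TPM normalization, gene annotation, and
# divergence statistics.

#' Call CAGE tag clusters from pooled CTSS data
#'
#' Same-strand CTSS positions within `merge_dist` bp of each other are
#' merged by single linkage.  Each cluster is then trimmed from both edges
#' while the edge pooled count is strictly below
#' `trim_fraction * summit count`, and finally split at every internal
#' valley whose pooled count falls strictly below
#' `valley_fraction * min(flanking local-summit counts)`, producing
#' single-summit tag clusters (TCs).  Children of a split partition the
#' trimmed parent: they are disjoint, ordered, and their pooled counts sum
#' to the parent's.
#'
#' @param ctss pooled CTSS table (`chrom`, `pos`, `strand`, `count`) from
#'   [pool_ctss()].  A library-keyed (non-pooled) table is an error.
#' @param merge_dist single-linkage merge distance in bp (>= 1).
#' @param trim_fraction,valley_fraction summit fractions in (0, 1).
#' @return `data.table` of TCs: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `summit` (leftmost position of maximal pooled
#'   count), `count` (pooled).  Sorted and non-overlapping per strand.
#' @export
call_tag_clusters <- function(ctss, merge_dist = 20L, trim_fraction = 0.1,
                              valley_fraction = 0.1) {
  stopifnot(merge_dist >= 1, trim_fraction >= 0, trim_fraction < 1,
            valley_fraction >= 0, valley_fraction < 1)
  # note: the strict < rules make 0 a natural off switch for either
  # fraction (nothing is ever below 0), while any positive
  # valley_fraction splits at every internal zero-count valley
  if (!"count" %in% names(ctss))
    stopf("expected pooled CTSS input with a 'count' column (see pool_ctss)")
  if (nrow(ctss) == 0L)
    return(data.table(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      summit = integer(), count = numeric()))
  x <- as.data.table(ctss)[count > 0][order(chrom, strand, pos)]
  x[, grp := cumsum(c(TRUE, diff(pos) > merge_dist)), by = .(chrom, strand)]
  out <- x[, cluster_one(pos, count, trim_fraction, valley_fraction),
           by = .(chrom, strand, grp)]
  out[, grp := NULL]
  setorder(out, chrom, strand, start)
  out[]
}

# Trim and valley-split one merged group of positions (sorted).
cluster_one <- function(pos, count, trim_fraction, valley_fraction) {
  # trim edges: strict < against trim_fraction * summit count
  thr <- trim_fraction * max(count)
  keep_lo <- 1L
  keep_hi <- length(pos)
  while (keep_lo < keep_hi && count[keep_lo] < thr) keep_lo <- keep_lo + 1L
  while (keep_hi > keep_lo && count[keep_hi] < thr) keep_hi <- keep_hi - 1L
  pos <- pos[keep_lo:keep_hi]
  count <- count[keep_lo:keep_hi]

  # dense profile over the trimmed span
  span <- pos[length(pos)] - pos[1L] + 1L
  prof <- numeric(span)
  prof[pos - pos[1L] + 1L] <- count

  cut_at <- valley_cuts(prof, valley_fraction)  # indices into prof
  piece <- findInterval(pos - pos[1L] + 1L, c(1L, cut_at + 1L))
  segs <- split(seq_along(pos), piece)
  rbindlist(lapply(segs, function(i) {
    p <- pos[i]; cnt <- count[i]
    data.table(start = p[1L], end = p[length(p)] + 1L,
               summit = p[which.max(cnt)], count = sum(cnt))
  }))
}

# Positions (indices) after which to cut a dense profile: for each pair of
# consecutive local maxima, if the minimum between them is strictly below
# valley_fraction * min(peak heights), cut at the leftmost argmin.
valley_cuts <- function(prof, valley_fraction) {
  n <- length(prof)
  if (n < 3L) return(integer())
  # local maxima with plateau handling (leftmost position of each plateau)
  r <- rle(prof)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_max <- vapply(seq_len(k), function(i) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == k) -Inf else r$values[i + 1L]
    r$values[i] > left && r$values[i] > right
  }, TRUE)
  peaks <- starts[is_max]
  heights <- r$values[is_max]
  if (length(peaks) < 2L) return(integer())
  cuts <- integer()
  for (j in seq_len(length(peaks) - 1L)) {
    lo <- peaks[j] + 1L
    hi <- peaks[j + 1L] - 1L
    seg <- prof[lo:hi]
    vmin <- min(seg)
    if (vmin < valley_fraction * min(heights[j], heights[j + 1L]))
      cuts <- c(cuts, lo + which.min(seg) - 1L)  # leftmost argmin
  }
  cuts
}

#' Quantify tag clusters per library and normalize to TPM
#'
#' Counts CAGE 5' ends falling into each TC's `[start, end)` on the TC
#' strand, per library, and converts to tags per million using the
#' library's total mapped tags.
#'
#' @param tcs TC table from [call_tag_clusters()].
#' @param ctss per-library CTSS table from [read_ctss()].
#' @param libs library table; totals must be positive.
#' @return `tcs` with added columns `count_<id>` and `tpm_<id>` per
#'   library, plus `tpm_pooled` (sum of per-library TPM).
#' @export
quantify_and_normalize <- function(tcs, ctss, libs) {
  if (any(is.na(libs$total_mapped_tags) | libs$total_mapped_tags <= 0))
    stopf("library with missing or non-positive total_mapped_tags")
  miss <- setdiff(libs$id, names(ctss))
  if (length(miss)) stopf("library missing from CTSS table: %s", miss[1L])
  tcs <- copy(as.data.table(tcs))
  tcs[, tc_idx := .I]
  cx <- as.data.table(ctss)
  cx[, pos2 := pos]
  setkey(cx, chrom, strand, pos, pos2)
  q <- tcs[, .(tc_idx, chrom, strand, start, end1 = end - 1L)]
  ov <- foverlaps(q, cx, by.x = c("chrom", "strand", "start", "end1"),
                  by.y = c("chrom", "strand", "pos", "pos2"), nomatch = NULL)
  for (id in libs$id) {
    sums <- ov[, sum(get(id)), by = tc_idx]
    v <- numeric(nrow(tcs))
    v[sums$tc_idx] <- sums$V1
    tot <- libs$total_mapped_tags[libs$id == id]
    tcs[, (paste0("count_", id)) := v]
    tcs[, (paste0("tpm_", id)) := v / tot * 1e6]
  }
  tcs[, tpm_pooled := rowSums(as.matrix(.SD)),
      .SDcols = paste0("tpm_", libs$id)]
  tcs[, tc_idx := NULL]
  tcs[]
}

#' Annotate tag clusters against gene TSSs
#'
#' A TC is labelled `mRNA_TSS`/`ncRNA_TSS` when the nearest same-strand
#' gene TSS lies within `max_dist` bp of the summit (ties broken towards
#' the smaller coordinate); otherwise `PROMPT` when an opposite-strand
#' gene TSS lies within `prompt_dist` bp with the TC upstream of and
#' antisense to the gene (divergent orientation); otherwise `distal`.
#'
#' @param tcs TC table with `summit`, `strand`, `chrom`.
#' @param tss gene TSS table from [gene_tss()] (`chrom`, `pos`, `strand`,
#'   `biotype` in `{mRNA, ncRNA}`).
#' @param max_dist sense annotation distance (bp).
#' @param prompt_dist antisense upstream distance (bp).
#' @return `tcs` with an `annotation` column.
#' @export
annotate_tcs <- function(tcs, tss, max_dist = 250L, prompt_dist = 500L) {
  tcs <- copy(as.data.table(tcs))
  tss <- as.data.table(tss)
  ann <- rep("distal", nrow(tcs))
  for (i in seq_len(nrow(tcs))) {
    s <- tcs$summit[i]
    same <- tss[chrom == tcs$chrom[i] & strand == tcs$strand[i]]
    if (nrow(same)) {
      d <- abs(same$pos - s)
      if (min(d) <= max_dist) {
        cand <- which(d == min(d))
        j <- cand[which.min(same$pos[cand])]  # tie -> smaller coordinate
        ann[i] <- ifelse(same$biotype[j] == "ncRNA", "ncRNA_TSS", "mRNA_TSS")
        next
      }
    }
    anti <- tss[chrom == tcs$chrom[i] & strand != tcs$strand[i]]
    if (nrow(anti)) {
      # TC upstream of and antisense to the gene: TC and gene point apart
      d <- if (tcs$strand[i] == "-") anti$pos - s else s - anti$pos
      if (any(d > 0 & d <= prompt_dist)) ann[i] <- "PROMPT"
    }
  }
  tcs[, annotation := ann]
  tcs[]
}

#' Divergence distances of plus-strand tag clusters
#'
#' For each plus-strand TC, the distance from its summit to the summit of
#' the nearest upstream, non-overlapping minus-strand TC, together with
#' the cumulative fraction of plus-strand TCs whose distance falls within
#' each observed distance, and a divergent flag at `threshold` bp.
#'
#' @param tcs TC table on both strands.
#' @param max_dist maximal search distance (bp).
#' @param threshold distance defining a divergent event (bp).
#' @return list with `distances` (per plus-strand TC; `NA` when
#'   unidirectional), `divergent` flags, and `curve`
#'   (`data.table(distance, cum_fraction)`, non-decreasing, <= 1).
#' @export
divergence_profile <- function(tcs, max_dist = Inf, threshold = 500L) {
  tcs <- as.data.table(tcs)
  plus <- tcs[strand == "+"]
  minus <- tcs[strand == "-"]
  dist <- rep(NA_real_, nrow(plus))
  for (i in seq_len(nrow(plus))) {
    cand <- minus[chrom == plus$chrom[i] & summit < plus$summit[i] &
                    end <= plus$start[i]]
    if (nrow(cand)) {
      d <- plus$summit[i] - max(cand$summit)
      if (d <= max_dist) dist[i] <- d
    }
  }
  ds <- sort(dist[!is.na(dist)])
  curve <- data.table(distance = ds,
                      cum_fraction = seq_along(ds) / nrow(plus))
  curve <- curve[!duplicated(distance, fromLast = TRUE)]
  list(distances = dist,
       divergent = !is.na(dist) & dist <= threshold,
       curve = curve)
}

#' Distance to the closest upstream antisense gene TSS
#'
#' Head-to-head composition: for each strand-aware summit, the distance to
#' the closest opposite-strand gene TSS positioned so that the element and
#' the gene point apart (the element lies upstream of and antisense to the
#' gene).  `Inf` when no such TSS exists on the chromosome.
#'
#' @param summits `data.table` with `chrom`, `pos`, `strand`.
#' @param tss gene TSS table.
#' @return numeric vector of distances (bp), `Inf` when absent.
#' @export
head_to_head_distance <- function(summits, tss) {
  summits <- as.data.table(summits)
  tss <- as.data.table(tss)
  vapply(seq_len(nrow(summits)), function(i) {
    anti <- tss[chrom == summits$chrom[i] & strand != summits$strand[i]]
    if (nrow(anti) == 0L) return(Inf)
    d <- if (summits$strand[i] == "-") anti$pos - summits$pos[i]
         else summits$pos[i] - anti$pos
    d <- d[d > 0]
    if (length(d)) min(d) else Inf
  }, 0)
}
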