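# Divergent quantification windows anchored on DNase hypersensitive
# sites: window placement maximizing CAGE coverage, strand-wise
# quantification, major/minor assignment, exosome sensitivity,
# directionality and convergence calls.

#' Place divergent quantification windows on DHSs
#'
#' For each DHS, an anchor is scanned over
#' `[center - search_radius, center + search_radius]` and chosen to
#' maximize the divergent CAGE coverage in exosome-KD data: minus-strand
#' tags in the upstream window `[anchor - L, anchor)` plus plus-strand
#' tags in the downstream window `[anchor, anchor + L)`.  Ties are broken
#' towards the anchor nearest the DHS center, then the smaller
#' coordinate.  A DHS with zero coverage keeps its center as anchor.
#'
#' @param dhs `data.table` with `id`, `chrom`, `start`, `end`.
#' @param ctss_kd pooled CTSS table over the exosome-KD libraries
#'   (`chrom`, `pos`, `strand`, `count`).
#' @param L window width in bp.
#' @param search_radius anchor search radius in bp.
#' @return `data.table` with `id`, `chrom`, `center`, `anchor`; the
#'   upstream window `[anchor - L, anchor)` carries the minus strand, the
#'   downstream `[anchor, anchor + L)` the plus strand.
#' @export
place_windows <- function(dhs, ctss_kd, L = 200L, search_radius = 100L) {
  dhs <- as.data.table(dhs)
  stopifnot(all(dhs$end > dhs$start))
  res <- copy(dhs)[, center := as.integer(floor((start + end) / 2))]
  res[, anchor := vapply(seq_len(.N), function(i) {
    best_anchor(ctss_kd, chrom[i], center[i], L, search_radius,
                up_strand = "-", down_strand = "+")$anchor
  }, 0L)]
  res[, .(id, chrom, center, anchor)]
}

# shared anchor scan for divergent/convergent configurations
best_anchor <- function(ctss, chr, center, L, r, up_strand, down_strand) {
  anchors <- (center - r):(center + r)
  sub <- ctss[chrom == chr & pos >= center - r - L & pos < center + r + L]
  score <- numeric(length(anchors))
  for (st in c(up_strand, down_strand)) {
    s <- sub[strand == st][order(pos)]
    if (nrow(s) == 0L) next
    cw <- cumsum(s$count)
    cnt_upto <- function(p) {  # sum of counts at pos < p
      i <- findInterval(p - 1L, s$pos)
      ifelse(i > 0L, cw[pmax(i, 1L)], 0)
    }
    if (st == up_strand) score <- score + (cnt_upto(anchors) - cnt_upto(anchors - L))
    else score <- score + (cnt_upto(anchors + L) - cnt_upto(anchors))
  }
  best <- max(score)
  cand <- which(score == best)
  cand <- cand[order(abs(anchors[cand] - center), anchors[cand])][1L]
  list(anchor = anchors[cand], score = best)
}

#' Quantify strand-specific DHS expression per library
#'
#' Sums CTSS counts per library in the upstream (minus-strand) and
#' downstream (plus-strand) windows and converts to TPM.  The major
#' strand is the strand with the larger pooled exosome-KD TPM (tie:
#' plus).  Per strand, the CAGE summit is the leftmost position of
#' maximal pooled-KD count inside the window, reported most upstream
#' relative to the strand on ties (`NA` with zero coverage).
#'
#' @param windows window table from [place_windows()].
#' @param ctss per-library CTSS table.
#' @param libs library table.
#' @param L window width used in [place_windows()].
#' @return list with `expr` (`data.table`: `id`, `lib`, `tpm_plus`,
#'   `tpm_minus`) and `quant` (`data.table`: `id`, `chrom`, `anchor`,
#'   `major_strand`, `summit_major`, `summit_minor`, pooled-KD and control
#'   mean TPM per strand role).
#' @export
quantify_dhs <- function(windows, ctss, libs, L = 200L) {
  windows <- as.data.table(windows)
  kd_ids <- libs$id[libs$condition == "exosomeKD"]
  ct_ids <- libs$id[libs$condition == "control"]
  cx <- as.data.table(ctss)
  cx[, pos2 := pos]
  setkey(cx, chrom, strand, pos, pos2)
  wins <- rbind(
    windows[, .(id, chrom, strand = "-", start = anchor - L, end1 = anchor - 1L)],
    windows[, .(id, chrom, strand = "+", start = anchor, end1 = anchor + L - 1L)])
  ov <- foverlaps(wins, cx, by.x = c("chrom", "strand", "start", "end1"),
                  by.y = c("chrom", "strand", "pos", "pos2"), nomatch = NULL)
  tot <- stats::setNames(libs$total_mapped_tags, libs$id)
  expr <- rbindlist(lapply(libs$id, function(lid) {
    agg <- ov[, .(count = sum(get(lid))), by = .(id, strand)]
    wide <- dcast(agg, id ~ strand, value.var = "count", fill = 0)
    for (cc in c("+", "-")) if (!cc %in% names(wide)) wide[, (cc) := 0]
    out <- merge(windows[, .(id)], wide, by = "id", all.x = TRUE)
    out[is.na(`+`), `+` := 0][is.na(`-`), `-` := 0]
    data.table(id = out$id, lib = lid,
               tpm_plus = out$`+` / tot[[lid]] * 1e6,
               tpm_minus = out$`-` / tot[[lid]] * 1e6)
  }))
  # pooled-KD per strand decides major; summits from pooled-KD counts
  kd_pool <- ov[, .(count = rowSums(as.matrix(.SD))), .SDcols = kd_ids,
                by = .(id, strand, pos)]
  kd_pool <- kd_pool[, .(count = sum(count)), by = .(id, strand, pos)]
  quant <- windows[, .(id, chrom, center, anchor)]
  strand_sum <- dcast(kd_pool[, .(n = sum(count)), by = .(id, strand)],
                      id ~ strand, value.var = "n", fill = 0)
  for (cc in c("+", "-")) if (!cc %in% names(strand_sum)) strand_sum[, (cc) := 0]
  quant <- merge(quant, strand_sum, by = "id", all.x = TRUE)
  quant[is.na(`+`), `+` := 0][is.na(`-`), `-` := 0]
  quant[, major_strand := ifelse(`-` > `+`, "-", "+")]  # tie -> plus
  summit_of <- function(did, st) {
    s <- kd_pool[id == did & strand == st]
    if (nrow(s) == 0L || sum(s$count) == 0) return(NA_real_)
    mx <- s$pos[s$count == max(s$count)]
    as.numeric(if (st == "+") min(mx) else max(mx))  # most upstream
  }
  quant[, summit_plus := vapply(id, summit_of, 0, st = "+")]
  quant[, summit_minus := vapply(id, summit_of, 0, st = "-")]
  quant[, `:=`(
    summit_major = ifelse(major_strand == "+", summit_plus, summit_minus),
    summit_minor = ifelse(major_strand == "+", summit_minus, summit_plus))]
  mean_tpm <- function(ids, col) {
    e <- expr[lib %in% ids, .(v = mean(get(col))), by = id]
    e$v[match(quant$id, e$id)]
  }
  quant[, `:=`(
    plus_kd = mean_tpm(kd_ids, "tpm_plus"),
    minus_kd = mean_tpm(kd_ids, "tpm_minus"),
    plus_ctrl = mean_tpm(ct_ids, "tpm_plus"),
    minus_ctrl = mean_tpm(ct_ids, "tpm_minus"))]
  quant[, `:=`(
    tpm_major_kd = ifelse(major_strand == "+", plus_kd, minus_kd),
    tpm_minor_kd = ifelse(major_strand == "+", minus_kd, plus_kd),
    tpm_major_ctrl = ifelse(major_strand == "+", plus_ctrl, minus_ctrl),
    tpm_minor_ctrl = ifelse(major_strand == "+", minus_ctrl, plus_ctrl))]
  quant[, c("+", "-", "plus_kd", "minus_kd", "plus_ctrl", "minus_ctrl") := NULL]
  quant[, `:=`(
    sens_major = exosome_sensitivity(tpm_major_ctrl, tpm_major_kd),
    sens_minor = exosome_sensitivity(tpm_minor_ctrl, tpm_minor_kd),
    directionality = directionality_score(tpm_major_kd, tpm_minor_kd))]
  list(expr = expr[], quant = quant[])
}

#' Exosome sensitivity score
#'
#' The fraction of expression observed only upon exosome depletion:
#' `max(0, 1 - control / kd)`, ranging from 0 (insensitive; expression
#' fully captured in control libraries) to 1 (expression only observed
#' upon knockdown).  Undefined (`NA`) when the knockdown expression is 0;
#' such scores propagate as missing and are excluded downstream.
#'
#' @param control_tpm,kd_tpm mean TPM over the replicates of each
#'   condition (vectorized).
#' @return numeric in `[0, 1]` or `NA`.
#' @export
exosome_sensitivity <- function(control_tpm, kd_tpm) {
  stopifnot(all(control_tpm >= 0, na.rm = TRUE),
            all(kd_tpm >= 0, na.rm = TRUE))
  ifelse(kd_tpm > 0, pmax(0, 1 - control_tpm / kd_tpm), NA_real_)
}

#' Transcriptional directionality score
#'
#' `(major - minor) / (major + minor)` on exosome-KD expression with the
#' major strand fixed per DHS: 0 for perfectly balanced bidirectional
#' output, 1 for fully unidirectional.  `NA` when both strands are 0.
#'
#' @param major_tpm_kd,minor_tpm_kd KD expression per strand role.
#' @return numeric in `[0, 1]` or `NA`.
#' @export
directionality_score <- function(major_tpm_kd, minor_tpm_kd) {
  stopifnot(all(major_tpm_kd >= 0, na.rm = TRUE),
            all(minor_tpm_kd >= 0, na.rm = TRUE))
  tot <- major_tpm_kd + minor_tpm_kd
  ifelse(tot > 0, (major_tpm_kd - minor_tpm_kd) / tot, NA_real_)
}

#' Detect convergent transcription at a DHS
#'
#' `TRUE` iff the best convergent window configuration (plus strand
#' upstream, minus strand downstream) achieves strictly greater pooled-KD
#' coverage than the best divergent configuration over the same anchor
#' scan.
#'
#' @inheritParams place_windows
#' @return logical vector per DHS.
#' @export
detect_convergent <- function(dhs, ctss_kd, L = 200L, search_radius = 100L) {
  dhs <- as.data.table(dhs)
  centers <- as.integer(floor((dhs$start + dhs$end) / 2))
  vapply(seq_len(nrow(dhs)), function(i) {
    div <- best_anchor(ctss_kd, dhs$chrom[i], centers[i], L, search_radius,
                       up_strand = "-", down_strand = "+")
    conv <- best_anchor(ctss_kd, dhs$chrom[i], centers[i], L, search_radius,
                        up_strand = "+", down_strand = "-")
    conv$score > div$score
  }, TRUE)
}
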