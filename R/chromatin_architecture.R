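# DHS classes in their three-dimensional context: TAD allocation,
# boundary proximity, TRE pair enumeration, within-TAD co-occurrence
# GLMs, TAD composition clustering and interaction-target models.

#' Allocate DHSs to TADs
#'
#' Each DHS window (CAGE summit +/- 200 bp by convention) is assigned the
#' TAD it overlaps by at least `min_overlap` bp; with two qualifying TADs
#' the larger overlap wins (tie: the upstream TAD) and the case is
#' flagged.  A DHS with no TAD overlap is `BETWEEN`.  Distance to the
#' nearest TAD boundary and a `near_boundary` flag (<= `boundary_cutoff`)
#' are reported.
#'
#' @param windows `data.table` with `id`, `chrom`, `start`, `end`.
#' @param tads `data.table` with `id`, `chrom`, `start`, `end`;
#'   overlapping TADs on a chromosome are an error.
#' @param min_overlap minimal overlap (bp) for allocation.
#' @param boundary_cutoff near-boundary distance (bp).
#' @return `data.table`: `id`, `tad` (`"BETWEEN"` when unallocated),
#'   `overlap`, `dist_boundary`, `near_boundary`, `ambiguous`.
#' @export
assign_tads <- function(windows, tads, min_overlap = 200L,
                        boundary_cutoff = 1000L) {
  w <- as.data.table(windows)
  td <- as.data.table(tads)[order(chrom, start)]
  bad <- td[, any(start[-1L] < head(end, -1L)), by = chrom]$V1
  if (any(bad)) stopf("overlapping TADs on a chromosome")
  tv <- td[, .(tad = id, chrom, start, end1 = end - 1L, tstart = start,
               tend = end)]
  setkey(tv, chrom, start, end1)
  ov <- foverlaps(w[, .(id, chrom, start, end1 = end - 1L, wstart = start,
                        wend = end)],
                  tv, by.x = c("chrom", "start", "end1"), nomatch = NULL)
  ov[, overlap := pmin(wend, tend) - pmax(wstart, tstart)]
  ov <- ov[overlap >= min_overlap]
  setorder(ov, id, -overlap, tstart)
  best <- ov[, .(tad = tad[1L], overlap = overlap[1L], ambiguous = .N > 1L),
             by = id]
  res <- merge(w[, .(id, chrom, start, end)], best, by = "id", all.x = TRUE)
  res[is.na(tad), `:=`(tad = "BETWEEN", overlap = 0L, ambiguous = FALSE)]
  # distance from the window midpoint to the nearest TAD boundary
  res[, mid := floor((start + end) / 2)]
  bnd <- td[, .(b = c(start, end)), by = chrom]
  res[, dist_boundary := vapply(seq_len(.N), function(i) {
    bs <- bnd[chrom == res$chrom[i], b]
    if (length(bs)) min(abs(bs - res$mid[i])) else Inf
  }, 0)]
  res[, near_boundary := dist_boundary <= boundary_cutoff]
  res[, c("start", "end", "mid") := NULL]
  res[]
}

#' Inside/between-TAD fractions per class and boundary enrichment
#'
#' @param assignments from [assign_tads()].
#' @param classes `data.table` with `id`, `class`.
#' @return list with `fractions` (class x {inside, between}),
#'   `boundary_fisher` (per-class Fisher odds/p of near-boundary
#'   inclusion).
#' @export
tad_class_summary <- function(assignments, classes) {
  a <- merge(as.data.table(assignments), as.data.table(classes), by = "id")
  a[, inside := tad != "BETWEEN"]
  fr <- a[, .(inside = mean(inside), between = mean(!inside), n = .N),
          by = class]
  bf <- vapply(unique(a$class), function(cl) {
    inc <- a$class == cl
    f <- stats::fisher.test(matrix(c(
      sum(inc & a$near_boundary), sum(inc & !a$near_boundary),
      sum(!inc & a$near_boundary), sum(!inc & !a$near_boundary)),
      2, byrow = TRUE))
    c(odds_ratio = unname(f$estimate), p = f$p.value)
  }, c(odds_ratio = 0, p = 0))
  list(fractions = fr, boundary_fisher = t(bf))
}

#' Enumerate TRE pairs within a maximal distance
#'
#' All unordered pairs of DHSs on the same chromosome whose center
#' points lie within `max_dist` bp, annotated with the distance, a
#' same-TAD flag, the member classes, and whether the pair overlaps a
#' significantly interacting region pair (both members in the two
#' anchors, either orientation).
#'
#' @param dhs `data.table` with `id`, `chrom`, `center` (or
#'   `start`/`end`).
#' @param assignments from [assign_tads()].
#' @param classes `data.table` with `id`, `class`.
#' @param max_dist maximal center-point distance (bp).
#' @param interactions optional `data.table` of anchor pairs
#'   (`chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`).
#' @return `data.table`: `id_i`, `id_j` (i before j by coordinate),
#'   `distance`, `same_tad`, `class_i`, `class_j`,
#'   `overlaps_interaction`.
#' @export
enumerate_pairs <- function(dhs, assignments, classes, max_dist = 1e6,
                            interactions = NULL) {
  d <- as.data.table(dhs)
  if (!"center" %in% names(d))
    d[, center := floor((start + end) / 2)]
  d <- merge(d[, .(id, chrom, center)],
             as.data.table(assignments)[, .(id, tad)], by = "id")
  d <- merge(d, as.data.table(classes), by = "id")
  setorder(d, chrom, center)
  pairs <- d[, {
    n <- .N
    if (n < 2L) NULL else {
      idx <- rbindlist(lapply(seq_len(n - 1L), function(i) {
        j <- which(center[(i + 1L):n] - center[i] <= max_dist) + i
        if (length(j)) data.table(i = i, j = j) else NULL
      }))
      if (is.null(idx) || nrow(idx) == 0L) NULL else
        data.table(id_i = id[idx$i], id_j = id[idx$j],
                   distance = center[idx$j] - center[idx$i],
                   same_tad = tad[idx$i] == tad[idx$j] &
                     tad[idx$i] != "BETWEEN",
                   class_i = class[idx$i], class_j = class[idx$j],
                   c_i = center[idx$i], c_j = center[idx$j])
    }
  }, by = chrom]
  if (nrow(pairs) == 0L) return(pairs)
  pairs[, overlaps_interaction := FALSE]
  if (!is.null(interactions) && nrow(interactions)) {
    ia <- as.data.table(interactions)
    for (r in seq_len(nrow(ia))) {
      in1 <- pairs$chrom == ia$chrom1[r] &
        pairs$c_i >= ia$start1[r] & pairs$c_i < ia$end1[r]
      in2 <- pairs$chrom == ia$chrom2[r] &
        pairs$c_j >= ia$start2[r] & pairs$c_j < ia$end2[r]
      rev1 <- pairs$chrom == ia$chrom2[r] &
        pairs$c_i >= ia$start2[r] & pairs$c_i < ia$end2[r]
      rev2 <- pairs$chrom == ia$chrom1[r] &
        pairs$c_j >= ia$start1[r] & pairs$c_j < ia$end1[r]
      pairs[, overlaps_interaction := overlaps_interaction |
              (in1 & in2) | (rev1 & rev2)]
    }
  }
  pairs[, c("c_i", "c_j") := NULL]
  pairs[]
}

#' Within-TAD co-occurrence GLM for a focal DHS class
#'
#' Binomial logistic model of the odds that a pair involving the focal
#' class shares a TAD, as a function of the partner's class (deviation /
#' sum-to-zero coding, so each coefficient is the change in log-odds
#' relative to encountering an average/random partner) with the
#' log10 pair distance as covariate.  Only DHSs residing in TADs with at
#' least `min_tad_elements` members (or between TADs) enter.
#'
#' @param pairs from [enumerate_pairs()].
#' @param focal focal class label.
#' @param assignments from [assign_tads()] (for the TAD-size filter).
#' @param min_tad_elements minimal DHS count per eligible TAD.
#' @return `data.table`: `partner_class`, `estimate`, `se`, `z`, `p`,
#'   `stars`, plus the distance coefficient; attribute `"separation"`
#'   flags non-estimable fits.
#' @export
cooccurrence_glm <- function(pairs, focal, assignments = NULL,
                             min_tad_elements = 3L) {
  p <- as.data.table(pairs)
  if (!is.null(assignments)) {
    a <- as.data.table(assignments)
    sizes <- a[tad != "BETWEEN", .N, by = tad]
    ok_tad <- sizes[N >= min_tad_elements, tad]
    ok_id <- a[tad %in% ok_tad | tad == "BETWEEN", id]
    p <- p[id_i %in% ok_id & id_j %in% ok_id]
  }
  p <- p[class_i == focal | class_j == focal]
  if (nrow(p) == 0L) stopf("no pairs involving focal class %s", focal)
  p[, partner := ifelse(class_i == focal, class_j, class_i)]
  cooccurrence_glm_fit(y = as.integer(p$same_tad),
                       partner = factor(p$partner),
                       logd = log10(pmax(p$distance, 1)))
}

#' Cluster TADs by their DHS class composition
#'
#' Per-TAD counts of DHSs per class (TADs with at least `min_elements`
#' members), log2(count + 1) transformed and clustered with k-means
#' (k-means++ initialization, fixed seed).  Also reports the TAD-size
#' enrichment table: per total element count (grouping all TADs with
#' more than six elements), the class proportions.
#'
#' @param assignments from [assign_tads()].
#' @param classes `data.table` with `id`, `class`.
#' @param min_elements minimal DHS count per clustered TAD.
#' @param k number of TAD clusters.
#' @param seed RNG seed.
#' @return list with `clusters` (`data.table`: tad, cluster), `centers`,
#'   `size_enrichment`, `counts`.
#' @export
tad_composition_clusters <- function(assignments, classes,
                                     min_elements = 3L, k = 7L,
                                     seed = 1L) {
  a <- merge(as.data.table(assignments)[tad != "BETWEEN"],
             as.data.table(classes), by = "id")
  counts <- dcast(a[, .N, by = .(tad, class)], tad ~ class,
                  value.var = "N", fill = 0L)
  cls <- setdiff(names(counts), "tad")
  counts[, total := rowSums(as.matrix(.SD)), .SDcols = cls]
  eligible <- counts[total >= min_elements]
  if (nrow(eligible) < k)
    stopf("fewer eligible TADs (%d) than k = %d", nrow(eligible), k)
  mat <- log2(as.matrix(eligible[, cls, with = FALSE]) + 1)
  set.seed(seed)
  km <- kmeans_pp(mat, k)
  eff <- length(unique(km$cluster))
  if (eff < k) warnf("only %d effective TAD clusters (of k = %d)", eff, k)
  size_tab <- copy(counts)
  size_tab[, size_group := ifelse(total > 6L, ">6", as.character(total))]
  se <- size_tab[, lapply(.SD, function(v) sum(v) / sum(total)),
                 .SDcols = cls, by = size_group]
  list(clusters = data.table(tad = eligible$tad, cluster = km$cluster),
       centers = km$centers, size_enrichment = se[order(size_group)],
       counts = counts)
}

#' Interaction-target enhancer-potential model
#'
#' For significantly interacting DHS pairs, a binomial GLM of whether
#' the partner (target) DHS has hkCP (resp. dCP) enhancer potential
#' versus no STARR potential at all, as a function of the focal DHS
#' class (deviation coding) and log10 distance.
#'
#' @param pairs from [enumerate_pairs()] (uses
#'   `overlaps_interaction == TRUE` rows).
#' @param hk,dcp call tables from [starr_call()].
#' @param potential `"hkCP"` or `"dCP"`: which target potential to model.
#' @return as [cooccurrence_glm()]; `NULL` with a message when no
#'   interacting pairs are supplied.
#' @export
interaction_target_model <- function(pairs, hk, dcp,
                                     potential = c("hkCP", "dCP")) {
  potential <- match.arg(potential)
  p <- as.data.table(pairs)[overlaps_interaction == TRUE]
  if (nrow(p) == 0L) {
    message("no interacting pairs supplied; empty model")
    return(NULL)
  }
  act <- merge(as.data.table(hk)[, .(id, hk_active = active)],
               as.data.table(dcp)[, .(id, dcp_active = active)], by = "id")
  # direction both ways: each member in turn is the focal element
  both <- rbind(p[, .(focal_class = class_i, target = id_j,
                      distance = distance)],
                p[, .(focal_class = class_j, target = id_i,
                      distance = distance)])
  both <- merge(both, act, by.x = "target", by.y = "id")
  pos <- if (potential == "hkCP") both$hk_active else both$dcp_active
  none <- !both$hk_active & !both$dcp_active
  keep <- pos | none
  if (!any(pos[keep]) || all(pos[keep])) {
    res <- data.table(partner_class = sort(unique(both$focal_class[keep])),
                      estimate = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, stars = "")
    setattr(res, "separation", TRUE)
    return(res)
  }
  cooccurrence_glm_fit(y = as.integer(pos[keep]),
                       partner = factor(both$focal_class[keep]),
                       logd = log10(pmax(both$distance[keep], 1)))
}

# shared deviation-coded binomial fit (used by interaction_target_model)
cooccurrence_glm_fit <- function(y, partner, logd) {
  dat <- data.frame(y = y, partner = partner, logd = logd)
  if (nlevels(dat$partner) == 1L) {
    res <- data.table(partner_class = levels(dat$partner), estimate = 0,
                      se = NA_real_, z = NA_real_, p = NA_real_, stars = "")
    setattr(res, "separation", length(unique(y)) < 2L)
    return(res)
  }
  contrasts(dat$partner) <- stats::contr.sum(nlevels(dat$partner))
  fit <- suppressWarnings(
    stats::glm(y ~ partner + logd, family = stats::binomial(), data = dat))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 20, na.rm = TRUE)
  cf <- summary(fit)$coefficients
  lev <- levels(dat$partner)
  k <- length(lev)
  ix <- paste0("partner", seq_len(k - 1L))
  est <- cf[ix, "Estimate"]
  se <- cf[ix, "Std. Error"]
  V <- stats::vcov(fit)[ix, ix, drop = FALSE]
  res <- data.table(partner_class = lev,
                    estimate = c(est, -sum(est)),
                    se = c(se, sqrt(sum(V))))
  res[, z := estimate / se]
  res[, p := 2 * stats::pnorm(-abs(z))]
  res[, stars := ifelse(p < 0.001, "***",
                 ifelse(p < 0.01, "**", ifelse(p < 0.1, "*", "")))]
  dist_row <- data.table(partner_class = "log10_distance",
                         estimate = cf["logd", "Estimate"],
                         se = cf["logd", "Std. Error"],
                         z = cf["logd", "z value"],
                         p = cf["logd", "Pr(>|z|)"], stars = "")
  out <- rbind(res, dist_row)
  setattr(out, "separation", sep)
  out[]
}
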