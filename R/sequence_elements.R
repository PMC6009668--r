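# Core-promoter element scans around CAGE summits: motif models (minimal
# MEME format), exact p-values by dynamic-programming convolution,
# strand-oriented window scans, positional profiles, core-promoter
# composition clustering, and downstream 5'SS / polyadenylation
# profiles.

BASES <- c("A", "C", "G", "T")

IUPAC <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"), N = BASES)

#' Construct a motif model
#'
#' A motif model holds a per-position base probability matrix (rows
#' A/C/G/T summing to 1 per column), a background composition, and scores
#' sequences by summed log2 odds.  Probabilities are floored at `floor_p`
#' and renormalized so log-odds are finite.
#'
#' @param name motif name.
#' @param mat 4 x L numeric matrix (rows A, C, G, T).
#' @param background length-4 base composition (default uniform).
#' @param floor_p probability floor.
#' @return object of class `motif_model`.
#' @export
motif_model <- function(name, mat, background = rep(0.25, 4),
                        floor_p = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, all(mat >= 0))
  if (any(abs(colSums(mat) - 1) > 1e-9))
    stopf("motif %s: column probabilities must sum to 1", name)
  if (abs(sum(background) - 1) > 1e-6)
    stopf("motif %s: background not normalized", name)
  mat <- pmax(mat, floor_p)
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- BASES
  structure(list(name = name, mat = mat, background = background,
                 score_mat = log2(mat / background)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model %s: length %d>\n", x$name, ncol(x$mat)))
  invisible(x)
}

#' Motif model from an IUPAC consensus
#'
#' Degenerate bases expand to probability columns sharing the mass among
#' the allowed bases.
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string (e.g. `"AWTAAA"`).
#' @inheritParams motif_model
#' @return `motif_model`.
#' @export
motif_from_consensus <- function(name, consensus,
                                 background = rep(0.25, 4)) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  cols <- lapply(letters, function(ch) {
    allowed <- IUPAC[[ch]]
    if (is.null(allowed)) stopf("unknown IUPAC code '%s'", ch)
    p <- rep(0, 4)
    p[match(allowed, BASES)] <- 1 / length(allowed)
    p
  })
  motif_model(name, do.call(cbind, cols), background)
}

# ---- minimal MEME motif format ---------------------------------------

#' Read motifs in minimal MEME format
#'
#' @param path MEME minimal motif file.
#' @return named list of [motif_model()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    tok <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF", lines)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[(s + 1):length(lines)])[1] + s
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    motifs[[name]] <- motif_model(name, t(m), bg)
  }
  motifs
}

#' Write motifs in minimal MEME format
#'
#' @param motifs list of [motif_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- motifs[[1]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "", "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
           "")
  for (m in motifs) {
    out <- c(out, sprintf("MOTIF %s", m$name),
             sprintf("letter-probability matrix: alength= 4 w= %d",
                     ncol(m$mat)),
             apply(m$mat, 2, function(p)
               sprintf(" %.6f %.6f %.6f %.6f", p[1], p[2], p[3], p[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Built-in core-promoter and processing motif models
#'
#' Consensus-derived toy matrices for the nine core-promoter elements
#' used throughout (TATA, Inr, DPE, MTE, E-box/Ohler5, Ohler1, DRE,
#' Ohler6, Trl) plus a canonical splice-donor model (`donor5SS`) and the
#' degenerate polyadenylation hexamer (`polyA`).  These are synthetic
#' stand-ins built from published consensus strings, intended for testing
#' and for the synthetic data generator; real analyses should load
#' curated matrices via [read_meme()].
#'
#' @param background base composition.
#' @return named list of [motif_model()] objects.
#' @export
builtin_motifs <- function(background = rep(0.25, 4)) {
  cons <- c(TATA = "STATAWAWR", Inr = "TCAGTY", DPE = "RGWYGT",
            MTE = "CSARCSSAACGS", Ebox = "CACGTG", Ohler1 = "YGGTCACACTR",
            DRE = "WATCGATW", Ohler6 = "KTYRGTATWTTT", Trl = "GAGAGAG",
            polyA = "AWTAAA")
  out <- lapply(names(cons), function(nm)
    motif_from_consensus(nm, cons[[nm]], background))
  names(out) <- names(cons)
  # canonical donor site composition (positions -3..+6 around the exon/
  # intron boundary; GT dinucleotide near-invariant)
  donor <- cbind(c(.35, .35, .20, .10),  # -3  M-ish
                 c(.60, .10, .10, .20),  # -2  A
                 c(.10, .03, .80, .07),  # -1  G
                 c(.001, .001, .997, .001),  # +1 G
                 c(.001, .001, .001, .997),  # +2 T
                 c(.55, .03, .37, .05),  # +3 R
                 c(.70, .08, .10, .12),  # +4 A
                 c(.08, .06, .80, .06),  # +5 G
                 c(.16, .16, .20, .48))  # +6 T
  out$donor5SS <- motif_model("donor5SS", donor, background)
  out
}

# ---- exact p-values ---------------------------------------------------

#' Exact motif score p-values by dynamic programming
#'
#' Computes the exact null distribution of the motif log-odds score under
#' the background composition by dynamic-programming convolution over
#' positions: the distribution over attainable score sums is carried
#' forward one motif column at a time, merging scores that agree to
#' `tol` bits (far finer than 0.01-bit discretization), so the upper-tail
#' map `p(s) = P(score >= s)` agrees with exhaustive enumeration over all
#' `4^L` words to floating-point accuracy.
#'
#' Scores within `tol` bits are treated as equal (both when merging the
#' support and when answering queries), so `pvalue(s)` returns
#' `P(score >= s - tol / 2)`.
#'
#' @param motif [motif_model()].
#' @param tol score equality tolerance in bits.
#' @return object of class `motif_pvalues` with `$pvalue(s)` (vectorized),
#'   the score `support` and tail probabilities `tail_p`.
#' @export
motif_pvalue_table <- function(motif, tol = 1e-7) {
  sm <- motif$score_mat
  bg <- motif$background
  if (abs(sum(bg) - 1) > 1e-6) stopf("non-normalized background")
  vals <- 0
  probs <- 1
  for (j in seq_len(ncol(sm))) {
    nv <- as.vector(outer(vals, sm[, j], "+"))
    np <- as.vector(outer(probs, bg, "*"))
    key <- round(nv / tol)
    # group true ties by the rounded key but keep the exact score sums
    # (probability-weighted representative), so the support does not
    # drift onto the rounding grid; rowsum orders groups ascending
    wsum <- rowsum(cbind(np, np * nv), key)
    probs <- wsum[, 1]
    vals <- wsum[, 2] / probs
    if (length(vals) > 5e6)
      stopf("motif %s: score support too large for exact convolution",
            motif$name)
  }
  tail_p <- rev(cumsum(rev(probs)))
  support <- vals
  pvalue <- function(s) {
    # smallest support value >= s - tol/2; beyond the maximum -> 0
    i <- findInterval(s - tol / 2, support) + 1L
    ifelse(i > length(support), 0, tail_p[pmax(i, 1L)])
  }
  structure(list(support = support, prob = probs, tail_p = tail_p,
                 pvalue = pvalue, tol = tol, name = motif$name),
            class = "motif_pvalues")
}

#' Minimal score reaching a significance threshold
#'
#' @param ptab [motif_pvalue_table()] result.
#' @param p_threshold significance level.
#' @return smallest support score with `p < p_threshold` (`Inf` if none).
#' @export
score_cutoff <- function(ptab, p_threshold) {
  i <- which(ptab$tail_p < p_threshold)
  if (length(i)) ptab$support[min(i)] else Inf
}

# ---- scanning ---------------------------------------------------------

encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], BASES)
  x
}

# scores of a motif at every start offset of an encoded window
pwm_scores <- function(enc, sm) {
  L <- ncol(sm)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric())
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- sm[cbind(enc[j:(j + n - 1L)], j)]
    v[is.na(v)] <- min(sm)  # N bases score minimally
    sc <- sc + v
  }
  sc
}

# strand-oriented window sequence around a 0-based summit
oriented_window <- function(genome, chrom, pos, strand, up, down) {
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (strand == "+") { a <- pos - up; b <- pos + down }
  else { a <- pos - down; b <- pos + up }
  a0 <- max(a, 0L); b0 <- min(b, len - 1L)
  truncated <- (a0 != a) || (b0 != b)
  s <- as.character(Biostrings::subseq(genome[[chrom]], a0 + 1L, b0 + 1L))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # offset (TSS-relative, negative upstream) of the first character
  first_off <- if (strand == "+") a0 - pos else pos - b0
  list(seq = s, first_off = first_off, truncated = truncated)
}

#' Scan motif occurrences around CAGE summits
#'
#' Scans the strand-oriented sequence window `[-flank, +flank]` around
#' each summit and keeps, per motif and window, the maximum-score hit.
#' Hits are significant iff their exact p-value ([motif_pvalue_table()])
#' is below `p_threshold`.  Offsets are TSS-relative (negative =
#' upstream) and refer to the motif start.  Windows truncated at contig
#' edges are scanned as-is and flagged.
#'
#' @param genome `DNAStringSet`.
#' @param summits `data.table` with `id`, `strand_role` (`"major"` /
#'   `"minor"`), `chrom`, `pos` (0-based summit), `strand`.
#' @param motifs named list of [motif_model()].
#' @param flank half-window in bp.
#' @param p_threshold significance threshold on the exact p-value.
#' @return `data.table`: `id`, `strand_role`, `motif`, `offset`, `score`,
#'   `p_value`, `significant`, `truncated`.
#' @export
scan_windows <- function(genome, summits, motifs, flank = 50L,
                         p_threshold = 0.001) {
  summits <- as.data.table(summits)[!is.na(pos)]
  ptabs <- lapply(motifs, motif_pvalue_table)
  out <- vector("list", nrow(summits) * length(motifs))
  kk <- 0L
  for (i in seq_len(nrow(summits))) {
    w <- oriented_window(genome, summits$chrom[i], summits$pos[i],
                         summits$strand[i], flank, flank)
    enc <- encode_seq(w$seq)
    for (mn in names(motifs)) {
      sm <- motifs[[mn]]$score_mat
      sc <- pwm_scores(enc, sm)
      if (length(sc) == 0L) next
      b <- which.max(sc)
      pv <- ptabs[[mn]]$pvalue(sc[b])
      kk <- kk + 1L
      out[[kk]] <- data.table(
        id = summits$id[i], strand_role = summits$strand_role[i],
        motif = mn, offset = w$first_off + b - 1L, score = sc[b],
        p_value = pv, significant = pv < p_threshold,
        truncated = w$truncated)
    }
  }
  rbindlist(out[seq_len(kk)])
}

#' Positional profile of motif occurrences
#'
#' Fraction of elements with a significant motif hit at each TSS-relative
#' offset, per motif and strand role.
#'
#' @param hits hit table from [scan_windows()].
#' @param n_elements number of scanned elements per strand role
#'   (denominator), a named vector or scalar.
#' @return `data.table`: `motif`, `strand_role`, `offset`, `fraction`.
#' @export
positional_profile <- function(hits, n_elements) {
  h <- as.data.table(hits)[significant == TRUE]
  if (nrow(h) == 0L)
    return(data.table(motif = character(), strand_role = character(),
                      offset = integer(), fraction = numeric()))
  prof <- h[, .N, by = .(motif, strand_role, offset)]
  denom <- function(sr) if (length(n_elements) > 1L) n_elements[[sr]]
                        else n_elements
  prof[, fraction := N / vapply(strand_role, denom, 0)]
  prof[, N := NULL]
  setorder(prof, motif, strand_role, offset)
  prof[]
}

#' Cluster core-promoter element compositions
#'
#' Rows are DHS strand windows, columns are motifs, values are the
#' maximum match score (non-significant windows contribute the motif's
#' minimum attainable score).  Columns are z-scaled, rows clustered by
#' Ward agglomerative hierarchical clustering on Euclidean distances, and
#' the tree cut at `k` clusters.  Per class x cluster, the log2
#' enrichment of the class's strand windows versus all strand windows is
#' computed with one-sided Fisher tests.
#'
#' @param hits hit table from [scan_windows()] (all scanned windows).
#' @param motifs named list of motifs scanned (defines columns and
#'   minimum scores).
#' @param classes optional `data.table` with `id`, `class` for the
#'   enrichment matrix.
#' @param k number of composition clusters.
#' @return list with `cluster` (`data.table`: `id`, `strand_role`,
#'   `cluster`), `matrix`, and (when classes are given) `enrichment` and
#'   `fisher_p`.
#' @export
cluster_core_promoters <- function(hits, motifs, classes = NULL, k = 10L) {
  h <- as.data.table(hits)
  min_score <- vapply(motifs, function(m) sum(apply(m$score_mat, 2, min)), 0)
  h[, val := ifelse(significant, score, min_score[motif])]
  wide <- dcast(h, id + strand_role ~ motif, value.var = "val",
                fill = NA)
  for (mn in names(motifs))
    wide[is.na(get(mn)), (mn) := min_score[[mn]]]
  mat <- as.matrix(wide[, names(motifs), with = FALSE])
  if (k > nrow(mat)) stopf("k = %d exceeds %d rows", k, nrow(mat))
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stopf("degenerate scaling: constant motif score column(s): %s",
          paste(names(motifs)[sds == 0], collapse = ", "))
  z <- scale(mat)
  hc <- stats::hclust(stats::dist(z), method = "ward.D")
  cl <- stats::cutree(hc, k = k)
  res <- data.table(id = wide$id, strand_role = wide$strand_role,
                    cluster = cl)
  out <- list(cluster = res, matrix = mat)
  if (!is.null(classes)) {
    cc <- merge(res, as.data.table(classes), by = "id")
    tot_frac <- table(factor(cc$cluster, levels = seq_len(k))) / nrow(cc)
    classes_u <- sort(unique(cc$class))
    enr <- matrix(NA_real_, length(classes_u), k,
                  dimnames = list(classes_u, seq_len(k)))
    fp <- enr
    for (cls in classes_u) {
      inc <- cc$class == cls
      cf <- table(factor(cc$cluster[inc], levels = seq_len(k))) / sum(inc)
      enr[cls, ] <- log2(as.numeric(cf) / as.numeric(tot_frac))
      for (j in seq_len(k)) {
        a <- sum(inc & cc$cluster == j)
        fp[cls, j] <- stats::fisher.test(
          matrix(c(a, sum(inc) - a,
                   sum(!inc & cc$cluster == j),
                   sum(!inc & cc$cluster != j)), 2, byrow = TRUE),
          alternative = "greater")$p.value
      }
    }
    out$enrichment <- enr
    out$fisher_p <- fp
  }
  out
}

#' Downstream RNA-processing motif profiles
#'
#' For each window size `w` on a grid up to `max_window`, the mean (over
#' elements) number of predicted sites per bp in the strand-oriented
#' downstream window `[summit, summit + w)`, minus the same statistic
#' over random background positions.  Polyadenylation sites are exact
#' degenerate AWTAAA hexamer matches; 5' splice sites are donor-PWM hits
#' with exact p-value below `p_threshold`.
#'
#' @param genome `DNAStringSet`.
#' @param summits `data.table` with `chrom`, `pos`, `strand` (one row per
#'   element strand).
#' @param background_positions same layout; TSS-unlikely positions.
#' @param motif `"polyA"` or `"five_prime_SS"`.
#' @param max_window largest window (bp).
#' @param step window grid step (bp).
#' @param p_threshold PWM significance threshold (5'SS only).
#' @param donor donor-site [motif_model()] (default built-in).
#' @return `data.table`: `w`, `signal_rate`, `bg_rate`, `excess`
#'   (sites per bp).
#' @export
downstream_processing_profile <- function(genome, summits,
                                          background_positions,
                                          motif = c("polyA",
                                                    "five_prime_SS"),
                                          max_window = 1000L, step = 50L,
                                          p_threshold = 0.001,
                                          donor = NULL) {
  motif <- match.arg(motif)
  ws <- seq(step, max_window, by = step)
  cutoff <- NULL
  if (motif == "five_prime_SS") {
    donor <- donor %||% builtin_motifs()$donor5SS
    cutoff <- score_cutoff(motif_pvalue_table(donor), p_threshold)
  }
  rate_curve <- function(pts) {
    counts <- matrix(0, nrow(pts), length(ws))
    for (i in seq_len(nrow(pts))) {
      w <- oriented_window(genome, pts$chrom[i], pts$pos[i], pts$strand[i],
                           up = 0L, down = max_window - 1L)
      starts <- hit_starts(w$seq, motif, cutoff, donor)
      starts <- starts + w$first_off  # 0-based offsets from summit
      counts[i, ] <- vapply(ws, function(wd) sum(starts < wd), 0)
    }
    colMeans(sweep(counts, 2, ws, "/"))
  }
  sig <- rate_curve(as.data.table(summits)[!is.na(pos)])
  bg <- rate_curve(as.data.table(background_positions))
  data.table(w = ws, signal_rate = sig, bg_rate = bg, excess = sig - bg)
}

# 0-based match start offsets within a character sequence
hit_starts <- function(s, motif, cutoff = NULL, donor = NULL) {
  if (motif == "polyA") {
    # lookahead so that overlapping hexamer occurrences are all counted
    m <- gregexpr("(?=A[AT]TAAA)", s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(integer())
    as.integer(m) - 1L
  } else {
    sc <- pwm_scores(encode_seq(s), donor$score_mat)
    which(sc >= cutoff) - 1L
  }
}
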