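# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Strand must be "+" or "-" (or "." where allowed).
check_strand <- function(strand, allow_dot = FALSE) {
  ok <- strand %in% c("+", "-", if (allow_dot) ".")
  if (!all(ok)) stopf("invalid strand value(s): %s",
                      paste(unique(strand[!ok]), collapse = ", "))
  invisible(strand)
}

# Empirical noise-quantile convention: smallest value with strictly more
# than p of the mass at or below it, i.e. the order statistic
# x[floor(p * n) + 1] (capped at n).  With {0 x 9990, 5 x 10} and p = 0.999
# this returns 5, whereas x[ceiling(p * n)] would return 0.
empirical_threshold <- function(x, p) {
  stopifnot(length(x) >= 1, p >= 0, p <= 1)
  xs <- sort(x)
  xs[min(length(xs), floor(p * length(xs)) + 1L)]
}

# k-means with k-means++ initialization (stats::kmeans has no ++ init).
# Several ++ restarts guard against poor local optima; deterministic
# given the RNG state.  Returns the stats::kmeans object.
kmeans_pp <- function(x, k, iter.max = 100L, nstart_pp = 25L) {
  x <- as.matrix(x)
  ux <- unique(x)
  if (nrow(ux) < k)
    stopf("k-means: k = %d exceeds the number of distinct points (%d)",
          k, nrow(ux))
  best <- NULL
  for (s in seq_len(nstart_pp)) {
    centers <- kmeanspp_init(x, k)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 <= 0)) {
      # degenerate: remaining points coincide with chosen centers
      cand <- which(!duplicated(x))
      cand <- setdiff(cand, idx)
      idx <- c(idx, cand[seq_len(min(length(cand), 1L))])
      centers[j, ] <- x[idx[length(idx)], ]
    } else {
      pick <- sample.int(n, 1L, prob = d2 / sum(d2))
      idx <- c(idx, pick)
      centers[j, ] <- x[pick, ]
    }
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  # ensure distinct centers
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    pool <- unique(x)
    used <- apply(centers, 1, paste, collapse = "\r")
    avail <- pool[!(apply(pool, 1, paste, collapse = "\r") %in% used), ,
                  drop = FALSE]
    for (j in dup) {
      centers[j, ] <- avail[1L, ]
      avail <- avail[-1L, , drop = FALSE]
    }
  }
  centers
}

# chromosome sizes as a named integer vector, from a DNAStringSet or a
# named numeric vector.
chrom_sizes <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else if (is.numeric(genome) && !is.null(names(genome))) {
    genome
  } else {
    stopf("genome must be a DNAStringSet or a named numeric vector of sizes")
  }
}
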