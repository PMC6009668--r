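# Two-step unsupervised clustering of per-replicate DHS transcriptional
# features into six replicate-consistent classes, semantic labelling by
# per-cluster medians, and annotation crosstabs.

#' The six TRE class labels
#' @return character vector of semantic class labels (stable first).
#' @export
tre_classes <- function() {
  c("unidirectional_stable", "unidirectional_stable_PROMPT",
    "bidirectional_stable", "weak_bidirectional_unstable",
    "intermediate_bidirectional_unstable", "weak_unidirectional_unstable")
}

#' Build per-replicate DHS feature rows for clustering
#'
#' One row per transcribed DHS and replicate, with five features:
#' log2 major and minor strand KD expression (`log2(TPM + pseudo)`),
#' major and minor strand exosome sensitivity from the paired
#' control/KD replicate, and KD-derived directionality.  A sensitivity
#' is undefined — and treated as missing — when the strand's KD
#' expression in that replicate does not exceed the noise floor
#' (`noise_tpm`; a ratio against background-level expression carries no
#' information).  Missing values are imputed with the per-column mean,
#' then all columns are standardized to mean 0, sd 1.  Constant columns
#' are dropped with a warning.
#'
#' @param expr per-library strand expression from [quantify_dhs()].
#' @param quant DHS summary from [quantify_dhs()] (for `major_strand`).
#' @param libs library table (replicates pair condition libraries).
#' @param transcribed logical per DHS id in `quant`; only transcribed
#'   DHSs enter the feature table.
#' @param pseudo pseudocount for the log expression features.
#' @param noise_tpm per-library noise floor (TPM): a scalar, or a named
#'   vector over library ids.  0 disables the floor (sensitivity is
#'   then missing only at zero KD expression).
#' @return list with `mat` (standardized feature matrix), `rows`
#'   (`data.table` of `id`, `replicate`) and `raw` (unstandardized).
#' @export
build_features <- function(expr, quant, libs, transcribed = NULL,
                           pseudo = 1, noise_tpm = 0) {
  quant <- as.data.table(quant)
  if (!is.null(transcribed)) quant <- quant[transcribed]
  e <- merge(as.data.table(expr), quant[, .(id, major_strand)], by = "id")
  e <- merge(e, libs[, .(lib = id, condition, replicate)], by = "lib")
  e[, `:=`(tpm_major = ifelse(major_strand == "+", tpm_plus, tpm_minus),
           tpm_minor = ifelse(major_strand == "+", tpm_minus, tpm_plus))]
  w <- dcast(e, id + replicate ~ condition,
             value.var = c("tpm_major", "tpm_minor"))
  if (length(noise_tpm) > 1L) {
    kd_libs <- libs[condition == "exosomeKD"]
    floor_tpm <- stats::setNames(noise_tpm[kd_libs$id], kd_libs$replicate)
    w[, floor_r := floor_tpm[as.character(replicate)]]
  } else w[, floor_r := noise_tpm]
  feat <- w[, .(id, replicate,
                e_major = log2(tpm_major_exosomeKD + pseudo),
                e_minor = log2(tpm_minor_exosomeKD + pseudo),
                s_major = ifelse(tpm_major_exosomeKD > floor_r,
                                 exosome_sensitivity(tpm_major_control,
                                                     tpm_major_exosomeKD),
                                 NA_real_),
                s_minor = ifelse(tpm_minor_exosomeKD > floor_r,
                                 exosome_sensitivity(tpm_minor_control,
                                                     tpm_minor_exosomeKD),
                                 NA_real_),
                dir = directionality_score(tpm_major_exosomeKD,
                                           tpm_minor_exosomeKD))]
  cols <- c("e_major", "e_minor", "s_major", "s_minor", "dir")
  raw <- as.matrix(feat[, cols, with = FALSE])
  colnames(raw) <- cols
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j]
    if (all(is.na(v))) v[] <- 0           # no information: drops below
    else if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    raw[, j] <- v
  }
  sds <- apply(raw, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warnf("dropping constant feature column(s): %s",
          paste(cols[!keep], collapse = ", "))
  mat <- scale(raw[, keep, drop = FALSE])
  list(mat = mat, rows = feat[, .(id, replicate)],
       raw = raw[, keep, drop = FALSE])
}

#' Two-step consensus clustering of DHS feature rows
#'
#' Step 1 clusters all DHS-by-replicate rows into `k` groups by k-means
#' (k-means++ initialization, fixed seed).  Step 2 summarizes each DHS as
#' its `k`-dimensional composition vector (fraction of its rows per
#' step-1 group) and clusters those vectors by k-means (same `k`, same
#' seed policy) into consensus clusters.  The final class of a DHS is the
#' modal step-1 group among its rows; ties are resolved by the largest
#' component of its consensus cluster's centroid (then the smallest group
#' index).  `replicate_agreement` is the modal count; a DHS is removed
#' iff agreement falls below `removal_min_agreement`.
#'
#' @param features feature list from [build_features()].
#' @param k number of clusters (6 classes by default).
#' @param seed RNG seed for both k-means steps.
#' @param removal_min_agreement minimal modal count to keep a DHS.
#' @return `data.table` with `id`, `cluster` (1..k), `consensus`,
#'   `agreement`, `removed`.
#' @export
two_step_cluster <- function(features, k = 6L, seed = 1L,
                             removal_min_agreement = 2L) {
  mat <- features$mat
  rows <- features$rows
  ids <- unique(rows$id)
  if (k > length(ids)) stopf("k = %d exceeds the number of DHSs (%d)",
                             k, length(ids))
  set.seed(seed)
  km1 <- kmeans_pp(mat, k)
  g <- km1$cluster
  comp <- matrix(0, length(ids), k, dimnames = list(ids, NULL))
  for (j in seq_len(k)) {
    tab <- tapply(g == j, rows$id, mean)
    comp[names(tab), j] <- tab
  }
  km2 <- kmeans_pp(comp, k)
  res <- rbindlist(lapply(seq_along(ids), function(i) {
    gi <- g[rows$id == ids[i]]
    tab <- tabulate(gi, nbins = k)
    m <- max(tab)
    cand <- which(tab == m)
    if (length(cand) > 1L) {
      cen <- km2$centers[km2$cluster[i], ]
      cand <- cand[order(-cen[cand], cand)]
    }
    data.table(id = ids[i], cluster = cand[1L],
               consensus = km2$cluster[i], agreement = m)
  }))
  res[, removed := agreement < removal_min_agreement]
  res[]
}

#' Map clusters to the six semantic TRE class labels
#'
#' Clusters are labelled from their medians over non-removed member DHSs:
#' major-strand sensitivity `s`, directionality `d`, the fraction `m` of
#' members whose minor strand is expressed above noise, median minor
#' sensitivity `sm`, and median major KD expression `e`.  Rules: a
#' cluster is *stable* iff `s < sens_cut`; among stable clusters,
#' `bidirectional_stable` iff `d < dir_bidir`, else
#' `unidirectional_stable_PROMPT` iff `m >= minor_frac` and
#' `sm > minor_sens`, else `unidirectional_stable`.  Among unstable
#' clusters, `weak_unidirectional_unstable` iff `d > dir_uni`; the
#' remaining two are split by `e` (lower ->
#' `weak_bidirectional_unstable`, higher ->
#' `intermediate_bidirectional_unstable`).  Each label must be used
#' exactly once; otherwise labelling fails with the cluster medians in
#' the error.
#'
#' @param assignments from [two_step_cluster()].
#' @param quant DHS summary from [quantify_dhs()].
#' @param minor_expressed logical per DHS id in `quant`: minor strand
#'   above noise in enough replicates (see [filter_by_noise()]).
#' @param sens_cut,dir_bidir,dir_uni,minor_frac,minor_sens rule cutoffs.
#' @return list with `labels` (`data.table`: `cluster`, `class`,
#'   `superclass`), `medians`, and `assignments` augmented with `class`.
#' @export
label_classes <- function(assignments, quant, minor_expressed,
                          sens_cut = 0.5, dir_bidir = 0.4, dir_uni = 0.7,
                          minor_frac = 0.5, minor_sens = 0.5) {
  qsub <- as.data.table(quant)[, .(id, sens_major, sens_minor,
                                   directionality, tpm_major_kd)]
  a <- merge(as.data.table(assignments)[removed == FALSE], qsub,
             by = "id")
  me <- data.table(id = qsub$id, minor_ex = minor_expressed)
  a <- merge(a, me, by = "id")
  med <- a[, .(
    s = stats::median(sens_major, na.rm = TRUE),
    d = stats::median(directionality, na.rm = TRUE),
    e = stats::median(tpm_major_kd, na.rm = TRUE),
    m = mean(minor_ex),
    sm = stats::median(sens_minor, na.rm = TRUE),
    n = .N), by = cluster][order(cluster)]
  k <- nrow(med)
  if (k != 6L) stopf("expected 6 clusters with members, got %d", k)
  fail <- function(why) {
    stopf("class labelling failed (%s); cluster medians:\n%s", why,
          paste(utils::capture.output(print(med)), collapse = "\n"))
  }
  lab <- rep(NA_character_, k)
  stable <- which(med$s < sens_cut)
  if (length(stable) != 3L)
    fail(sprintf("%d stable clusters (major sensitivity < %.2f), need 3",
                 length(stable), sens_cut))
  bi <- stable[med$d[stable] < dir_bidir]
  if (length(bi) != 1L) fail("bidirectional_stable rule not unique")
  lab[bi] <- "bidirectional_stable"
  rest <- setdiff(stable, bi)
  pr <- rest[med$m[rest] >= minor_frac &
               !is.na(med$sm[rest]) & med$sm[rest] > minor_sens]
  if (length(pr) != 1L) fail("PROMPT rule not unique among stable clusters")
  lab[pr] <- "unidirectional_stable_PROMPT"
  lab[setdiff(rest, pr)] <- "unidirectional_stable"
  unstable <- setdiff(seq_len(k), stable)
  wu <- unstable[med$d[unstable] > dir_uni]
  if (length(wu) != 1L) fail("weak_unidirectional_unstable rule not unique")
  lab[wu] <- "weak_unidirectional_unstable"
  rem <- setdiff(unstable, wu)
  lab[rem[which.min(med$e[rem])]] <- "weak_bidirectional_unstable"
  lab[rem[which.max(med$e[rem])]] <- "intermediate_bidirectional_unstable"
  if (anyNA(lab) || anyDuplicated(lab)) fail("labels not a bijection")
  labels <- data.table(cluster = med$cluster, class = lab,
                       superclass = ifelse(
                         lab %in% tre_classes()[1:3], "stable", "unstable"))
  out <- merge(as.data.table(assignments),
               labels[, .(cluster, class, superclass)],
               by = "cluster", all.x = TRUE, sort = FALSE)
  out[removed == TRUE, c("class", "superclass") := NA_character_]
  list(labels = labels, medians = med, assignments = out[])
}

#' Gene-annotation crosstab of DHS classes
#'
#' Gene TSSs are extended `up` bp upstream and `down` bp downstream with
#' respect to the gene strand; each DHS is categorized by the strands of
#' the TSS windows it intersects: both strands -> `divergent_gene_pair`,
#' one -> `unidirectional_gene`, none -> `distal`.  A chi-squared test
#' compares each class against the rest.
#'
#' @param dhs `data.table` with `id`, `chrom`, `start`, `end`.
#' @param classes `data.table` with `id`, `class`.
#' @param tss gene TSS table ([gene_tss()]).
#' @param up,down extension in bp relative to the gene strand.
#' @return list with `category` (per DHS), `table`
#'   (class x category counts) and `tests` (per-class chi-squared
#'   p-values).
#' @export
class_annotation_table <- function(dhs, classes, tss, up = 200L,
                                   down = 100L) {
  dhs <- as.data.table(dhs)
  tssx <- as.data.table(tss)[, .(
    chrom, strand,
    start = as.integer(ifelse(strand == "+", pos - up, pos - down)),
    end1 = as.integer(ifelse(strand == "+", pos + down, pos + up)))]
  setkey(tssx, chrom, start, end1)
  q <- dhs[, .(id, chrom, start, end1 = end - 1L)]
  ov <- foverlaps(q, tssx, by.x = c("chrom", "start", "end1"),
                  nomatch = NULL)
  strands <- ov[, .(p = any(strand == "+"), m = any(strand == "-")),
                by = "id"]
  cat <- data.table(id = dhs$id, category = "distal")
  cat[strands[p & m], on = "id", category := "divergent_gene_pair"]
  cat[strands[xor(p, m)], on = "id", category := "unidirectional_gene"]
  cc <- merge(cat, as.data.table(classes), by = "id")
  tab <- table(cc$class, factor(cc$category,
                                levels = c("divergent_gene_pair",
                                           "unidirectional_gene", "distal")))
  tests <- vapply(rownames(tab), function(cl) {
    m <- rbind(tab[cl, ], colSums(tab) - tab[cl, ])
    suppressWarnings(stats::chisq.test(m)$p.value)
  }, 0)
  list(category = cat, table = tab, tests = tests)
}
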