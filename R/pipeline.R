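# End-to-end orchestration: read a data bundle, run the stages in
# dependency order (tag clustering -> noise -> DHS quantification ->
# classification -> motifs -> STARR/ChIP -> TADs) and assemble a report.

#' Read a dataset bundle from disk
#'
#' Reads the file layout written by [write_dataset()]: manifest + CTSS
#' BED6 files, DHS/gene/TAD BEDs, interactions BEDPE, STARR bedGraphs,
#' mark BEDs and the genome FASTA.  Missing optional components (STARR,
#' marks, TADs, interactions, genome) are returned as `NULL`.
#'
#' @param dir bundle directory.
#' @return list of pipeline inputs.
#' @export
read_dataset <- function(dir) {
  must <- function(p) if (file.exists(p)) p else
    stopf("missing input: %s", p)
  opt <- function(p) if (file.exists(p)) p else NULL
  libs <- read_manifest(must(file.path(dir, "manifest.tsv")))
  ctss <- read_ctss(libs = libs)
  libs <- attr(ctss, "libraries")
  dhs <- read_intervals(must(file.path(dir, "dhs.bed")), "bed6")
  genes <- read_intervals(must(file.path(dir, "genes.bed")), "bed6")
  genes[, c("id", "biotype") := tstrsplit(id, "|", fixed = TRUE)]
  genes[is.na(biotype), biotype := "mRNA"]
  tss <- gene_tss(genes)
  gp <- opt(file.path(dir, "genome.fa"))
  genome <- if (!is.null(gp)) Biostrings::readDNAStringSet(gp) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*", "", names(genome))
  tp <- opt(file.path(dir, "tads.bed"))
  tads <- if (!is.null(tp)) read_intervals(tp, "bed6") else NULL
  ip <- opt(file.path(dir, "interactions.bedpe"))
  interactions <- if (!is.null(ip)) {
    x <- fread(ip, header = FALSE)
    setnames(x, 1:6, c("chrom1", "start1", "end1", "chrom2", "start2",
                       "end2"))
    x
  } else NULL
  starr <- list()
  for (tr in c("hk_signal", "dcp_signal", "input")) {
    p <- opt(file.path(dir, paste0("starr_", tr, ".bedGraph")))
    if (!is.null(p)) starr[[tr]] <- read_signal_track(p)
  }
  marks <- list()
  for (p in list.files(dir, pattern = "^marks_.*\\.bed$", full.names = TRUE))
    marks[[sub("^marks_(.*)\\.bed$", "\\1", basename(p))]] <-
      read_intervals(p, "bed3")
  list(libs = libs, ctss = ctss, dhs = dhs[, .(id, chrom, start, end)],
       genes = genes, tss = tss, genome = genome, tads = tads,
       interactions = interactions,
       starr = if (length(starr) == 3L) starr else NULL,
       marks = if (length(marks)) marks else NULL)
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a dataset bundle (a directory or the list from
#' [read_dataset()] / [generate_dataset()]): tag clustering and
#' annotation, noise estimation and filtering, DHS window placement and
#' quantification, two-step classification with semantic labels,
#' annotation and STARR crosstabs, mark proportions, TAD allocation and
#' co-occurrence models, and divergence summaries.  Stages whose inputs
#' are absent are skipped with a notice.
#'
#' @param input bundle directory or input list.
#' @param merge_dist,trim_fraction,valley_fraction tag clustering
#'   parameters (see [call_tag_clusters()]).
#' @param L,search_radius DHS window parameters ([place_windows()]).
#' @param k number of DHS classes ([two_step_cluster()]).
#' @param noise_quantile,n_noise_windows noise estimation parameters.
#' @param starr_threshold STARR activity threshold ([starr_call()]).
#' @param seed RNG seed used for every stochastic stage.
#' @param out_dir optional output directory for stage TSVs and the
#'   report.
#' @return list of stage results (see the methods vignette).
#' @export
run_pipeline <- function(input, merge_dist = 20L, trim_fraction = 0.1,
                         valley_fraction = 0.1, L = 200L,
                         search_radius = 100L, k = 6L,
                         noise_quantile = 0.999,
                         n_noise_windows = 10000L,
                         starr_threshold = 1.5, seed = 1L,
                         out_dir = NULL) {
  if (is.character(input)) input <- read_dataset(input)
  libs <- input$libs
  ctss <- input$ctss
  res <- list(params = list(merge_dist = merge_dist,
                            trim_fraction = trim_fraction,
                            valley_fraction = valley_fraction, L = L,
                            search_radius = search_radius, k = k,
                            noise_quantile = noise_quantile,
                            starr_threshold = starr_threshold,
                            seed = seed))

  message("stage: tag clustering")
  pooled <- pool_ctss(ctss, libs$id)
  tcs <- call_tag_clusters(pooled, merge_dist, trim_fraction,
                           valley_fraction)
  tcs <- quantify_and_normalize(tcs, ctss, libs)

  message("stage: noise estimation")
  sizes <- if (!is.null(input$genome)) chrom_sizes(input$genome) else {
    s <- pooled[, .(len = max(pos) + 1000L), by = chrom]
    stats::setNames(s$len, s$chrom)
  }
  exclusion <- rbind(
    input$dhs[, .(chrom, start = pmax(0L, start - 500L),
                  end = end + 500L)],
    input$tss[, .(chrom, start = pmax(0L, pos - 500L),
                  end = pos + 501L)])
  thresholds <- estimate_noise_threshold(ctss, exclusion, sizes, libs,
                                         n_windows = n_noise_windows,
                                         quantile = noise_quantile,
                                         seed = seed)
  res$thresholds <- thresholds
  tc_tpm <- setnames(copy(tcs[, paste0("tpm_", libs$id), with = FALSE]),
                     paste0("tpm_", libs$id), libs$id)
  keep <- filter_by_noise(tc_tpm, thresholds, libs)
  tcs[, `:=`(kept_control = keep$kept_control, kept_kd = keep$kept_kd,
             kept_any = keep$kept_any)]
  res$tcs <- tcs
  tcs_kept <- annotate_tcs(tcs[kept_any == TRUE], input$tss)
  res$tcs_kept <- tcs_kept
  res$divergence <- summarize_divergence(tcs_kept)

  message("stage: DHS quantification")
  kd_ids <- libs$id[libs$condition == "exosomeKD"]
  pooled_kd <- pool_ctss(ctss, kd_ids)
  windows <- place_windows(input$dhs, pooled_kd, L, search_radius)
  qd <- quantify_dhs(windows, ctss, libs, L)
  expr_w <- dcast(qd$expr, id ~ lib, value.var = c("tpm_plus", "tpm_minus"))
  plus_cols <- paste0("tpm_plus_", libs$id)
  minus_cols <- paste0("tpm_minus_", libs$id)
  tp <- filter_by_noise(
    setnames(copy(expr_w[, plus_cols, with = FALSE]), plus_cols, libs$id),
    thresholds, libs)
  tm <- filter_by_noise(
    setnames(copy(expr_w[, minus_cols, with = FALSE]), minus_cols, libs$id),
    thresholds, libs)
  transcribed <- tp$kept_any | tm$kept_any
  quant <- qd$quant[match(expr_w$id, id)]
  quant[, transcribed := transcribed]
  quant[, convergent := detect_convergent(
    input$dhs[match(quant$id, id)], pooled_kd, L, search_radius)]
  minor_pass <- fifelse(quant$major_strand == "+", tm$kept_any,
                        tp$kept_any)
  res$windows <- windows
  res$quant <- quant
  res$expr <- qd$expr

  message("stage: classification")
  tq <- quant[transcribed == TRUE & !is.na(sens_major)]
  thr_vec <- stats::setNames(thresholds$tpm_threshold, thresholds$lib)
  feats <- build_features(qd$expr[id %in% tq$id], tq, libs,
                          noise_tpm = thr_vec)
  assign <- two_step_cluster(feats, k = k, seed = seed)
  minor_ex <- minor_pass[match(tq$id, quant$id)]
  lab <- label_classes(assign, tq, minor_ex)
  res$features <- feats
  res$classes <- lab$assignments
  res$class_labels <- lab$labels
  res$class_medians <- lab$medians
  cls <- lab$assignments[removed == FALSE, .(id, class)]
  res$annotation_crosstab <- class_annotation_table(
    input$dhs[id %in% cls$id], cls, input$tss)

  if (!is.null(input$starr)) {
    message("stage: STARR enhancer potential")
    tracks <- lapply(input$starr, function(tr)
      if (inherits(tr, "signal_track")) tr else signal_track(tr))
    tdhs <- input$dhs[id %in% cls$id]
    hk <- starr_call(tdhs, tracks$hk_signal, tracks$input,
                     threshold = starr_threshold)
    dcp <- starr_call(tdhs, tracks$dcp_signal, tracks$input,
                      threshold = starr_threshold)
    res$starr <- list(hk = hk, dcp = dcp,
                      crosstab = class_starr_enrichment(cls, hk, dcp))
    tpm_major <- quant$tpm_major_kd[match(hk$id, quant$id)]
    res$starr$assoc_hk <- binned_association(hk$lfc, log10(tpm_major + 0.1))
    res$starr$assoc_dcp <- binned_association(dcp$lfc, log10(tpm_major + 0.1))
  } else message("stage: STARR skipped (no tracks)")

  if (!is.null(input$marks)) {
    message("stage: chromatin marks")
    su <- quant[id %in% cls$id & !is.na(summit_major),
                .(id, chrom, pos = summit_major)]
    res$marks <- mark_proportions(cls, su, input$marks)
  } else message("stage: marks skipped")

  if (!is.null(input$tads)) {
    message("stage: chromatin architecture")
    wins <- quant[id %in% cls$id,
                  .(id, chrom, start = pmax(0L, summit_major - 200L),
                    end = summit_major + 201L)]
    tadv <- input$tads[, .(id, chrom, start, end)]
    ta <- assign_tads(wins, tadv)
    pairs <- enumerate_pairs(
      input$dhs[id %in% cls$id], ta, cls,
      interactions = input$interactions)
    res$tads <- list(assignments = ta,
                     summary = tad_class_summary(ta, cls),
                     pairs = pairs)
    res$tads$glm <- lapply(stats::setNames(nm = unique(cls$class)),
                           function(f) tryCatch(
                             cooccurrence_glm(pairs, f, ta),
                             error = function(e) NULL))
  } else message("stage: TADs skipped")

  if (!is.null(out_dir)) res$dir <- write_pipeline_outputs(res, out_dir)
  res
}

#' Divergence fractions at 250/500 bp, per annotation category
#'
#' Wraps [divergence_profile()] over all filtered TCs and per annotation
#' category, reporting the fraction of plus-strand TCs with an upstream
#' minus-strand TC summit within 250 and 500 bp.
#'
#' @param tcs annotated TC table (column `annotation`; absent column
#'   treats all TCs as one category).
#' @return `data.table`: `category`, `n_plus`, `frac_250`, `frac_500`.
#' @export
summarize_divergence <- function(tcs) {
  tcs <- as.data.table(tcs)
  cats <- if ("annotation" %in% names(tcs))
    c("all", unique(tcs$annotation)) else "all"
  dp <- divergence_profile(tcs)  # partners may be any minus-strand TC
  idx <- which(tcs$strand == "+")
  rbindlist(lapply(cats, function(cat) {
    in_cat <- if (cat == "all") rep(TRUE, length(idx)) else
      tcs$annotation[idx] == cat
    if (!sum(in_cat))
      return(data.table(category = cat, n_plus = 0L,
                        frac_250 = NA_real_, frac_500 = NA_real_))
    d <- dp$distances[in_cat]
    data.table(category = cat, n_plus = sum(in_cat),
               frac_250 = mean(!is.na(d) & d <= 250),
               frac_500 = mean(!is.na(d) & d <= 500))
  }))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(res$thresholds, file.path(out_dir, "noise_thresholds.tsv"))
  write_table(res$tcs_kept, file.path(out_dir, "tag_clusters.tsv"))
  write_table(res$quant, file.path(out_dir, "dhs_quant.tsv"))
  write_table(res$classes, file.path(out_dir, "dhs_classes.tsv"))
  write_table(res$divergence, file.path(out_dir, "divergence.tsv"))
  rep_lines <- c(
    "divtx pipeline report", "",
    sprintf("transcribed DHSs: %d", nrow(res$classes)),
    sprintf("removed (replicate disagreement): %d",
            sum(res$classes$removed)),
    "", "class counts:",
    utils::capture.output(print(table(res$classes$class))),
    "", "annotation crosstab:",
    utils::capture.output(print(res$annotation_crosstab$table)),
    "", "divergence fractions:",
    utils::capture.output(print(res$divergence)))
  if (!is.null(res$starr))
    rep_lines <- c(rep_lines, "", "STARR crosstab (proportions):",
                   utils::capture.output(
                     print(round(res$starr$crosstab$proportions, 3))))
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
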