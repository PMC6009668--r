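# Fully synthetic dataset with planted TRE classes: genome, DHSs, CTSS
# files for 4 + 4 replicates, gene annotation, planted motifs, STARR
# tracks, ChIP marks, TADs and interactions, plus a machine-readable
# truth table.  The generator's defaults define the study conditions
# used throughout the test suite; see the methods vignette for the
# rationale behind each value.

#' Default planted class parameters
#'
#' Mean exosome-KD expression (TPM) and exosome sensitivity per strand
#' role for each of the six TRE classes, chosen to reproduce the
#' qualitative class structure: highly expressed, stable, strongly
#' directional gene promoters (with or without a PROMPT), balanced
#' stable head-to-head pairs, and three lowly expressed unstable
#' (enhancer-like) classes of increasing directionality.
#'
#' @return `data.table` with one row per class: `class`, `tpm_major`,
#'   `tpm_minor`, `sens_major`, `sens_minor`, `has_gene`,
#'   `gene_both_strands`.
#' @export
default_class_params <- function() {
  data.table(
    class = tre_classes(),
    tpm_major = c(50, 50, 40, 2, 6, 3),
    tpm_minor = c(0.2, 2, 25, 1.5, 2, 0.1),
    sens_major = c(0.1, 0.1, 0.1, 0.8, 0.7, 0.8),
    sens_minor = c(0.5, 0.8, 0.15, 0.85, 0.8, 0.5),
    has_gene = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    gene_both_strands = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
}

# geometric positional tag profile around a planted summit
tag_profile <- function(half_width = 10L, decay = 0.55) {
  off <- -half_width:half_width
  w <- decay^abs(off)
  list(offsets = off, w = w / sum(w))
}

#' Generate the default synthetic dataset
#'
#' Produces a random genome, DHSs with planted classes arranged in TADs
#' (stable classes preferring TAD-edge positions), strand-specific CTSS
#' count piles for 4 control + 4 exosome-KD replicates (negative
#' binomial tag counts spread over a geometric positional profile;
#' control means scaled by `1 - sensitivity`), Poisson background noise
#' at TSS-unlikely positions, filler gene promoters carrying the bulk of
#' the library mass, planted core-promoter / processing motifs written
#' into the genome sequence, STARR signal/input tracks (housekeeping
#' strength increasing with planted expression, developmental strength
#' concentrated on unstable classes), binary ChIP marks, TADs and
#' significant interactions — together with a truth table.
#'
#' @param n_per_class DHSs planted per class.
#' @param class_params table as [default_class_params()].
#' @param library_depth expected tags per library (all libraries share
#'   this depth; TPM = count / depth * 1e6 up to realization noise).
#'   The default matches the sequencing scale of the emulated
#'   experiment (tens of millions of mapped tags); the genome and
#'   element counts, not the per-element tag counts, are what is scaled
#'   down.
#' @param dispersion negative-binomial dispersion (1/size) of per-
#'   replicate counts; 0.02 (biological coefficient of variation ~0.14)
#'   reflects biological replicates of a treated cell line.
#' @param n_filler_genes filler gene promoters absorbing the remaining
#'   library mass.
#' @param noise_positions number of background noise positions.
#' @param noise_tpm_per_position expected background TPM per noise
#'   position and library (the Poisson count mean is this times
#'   `library_depth / 1e6`, so background expression is depth-
#'   invariant).
#' @param spacing distance between planted element slots (bp).
#' @param n_chrom number of chromosomes.
#' @param colocalization probability that a DHS in a TAD takes the TAD's
#'   archetype class (0 = no planted co-localization).
#' @param seed RNG seed; the full bundle is deterministic given it.
#' @param out_dir optional directory; when given, all files are written
#'   via [write_dataset()].
#' @return list with `genome`, `dhs`, `ctss`, `libs`, `genes`, `tss`,
#'   `tads`, `interactions`, `marks`, `starr` (span tables), `truth`,
#'   `motif_truth`, `params` (and `dir` when written).
#' @export
generate_dataset <- function(n_per_class = 100L,
                             class_params = default_class_params(),
                             library_depth = 4e7, dispersion = 0.02,
                             n_filler_genes = 200L,
                             noise_positions = 20000L,
                             noise_tpm_per_position = 0.14,
                             spacing = 3000L, n_chrom = 4L,
                             colocalization = 0.7, seed = 1L,
                             out_dir = NULL) {
  set.seed(seed)
  noise_lambda <- noise_tpm_per_position * library_depth / 1e6
  cp <- as.data.table(class_params)
  n_dhs <- n_per_class * nrow(cp)
  n_slots <- n_dhs + n_filler_genes
  prof <- tag_profile()
  if (max(abs(prof$offsets)) + 60L > spacing / 4)
    stopf("inconsistent config: spacing too small for planted elements")

  # ---- layout: slots on chromosomes, TADs over slots ------------------
  per_chrom <- ceiling(n_slots / n_chrom)
  slot <- data.table(slot = seq_len(n_slots))
  slot[, chrom := paste0("chrS", 1L + (slot - 1L) %/% per_chrom)]
  slot[, pos := 5000L + ((slot - 1L) %% per_chrom) * spacing]
  sizes <- slot[, .(len = max(pos) + 5000L), by = chrom]
  chrom_len <- stats::setNames(sizes$len, sizes$chrom)

  is_dhs <- sample(c(rep(TRUE, n_dhs), rep(FALSE, n_filler_genes)))
  slot[, kind := ifelse(is_dhs, "dhs", "gene")]

  # TADs: consecutive runs of 4-8 slots per chromosome
  slot[, tad := {
    n <- .N; tl <- integer(n); i <- 1L; t <- 0L
    while (i <= n) { t <- t + 1L; s <- sample(4:8, 1L)
      tl[i:min(n, i + s - 1L)] <- t; i <- i + s }
    paste0(chrom, "_tad", tl)
  }, by = chrom]
  tads <- slot[, .(start = min(pos) - spacing %/% 2L,
                   end = max(pos) + spacing %/% 2L), by = .(chrom, tad)]
  setnames(tads, "tad", "id")
  tads[start < 0, start := 0L]

  # class assignment: exact counts per class, planted co-localization
  dhs_slots <- slot[kind == "dhs"]
  remaining <- stats::setNames(rep(n_per_class, nrow(cp)), cp$class)
  cls <- rep(NA_character_, nrow(dhs_slots))
  for (td in unique(dhs_slots$tad)) {
    ix <- which(dhs_slots$tad == td)
    if (sum(remaining) == 0L) break
    arch <- sample(names(remaining), 1L, prob = pmax(remaining, 0))
    for (i in ix) {
      take_arch <- stats::runif(1) < colocalization && remaining[arch] > 0L
      pool <- names(remaining)[remaining > 0L]
      pick <- if (take_arch) arch else
        if (length(pool) == 1L) pool else sample(pool, 1L,
                                                 prob = remaining[pool])
      cls[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
  }
  dhs_slots[, class := cls]
  # stable classes drift to TAD-edge slots
  dhs_slots[, edge_rank := {
    r <- pmin(seq_len(.N) - 1L, rev(seq_len(.N)) - 1L)
    frank(r, ties.method = "first")
  }, by = tad]
  dhs_slots[, stable := class %in% tre_classes()[1:3]]
  dhs_slots[, class := {
    ord <- order(-stable)          # stable first
    class[ord][frank(edge_rank, ties.method = "first")]
  }, by = tad]
  dhs_slots[, stable := class %in% tre_classes()[1:3]]

  dhs <- dhs_slots[, .(id = sprintf("dhs%04d", .I), chrom, center = pos,
                       tad, class)]
  dhs[, `:=`(start = center - 150L, end = center + 150L,
             major_strand = sample(c("+", "-"), .N, replace = TRUE))]
  dhs <- merge(dhs, cp, by = "class", sort = FALSE)
  # per-DHS lognormal expression factor with mean 1
  sdlog <- 0.25
  dhs[, expr_factor := stats::rlnorm(.N, -sdlog^2 / 2, sdlog)]
  dhs[, `:=`(tpm_major_true = tpm_major * expr_factor,
             tpm_minor_true = tpm_minor * expr_factor)]
  # divergent geometry: minus-strand summit upstream, plus downstream
  dhs[, `:=`(summit_plus = center + 25L, summit_minus = center - 25L)]
  dhs[, `:=`(summit_major = ifelse(major_strand == "+", summit_plus,
                                   summit_minus),
             summit_minor = ifelse(major_strand == "+", summit_minus,
                                   summit_plus))]

  # ---- libraries ------------------------------------------------------
  libs <- libraries(
    id = c(paste0("ctrl", 1:4), paste0("kd", 1:4)),
    condition = rep(c("control", "exosomeKD"), each = 4L),
    replicate = rep(1:4, 2L))

  # ---- CTSS counts ----------------------------------------------------
  depth_factor <- library_depth / 1e6
  size_nb <- 1 / dispersion
  draw_pile <- function(chrom, summit, strand, mu_kd, sens) {
    mus <- c(rep(mu_kd * (1 - sens), 4L), rep(mu_kd, 4L))
    tot <- stats::rnbinom(8L, size = size_nb, mu = mus * depth_factor)
    if (all(tot == 0L)) return(NULL)
    counts <- vapply(tot, function(tt)
      if (tt == 0L) integer(length(prof$w))
      else as.integer(stats::rmultinom(1L, tt, prof$w)),
      integer(length(prof$w)))
    keep <- rowSums(counts) > 0L
    if (!any(keep)) return(NULL)
    out <- data.table(chrom = chrom, pos = summit + prof$offsets[keep],
                      strand = strand)
    out[, (libs$id) := as.data.table(counts[keep, , drop = FALSE])]
    out
  }
  piles <- vector("list", 2L * nrow(dhs))
  for (i in seq_len(nrow(dhs))) {
    mj <- dhs$major_strand[i]
    piles[[2L * i - 1L]] <- draw_pile(
      dhs$chrom[i], if (mj == "+") dhs$summit_plus[i] else dhs$summit_minus[i],
      mj, dhs$tpm_major_true[i], dhs$sens_major[i])
    piles[[2L * i]] <- draw_pile(
      dhs$chrom[i], if (mj == "+") dhs$summit_minus[i] else dhs$summit_plus[i],
      ifelse(mj == "+", "-", "+"), dhs$tpm_minor_true[i], dhs$sens_minor[i])
  }

  # filler gene promoters: absorb the remaining library mass
  gene_slots <- slot[kind == "gene"]
  planted_tpm <- dhs[, sum(tpm_major_true + tpm_minor_true)]
  noise_tpm <- noise_positions * noise_lambda / depth_factor
  filler_total <- max(0, 1e6 - planted_tpm - noise_tpm)
  ft <- stats::rlnorm(nrow(gene_slots), 0, 0.8)
  gene_slots[, `:=`(tpm = ft / sum(ft) * filler_total,
                    strand = sample(c("+", "-"), .N, replace = TRUE),
                    id = sprintf("fgene%03d", seq_len(.N)))]
  fpiles <- vector("list", nrow(gene_slots))
  for (i in seq_len(nrow(gene_slots)))
    fpiles[[i]] <- draw_pile(gene_slots$chrom[i], gene_slots$pos[i],
                             gene_slots$strand[i], gene_slots$tpm[i],
                             sens = 0.05)

  # background noise at TSS-unlikely positions
  npos <- data.table(
    chrom = sample(names(chrom_len), noise_positions, replace = TRUE,
                   prob = chrom_len / sum(chrom_len)))
  npos[, pos := as.integer(floor(stats::runif(.N) * chrom_len[chrom]))]
  npos[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  # keep only positions > 600 bp from any planted slot center
  npos[, slot_d := {
    rel <- (pos - 5000L) / spacing
    near <- 5000L + round(rel) * spacing
    abs(pos - near)
  }]
  npos <- npos[slot_d > 600L][, slot_d := NULL]
  nmat <- matrix(stats::rpois(nrow(npos) * 8L, noise_lambda),
                 ncol = 8L, dimnames = list(NULL, libs$id))
  npos <- npos[rowSums(nmat) > 0L]
  nmat <- nmat[rowSums(nmat) > 0L, , drop = FALSE]
  npos[, (libs$id) := as.data.table(nmat)]

  ctss <- rbindlist(c(piles, fpiles, list(npos)))
  ctss <- ctss[, lapply(.SD, sum), by = .(chrom, pos, strand),
               .SDcols = libs$id]
  setkey(ctss, chrom, pos, strand)
  libs[, total_mapped_tags :=
         vapply(id, function(l) sum(as.numeric(ctss[[l]])), 0)]
  setattr(ctss, "libraries", libs)

  # ---- gene annotation ------------------------------------------------
  gene_rows <- list(
    gene_slots[, .(id, chrom, tss = pos, strand, biotype = "mRNA")])
  gd <- dhs[has_gene == TRUE]
  gene_rows$dhs_major <- gd[, .(id = paste0("g_", id), chrom,
                                tss = summit_major, strand = major_strand,
                                biotype = "mRNA")]
  gb <- dhs[gene_both_strands == TRUE]
  gene_rows$dhs_minor <- gb[, .(id = paste0("g2_", id), chrom,
                                tss = summit_minor,
                                strand = ifelse(major_strand == "+", "-", "+"),
                                biotype = "mRNA")]
  tss <- rbindlist(gene_rows)[, .(chrom, pos = tss, strand, id, biotype)]
  genes <- tss[, .(chrom,
                   start = ifelse(strand == "+", pos, pmax(0L, pos - 1499L)),
                   end = ifelse(strand == "+", pos + 1500L, pos + 1L),
                   id, score = 0, strand, biotype)]

  # ---- STARR tracks ---------------------------------------------------
  stable_cls <- tre_classes()[1:3]
  dhs[, hk_lfc := pmax(0, 0.55 * log2(tpm_major_true + 1) +
                         stats::rnorm(.N, 0, 0.25))]
  dhs[, dcp_lfc := pmax(0, ifelse(class %in% stable_cls,
                                  stats::rnorm(.N, 0.4, 0.25),
                                  stats::rnorm(.N, 2.5, 0.4)))]
  base <- 100
  starr_spans <- function(lfc_col) {
    pk <- dhs[, .(chrom, start = center - 100L, end = center + 101L,
                  value = base * 2^get(lfc_col))]
    rbindlist(lapply(names(chrom_len), function(ch) {
      p <- pk[chrom == ch][order(start)]
      bounds <- c(0L, rbind(p$start, p$end), chrom_len[[ch]])
      bgs <- bounds[seq(1, length(bounds), 2)]
      bge <- bounds[seq(2, length(bounds), 2)]
      rbind(data.table(chrom = ch, start = bgs[bgs < bge],
                       end = bge[bgs < bge], value = base), p,
            fill = TRUE)[order(start)]
    }))
  }
  starr <- list(
    hk_signal = starr_spans("hk_lfc"),
    dcp_signal = starr_spans("dcp_lfc"),
    input = rbindlist(lapply(names(chrom_len), function(ch)
      data.table(chrom = ch, start = 0L, end = chrom_len[[ch]],
                 value = base))))

  # ---- binary ChIP marks ----------------------------------------------
  mark_rate <- list(H3K4me3 = c(stable = 0.85, unstable = 0.15),
                    H3K4me1 = c(stable = 0.2, unstable = 0.8))
  marks <- lapply(mark_rate, function(r) {
    pr <- ifelse(dhs$class %in% stable_cls, r[["stable"]], r[["unstable"]])
    hit <- stats::runif(nrow(dhs)) < pr
    data.table(chrom = dhs$chrom[hit],
               start = dhs$center[hit] - 25L, end = dhs$center[hit] + 25L)
  })

  # ---- interactions ---------------------------------------------------
  inter <- dhs[, if (.N >= 2L) {
    i <- sample(.N, 2L)
    data.table(chrom1 = chrom[i[1]], start1 = center[i[1]] - 500L,
               end1 = center[i[1]] + 500L, chrom2 = chrom[i[2]],
               start2 = center[i[2]] - 500L, end2 = center[i[2]] + 500L)
  }, by = tad][stats::runif(.N) < 0.5][, tad := NULL]
  inter[start1 > start2, `:=`(start1 = start2, end1 = end2,
                              start2 = start1, end2 = end1)]

  # ---- genome sequence with planted motifs ----------------------------
  genome <- Biostrings::DNAStringSet(vapply(names(chrom_len), function(ch)
    paste(sample(BASES, chrom_len[[ch]], replace = TRUE), collapse = ""),
    ""))
  names(genome) <- names(chrom_len)
  motif_truth <- plant_motifs(genome, dhs, cp)
  genome <- motif_truth$genome
  motif_truth <- motif_truth$truth

  truth <- dhs[, .(id, chrom, center, start, end, class, tad,
                   major_strand, summit_major, summit_minor,
                   tpm_major_true, tpm_minor_true, sens_major, sens_minor,
                   hk_lfc, dcp_lfc)]
  out <- list(genome = genome, dhs = dhs[, .(id, chrom, start, end)],
              ctss = ctss, libs = libs, genes = genes, tss = tss,
              tads = tads[, .(id, chrom, start, end)],
              interactions = inter, marks = marks, starr = starr,
              truth = truth, motif_truth = motif_truth,
              params = list(n_per_class = n_per_class,
                            library_depth = library_depth,
                            dispersion = dispersion, seed = seed,
                            colocalization = colocalization))
  if (!is.null(out_dir)) out$dir <- write_dataset(out, out_dir)
  out
}

# write planted motif instances into the genome sequence; strand-aware
# (minor/antisense summits receive reverse-complemented instances)
plant_motifs <- function(genome, dhs, cp) {
  stable_cls <- tre_classes()[1:3]
  plan <- list(
    stable_major = list(classes = stable_cls, role = "major",
                        motifs = list(c("Ohler1", "CGGTCACACTG", -50, 0.6),
                                      c("DRE", "TATCGATA", -38, 0.5),
                                      c("Inr", "TCAGTC", -2, 0.5),
                                      c("TATA", "CTATAAATA", -29, 0.2))),
    unstable_major = list(classes = setdiff(tre_classes(), stable_cls),
                          role = "major",
                          motifs = list(c("Trl", "GAGAGAG", -40, 0.6),
                                        c("Inr", "TCAGTC", -2, 0.3))),
    prompt_minor = list(classes = "unidirectional_stable_PROMPT",
                        role = "minor",
                        motifs = list(c("Trl", "GAGAGAG", -40, 0.6))))
  seqs <- as.list(as.character(genome))
  rows <- list()
  for (pl in plan) {
    sub <- dhs[class %in% pl$classes]
    for (ms in pl$motifs) {
      nm <- ms[[1]]; inst <- ms[[2]]
      off <- as.integer(ms[[3]]); rate <- as.numeric(ms[[4]])
      hit <- stats::runif(nrow(sub)) < rate
      for (i in which(hit)) {
        st <- if (pl$role == "major") sub$major_strand[i] else
          ifelse(sub$major_strand[i] == "+", "-", "+")
        summit <- if (pl$role == "major") sub$summit_major[i] else
          sub$summit_minor[i]
        seqs[[sub$chrom[i]]] <- write_instance(
          seqs[[sub$chrom[i]]], inst, summit, st, off)
        rows[[length(rows) + 1L]] <- data.table(
          id = sub$id[i], strand_role = pl$role, motif = nm, offset = off)
      }
    }
  }
  # downstream processing motifs: 5'SS on stable majors, polyA on
  # unstable strands and PROMPT minors
  ss <- dhs[class %in% stable_cls]
  hit <- stats::runif(nrow(ss)) < 0.8
  for (i in which(hit)) {
    off <- sample(30:100, 1L)
    seqs[[ss$chrom[i]]] <- write_instance(
      seqs[[ss$chrom[i]]], "CAGGTAAGT", ss$summit_major[i],
      ss$major_strand[i], off)
    rows[[length(rows) + 1L]] <- data.table(
      id = ss$id[i], strand_role = "major", motif = "donor5SS",
      offset = off)
  }
  pa_major <- dhs[!class %in% stable_cls]
  pa <- rbind(pa_major[, .(id, chrom, summit = summit_major,
                           strand = major_strand)],
              dhs[class == "unidirectional_stable_PROMPT",
                  .(id, chrom, summit = summit_minor,
                    strand = ifelse(major_strand == "+", "-", "+"))])
  hit <- stats::runif(nrow(pa)) < 0.8
  for (i in which(hit)) {
    off <- sample(20:90, 1L)
    seqs[[pa$chrom[i]]] <- write_instance(
      seqs[[pa$chrom[i]]], "AATAAA", pa$summit[i], pa$strand[i], off)
    rows[[length(rows) + 1L]] <- data.table(
      id = pa$id[i], strand_role = "processing", motif = "polyA",
      offset = off)
  }
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(genome)
  list(genome = g, truth = rbindlist(rows))
}

# place `inst` so that, read on `strand`, its first base sits at
# TSS-relative `offset` from the 0-based `summit`
write_instance <- function(seq, inst, summit, strand, offset) {
  L <- nchar(inst)
  if (strand == "+") {
    a <- summit + offset          # 0-based start
    substr(seq, a + 1L, a + L) <- inst
  } else {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(inst)))
    a <- summit - offset - L + 1L
    substr(seq, a + 1L, a + L) <- rc
  }
  seq
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits `genome.fa`, per-library `ctss_<id>.bed` + `manifest.tsv`,
#' `dhs.bed`, `genes.bed` (gene bodies, name = `id|biotype`),
#' `tads.bed`, `interactions.bedpe`, `marks_<mark>.bed`,
#' `starr_{hk,dcp}_signal.bedGraph`, `starr_input.bedGraph`,
#' `truth.tsv` and `motif_truth.tsv`.
#'
#' @param sim result of [generate_dataset()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  paths <- write_ctss(sim$ctss, dir, sim$libs)
  man <- copy(sim$libs)[, file := basename(paths[id])]
  fwrite(man, file.path(dir, "manifest.tsv"), sep = "\t")
  fwrite(sim$dhs[, .(chrom, start, end, id, 0, ".")],
         file.path(dir, "dhs.bed"), sep = "\t", col.names = FALSE)
  fwrite(sim$genes[, .(chrom, start, end, paste0(id, "|", biotype),
                       0, strand)],
         file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)
  fwrite(sim$tads[, .(chrom, start, end, id, 0, ".")],
         file.path(dir, "tads.bed"), sep = "\t", col.names = FALSE)
  fwrite(sim$interactions, file.path(dir, "interactions.bedpe"),
         sep = "\t", col.names = FALSE)
  for (mk in names(sim$marks))
    fwrite(sim$marks[[mk]], file.path(dir, paste0("marks_", mk, ".bed")),
           sep = "\t", col.names = FALSE)
  for (tr in names(sim$starr))
    fwrite(sim$starr[[tr]],
           file.path(dir, paste0("starr_", tr, ".bedGraph")),
           sep = "\t", col.names = FALSE)
  fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  fwrite(sim$motif_truth, file.path(dir, "motif_truth.tsv"), sep = "\t")
  invisible(dir)
}

#' Lightweight TAD architecture simulator
#'
#' Positions DHSs along one chromosome, tiles them into TADs and assigns
#' classes with a tunable same-TAD co-localization strength
#' (`colocalization = 0` gives the class-exchangeable null).  Used for
#' co-occurrence GLM experiments without generating sequence data.
#'
#' @param n_dhs number of DHSs.
#' @param spacing distance between DHS centers (bp).
#' @param tad_size_range inclusive range of DHSs per TAD.
#' @param colocalization probability of drawing the TAD archetype class.
#' @param seed RNG seed.
#' @return list with `dhs` (`id`, `chrom`, `center`), `assignments`
#'   (`id`, `tad`), `classes` (`id`, `class`), `tads`.
#' @export
simulate_tad_architecture <- function(n_dhs = 300L, spacing = 5000L,
                                      tad_size_range = c(3L, 8L),
                                      colocalization = 0.7, seed = 1L) {
  set.seed(seed)
  d <- data.table(id = sprintf("d%04d", seq_len(n_dhs)), chrom = "chrS1",
                  center = 5000L + (seq_len(n_dhs) - 1L) * spacing)
  tl <- integer(n_dhs); i <- 1L; t <- 0L
  while (i <= n_dhs) {
    t <- t + 1L
    s <- sample(tad_size_range[1]:tad_size_range[2], 1L)
    tl[i:min(n_dhs, i + s - 1L)] <- t
    i <- i + s
  }
  d[, tad := paste0("tad", tl)]
  arch <- stats::setNames(sample(tre_classes(), t, replace = TRUE),
                          paste0("tad", seq_len(t)))
  d[, class := {
    a <- arch[[tad[1L]]]
    ifelse(stats::runif(.N) < colocalization, a,
           sample(tre_classes(), .N, replace = TRUE))
  }, by = tad]
  tads <- d[, .(start = min(center) - spacing %/% 2L,
                end = max(center) + spacing %/% 2L), by = .(chrom, tad)]
  setnames(tads, "tad", "id")
  list(dhs = d[, .(id, chrom, center)],
       assignments = d[, .(id, tad)],
       classes = d[, .(id, class)],
       tads = tads[, .(id, chrom, start, end)])
}

# adjusted Rand index between two labelings (standard contingency-table
# formula); cross-checked in the test suite against an independent
# implementation
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- si * sj / n
  (sij - expected) / ((si + sj) / 2 - expected)
}

#' Recovery metrics of pipeline outputs against the planted truth
#'
#' @param truth truth table from [generate_dataset()].
#' @param labelled labelled assignments (`id`, `class`, `removed`) from
#'   [label_classes()].
#' @param quant optional DHS summary from [quantify_dhs()] for
#'   sensitivity / directionality recovery (restricted to planted KD
#'   expression >= `min_tpm`).
#' @param min_tpm expression floor for the MAE metrics.
#' @return list with `accuracy`, `ari`, `removed_fraction`, and (given
#'   `quant`) `sens_mae`, `dir_mae`.
#' @export
truth_report <- function(truth, labelled, quant = NULL, min_tpm = 5) {
  tr <- as.data.table(truth)
  lb <- as.data.table(labelled)
  if (!all(lb$id %in% tr$id)) stopf("id mismatch between truth and outputs")
  m <- merge(tr, lb, by = "id", suffixes = c("_true", ""))
  kept <- m[removed == FALSE]
  out <- list(
    accuracy = mean(kept$class == kept$class_true),
    ari = ari(kept$class, kept$class_true),
    removed_fraction = mean(m$removed))
  if (!is.null(quant)) {
    q <- merge(tr, as.data.table(quant), by = "id",
               suffixes = c("_true", ""))
    qm <- q[tpm_major_true >= min_tpm]
    out$sens_mae <- qm[, mean(abs(sens_major - sens_major_true),
                              na.rm = TRUE)]
    dir_true <- (q$tpm_major_true - q$tpm_minor_true) /
      (q$tpm_major_true + q$tpm_minor_true)
    out$dir_mae <- mean(abs(q$directionality - dir_true)[
      q$tpm_major_true >= min_tpm], na.rm = TRUE)
  }
  out
}
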