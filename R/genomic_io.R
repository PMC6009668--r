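# Readers and writers for the standard formats the pipeline touches.
#
# Conventions: all intervals are 0-based half-open [start, end); CTSS
# positions are 0-based single bases; strands are "+", "-" (and "." for
# unstranded intervals).  Chromosome names are taken verbatim.

#' Define a set of CAGE libraries
#'
#' A library table describes the 4 + 4 replicate design: four control and
#' four exosome-knockdown libraries.  `total_mapped_tags` is the
#' genome-wide sum of the library's CTSS counts and is the denominator for
#' tags-per-million normalization; when `NA` it is computed from the data
#' by [read_ctss()].
#'
#' @param id character vector of unique library ids.
#' @param condition `"control"` or `"exosomeKD"` per library.
#' @param replicate integer replicate index (1..4) per library.
#' @param total_mapped_tags positive totals, or `NA` to fill from data.
#' @param file optional CTSS BED6 path per library.
#' @return a `data.table` with one row per library.
#' @export
libraries <- function(id, condition, replicate, total_mapped_tags = NA_real_,
                      file = NA_character_) {
  if (anyDuplicated(id)) stopf("duplicate library ids")
  if (!all(condition %in% c("control", "exosomeKD")))
    stopf("condition must be 'control' or 'exosomeKD'")
  bad <- !is.na(total_mapped_tags) & total_mapped_tags <= 0
  if (any(bad)) stopf("total_mapped_tags must be positive")
  data.table(id = as.character(id), condition = condition,
             replicate = as.integer(replicate),
             total_mapped_tags = as.numeric(total_mapped_tags),
             file = as.character(file))
}

#' Read a library manifest
#'
#' Tab-separated file with columns `id`, `condition`, `replicate`, `file`
#' and optionally `total_mapped_tags`.  Relative CTSS paths are resolved
#' against the manifest's directory.
#'
#' @param path manifest path.
#' @return library `data.table` as from [libraries()].
#' @export
read_manifest <- function(path) {
  m <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = "id"))
  need <- c("id", "condition", "replicate", "file")
  if (!all(need %in% names(m)))
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  if (!"total_mapped_tags" %in% names(m)) m[, total_mapped_tags := NA_real_]
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m[rel, file := file.path(dirname(path), file)]
  libraries(m$id, m$condition, m$replicate, m$total_mapped_tags, m$file)
}

#' Read CTSS (CAGE TSS) count tables
#'
#' Accepts one BED6 file per library (score = tag count at the single base
#' `[start, start + 1)`) or a single multi-column TSV
#' (`chrom`, `pos`, `strand`, one count column per library).  Records are
#' merged on `(chrom, pos, strand)`; libraries absent at a position get
#' count 0.
#'
#' @param path character vector of BED6 paths (one per library, matched to
#'   `libs$id` by name or by `libs$file`), or a single TSV path.
#' @param libs library table from [libraries()]/[read_manifest()].  When
#'   `path` is missing, files are taken from `libs$file`.
#' @return a keyed `data.table` with columns `chrom`, `pos`, `strand` and
#'   one integer count column per library id, plus updated `libs` in
#'   attribute `"libraries"` (totals filled from the data).
#' @export
read_ctss <- function(path = NULL, libs) {
  if (is.null(path)) {
    path <- stats::setNames(libs$file, libs$id)
    if (anyNA(path)) stopf("no CTSS paths: supply `path` or manifest files")
  }
  if (length(path) == 1L && !grepl("\\.bed(\\.gz)?$", path)) {
    tab <- fread(path, sep = "\t", header = TRUE)
    need <- c("chrom", "pos", "strand")
    if (!all(need %in% names(tab))) stopf("CTSS TSV must have chrom/pos/strand")
    miss <- setdiff(libs$id, names(tab))
    for (id in miss) tab[, (id) := 0L]
    tab <- tab[, c(need, libs$id), with = FALSE]
  } else {
    if (is.null(names(path))) {
      if (length(path) != nrow(libs))
        stopf("need one CTSS file per library")
      names(path) <- libs$id
    }
    parts <- lapply(names(path), function(id) {
      b <- read_ctss_bed(path[[id]])
      if (nrow(b)) b[, lib := id]
      b
    })
    long <- rbindlist(parts)
    if (nrow(long) == 0L) {
      tab <- data.table(chrom = character(), pos = integer(),
                        strand = character())
      for (id in libs$id) tab[, (id) := integer()]
    } else {
      tab <- dcast(long, chrom + pos + strand ~ lib, value.var = "count",
                   fill = 0L, fun.aggregate = sum)
      miss <- setdiff(libs$id, names(tab))
      for (id in miss) tab[, (id) := 0L]
      tab <- tab[, c("chrom", "pos", "strand", libs$id), with = FALSE]
    }
  }
  validate_ctss(tab, libs$id)
  setkey(tab, chrom, pos, strand)
  fill <- is.na(libs$total_mapped_tags)
  if (any(fill)) {
    tot <- vapply(libs$id, function(id) sum(as.numeric(tab[[id]])), 0)
    libs <- copy(libs)[fill, total_mapped_tags := tot[fill]]
  }
  setattr(tab, "libraries", libs)
  tab[]
}

read_ctss_bed <- function(path) {
  b <- read_bed(path, kind = "bed6")
  if (nrow(b) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character(), count = integer()))
  bad <- which(b$end != b$start + 1L)
  if (length(bad))
    stopf("%s: CTSS records must be single-base (line %d)", path, bad[1L])
  if (any(b$score < 0))
    stopf("%s: negative CTSS count (line %d)", path, which(b$score < 0)[1L])
  check_strand(b$strand)
  data.table(chrom = b$chrom, pos = b$start, strand = b$strand,
             count = as.integer(b$score))
}

validate_ctss <- function(tab, lib_ids) {
  for (id in lib_ids)
    if (any(tab[[id]] < 0)) stopf("negative count in library %s", id)
  if (nrow(tab) && anyDuplicated(tab, by = c("chrom", "pos", "strand")))
    stopf("duplicate (chrom, pos, strand) in CTSS table")
  invisible(tab)
}

#' Pool CTSS counts across libraries
#'
#' @param ctss CTSS table from [read_ctss()] (or any table with per-library
#'   count columns).
#' @param lib_ids library ids to pool; default all count columns.
#' @return `data.table` with columns `chrom`, `pos`, `strand`, `count`.
#' @export
pool_ctss <- function(ctss, lib_ids = NULL) {
  if (is.null(lib_ids))
    lib_ids <- setdiff(names(ctss), c("chrom", "pos", "strand"))
  out <- ctss[, .(chrom, pos, strand)]
  out[, count := rowSums(as.matrix(ctss[, lib_ids, with = FALSE]))]
  out <- out[count > 0]
  setkey(out, chrom, pos, strand)
  out[]
}

# ---- interval readers -------------------------------------------------

read_bed <- function(path, kind) {
  ncol_min <- c(bed3 = 3L, bed6 = 6L, bed12 = 12L)[[kind]]
  raw <- if (file.size(path) == 0L) data.table() else
    fread(path, sep = "\t", header = FALSE, fill = TRUE,
          colClasses = list(character = 1))
  if (nrow(raw) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), id = character(),
                      score = numeric(), strand = character()))
  if (ncol(raw) < ncol_min)
    stopf("%s: expected >= %d columns for %s", path, ncol_min, kind)
  out <- data.table(chrom = raw[[1]],
                    start = suppressWarnings(as.integer(raw[[2]])),
                    end = suppressWarnings(as.integer(raw[[3]])))
  bad <- which(is.na(out$start) | is.na(out$end))
  if (length(bad)) stopf("%s: malformed coordinates (line %d)", path, bad[1L])
  bad <- which(out$start >= out$end)
  if (length(bad)) stopf("%s: start >= end (line %d)", path, bad[1L])
  if (ncol_min >= 6L) {
    out[, `:=`(id = as.character(raw[[4]]),
               score = suppressWarnings(as.numeric(raw[[5]])),
               strand = as.character(raw[[6]]))]
    check_strand(out$strand, allow_dot = TRUE)
  } else {
    out[, `:=`(id = paste0("iv", .I), score = NA_real_, strand = ".")]
  }
  out
}

#' Read genomic intervals (BED3/6/12 or GTF)
#'
#' Returns 0-based half-open intervals.  GTF `gene` records (1-based,
#' closed) are converted on read; gene/BED12 entries additionally carry a
#' strand-aware TSS point in column `tss` (`start` for "+", `end - 1` for
#' "-") and a `biotype` when the GTF provides `gene_biotype`.
#'
#' @param path file path.
#' @param kind one of `"bed3"`, `"bed6"`, `"bed12"`, `"gtf"`.
#' @return `data.table` with columns `chrom`, `start`, `end`, `id`,
#'   `score`, `strand` (+ `tss`, `biotype` for gene-bearing kinds).
#' @export
read_intervals <- function(path, kind = c("bed6", "bed3", "bed12", "gtf")) {
  kind <- match.arg(kind)
  if (kind == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    keep <- if ("type" %in% names(md)) md$type == "gene" else TRUE
    gr <- gr[keep]
    md <- S4Vectors::mcols(gr)
    out <- data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      id = if ("gene_id" %in% names(md)) as.character(md$gene_id)
           else paste0("gene", seq_along(gr)),
      score = NA_real_,
      strand = as.character(GenomicRanges::strand(gr)))
    check_strand(out$strand)
    out[, biotype := if ("gene_biotype" %in% names(md))
      as.character(md$gene_biotype) else "mRNA"]
  } else {
    out <- read_bed(path, kind)
  }
  if (kind %in% c("bed12", "gtf")) {
    # block structure of BED12 is ignored; only the span and TSS are used
    out[, tss := ifelse(strand == "-", end - 1L, start)]
  }
  out[]
}

#' Strand-aware TSS points from an interval table
#'
#' @param intervals interval `data.table` with `strand` in `{+,-}`.
#' @param biotype biotype per interval (recycled); kept as a column.
#' @return `data.table` with `chrom`, `pos`, `strand`, `id`, `biotype`.
#' @export
gene_tss <- function(intervals, biotype = NULL) {
  check_strand(intervals$strand)
  bt <- biotype %||% (if ("biotype" %in% names(intervals)) intervals$biotype
                      else "mRNA")
  data.table(chrom = intervals$chrom,
             pos = ifelse(intervals$strand == "-", intervals$end - 1L,
                          intervals$start),
             strand = intervals$strand, id = intervals$id, biotype = bt)
}

# ---- signal tracks ----------------------------------------------------

#' Read a quantitative signal track (bedGraph or wiggle)
#'
#' The returned accessor reports the signal at any base (0 outside covered
#' spans) and the maximum (with its position) over an interval.
#' Overlapping spans with conflicting values are an error.
#'
#' @param path bedGraph (`.bedGraph`/`.bg`) or wiggle (`.wig`) file.
#' @param format override format detection.
#' @return object of class `signal_track`; see [track_value()],
#'   [track_max()].
#' @export
read_signal_track <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.wig(\\.gz)?$", path)) "wig" else "bedGraph")
  gr <- rtracklayer::import(path, format = format)
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = as.numeric(S4Vectors::mcols(gr)$score))
  signal_track(dt)
}

#' Build a signal track from an interval table
#'
#' @param spans `data.table` with `chrom`, `start`, `end`, `value`
#'   (0-based half-open).
#' @return `signal_track` object.
#' @export
signal_track <- function(spans) {
  spans <- as.data.table(spans)[order(chrom, start)]
  # resolve exact duplicates, reject conflicting overlaps
  spans <- unique(spans)
  ov <- spans[, any(start[-1L] < head(end, -1L)), by = chrom]$V1
  if (any(ov)) stopf("signal track has overlapping spans with conflicting values")
  structure(list(spans = split(spans, spans$chrom)), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  n <- sum(vapply(x$spans, nrow, 0L))
  cat(sprintf("<signal_track: %d spans on %d sequences>\n",
              n, length(x$spans)))
  invisible(x)
}

#' Signal value at single bases
#'
#' @param track `signal_track`.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based positions.
#' @return numeric vector; 0 outside covered spans.
#' @export
track_value <- function(track, chrom, pos) {
  sp <- track$spans[[chrom]]
  if (is.null(sp)) return(rep(0, length(pos)))
  i <- findInterval(pos, sp$start)
  v <- rep(0, length(pos))
  hit <- i >= 1L & pos < sp$end[pmax(i, 1L)]
  v[hit] <- sp$value[i[hit]]
  v
}

#' Maximum signal over an interval
#'
#' @param track `signal_track`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return list with `max` (0 if the interval is uncovered) and `pos`, the
#'   leftmost 0-based base achieving it.
#' @export
track_max <- function(track, chrom, start, end) {
  stopifnot(start < end)
  v <- track_value(track, chrom, start:(end - 1L))
  i <- which.max(v)
  list(max = v[i], pos = start + i - 1L)
}

# ---- writers ----------------------------------------------------------

#' Write tables to disk
#'
#' `format = "tsv"` writes any table with a header (empty input gives a
#' header-only file).  `format = "bed"` expects interval-like input
#' (`chrom`, `start`, `end`, `id`, `score`, `strand`); tag-cluster tables
#' are written as BED6 with the summit in the name field and pooled TPM
#' (or count) in the score field.
#'
#' @param x `data.table`/`data.frame`.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly; the output round-trips through the matching
#'   reader.
#' @export
write_table <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  x <- as.data.table(x)
  if (format == "tsv") {
    fwrite(x, path, sep = "\t", quote = FALSE)
  } else {
    if ("summit" %in% names(x)) {
      sc <- if ("tpm_pooled" %in% names(x)) x$tpm_pooled
            else if ("count" %in% names(x)) x$count else 0
      bed <- data.table(x$chrom, x$start, x$end, paste0("summit:", x$summit),
                        sc, x$strand)
    } else {
      bed <- data.table(x$chrom, x$start, x$end,
                        x$id %||% ".", x$score %||% 0, x$strand %||% ".")
      bed[is.na(V5), V5 := 0]
    }
    fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write a CTSS table as one BED6 file per library
#'
#' @param ctss CTSS table from [read_ctss()].
#' @param dir output directory.
#' @param libs library table; files named `ctss_<id>.bed`.
#' @return named vector of written paths.
#' @export
write_ctss <- function(ctss, dir, libs) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0("ctss_", libs$id, ".bed")),
                           libs$id)
  for (id in libs$id) {
    sub <- ctss[ctss[[id]] > 0,
                .(chrom, pos, pos + 1L, ".", get(id), strand)]
    fwrite(sub, paths[[id]], sep = "\t", quote = FALSE, col.names = FALSE)
  }
  paths
}
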