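# Shared fixtures.  The default synthetic dataset and the pipeline run on
# it are expensive (about a minute together), so they are generated once
# per test session and reused by every file that needs them.

.fixture_env <- new.env(parent = emptyenv())

get_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- generate_dataset(seed = 1)
  .fixture_env$sim
}

get_res <- function() {
  if (is.null(.fixture_env$res))
    .fixture_env$res <- suppressMessages(run_pipeline(get_sim(), seed = 1))
  .fixture_env$res
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# a small 4 + 4 library table
make_libs <- function(total = 1e6) {
  libraries(id = c(paste0("c", 1:4), paste0("k", 1:4)),
            condition = rep(c("control", "exosomeKD"), each = 4),
            replicate = rep(1:4, 2), total_mapped_tags = total)
}

# pooled CTSS table from parallel vectors
make_pooled <- function(pos, count, strand = "+", chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, count = as.numeric(count))
}

# random DNA as a DNAStringSet
random_genome <- function(lens, seed = 1) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = ""), ""))
  names(g) <- names(lens)
  g
}
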