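#!/usr/bin/env Rscript
# Optional annotation-count checks against pinned GENCODE v35 releases.
#
# These verify the two exact reference counts the package's CDS-grouping
# and CDSI-classification rules imply on the real annotation:
#   1. basic annotation + pc_translations: 17,050 protein-coding isoforms
#      fall in multi-member identical-CDS groups forming 6,724 groups;
#   2. comprehensive annotation: 26,457 isoforms flagged CDS-incomplete
#      (cds_start_NF / cds_end_NF transcript tags).
#
# They need the (large) GENCODE files downloaded locally and therefore do
# not run in the offline test suite:
#
#   Rscript scripts/gencode_checks.R \
#     --basic-gtf gencode.v35.basic.annotation.gtf \
#     --translations gencode.v35.pc_translations.fa \
#     --comprehensive-gtf gencode.v35.annotation.gtf
#
# Parsing the full annotation takes a few minutes.

suppressMessages(library(cdsqtl))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
}

basic <- get_arg("--basic-gtf")
fa <- get_arg("--translations")
comp <- get_arg("--comprehensive-gtf")

if (!is.null(basic) && !is.null(fa)) {
  cat_basic <- read_annotation(basic, fa)
  groups <- build_cds_groups(cat_basic)
  sizes <- lengths(groups$groups)
  n_iso <- sum(sizes[sizes >= 2L])
  n_grp <- sum(sizes >= 2L)
  cat(sprintf("multi-member-group isoforms: %d (expected 17050)\n", n_iso))
  cat(sprintf("multi-member groups:         %d (expected 6724)\n", n_grp))
}

if (!is.null(comp)) {
  cat_comp <- read_annotation(comp)
  n_cdsi <- length(classify_cdsi(cat_comp))
  cat(sprintf("CDS-incomplete isoforms:     %d (expected 26457)\n", n_cdsi))
}

if (is.null(basic) && is.null(comp)) {
  cat("no inputs supplied; see header for usage\n")
}
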