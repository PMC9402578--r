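# Shared fixtures, all built in code.

suppressMessages(library(data.table))

# Write a small GTF from a list of transcripts:
#   list(list(id, gene, chrom, strand, exons = matrix, tags = chr), ...)
write_toy_gtf <- function(transcripts, path = tempfile(fileext = ".gtf")) {
  lines <- unlist(lapply(transcripts, function(tx) {
    tagattr <- paste0(vapply(tx$tags %||% character(0),
                             function(t) sprintf(' tag "%s";', t), ""),
                      collapse = "")
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";%s',
                     tx$gene, tx$id, tx$biotype %||% "protein_coding", tagattr)
    em <- tx$exons
    c(paste(tx$chrom, "toy", "transcript", min(em[, 1]), max(em[, 2]), ".",
            tx$strand, ".", attr9, sep = "\t"),
      vapply(seq_len(nrow(em)), function(j) {
        paste(tx$chrom, "toy", "exon", em[j, 1], em[j, 2], ".", tx$strand,
              ".", attr9, sep = "\t")
      }, ""))
  }))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(mapply(function(id, s) c(paste0(">", id), s),
                           names(seqs), seqs, SIMPLIFY = FALSE)), path)
  path
}

# A tiny two-gene catalog used across tests.
toy_catalog <- function() {
  gtf <- write_toy_gtf(list(
    list(id = "T1", gene = "G1", chrom = "chr1", strand = "+",
         exons = cbind(c(100, 300), c(200, 400)), tags = "basic"),
    list(id = "T2", gene = "G1", chrom = "chr1", strand = "+",
         exons = cbind(100, 400), tags = "basic"),
    list(id = "T3", gene = "G2", chrom = "chr1", strand = "-",
         exons = cbind(c(1000, 1300), c(1100, 1400)),
         tags = c("basic", "cds_start_NF"))
  ))
  fa <- write_toy_fasta(c("T1|x" = "MKT", "T2|x" = "MKT", "T3|x" = "MKV"))
  read_annotation(gtf, fa)
}

# Deterministic dosage matrix with independent variants (no LD), for
# oracle-style association tests.
toy_genotypes <- function(n = 60, p = 10, chrom = "chr1",
                          pos = seq(1000, by = 1000, length.out = p),
                          seed = 42) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p, 2, 0.3), n, p,
                dimnames = list(sprintf("S%03d", 1:n),
                                sprintf("var%02d", 1:p)))
  variants <- data.table(variant_id = colnames(dos), chrom = chrom,
                         pos = as.integer(pos), ref = "A", alt = "G",
                         maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2))
  cdsqtl:::new_genotype_matrix(variants, dos)
}
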