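#' @importFrom data.table data.table setkey setorder rbindlist fread fwrite :=
#' @importFrom stats cor cov pt pbeta qnorm pchisq sd var rnorm runif rbinom
#'   optim smooth.spline predict quantile density median setNames plogis
#'   qlogis
#' @importFrom utils head tail
NULL

# Internal GTF attribute parser. GENCODE attribute dialect:
#   key "value"; key "value"; ...
# The "tag" key may repeat (e.g. tag "basic"; tag "cds_start_NF"), so tags
# are collected into a single comma-separated field rather than overwriting.
parse_gtf_attributes <- function(attr_strings) {
  lapply(attr_strings, function(s) {
    m <- gregexpr('(\\S+)\\s+"([^"]*)"', s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(list(tags = character(0)))
    pieces <- regmatches(s, gregexpr('(\\S+)\\s+"([^"]*)"', s, perl = TRUE))[[1]]
    keys <- sub('^(\\S+)\\s+.*$', "\\1", pieces)
    vals <- sub('^\\S+\\s+"([^"]*)"$', "\\1", pieces)
    out <- as.list(vals[keys != "tag"])
    names(out) <- keys[keys != "tag"]
    out$tags <- vals[keys == "tag"]
    out
  })
}

#' Read a GENCODE-dialect GTF and optional protein FASTA into an isoform catalog
#'
#' Parses `transcript` and `exon` rows of a GTF file, computes strand-aware
#' TSS/TES per transcript, flags CDS-incomplete ends from the GENCODE
#' `cds_start_NF` / `cds_end_NF` transcript tags, and (optionally) attaches a
#' protein-sequence identity key per transcript from a translations FASTA
#' (headers in the GENCODE `pc_translations` dialect; the first `|`-delimited
#' field matching a transcript id is used, falling back to the first field).
#'
#' @param gtf_path path to a GTF file.
#' @param protein_fasta_path optional path to a protein FASTA keyed by
#'   transcript id.
#' @return An `IsoformCatalog`: a list with `isoforms` (a `data.table` with
#'   one row per transcript: `isoform_id`, `gene_id`, `chrom`, `strand`,
#'   `exons` (list column of two-column start/end matrices, 1-based
#'   inclusive), `tss`, `tes`, `biotype`, `cds_incomplete_start`,
#'   `cds_incomplete_end`, `protein_key`) and `genes` (named list mapping
#'   gene id to its isoform ids).
#' @export
read_annotation <- function(gtf_path, protein_fasta_path = NULL) {
  lines <- readLines(gtf_path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line ", idx[which(nf != 9L)[1]], " in ", gtf_path,
         " (expected 9 tab-separated fields, got ", nf[nf != 9L][1], ")")
  }
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("transcript", "exon")
  fields <- fields[use]
  feat <- feat[use]
  attrs <- parse_gtf_attributes(vapply(fields, `[[`, "", 9L))
  get_attr <- function(key, default = NA_character_) {
    vapply(attrs, function(a) if (is.null(a[[key]])) default else a[[key]], "")
  }
  dt <- data.table(
    feature = feat,
    chrom = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 4L)),
    end = as.integer(vapply(fields, `[[`, "", 5L)),
    strand = vapply(fields, `[[`, "", 7L),
    gene_id = get_attr("gene_id"),
    transcript_id = get_attr("transcript_id"),
    biotype = get_attr("transcript_type"),
    tags = lapply(attrs, `[[`, "tags")
  )
  tx <- dt[feature == "transcript"]
  ex <- dt[feature == "exon"]
  if (nrow(tx) == 0L) stop("no transcript rows found in ", gtf_path)

  exon_map <- split(seq_len(nrow(ex)), ex$transcript_id)
  records <- vector("list", nrow(tx))
  rejected <- character(0)
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    ei <- exon_map[[tid]]
    if (is.null(ei) || length(ei) == 0L) {
      rejected <- c(rejected, tid)
      next
    }
    em <- cbind(start = ex$start[ei], end = ex$end[ei])
    em <- em[order(em[, 1L]), , drop = FALSE]
    strand <- tx$strand[i]
    tss <- if (strand == "+") em[1L, 1L] else em[nrow(em), 2L]
    tes <- if (strand == "+") em[nrow(em), 2L] else em[1L, 1L]
    tags <- tx$tags[[i]]
    records[[i]] <- list(
      isoform_id = tid,
      gene_id = tx$gene_id[i],
      chrom = tx$chrom[i],
      strand = strand,
      exons = list(em),
      tss = as.integer(tss),
      tes = as.integer(tes),
      biotype = tx$biotype[i],
      cds_incomplete_start = "cds_start_NF" %in% tags,
      cds_incomplete_end = "cds_end_NF" %in% tags,
      tags = list(tags)
    )
  }
  if (length(rejected)) {
    warning(length(rejected), " transcript(s) with zero exons rejected: ",
            paste(head(rejected, 5L), collapse = ", "))
  }
  isoforms <- rbindlist(records[!vapply(records, is.null, TRUE)])
  if (anyDuplicated(isoforms$isoform_id)) {
    stop("duplicate transcript ids in ", gtf_path)
  }
  isoforms[, protein_key := NA_character_]
  if (!is.null(protein_fasta_path)) {
    aa <- Biostrings::readAAStringSet(protein_fasta_path)
    hdr_fields <- strsplit(names(aa), "|", fixed = TRUE)
    key_of <- vapply(hdr_fields, function(f) {
      hit <- f[f %in% isoforms$isoform_id]
      if (length(hit)) hit[1L] else f[1L]
    }, "")
    seqs <- toupper(sub("\\*+$", "", as.character(aa)))
    names(seqs) <- key_of
    isoforms[, protein_key := unname(seqs[isoform_id])]
  }
  new_isoform_catalog(isoforms)
}

new_isoform_catalog <- function(isoforms) {
  setkey(isoforms, isoform_id)
  genes <- split(isoforms$isoform_id, isoforms$gene_id)
  structure(list(isoforms = isoforms, genes = genes),
            class = "IsoformCatalog")
}

#' @export
print.IsoformCatalog <- function(x, ...) {
  cat("IsoformCatalog:", nrow(x$isoforms), "isoforms in",
      length(x$genes), "genes\n")
  cat("  CDS-incomplete:",
      sum(x$isoforms$cds_incomplete_start | x$isoforms$cds_incomplete_end),
      "| with protein key:", sum(!is.na(x$isoforms$protein_key)), "\n")
  invisible(x)
}

#' Write an isoform catalog back to GTF
#'
#' Emits one `transcript` row and one `exon` row per exon, preserving gene
#' and transcript ids, biotype and tags, in the GENCODE attribute dialect.
#' `read_annotation()` on the output reproduces the catalog (protein keys
#' excepted, which live in the FASTA).
#'
#' @param catalog an `IsoformCatalog`.
#' @param path output file path.
#' @export
write_annotation_gtf <- function(catalog, path) {
  iso <- catalog$isoforms
  lines <- character(0)
  for (i in seq_len(nrow(iso))) {
    em <- iso$exons[[i]]
    tagattr <- paste0(vapply(iso$tags[[i]],
                             function(t) sprintf(' tag "%s";', t), ""),
                      collapse = "")
    attr9 <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";%s',
                     iso$gene_id[i], iso$isoform_id[i], iso$biotype[i], tagattr)
    lines <- c(lines,
               paste(iso$chrom[i], "cdsqtl", "transcript",
                     min(em[, 1L]), max(em[, 2L]), ".", iso$strand[i], ".",
                     attr9, sep = "\t"),
               vapply(seq_len(nrow(em)), function(j) {
                 paste(iso$chrom[i], "cdsqtl", "exon", em[j, 1L], em[j, 2L],
                       ".", iso$strand[i], ".", attr9, sep = "\t")
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Group isoforms that encode an identical protein
#'
#' Within each gene, isoforms whose protein keys are byte-identical (after
#' uppercasing and stripping terminal stop symbols, done at read time) are
#' placed in one integration group. Isoforms without a protein key become
#' flagged singleton groups. Group ids are deterministic: the gene id plus
#' the sorted member ids.
#'
#' @param catalog an `IsoformCatalog`.
#' @return A `CdsGroupSet`: list with `groups` (named list of member id
#'   vectors), `membership` (named character: isoform id -> group id) and
#'   `unkeyed` (ids lacking a protein key, kept as singletons).
#' @export
build_cds_groups <- function(catalog) {
  iso <- catalog$isoforms
  groups <- list()
  membership <- character(0)
  unkeyed <- character(0)
  for (gene in names(catalog$genes)) {
    ids <- catalog$genes[[gene]]
    keys <- iso[ids, protein_key]
    has_key <- !is.na(keys)
    unkeyed <- c(unkeyed, ids[!has_key])
    parts <- c(split(ids[has_key], keys[has_key]),
               as.list(ids[!has_key]))
    for (members in parts) {
      members <- sort(members)
      gid <- paste0(gene, "::", paste(members, collapse = "+"))
      groups[[gid]] <- members
      membership[members] <- gid
    }
  }
  structure(list(groups = groups, membership = membership, unkeyed = unkeyed),
            class = "CdsGroupSet")
}

#' @export
print.CdsGroupSet <- function(x, ...) {
  sizes <- lengths(x$groups)
  cat("CdsGroupSet:", length(x$groups), "groups over", sum(sizes),
      "isoforms;", sum(sizes >= 2L), "multi-member groups covering",
      sum(sizes[sizes >= 2L]), "isoforms\n")
  invisible(x)
}

#' Identify CDS-incomplete (CDSI) isoforms
#'
#' Returns isoforms flagged as CDS-incomplete at the start and/or end.
#' Flags are derived at read time from the GENCODE `cds_start_NF` /
#' `cds_end_NF` transcript tags.
#'
#' @param catalog an `IsoformCatalog`.
#' @return character vector of isoform ids (sorted; possibly empty).
#' @export
classify_cdsi <- function(catalog) {
  iso <- catalog$isoforms
  sort(iso[cds_incomplete_start | cds_incomplete_end, isoform_id])
}
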