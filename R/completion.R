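# Long-read candidate-isoform completion filters: end proximity to
# reference TSS/TES catalogs, longest-ORF extraction, coding-probability
# thresholding, CDSI-junction matching, TSS-usage contingency testing, and
# the per-gene minimal-isoform summary.

# distance from a point to a set of 1-based inclusive intervals (0 inside)
point_interval_dist <- function(pos, chrom, intervals) {
  iv <- intervals[intervals$chrom == chrom, ]
  if (!nrow(iv)) return(Inf)
  min(pmax(iv$start - pos, pos - iv$end, 0))
}

#' Filter candidate isoforms on 5'/3'-end proximity to reference catalogs
#'
#' A candidate passes when its 5' end lies within `max_dist` bp (inclusive)
#' of a reference TSS interval AND its 3' end within `max_dist` bp of a
#' reference TES interval; distance to an interval is 0 inside it. For
#' minus-strand candidates the 5' end is the higher genomic coordinate
#' (callers supply `five_prime_end` / `three_prime_end` already
#' strand-resolved).
#'
#' @param candidates `data.table` with `candidate_id`, `chrom`, `strand`,
#'   `five_prime_end`, `three_prime_end`.
#' @param tss_ref,tes_ref interval tables (`chrom`, `start`, `end`,
#'   1-based inclusive, e.g. from [read_bed()]).
#' @param max_dist inclusive proximity threshold (default 50 bp).
#' @return the candidates table with added logical columns `tss_ok`,
#'   `tes_ok`, `end_pass`.
#' @export
end_proximity_filter <- function(candidates, tss_ref, tes_ref, max_dist = 50) {
  if (!nrow(tss_ref) || !nrow(tes_ref)) warning("empty reference set: all candidates fail")
  out <- copy(candidates)
  out[, tss_ok := vapply(seq_len(.N), function(i)
    point_interval_dist(five_prime_end[i], chrom[i], tss_ref) <= max_dist, TRUE)]
  out[, tes_ok := vapply(seq_len(.N), function(i)
    point_interval_dist(three_prime_end[i], chrom[i], tes_ref) <= max_dist, TRUE)]
  out[, end_pass := tss_ok & tes_ok]
  out[]
}

#' Longest complete open reading frame of a spliced mRNA sequence
#'
#' Scans the three forward frames of the sense-strand sequence for
#' ATG...stop spans and returns the longest (ties broken 5'-most). Codons
#' containing N translate to `X` and flag the call.
#'
#' @param spliced_sequence nucleotide string over A/C/G/T/N.
#' @return `NULL` if no complete ORF; otherwise a list with
#'   `start_offset`, `end_offset` (0-based half-open on the input),
#'   `length_nt`, `protein` and `has_ambiguous`.
#' @export
longest_orf <- function(spliced_sequence) {
  s <- toupper(spliced_sequence)
  n <- nchar(s)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  codons_all <- substring(s, seq_len(max(n - 2, 0)), seq_len(max(n - 2, 0)) + 2L)
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- codons_all[starts]
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        len <- (i - open_at + 1L) * 3L
        if (is.null(best) || len > best$length_nt) {
          best <- list(start_offset = starts[open_at] - 1L,
                       end_offset = starts[i] + 2L, length_nt = len)
        }
        open_at <- NA_integer_
      }
    }
  }
  if (is.null(best)) return(NULL)
  orf <- substr(s, best$start_offset + 1L, best$end_offset)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(chartr("N", "N", orf)),
                                           if.fuzzy.codon = "X"))
  best$protein <- sub("\\*$", "", aa)
  best$has_ambiguous <- grepl("X", best$protein, fixed = TRUE)
  best
}

#' Coding-probability filter
#'
#' Pass at `coding_probability >= min_prob` (inclusive); candidates with a
#' missing probability are bucketed as `unscored`, not dropped.
#'
#' @param candidates `data.table` with a `coding_probability` column.
#' @param min_prob threshold (default 0.364, the published human cutoff of
#'   the CPAT logistic model whose output this column carries).
#' @return candidates with an added `coding_status` column
#'   (`pass`/`fail`/`unscored`) and logical `coding_pass`.
#' @export
coding_filter <- function(candidates, min_prob = 0.364) {
  out <- copy(candidates)
  out[, coding_status := ifelse(is.na(coding_probability), "unscored",
                         ifelse(coding_probability >= min_prob, "pass", "fail"))]
  out[, coding_pass := coding_status == "pass"]
  out[]
}

#' Does a candidate's intron chain contain an exact target junction?
#'
#' @param introns two-column matrix of (donor, acceptor) 1-based intron
#'   boundaries, or a list of such pairs.
#' @param target numeric length-2 vector (donor, acceptor).
#' @return TRUE iff the exact pair occurs.
#' @export
junction_match <- function(introns, target) {
  if (is.list(introns) && !is.matrix(introns)) {
    introns <- do.call(rbind, introns)
  }
  if (is.null(introns) || nrow(introns) == 0L) return(FALSE)
  any(introns[, 1L] == target[1L] & introns[, 2L] == target[2L])
}

#' Chi-squared test of TSS class versus splice-acceptor class
#'
#' Pearson chi-squared on a 2x2 contingency table, 1 df, no continuity
#' correction (the intended use has large counts; set `correct = TRUE` for
#' the Yates version).
#'
#' @param counts 2x2 numeric matrix of non-negative counts.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with `chi2` and `p`.
#' @export
tss_usage_test <- function(counts, correct = FALSE) {
  stopifnot(is.matrix(counts), all(dim(counts) == 2L), all(counts >= 0),
            sum(counts) > 0)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal: chi-squared test undefined")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-gene summary of completed candidate isoforms
#'
#' For each gene, passing candidates are sorted by read count (descending,
#' ties by candidate id) and the smallest prefix whose cumulative read
#' share reaches 0.5 is reported.
#'
#' @param candidates `data.table` with `candidate_id`, `gene_id`,
#'   `read_count` and a logical `pass` column (e.g. the conjunction of the
#'   completion filters).
#' @return `data.table`: `gene_id`, `n_passing`, `n_covering_half`,
#'   `top_candidates` (comma-separated minimal set); genes whose passing
#'   candidates have zero total reads get NA with a warning.
#' @export
summarize_completion <- function(candidates) {
  cand <- candidates[pass == TRUE]
  cand[order(gene_id, -read_count, candidate_id)][, {
    tot <- sum(read_count)
    if (tot == 0) {
      warning("gene ", gene_id[1L], ": zero total reads")
      list(n_passing = .N, n_covering_half = NA_integer_,
           top_candidates = NA_character_)
    } else {
      k <- which(cumsum(read_count) / tot >= 0.5)[1L]
      list(n_passing = .N, n_covering_half = k,
           top_candidates = paste(candidate_id[seq_len(k)], collapse = ","))
    }
  }, by = gene_id]
}

#' @importFrom data.table copy setattr
NULL
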