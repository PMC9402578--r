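# End-to-end orchestration: one config, fixed seeds, structured per-stage
# logging, and the QTL-type overlap report (gene eQTL / i-eQTL / i-rQTL /
# i2-eQTL / i2-rQTL taxonomy).

#' Run configuration for the end-to-end pipeline
#'
#' @param input_dir directory holding the input files (the layout written
#'   by [simulate_all()]: `genotypes.vcf`, `annotation.gtf`, `proteins.fa`,
#'   `gene_fpkm.tsv`, `iso_fpkm.tsv`, plus optional `gwas.tsv`,
#'   `intervals.bed`, `junction_qtl.tsv`).
#' @param out_dir output directory for result tables and the manifest.
#' @param modes QTL analysis modes to run.
#' @param window,maf_min,B,q_max,n_factors,rtc_min,r2_min stage thresholds.
#' @param seed integer seed driving every random procedure.
#' @return a `RunConfig` list.
#' @export
run_config <- function(input_dir, out_dir,
                       modes = c("gene_eqtl", "i_eqtl", "i_rqtl",
                                 "i2_eqtl", "i2_rqtl"),
                       window = 1e6, maf_min = 0.05, B = 1000,
                       q_max = 0.05, n_factors = 15, rtc_min = 0.8,
                       r2_min = 0.8, seed = 1L) {
  structure(as.list(environment()), class = "RunConfig")
}

stage_log <- function(manifest, stage, ...) {
  info <- list(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(info), unlist(info), sep = "=", collapse = " ")))
  manifest$stages[[stage]] <- info
  manifest
}

#' Run the pipeline end to end
#'
#' Fixed stage order: annotation -> phenotypes per mode -> cis-QTL
#' (permutation pass + Storey FDR) -> junction curation (when a junction
#' table is present) -> colocalization (when a GWAS catalog and intervals
#' are present) -> overlap report. Result tables are written under
#' `out_dir` and a manifest (thresholds, seed, per-stage row counts) is
#' saved as JSON.
#'
#' @param config a `RunConfig`.
#' @return list with `results` (per-mode `CisQtlResult` tables),
#'   `phenotypes` (per-mode matrices), `coloc`, `curated`, `overlap` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "modes")],
                   modes = config$modes, stages = list())
  inp <- function(f) file.path(config$input_dir, f)

  catalog <- read_annotation(inp("annotation.gtf"),
                             if (file.exists(inp("proteins.fa"))) inp("proteins.fa"))
  manifest <- stage_log(manifest, "annotation",
                        isoforms = nrow(catalog$isoforms),
                        genes = length(catalog$genes))
  groups <- build_cds_groups(catalog)
  genotypes <- read_vcf_dosages(inp("genotypes.vcf"))
  gene_fpkm <- read_matrix_tsv(inp("gene_fpkm.tsv"))
  iso_fpkm <- read_matrix_tsv(inp("iso_fpkm.tsv"))
  manifest <- stage_log(manifest, "inputs",
                        variants = nrow(genotypes$variants),
                        samples = nrow(genotypes$dosages))

  results <- list(); phenos <- list(); gene_ofs <- list()
  for (mode in config$modes) {
    ph <- build_phenotypes(gene_fpkm, iso_fpkm, catalog, mode = mode,
                           groups = groups, n_factors = config$n_factors)
    res <- map_cis_qtl(ph$phenotypes, genotypes, ph$anchors,
                       window = config$window, maf_min = config$maf_min,
                       B = config$B, seed = config$seed)
    fwrite(res, file.path(config$out_dir, paste0(mode, "_qtl.tsv")), sep = "\t")
    manifest <- stage_log(manifest, paste0("cis_qtl_", mode),
                          phenotypes = nrow(res),
                          significant = sum(res$qvalue <= config$q_max))
    results[[mode]] <- res
    phenos[[mode]] <- ph$phenotypes
    gene_ofs[[mode]] <- ph$gene_of
  }

  curated <- NULL
  if (file.exists(inp("junction_qtl.tsv")) && "i_rqtl" %in% config$modes) {
    jq <- fread(inp("junction_qtl.tsv"))
    if (!nrow(jq)) jq <- data.table(junction_id = character(0),
                                    isoform_id = character(0), p = numeric(0),
                                    q = numeric(0), slope = numeric(0))
    curated <- curate_signals(results$i_rqtl, jq, qtl_fdr_max = config$q_max)
    fwrite(curated, file.path(config$out_dir, "curated_irqtl.tsv"), sep = "\t")
    manifest <- stage_log(manifest, "curation", kept = nrow(curated),
                          unmatched = attr(curated, "n_unmatched"))
  }

  coloc <- NULL
  if (file.exists(inp("gwas.tsv")) && file.exists(inp("intervals.bed"))) {
    gwas <- fread(inp("gwas.tsv"))
    intervals <- read_bed(inp("intervals.bed"))
    mode0 <- config$modes[1L]
    coloc <- colocalize_catalog(results[[mode0]], phenos[[mode0]], genotypes,
                                gwas, intervals, q_max = config$q_max,
                                rtc_min = config$rtc_min,
                                r2_min = config$r2_min)
    if (nrow(coloc)) fwrite(coloc, file.path(config$out_dir, "rtc.tsv"), sep = "\t")
    manifest <- stage_log(manifest, "colocalization", records = nrow(coloc),
                          passing = if (nrow(coloc)) sum(coloc$pass) else 0L)
  }

  overlap <- NULL
  core <- intersect(c("gene_eqtl", "i_eqtl", "i_rqtl"), config$modes)
  if (length(core) == 3L) {
    overlap <- overlap_report(results[core], gene_ofs[core],
                              q_max = config$q_max)
    jsonlite::write_json(overlap, file.path(config$out_dir, "overlap.json"),
                         auto_unbox = TRUE)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  list(results = results, phenotypes = phenos, coloc = coloc,
       curated = curated, overlap = overlap, manifest = manifest)
}

#' Gene-level overlap report across QTL types
#'
#' Collapses per-phenotype significance to the gene level for each mode
#' and reports marginal counts plus every intersection cell of the
#' three-way Venn (membership strings like `"gene_eqtl+i_rqtl"`).
#'
#' @param results named list of `CisQtlResult` tables (one per mode).
#' @param gene_of_list named list of named vectors mapping phenotype id ->
#'   gene id, aligned with `results`.
#' @param q_max significance cutoff (default 0.05).
#' @return list with `marginal` (named counts of significant genes per
#'   mode) and `cells` (named counts per exclusive Venn cell, empty cells
#'   included as 0).
#' @export
overlap_report <- function(results, gene_of_list, q_max = 0.05) {
  modes <- names(results)
  sig_genes <- lapply(modes, function(m) {
    r <- results[[m]]
    unique(unname(gene_of_list[[m]][r[qvalue <= q_max, phenotype_id]]))
  })
  names(sig_genes) <- modes
  all_genes <- unique(unlist(sig_genes))
  membership <- vapply(all_genes, function(g) {
    paste(modes[vapply(sig_genes, function(s) g %in% s, TRUE)],
          collapse = "+")
  }, "")
  cells <- table(membership)
  combos <- unlist(lapply(seq_along(modes), function(k) {
    apply(utils::combn(modes, k), 2L, paste, collapse = "+")
  }))
  full <- setNames(integer(length(combos)), combos)
  full[names(cells)] <- as.integer(cells)
  list(marginal = vapply(sig_genes, length, 0L), cells = as.list(full))
}
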