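# Synthetic-data generators.
#
# The generators emit miniature datasets with the statistical structure the
# pipeline assumes: LD-blocked biallelic genotypes with bounded MAF, genes
# with several isoforms (some sharing an identical CDS, some CDS-incomplete
# with a private junction), FPKM matrices in which genotype shifts gene
# totals and/or isoform fractions on the logit scale, and distal gene
# modules responding to an isoform ratio. Everything is a deterministic
# function of `seed`.

#' Simulation configuration
#'
#' Central knob set for all generators. Defaults describe a miniature but
#' realistic immune-cell cohort: 100 donors, tightly linked 10-variant LD
#' blocks (within-block dosage r-squared around 0.85), MAF in 0.1-0.5,
#' standardized cis effects of one logit (ratios) or one log-unit (totals),
#' residual noise of 0.5 sd, and substantial isoform-level quantification
#' noise between same-CDS isoforms (`split_noise_sd`).
#'
#' @param n_samples number of samples (>= 10).
#' @param n_genes number of gene loci, spaced 2 Mb apart on one synthetic
#'   chromosome so cis windows never overlap.
#' @param isoforms_per_gene integer range (low, high) of isoforms per gene.
#' @param frac_shared_cds fraction of multi-isoform genes carrying a pair of
#'   isoforms with an identical protein key.
#' @param frac_cdsi fraction of isoforms flagged CDS-incomplete, each with a
#'   junction private to it within its gene.
#' @param n_variants_per_locus variants simulated per gene locus.
#' @param ld_block_size variants per LD block.
#' @param ld_flip_prob per-haplotype allele flip probability within a block
#'   (0 gives perfect within-block LD).
#' @param maf_range (low, high) allele-frequency range; empirical MAF is
#'   rejection-sampled to stay at or above `low`.
#' @param effect_gene_eqtl standardized slope of planted gene-level effects
#'   on log total expression.
#' @param effect_irqtl logit-scale slope of planted ratio effects per
#'   standardized dosage.
#' @param noise_sd residual sd on log totals and logit isoform scores.
#' @param split_noise_sd extra logit-scale noise on members of multi-member
#'   CDS groups, emulating unstable read assignment between isoforms that
#'   differ only outside the CDS.
#' @param frac_low_expressed fraction of genes pushed below the FPKM
#'   filters on purpose.
#' @param n_trans_module_genes distal genes responding to a driver isoform
#'   ratio when a `trans` effect is planted.
#' @param effect_trans standardized slope of the trans module response.
#' @param seed integer seed; fully determines all outputs.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_samples = 100, n_genes = 20,
                       isoforms_per_gene = c(2L, 4L),
                       frac_shared_cds = 0.5, frac_cdsi = 0.2,
                       n_variants_per_locus = 50L, ld_block_size = 10L,
                       ld_flip_prob = 0.02, maf_range = c(0.1, 0.5),
                       effect_gene_eqtl = 1.0, effect_irqtl = 1.0,
                       noise_sd = 0.5, split_noise_sd = 1.0,
                       frac_low_expressed = 0.1,
                       n_trans_module_genes = 20L, effect_trans = 0.5,
                       seed = 1L) {
  stopifnot(n_samples >= 10, n_genes >= 1,
            frac_shared_cds >= 0, frac_shared_cds <= 1,
            frac_cdsi >= 0, frac_cdsi <= 1,
            ld_flip_prob >= 0, ld_flip_prob <= 0.5,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            noise_sd > 0, seed == as.integer(seed))
  structure(as.list(environment()), class = "SimulationConfig")
}

locus_center <- function(l) 2e6 * l

#' Simulate LD-blocked genotype dosages
#'
#' Each gene locus carries `n_variants_per_locus` variants in consecutive
#' LD blocks. Per block, one latent haplotype pair is drawn per sample at a
#' frequency uniform in `maf_range`; each variant copies the latent
#' haplotypes with per-allele flip probability `ld_flip_prob`. Blocks are
#' redrawn until every variant's empirical MAF reaches `maf_range[1]`.
#'
#' @param config a `SimulationConfig`.
#' @return a `GenotypeMatrix` whose `variants` table carries extra `locus`
#'   and `block` columns.
#' @export
simulate_genotypes <- function(config) {
  if (config$n_samples < 10) stop("n_samples < 10: downstream statistics degenerate")
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_variants_per_locus
  bs <- config$ld_block_size
  low <- config$maf_range[1]
  var_list <- vector("list", config$n_genes)
  dos_list <- vector("list", config$n_genes)
  samples <- sprintf("S%03d", seq_len(n))
  for (l in seq_len(config$n_genes)) {
    center <- locus_center(l)
    pos <- sort(sample(seq(center - 100000L, center + 100000L), p))
    block_of <- rep(seq_len(ceiling(p / bs)), each = bs)[seq_len(p)]
    dos <- matrix(0, n, p)
    for (b in unique(block_of)) {
      vb <- which(block_of == b)
      for (try in 1:1000) {
        q <- runif(1, low, config$maf_range[2])
        h1 <- rbinom(n, 1, q); h2 <- rbinom(n, 1, q)
        ok <- TRUE
        block_dos <- matrix(0, n, length(vb))
        for (k in seq_along(vb)) {
          f1 <- rbinom(n, 1, config$ld_flip_prob)
          f2 <- rbinom(n, 1, config$ld_flip_prob)
          d <- abs(h1 - f1) + abs(h2 - f2)
          af <- mean(d) / 2
          if (min(af, 1 - af) < low) { ok <- FALSE; break }
          block_dos[, k] <- d
        }
        if (ok) { dos[, vb] <- block_dos; break }
        if (try == 1000) {
          warning("LD block accepted after exhausting rejection budget")
          dos[, vb] <- block_dos
        }
      }
    }
    var_list[[l]] <- data.table(
      variant_id = sprintf("v%02d_%03d", l, seq_len(p)),
      chrom = "chrS", pos = as.integer(pos),
      ref = "A", alt = "G",
      maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
      locus = l, block = block_of)
    dos_list[[l]] <- dos
  }
  dosages <- do.call(cbind, dos_list)
  rownames(dosages) <- samples
  new_genotype_matrix(rbindlist(var_list), dosages)
}

random_protein <- function(len = 50L) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

#' Simulate a transcript annotation with shared-CDS and CDSI isoforms
#'
#' One gene per locus (centered on its variants) with 6 exons; each isoform
#' beyond the first skips a distinct internal exon, so every isoform owns a
#' private junction. A configured fraction of multi-isoform genes carries a
#' pair of isoforms with identical protein keys; a configured fraction of
#' isoforms is flagged CDS-incomplete (`cds_start_NF`).
#'
#' @param config a `SimulationConfig`.
#' @return list with `catalog` (an `IsoformCatalog`), `cds_groups_truth`
#'   (named list of the planted multi-member groups), `cdsi_truth`
#'   (character vector of planted CDSI isoform ids) and `cdsi_junctions`
#'   (`data.table` of each CDSI isoform's private junction, as 1-based
#'   donor/acceptor intron boundaries).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 1L)
  records <- list()
  cds_groups_truth <- list()
  cdsi_truth <- character(0)
  cdsi_junctions <- list()
  exon_len <- 300L; intron_len <- 2000L; n_ex <- 6L
  for (l in seq_len(config$n_genes)) {
    gene <- sprintf("GENE%02d", l)
    strand <- if (l %% 2L == 1L) "+" else "-"
    gstart <- as.integer(locus_center(l) - 8000L)
    exon_starts <- gstart + (seq_len(n_ex) - 1L) * (exon_len + intron_len)
    exons_all <- cbind(start = exon_starts, end = exon_starts + exon_len - 1L)
    k_range <- config$isoforms_per_gene[1]:config$isoforms_per_gene[2]
    k <- k_range[sample.int(length(k_range), 1L)]
    share <- k >= 2L && runif(1) < config$frac_shared_cds
    shared_key <- random_protein()
    iso_rows <- vector("list", k)
    for (j in seq_len(k)) {
      skip <- if (j == 1L) integer(0) else 1L + j %% 4L + 1L  # internal exon 2..5
      em <- exons_all[setdiff(seq_len(n_ex), skip), , drop = FALSE]
      iid <- sprintf("%s.I%d", gene, j)
      cdsi <- runif(1) < config$frac_cdsi
      # shared-CDS pair: isoforms 1 and 2 (skipped exon treated as UTR-only)
      key <- if (share && j <= 2L) shared_key else random_protein()
      if (cdsi) {
        cdsi_truth <- c(cdsi_truth, iid)
        key <- NA_character_  # CDS fragments carry no translation record
        if (length(skip)) {
          cdsi_junctions[[iid]] <- data.table(
            isoform_id = iid, gene_id = gene,
            donor = exons_all[skip - 1L, "end"] + 1L,
            acceptor = exons_all[skip + 1L, "start"] - 1L)
        }
      }
      tags <- c(if (cdsi) "cds_start_NF", if (!cdsi) "basic")
      iso_rows[[j]] <- data.table(
        isoform_id = iid, gene_id = gene, chrom = "chrS", strand = strand,
        exons = list(em),
        tss = if (strand == "+") em[1L, 1L] else em[nrow(em), 2L],
        tes = if (strand == "+") em[nrow(em), 2L] else em[1L, 1L],
        biotype = "protein_coding",
        cds_incomplete_start = cdsi, cds_incomplete_end = FALSE,
        tags = list(tags), protein_key = key)
    }
    rows <- rbindlist(iso_rows)
    if (share && !any(rows$cds_incomplete_start[1:2])) {
      members <- sort(rows$isoform_id[1:2])
      cds_groups_truth[[paste0(gene, "::", paste(members, collapse = "+"))]] <-
        members
    }
    records[[l]] <- rows
  }
  iso <- rbindlist(records)
  list(catalog = new_isoform_catalog(iso),
       cds_groups_truth = cds_groups_truth,
       cdsi_truth = sort(cdsi_truth),
       cdsi_junctions = rbindlist(cdsi_junctions))
}

#' Write the protein keys of a catalog as a translations FASTA
#' @param catalog an `IsoformCatalog`.
#' @param path output FASTA path. Headers are `<isoform_id>|synthetic`.
#' @export
write_protein_fasta <- function(catalog, path) {
  iso <- catalog$isoforms[!is.na(protein_key)]
  aa <- Biostrings::AAStringSet(iso$protein_key)
  names(aa) <- paste0(iso$isoform_id, "|synthetic")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Simulate FPKM matrices with planted genotype effects
#'
#' Gene totals follow `T = exp(mu + beta_e g + eps)`; isoform fractions are
#' logistic-normal: per-isoform logit scores `alpha_i + beta_r g [target] +
#' eta_i` softmax-normalized and multiplied by `T`. i2-level ratio effects
#' shift all members of a CDS group equally; `within_group_switch` plants
#' opposing shifts on the two members of a group (a 3'-UTR switch that
#' leaves the group total flat). A planted `trans` effect makes
#' `n_trans_module_genes` distal gene totals respond linearly to the driver
#' isoform's standardized ratio.
#'
#' @param genotypes a `GenotypeMatrix` from [simulate_genotypes()].
#' @param annotation result of [simulate_annotation()].
#' @param config a `SimulationConfig`.
#' @param effects optional named character vector `gene_id -> effect_type`
#'   with types in `none`, `gene_eqtl`, `i_rqtl`, `i2_rqtl`,
#'   `within_group_switch`, `trans`; by default a random mix (a quarter
#'   each of `gene_eqtl`, `i_rqtl` and, where a multi-member group exists,
#'   `i2_rqtl`).
#' @return list with `gene_fpkm` and `iso_fpkm` matrices (features x
#'   samples) and `truth` (a `PlantedTruth` `data.table`: `phenotype_id`,
#'   `gene_id`, `causal_variant_id`, `effect_type`, `effect_size`).
#' @export
simulate_expression <- function(genotypes, annotation, config, effects = NULL) {
  set.seed(config$seed + 2L)
  catalog <- annotation$catalog
  iso <- catalog$isoforms
  genes <- names(catalog$genes)
  n <- nrow(genotypes$dosages)
  stopifnot(n == config$n_samples)
  groups_by_gene <- lapply(annotation$cds_groups_truth, identity)
  gene_of_group <- sub("::.*$", "", names(groups_by_gene))

  if (is.null(effects)) {
    effects <- vapply(genes, function(g) {
      u <- runif(1)
      if (u < 0.25) "gene_eqtl"
      else if (u < 0.5) "i_rqtl"
      else if (u < 0.75 && g %in% gene_of_group) "i2_rqtl"
      else "none"
    }, "")
  }
  low_expr <- runif(length(genes)) < config$frac_low_expressed
  names(low_expr) <- genes

  truth <- list()
  gene_fpkm <- matrix(0, length(genes), n,
                      dimnames = list(genes, rownames(genotypes$dosages)))
  iso_fpkm <- matrix(0, nrow(iso), n,
                     dimnames = list(iso$isoform_id, rownames(genotypes$dosages)))
  frac_store <- list()  # per-gene fraction matrices for trans drivers

  for (g in genes) {
    l <- as.integer(sub("GENE", "", g))
    vmask <- genotypes$variants$locus == l
    vidx <- which(vmask)
    causal <- vidx[sample(length(vidx), 1L)]
    d <- genotypes$dosages[, causal]
    z <- if (sd(d) > 0) (d - mean(d)) / sd(d) else d * 0
    type <- effects[[g]]
    mu <- if (low_expr[[g]]) log(0.03) else log(20) + rnorm(1, 0, 0.5)
    beta_e <- if (type == "gene_eqtl") config$effect_gene_eqtl else 0
    tot <- exp(mu + beta_e * z + rnorm(n, 0, config$noise_sd))

    ids <- catalog$genes[[g]]
    members <- character(0)
    if (g %in% gene_of_group) {
      members <- groups_by_gene[[which(gene_of_group == g)[1L]]]
    }
    alpha <- rnorm(length(ids), 0, 1)
    scores <- matrix(rnorm(length(ids) * n, 0, config$noise_sd),
                     length(ids), n) + alpha
    rownames(scores) <- ids
    if (length(members) >= 2L) {
      scores[members, ] <- scores[members, ] +
        matrix(rnorm(length(members) * n, 0, config$split_noise_sd),
               length(members), n)
    }
    target <- NULL
    if (type == "i_rqtl") {
      target <- ids[sample(length(ids), 1L)]
      scores[target, ] <- scores[target, ] + config$effect_irqtl * z
    } else if (type == "i2_rqtl" && length(members) >= 2L) {
      scores[members, ] <- sweep(scores[members, , drop = FALSE], 2,
                                 config$effect_irqtl * z, `+`)
      target <- paste0(g, "::", paste(sort(members), collapse = "+"))
    }
    switch_pair <- NULL
    if (type == "within_group_switch" && length(members) >= 2L) {
      switch_pair <- members[1:2]
      target <- members[1L]
    }
    frac <- exp(scores)
    frac <- sweep(frac, 2, colSums(frac), `/`)
    if (!is.null(switch_pair)) {
      # pure reallocation between two same-CDS members: gene and group
      # totals stay exactly flat while the member ratio tracks dosage
      pair_tot <- colSums(frac[switch_pair, , drop = FALSE])
      w <- plogis(qlogis(frac[switch_pair[1L], ] / pair_tot) +
                  2 * config$effect_irqtl * z)
      frac[switch_pair[1L], ] <- pair_tot * w
      frac[switch_pair[2L], ] <- pair_tot * (1 - w)
    }
    frac_store[[g]] <- frac
    gene_fpkm[g, ] <- tot
    iso_fpkm[ids, ] <- sweep(frac, 2, tot, `*`)

    cv_id <- genotypes$variants$variant_id[causal]
    if (type == "gene_eqtl") {
      truth[[g]] <- data.table(phenotype_id = g, gene_id = g,
                               causal_variant_id = cv_id, effect_type = type,
                               effect_size = config$effect_gene_eqtl)
    } else if (type %in% c("i_rqtl", "i2_rqtl", "within_group_switch") &&
               !is.null(target)) {
      truth[[g]] <- data.table(phenotype_id = target, gene_id = g,
                               causal_variant_id = cv_id, effect_type = type,
                               effect_size = config$effect_irqtl)
    } else if (type == "trans") {
      # driver: an i_rqtl whose ratio drives a distal module (planted below)
      target <- ids[sample(length(ids), 1L)]
      scores2 <- config$effect_irqtl * z
      frac <- exp(log(frac) + outer(as.numeric(ids == target), scores2))
      frac <- sweep(frac, 2, colSums(frac), `/`)
      frac_store[[g]] <- frac
      iso_fpkm[ids, ] <- sweep(frac, 2, tot, `*`)
      truth[[g]] <- data.table(phenotype_id = target, gene_id = g,
                               causal_variant_id = cv_id, effect_type = "i_rqtl",
                               effect_size = config$effect_irqtl)
      attr(truth[[g]], "trans_driver") <- TRUE
    }
  }

  # distal module response to the driver ratio
  drivers <- which(vapply(truth, function(x) isTRUE(attr(x, "trans_driver")),
                          TRUE))
  for (di in drivers) {
    drv <- truth[[di]]
    ratio <- frac_store[[drv$gene_id]][drv$phenotype_id, ]
    zr <- (ratio - mean(ratio)) / sd(ratio)
    pool <- setdiff(genes, c(drv$gene_id, names(low_expr)[low_expr]))
    module <- sample(pool, min(config$n_trans_module_genes, length(pool)))
    for (mg in module) {
      shift <- exp(config$effect_trans * zr)
      gene_fpkm[mg, ] <- gene_fpkm[mg, ] * shift
      ids <- catalog$genes[[mg]]
      iso_fpkm[ids, ] <- sweep(iso_fpkm[ids, , drop = FALSE], 2, shift, `*`)
      truth[[paste0("trans_", mg)]] <- data.table(
        phenotype_id = mg, gene_id = drv$gene_id,
        causal_variant_id = drv$causal_variant_id, effect_type = "trans",
        effect_size = config$effect_trans)
    }
  }
  list(gene_fpkm = gene_fpkm, iso_fpkm = iso_fpkm,
       truth = rbindlist(truth))
}

#' Simulate auxiliary reference files
#'
#' Emits the side tables consumed by colocalization, characterization and
#' isoform completion: a GWAS catalog with positive controls at planted
#' causal variants and decoy traits elsewhere, per-locus recombination
#' intervals, CAGE TSS and PolyASite-style TES reference intervals at true
#' isoform ends plus decoys, a gene-set collection, and a junction-QTL
#' table mimicking LeafCutter output for CDSI-specific junctions.
#'
#' @param genotypes,annotation,truth outputs of the sibling generators.
#' @param config a `SimulationConfig`.
#' @return list of `data.table`s / lists: `gwas`, `intervals`, `cage_tss`,
#'   `polya_tes`, `gene_sets`, `junction_qtl`.
#' @export
simulate_aux <- function(genotypes, annotation, truth, config) {
  set.seed(config$seed + 3L)
  v <- genotypes$variants
  catalog <- annotation$catalog
  cis <- truth[effect_type %in% c("gene_eqtl", "i_rqtl", "i2_rqtl")]
  gwas <- list()
  if (nrow(cis)) {
    gwas[["pos"]] <- data.table(
      trait = paste0("trait_", cis$gene_id),
      variant_id = cis$causal_variant_id)
  }
  quiet <- setdiff(unique(v$locus),
                   as.integer(sub("GENE", "", unique(cis$gene_id))))
  if (length(quiet)) {
    picks <- v[locus %in% quiet][sample(.N, min(5L, .N))]
    gwas[["neg"]] <- data.table(trait = paste0("null_trait_", seq_len(nrow(picks))),
                                variant_id = picks$variant_id)
  }
  gwas <- rbindlist(gwas)
  gwas <- merge(gwas, v[, .(variant_id, chrom, pos)], by = "variant_id",
                sort = FALSE)[, .(trait, variant_id, chrom, pos)]

  intervals <- v[, .(start = min(pos), end = max(pos), chrom = chrom[1L]),
                 by = locus][, .(chrom, start, end,
                                 name = sprintf("interval_%02d", locus))]

  iso <- catalog$isoforms
  cage <- data.table(chrom = iso$chrom, start = pmax(1L, iso$tss - 10L),
                     end = iso$tss + 10L, name = paste0("cage_", iso$isoform_id))
  decoy <- data.table(chrom = iso$chrom, start = iso$tss + 5000L,
                      end = iso$tss + 5020L,
                      name = paste0("cage_decoy_", iso$isoform_id))
  cage <- rbind(cage, decoy)
  tes <- data.table(chrom = iso$chrom, start = pmax(1L, iso$tes - 10L),
                    end = iso$tes + 10L, name = paste0("tes_", iso$isoform_id))

  genes <- names(catalog$genes)
  module <- unique(truth[effect_type == "trans", phenotype_id])
  sets <- list()
  if (length(module)) sets$trans_module <- module
  for (k in 1:3) {
    sets[[sprintf("random_set_%d", k)]] <-
      sample(genes, min(10L, length(genes)))
  }

  cdsi <- annotation$cdsi_truth
  jq <- list()
  planted <- truth[effect_type == "i_rqtl"]
  for (iid in cdsi) {
    hit <- planted[phenotype_id == iid]
    if (nrow(hit)) {
      jq[[iid]] <- data.table(junction_id = paste0("J_", iid), isoform_id = iid,
                              lead_variant = hit$causal_variant_id[1L],
                              p = 1e-8, q = 1e-3,
                              slope = hit$effect_size[1L])
    } else {
      jq[[iid]] <- data.table(junction_id = paste0("J_", iid), isoform_id = iid,
                              lead_variant = v$variant_id[sample(nrow(v), 1L)],
                              p = runif(1, 0.05, 1), q = runif(1, 0.2, 1),
                              slope = rnorm(1))
    }
  }
  junction_qtl <- if (length(jq)) rbindlist(jq) else
    data.table(junction_id = character(0), isoform_id = character(0),
               lead_variant = character(0), p = numeric(0), q = numeric(0),
               slope = numeric(0))
  list(gwas = gwas, intervals = intervals, cage_tss = cage, polya_tes = tes,
       gene_sets = sets, junction_qtl = junction_qtl)
}

#' Run every generator and optionally write the files to a directory
#'
#' @param config a `SimulationConfig`.
#' @param dir optional output directory; when given, writes `genotypes.vcf`,
#'   `annotation.gtf`, `proteins.fa`, `gene_fpkm.tsv`, `iso_fpkm.tsv`,
#'   `gwas.tsv`, `intervals.bed`, `cage_tss.bed`, `polya_tes.bed`,
#'   `gene_sets.gmt`, `junction_qtl.tsv`.
#' @return list with `genotypes`, `annotation`, `expression`, `aux`,
#'   `config`.
#' @export
simulate_all <- function(config, dir = NULL) {
  genotypes <- simulate_genotypes(config)
  annotation <- simulate_annotation(config)
  expression <- simulate_expression(genotypes, annotation, config)
  aux <- simulate_aux(genotypes, annotation, expression$truth, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(genotypes, file.path(dir, "genotypes.vcf"))
    write_annotation_gtf(annotation$catalog, file.path(dir, "annotation.gtf"))
    write_protein_fasta(annotation$catalog, file.path(dir, "proteins.fa"))
    write_matrix_tsv(expression$gene_fpkm, file.path(dir, "gene_fpkm.tsv"),
                     id_col = "gene_id")
    write_matrix_tsv(expression$iso_fpkm, file.path(dir, "iso_fpkm.tsv"),
                     id_col = "isoform_id")
    fwrite(aux$gwas, file.path(dir, "gwas.tsv"), sep = "\t")
    write_bed(aux$intervals, file.path(dir, "intervals.bed"))
    write_bed(aux$cage_tss, file.path(dir, "cage_tss.bed"))
    write_bed(aux$polya_tes, file.path(dir, "polya_tes.bed"))
    write_gmt(aux$gene_sets, file.path(dir, "gene_sets.gmt"))
    fwrite(aux$junction_qtl, file.path(dir, "junction_qtl.tsv"), sep = "\t")
  }
  list(genotypes = genotypes, annotation = annotation,
       expression = expression, aux = aux, config = config)
}
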