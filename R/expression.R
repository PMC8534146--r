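# Shannon-entropy-based lineage-specific gene selection and prairie gene
# expression-change grouping.

#' Shannon entropy scores of gene expression across samples
#'
#' For each gene, relative expression `p_t = FPKM_t / sum_t FPKM_t` and
#' `H = -sum_t p_t log2 p_t` (with `0 * log 0 = 0`). Low entropy means
#' expression concentrated in few samples. Genes with all-zero expression get
#' `NA`.
#'
#' @param fpkm numeric matrix, genes x samples, with row and column names.
#' @return Named numeric vector of entropies in bits, in `[0, log2(ncol)]`.
#' @export
entropy_scores <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (ncol(fpkm) < 2) stop("need at least 2 samples")
  if (any(fpkm < 0)) stop("negative FPKM values")
  tot <- rowSums(fpkm)
  p <- fpkm / ifelse(tot > 0, tot, NA_real_)
  plogp <- ifelse(is.na(p) | p == 0, 0, p * log2(p))
  h <- -rowSums(plogp)
  h[tot == 0] <- NA_real_
  names(h) <- rownames(fpkm)
  h
}

# TSS point-in-domain assignment; genes outside any domain get NA.
assign_genes_to_domains <- function(genes, domains) {
  pts <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss + 1, width = 1))
  gd <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$start + 1,
                                                domains$end))
  hit <- GenomicRanges::findOverlaps(pts, gd, select = "first")
  data.frame(gene = genes$gene,
             domain_key = ifelse(is.na(hit), NA, domain_key(domains)[hit]),
             label = ifelse(is.na(hit), NA, domains$label[hit]),
             stringsAsFactors = FALSE)
}

#' Select lineage-specific genes
#'
#' A gene is selected when its expression entropy across all samples is below
#' `h_max`, it is highly expressed in the target stage (`FPKM >= fpkm_min`),
#' its relative expression in the target stage exceeds `rel_min` (strict), and
#' its target-stage expression strictly exceeds the reference stage.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param target_stage,reference_stage column names in `fpkm`.
#' @param h_max entropy cutoff in bits (default 1.7).
#' @param fpkm_min minimum target-stage FPKM (default 1, inclusive).
#' @param rel_min minimum relative expression (default 1/7, strict).
#' @param genes optional data.frame (`gene`, `chrom`, `tss`) of gene
#'   coordinates for domain assignment.
#' @param domains optional [fp_domains] object; with `genes`, the output gains
#'   `label`/`domain_key` columns and genes outside any domain are counted in
#'   the `n_outside_domains` attribute.
#' @return data.frame (`gene`, `entropy`, `fpkm_target`, `rel_target`,
#'   `fpkm_reference`, and domain columns when supplied), sorted by gene.
#' @export
select_lineage_specific <- function(fpkm, target_stage, reference_stage,
                                    h_max = 1.7, fpkm_min = 1,
                                    rel_min = 1 / 7,
                                    genes = NULL, domains = NULL) {
  fpkm <- as.matrix(fpkm)
  if (!target_stage %in% colnames(fpkm))
    stop("target stage '", target_stage, "' not in table")
  if (!reference_stage %in% colnames(fpkm))
    stop("reference stage '", reference_stage, "' not in table")
  h <- entropy_scores(fpkm)
  tot <- rowSums(fpkm)
  rel <- ifelse(tot > 0, fpkm[, target_stage] / tot, 0)
  keep <- !is.na(h) & h < h_max &
    fpkm[, target_stage] >= fpkm_min &
    rel > rel_min &
    fpkm[, target_stage] > fpkm[, reference_stage]
  out <- data.frame(gene = rownames(fpkm)[keep], entropy = h[keep],
                    fpkm_target = fpkm[keep, target_stage],
                    rel_target = rel[keep],
                    fpkm_reference = fpkm[keep, reference_stage],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(genes) && !is.null(domains)) {
    asg <- assign_genes_to_domains(genes, domains)
    out <- merge(out, asg, by = "gene", all.x = TRUE, sort = TRUE)
    attr(out, "n_outside_domains") <- sum(is.na(out$label))
  }
  out
}

#' Group prairie genes by expression change and compare host-domain mixing
#'
#' Prairie genes are split into increased (`FPKM_late > min_fold *
#' FPKM_early`) and decreased (`FPKM_early > min_fold * FPKM_late`) sets; the
#' DRs log-ratios of their host domains (from a [call_seg_mix()] result) are
#' compared between the two sets with a two-sided two-sample t-test. A
#' negative mean log-ratio for the increased set indicates that domains
#' harboring up-regulated genes became more forest-prairie mixed.
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param stage_early,stage_late column names in `fpkm`.
#' @param genes data.frame (`gene`, `chrom`, `tss`).
#' @param domains an [fp_domains] object.
#' @param calls a [call_seg_mix()] result between the two stages.
#' @param min_fold fold-change threshold (default 1: any strict change).
#' @return A list with `increased`, `decreased` (data.frames with gene,
#'   domain and log-ratio), and `t_test` (or NULL when a group is empty).
#' @export
expression_change_groups <- function(fpkm, stage_early, stage_late, genes,
                                     domains, calls, min_fold = 1) {
  fpkm <- as.matrix(fpkm)
  if (!stage_early %in% colnames(fpkm) || !stage_late %in% colnames(fpkm))
    stop("both stages must be present in the table")
  asg <- assign_genes_to_domains(genes, domains)
  prairie <- asg[!is.na(asg$label) & asg$label == "P", , drop = FALSE]
  e <- fpkm[prairie$gene, stage_early]
  l <- fpkm[prairie$gene, stage_late]
  lrmap <- calls$calls$log_ratio
  names(lrmap) <- calls$calls$key
  prairie$log_ratio <- unname(lrmap[prairie$domain_key])
  inc <- prairie[l > min_fold * e, , drop = FALSE]
  dec <- prairie[e > min_fold * l, , drop = FALSE]
  x <- inc$log_ratio[is.finite(inc$log_ratio)]
  y <- dec$log_ratio[is.finite(dec$log_ratio)]
  tt <- if (length(x) >= 2 && length(y) >= 2) stats::t.test(x, y) else NULL
  list(increased = inc, decreased = dec, t_test = tt)
}
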