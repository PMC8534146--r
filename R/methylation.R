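# Open-sea methylation: mask construction, per-domain open-sea methylation
# levels q, the methylation difference index (MDI), and per-sample summaries
# with group comparisons.

#' Build the open-sea mask
#'
#' Open sea is the genome minus CpG islands, their shores and shelves: every
#' CGI is extended by `shore_bp + shelf_bp` on each side (2 kb + 2 kb by
#' convention), the extensions are merged, and the complement within each
#' chromosome is returned.
#'
#' @param cgi data.frame (`chrom`, `start`, `end`) of CGI intervals.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param shore_bp,shelf_bp flank widths excluded around each CGI.
#' @return data.frame (`chrom`, `start`, `end`) of open-sea intervals.
#' @export
build_open_sea_mask <- function(cgi, chrom_sizes, shore_bp = 2000L,
                                shelf_bp = 2000L) {
  pad <- shore_bp + shelf_bp
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes), IRanges::IRanges(1, as.integer(chrom_sizes)))
  if (nrow(cgi) == 0) {
    open <- genome
  } else {
    excl <- GenomicRanges::GRanges(
      cgi$chrom,
      IRanges::IRanges(pmax(cgi$start - pad, 0) + 1,
                       pmin(cgi$end + pad,
                            unname(chrom_sizes[cgi$chrom]))))
    open <- GenomicRanges::setdiff(genome, GenomicRanges::reduce(excl))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(open)),
             start = GenomicRanges::start(open) - 1L,
             end = GenomicRanges::end(open), stringsAsFactors = FALSE)
}

#' Per-domain open-sea methylation level q
#'
#' The unweighted mean methylation fraction over open-sea CpGs with coverage
#' of at least `min_cov` inside each domain; `NA` when fewer than `min_cpg`
#' such CpGs are available.
#'
#' @param meth data.frame (`chrom`, `pos` 0-based, `meth_fraction`,
#'   `coverage`) of CpG-level calls.
#' @param domains an [fp_domains] object.
#' @param mask open-sea intervals from [build_open_sea_mask()].
#' @param min_cov minimum CpG coverage.
#' @param min_cpg minimum number of qualifying CpGs per domain.
#' @return data.frame (`key`, `chrom`, `id`, `label`, `n_cpg`, `q`).
#' @export
domain_open_sea_methylation <- function(meth, domains, mask, min_cov = 3L,
                                        min_cpg = 10L) {
  stopifnot(all(meth$meth_fraction >= 0 & meth$meth_fraction <= 1))
  ok <- meth$coverage >= min_cov
  pts <- GenomicRanges::GRanges(meth$chrom[ok],
                                IRanges::IRanges(meth$pos[ok] + 1, width = 1))
  gm <- GenomicRanges::GRanges(mask$chrom,
                               IRanges::IRanges(mask$start + 1, mask$end))
  in_sea <- GenomicRanges::countOverlaps(pts, gm) > 0
  gd <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$start + 1,
                                                domains$end))
  hit <- GenomicRanges::findOverlaps(pts[in_sea], gd, select = "first")
  frac <- meth$meth_fraction[ok][in_sea]
  res <- vapply(seq_len(nrow(domains)), function(r) {
    v <- frac[!is.na(hit) & hit == r]
    c(length(v), if (length(v) >= min_cpg) mean(v) else NA_real_)
  }, numeric(2))
  data.frame(key = domain_key(domains), chrom = domains$chrom,
             id = domains$id, label = domains$label,
             n_cpg = as.integer(res[1, ]), q = res[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Methylation difference index (MDI)
#'
#' For each interior domain i (in genomic order per chromosome):
#' `MDI_i = (q_i - (q_{i-1} + q_{i+1}) / 2) / ((q_{i-1} + q_i + q_{i+1}) / 3)`.
#' Positive values indicate the domain is more methylated than its two
#' flanking domains. The first and last domain of a chromosome, domains with
#' any undefined flank, and triplets with zero mean are `NA`.
#'
#' @param q_table a [domain_open_sea_methylation()] table in genomic order.
#' @return The table with an `mdi` column added.
#' @export
compute_mdi <- function(q_table) {
  q_table <- q_table[order(q_table$chrom, q_table$id), , drop = FALSE]
  mdi <- rep(NA_real_, nrow(q_table))
  for (ch in unique(q_table$chrom)) {
    idx <- which(q_table$chrom == ch)
    q <- q_table$q[idx]
    n <- length(q)
    if (n < 3) next
    for (i in 2:(n - 1)) {
      trip <- q[(i - 1):(i + 1)]
      if (any(is.na(trip))) next
      den <- mean(trip)
      if (den == 0) {
        message("zero-methylation triplet at ", ch, " domain ",
                q_table$id[idx[i]], ": MDI undefined")
        next
      }
      mdi[idx[i]] <- (trip[2] - (trip[1] + trip[3]) / 2) / den
    }
  }
  q_table$mdi <- mdi
  rownames(q_table) <- NULL
  q_table
}

#' Per-sample MDI summaries and group comparisons
#'
#' Computes the mean absolute MDI (and the signed mean, for transparency) per
#' domain label for every sample. When sample metadata are supplied, performs
#' two-sided two-sample t-tests of mean |MDI| between every pair of groups and
#' fits a least-squares slope of mean |MDI| against age, separately per label.
#'
#' @param mdi_tables named list (sample -> [compute_mdi()] table).
#' @param metadata optional data.frame (`sample`, `group`, `age`); `group`
#'   and `age` may be `NA`.
#' @return A list with `per_sample`, `group_tests`, `aging`.
#' @export
mdi_summary <- function(mdi_tables, metadata = NULL) {
  stopifnot(is.list(mdi_tables), !is.null(names(mdi_tables)))
  per_sample <- do.call(rbind, lapply(names(mdi_tables), function(s) {
    tab <- mdi_tables[[s]]
    do.call(rbind, lapply(c("F", "P"), function(L) {
      v <- tab$mdi[tab$label == L & !is.na(tab$mdi)]
      if (length(v) < 2) {
        warning("fewer than 2 defined MDI values for label ", L,
                " in sample ", s)
        return(NULL)
      }
      data.frame(sample = s, label = L, n = length(v),
                 mean_abs_mdi = mean(abs(v)), mean_mdi = mean(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  group_tests <- NULL
  aging <- NULL
  if (!is.null(metadata)) {
    ps <- merge(per_sample, metadata, by = "sample")
    if (!is.null(ps$group)) {
      groups <- unique(stats::na.omit(ps$group))
      if (length(groups) >= 2) {
        pairs <- utils::combn(groups, 2, simplify = FALSE)
        group_tests <- do.call(rbind, lapply(c("F", "P"), function(L) {
          do.call(rbind, lapply(pairs, function(pr) {
            x <- ps$mean_abs_mdi[ps$label == L & ps$group == pr[1]]
            y <- ps$mean_abs_mdi[ps$label == L & ps$group == pr[2]]
            if (length(x) < 2 || length(y) < 2) return(NULL)
            tt <- stats::t.test(x, y)
            data.frame(label = L, group1 = pr[1], group2 = pr[2],
                       mean1 = mean(x), mean2 = mean(y),
                       t = unname(tt$statistic), p_value = tt$p.value,
                       stringsAsFactors = FALSE)
          }))
        }))
      }
    }
    if (!is.null(ps$age) && sum(!is.na(ps$age)) >= 3) {
      aging <- do.call(rbind, lapply(c("F", "P"), function(L) {
        sub <- ps[ps$label == L & !is.na(ps$age), ]
        if (nrow(sub) < 3) return(NULL)
        fit <- stats::lm(mean_abs_mdi ~ age, data = sub)
        sm <- summary(fit)
        data.frame(label = L, slope = unname(stats::coef(fit)[2]),
                   p_value = sm$coefficients[2, 4], n = nrow(sub),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  list(per_sample = per_sample, group_tests = group_tests, aging = aging)
}
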