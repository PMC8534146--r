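# Segregation statistics: overall (ORs) and per-domain (DRs) segregation
# ratios, distance-resolved segregation Rs(d), top-decile contact composition
# TC10(d) with the critical genomic distance, replicate-calibrated seg/mix
# calls, the overall relative segregation ratio Ror, CpG/SINE segregation
# extent, and LAD-overlap analyses.
#
# Pair-counting convention (fixed, documented): same-type numerators follow
# the ordered index ranges of the defining formulas, so each unordered
# same-type domain (or bin) pair is counted twice, while each unordered
# cross-type pair enters the denominator once. All downstream comparisons are
# ratios of such ratios and do not depend on the global factor of 2 as long as
# the convention is fixed.

#' Overall segregation ratio (ORs)
#'
#' Ratio of inter-domain contacts between domains of the same type to
#' contacts between different types, for forests or prairies:
#' `ORs(F) = sum_{i,j in F, i != j} D_ij / sum_{i in F, j in P} D_ij`.
#' Intra-domain entries are excluded. A higher value indicates stronger
#' spatial segregation of the two domain types. Tables from several
#' chromosomes may be row-bound and passed together; sums pool across them.
#'
#' @param dct a `domain_contacts` table from [aggregate_domain_contacts()]
#'   (ICE-normalized input matrix).
#' @param label `"F"` or `"P"`.
#' @return A positive scalar.
#' @export
compute_ors <- function(dct, label = c("F", "P")) {
  label <- match.arg(label)
  inter <- !dct$intra
  same <- inter & dct$label_i == label & dct$label_j == label
  cross <- inter & ((dct$label_i == label) != (dct$label_j == label))
  den <- sum(dct$D[cross])
  if (den == 0) stop("no cross-type contact: ORs undefined (degenerate input)")
  2 * sum(dct$D[same]) / den
}

#' Per-domain segregation ratio (DRs)
#'
#' For each domain, the ratio of its inter-domain contacts with domains of the
#' same type to its contacts with the other type:
#' `DRs(i in F) = sum_{j in F, j != i} D_ij / sum_{j in P} D_ij`.
#' A zero cross-type denominator gives `NA` (undefined); a zero numerator with
#' positive denominator gives 0.
#'
#' @param dct a `domain_contacts` table.
#' @return data.frame with columns `key`, `chrom`, `id`, `label`, `drs`.
#' @export
compute_drs <- function(dct) {
  inter <- dct[!dct$intra, , drop = FALSE]
  doms <- unique(rbind(
    data.frame(key = inter$key_i, chrom = inter$chrom, id = inter$id_i,
               label = inter$label_i, stringsAsFactors = FALSE),
    data.frame(key = inter$key_j, chrom = inter$chrom, id = inter$id_j,
               label = inter$label_j, stringsAsFactors = FALSE)))
  doms <- doms[order(doms$chrom, doms$id), , drop = FALSE]
  drs <- vapply(seq_len(nrow(doms)), function(r) {
    k <- doms$key[r]
    lab <- doms$label[r]
    at_i <- inter$key_i == k
    at_j <- inter$key_j == k
    other_lab <- ifelse(at_i, inter$label_j, inter$label_i)
    touch <- at_i | at_j
    num <- sum(inter$D[touch & other_lab == lab])
    den <- sum(inter$D[touch & other_lab != lab])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  data.frame(key = doms$key, chrom = doms$chrom, id = doms$id,
             label = doms$label, drs = drs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Distance-resolved segregation ratio Rs(d)
#'
#' At each bin offset d, the ratio of same-type to cross-type contacts among
#' bin pairs exactly d bins apart, summed over both directions per bin (so
#' same-type pairs count twice, cross-type pairs once per endpoint of the
#' requested type). Unassigned and masked bins are excluded; a zero
#' denominator gives `NA` at that offset.
#'
#' @param m an (ICE-normalized) [contact_matrix].
#' @param bin_labels per-bin `"F"`/`"P"`/`NA` labels from [label_bins()].
#' @param label `"F"` or `"P"`.
#' @param offsets bin offsets to evaluate (default all).
#' @return data.frame with columns `d`, `offset_bp`, `same`, `cross`, `rs`.
#' @export
compute_rs_distance <- function(m, bin_labels, label = c("F", "P"),
                                offsets = NULL) {
  label <- match.arg(label)
  n <- m$n_bins
  stopifnot(length(bin_labels) == n)
  lab <- bin_labels
  lab[m$mask] <- NA
  other <- if (label == "F") "P" else "F"
  if (is.null(offsets)) offsets <- seq_len(n - 1)
  res <- lapply(offsets, function(d) {
    i <- seq_len(n - d)
    j <- i + d
    li <- lab[i]
    lj <- lab[j]
    v <- m$values[cbind(i, j)]
    same <- 2 * sum(v[!is.na(li) & !is.na(lj) & li == label & lj == label])
    cross <- sum(v[!is.na(li) & !is.na(lj) &
                     ((li == label & lj == other) |
                        (li == other & lj == label))])
    data.frame(d = d, offset_bp = d * m$resolution_bp,
               same = same, cross = cross,
               rs = if (cross == 0) NA_real_ else same / cross)
  })
  do.call(rbind, res)
}

#' Top-decile contact composition TC10(d) and the critical genomic distance
#'
#' For each genomic distance d, the top `top_frac` (default 10%) of contact
#' entries on that diagonal are selected (ties broken by lower bin index). If
#' any selected entry is zero the composition is assigned (0, 0, 0); otherwise
#' the selected pairs are classified by their endpoint labels into F-F, F-P
#' and P-P proportions. The critical genomic distance is the largest distance
#' whose composition is nonzero; if zero and nonzero compositions interleave
#' below it the result is flagged.
#'
#' @param m a normalized [contact_matrix].
#' @param bin_labels per-bin `"F"`/`"P"`/`NA` labels.
#' @param top_frac fraction of entries selected per diagonal.
#' @return A list with `table` (columns `d`, `offset_bp`, `n_d`, `p_ff`,
#'   `p_fp`, `p_pp`), `critical_distance_bp`, and `interleaved`.
#' @export
compute_tc10 <- function(m, bin_labels, top_frac = 0.1) {
  stopifnot(top_frac > 0, top_frac <= 1)
  n <- m$n_bins
  stopifnot(length(bin_labels) == n)
  lab <- bin_labels
  lab[m$mask] <- NA
  rows <- lapply(seq_len(n - 1), function(d) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- !is.na(lab[i]) & !is.na(lab[j])
    if (!any(ok)) return(NULL)
    i <- i[ok]
    j <- j[ok]
    v <- m$values[cbind(i, j)]
    k <- ceiling(top_frac * length(v))
    sel <- order(-v, i)[seq_len(k)]
    if (any(v[sel] == 0)) {
      p <- c(0, 0, 0)
    } else {
      li <- lab[i[sel]]
      lj <- lab[j[sel]]
      nff <- sum(li == "F" & lj == "F")
      npp <- sum(li == "P" & lj == "P")
      p <- c(nff, k - nff - npp, npp) / k
    }
    data.frame(d = d, offset_bp = d * m$resolution_bp, n_d = length(v),
               p_ff = p[1], p_fp = p[2], p_pp = p[3])
  })
  tab <- do.call(rbind, rows)
  nonzero <- tab$d[tab$p_ff + tab$p_fp + tab$p_pp > 0]
  crit <- if (length(nonzero) == 0) 0L else max(nonzero)
  zeros_below <- tab$d[tab$p_ff + tab$p_fp + tab$p_pp == 0 & tab$d < crit]
  interleaved <- length(zeros_below) > 0
  if (interleaved)
    warning("zero and nonzero TC10 compositions interleave below the ",
            "critical distance")
  list(table = tab,
       critical_distance_bp = as.numeric(crit) * m$resolution_bp,
       interleaved = interleaved)
}

# Coerce a compute_drs() data.frame (or a named numeric vector) to a named
# vector of DRs values.
drs_vector <- function(x) {
  if (is.data.frame(x)) {
    v <- x$drs
    names(v) <- x$key
    v
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Calibrate the seg/mix log-ratio threshold from replicates
#'
#' Computes per-domain log-ratios `ln(DRs_rep1 / DRs_rep2)` between two
#' replicate measurements of the same stage and returns the symmetric
#' threshold `T = max(|Q(1 - tail)|, |Q(tail)|)` of their empirical quantiles
#' (linear interpolation). Domains in the top/bottom `tail` of between-stage
#' log-ratios relative to this replicate-noise yardstick are later called
#' significantly more segregated/mixed.
#'
#' @param drs_rep1,drs_rep2 [compute_drs()] tables (or named numeric vectors)
#'   for the two replicates.
#' @param tail tail probability per side (default 0.025).
#' @return The threshold T (non-negative scalar).
#' @export
calibrate_threshold <- function(drs_rep1, drs_rep2, tail = 0.025) {
  v1 <- drs_vector(drs_rep1)
  v2 <- drs_vector(drs_rep2)
  shared <- intersect(names(v1), names(v2))
  a <- v1[shared]
  b <- v2[shared]
  ok <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  if (sum(ok) < 40)
    stop("insufficient replicate support: ", sum(ok),
         " domains with defined positive DRs in both replicates (need >= 40)")
  r <- log(a[ok] / b[ok])
  q <- stats::quantile(r, c(tail, 1 - tail), names = FALSE, type = 7)
  max(abs(q))
}

#' Call significantly more segregated or mixed domains between two stages
#'
#' Per shared domain, `log_ratio = ln(DRs_late / DRs_early)`; the call is
#' `seg` when `log_ratio > T`, `mix` when `log_ratio < -T`, `neutral`
#' otherwise, and `undefined` when either DRs is missing or zero.
#'
#' @param drs_early,drs_late [compute_drs()] tables (or named numeric vectors).
#' @param threshold symmetric threshold T from [calibrate_threshold()].
#' @return A list with `calls` (data.frame `key`, `label`, `log_ratio`,
#'   `call`), `threshold`, and `summary` (per-label counts and fractions of
#'   seg/mix/neutral among defined domains).
#' @export
call_seg_mix <- function(drs_early, drs_late, threshold) {
  stopifnot(threshold >= 0)
  ve <- drs_vector(drs_early)
  vl <- drs_vector(drs_late)
  shared <- intersect(names(ve), names(vl))
  labels <- rep(NA_character_, length(shared))
  if (is.data.frame(drs_early)) {
    labels <- drs_early$label[match(shared, drs_early$key)]
  } else if (is.data.frame(drs_late)) {
    labels <- drs_late$label[match(shared, drs_late$key)]
  }
  e <- ve[shared]
  l <- vl[shared]
  lr <- ifelse(is.na(e) | is.na(l) | e <= 0 | l <= 0, NA_real_, log(l / e))
  call <- ifelse(is.na(lr), "undefined",
                 ifelse(lr > threshold, "seg",
                        ifelse(lr < -threshold, "mix", "neutral")))
  calls <- data.frame(key = shared, label = labels, log_ratio = lr,
                      call = call, row.names = NULL, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(unique(stats::na.omit(labels)), function(L) {
    sub <- calls[!is.na(calls$label) & calls$label == L, ]
    nd <- sum(sub$call != "undefined")
    data.frame(label = L, n = nrow(sub), n_defined = nd,
               n_seg = sum(sub$call == "seg"),
               n_mix = sum(sub$call == "mix"),
               n_neutral = sum(sub$call == "neutral"),
               frac_seg = if (nd > 0) sum(sub$call == "seg") / nd else NA_real_,
               frac_mix = if (nd > 0) sum(sub$call == "mix") / nd else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, threshold = threshold, summary = summ)
}

#' Overall relative segregation ratio (Ror) between two samples
#'
#' `Ror = ln(n_ij / n_ji)` where `n_ij` is the number of shared domains with a
#' higher DRs in sample i than in sample j (ties excluded from both counts).
#' Positive values indicate that sample i is more segregated.
#'
#' @param drs_i,drs_j [compute_drs()] tables (or named numeric vectors).
#' @return A list with `n_ij`, `n_ji`, `ror`.
#' @export
compute_ror <- function(drs_i, drs_j) {
  vi <- drs_vector(drs_i)
  vj <- drs_vector(drs_j)
  shared <- intersect(names(vi), names(vj))
  a <- vi[shared]
  b <- vj[shared]
  ok <- is.finite(a) & is.finite(b)
  n_ij <- sum(a[ok] > b[ok])
  n_ji <- sum(a[ok] < b[ok])
  if (n_ij == 0 || n_ji == 0) {
    warning("zero count on one side: Ror is infinite")
    ror <- if (n_ij == 0 && n_ji == 0) NaN else if (n_ij == 0) -Inf else Inf
  } else {
    ror <- log(n_ij / n_ji)
  }
  list(n_ij = n_ij, n_ji = n_ji, ror = ror)
}

#' Segregation extent between two bin classes
#'
#' For two bin classes X and Y (for example `hChS` vs `hClS`), the extent of X
#' is the mean contact over X-X bin pairs divided by the mean contact over X-Y
#' pairs, and analogously for Y. All offsets are pooled; diagonal entries and
#' masked bins are excluded.
#'
#' @param m a normalized [contact_matrix].
#' @param cls a [classify_bins_cpg_sine()] track aligned to the matrix bins.
#' @param group_x,group_y class names, two of `hChS`, `hClS`, `lChS`, `lClS`.
#' @return Named numeric vector with the two extents.
#' @export
segregation_extent <- function(m, cls, group_x, group_y) {
  stopifnot(nrow(cls) == m$n_bins)
  keep <- rep(TRUE, m$n_bins)
  keep[m$mask] <- FALSE
  bx <- which(cls$cls == group_x & keep)
  by <- which(cls$cls == group_y & keep)
  if (length(bx) < 2 || length(by) < 2)
    stop("empty or singleton bin class: segregation extent undefined")
  v <- m$values
  mean_within <- function(b) {
    s <- sum(v[b, b]) - sum(diag(v)[b])
    s / (length(b) * (length(b) - 1))
  }
  mean_cross <- mean(v[bx, by])
  if (mean_cross == 0) stop("no cross-class contact")
  out <- c(mean_within(bx) / mean_cross, mean_within(by) / mean_cross)
  names(out) <- c(group_x, group_y)
  out
}

# Fraction of each domain's length covered by a set of intervals.
overlap_fraction <- function(domains, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(0, nrow(domains)))
  gd <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$start + 1,
                                                domains$end))
  gl <- GenomicRanges::reduce(
    GenomicRanges::GRanges(intervals$chrom,
                           IRanges::IRanges(intervals$start + 1,
                                            intervals$end)))
  hits <- GenomicRanges::findOverlaps(gd, gl)
  ov <- GenomicRanges::pintersect(gd[S4Vectors::queryHits(hits)],
                                  gl[S4Vectors::subjectHits(hits)])
  cov <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
  frac <- rep(0, nrow(domains))
  idx <- as.integer(names(cov))
  frac[idx] <- as.numeric(cov) / domains$length_bp[idx]
  frac
}

#' LAD overlap and segregation analysis across two stages
#'
#' Classifies each domain as LAD or iLAD per stage (at least `min_overlap` of
#' its length covered by LAD intervals), compares DRs of LAD-overlapping vs
#' non-overlapping prairie domains (Welch's two-sided t-test, per stage),
#' tests the association between forests switching iLAD to LAD and mix calls
#' (two-sided Fisher's exact test on the 2x2 table restricted to forests
#' starting in iLAD), and compares early vs late DRs of iLAD-to-LAD forests
#' (two-sided two-sample t-test).
#'
#' @param domains an [fp_domains] object.
#' @param lad_early,lad_late data.frames (`chrom`, `start`, `end`) of LAD
#'   intervals per stage.
#' @param drs_early,drs_late [compute_drs()] tables for the two stages.
#' @param calls a [call_seg_mix()] result between the stages.
#' @param min_overlap minimum covered length fraction to call a domain LAD.
#' @return A list with `status`, `welch_prairie`, `fisher_table`, `fisher`,
#'   and `ilad_to_lad_ttest`; an empty report if no LAD intervals are given.
#' @export
lad_overlap_analysis <- function(domains, lad_early, lad_late,
                                 drs_early, drs_late, calls,
                                 min_overlap = 0.5) {
  n_early <- if (is.null(lad_early)) 0 else nrow(lad_early)
  n_late <- if (is.null(lad_late)) 0 else nrow(lad_late)
  if (n_early == 0 && n_late == 0) {
    warning("no LAD intervals: empty report")
    return(list(status = NULL, welch_prairie = NULL, fisher_table = NULL,
                fisher = NULL, ilad_to_lad_ttest = NULL))
  }
  keys <- domain_key(domains)
  status <- data.frame(
    key = keys, label = domains$label,
    lad_early = overlap_fraction(domains, lad_early) >= min_overlap,
    lad_late = overlap_fraction(domains, lad_late) >= min_overlap,
    stringsAsFactors = FALSE)
  status$transition <- paste0(ifelse(status$lad_early, "LAD", "iLAD"), "->",
                              ifelse(status$lad_late, "LAD", "iLAD"))
  ve <- drs_vector(drs_early)
  vl <- drs_vector(drs_late)
  welch_one <- function(v, lad_flag) {
    p <- status$label == "P"
    x <- v[status$key[p & lad_flag]]
    y <- v[status$key[p & !lad_flag]]
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    stats::t.test(x, y, var.equal = FALSE)
  }
  welch <- list(early = welch_one(ve, status$lad_early),
                late = welch_one(vl, status$lad_late))
  # forests starting in iLAD: does switching into LAD associate with mixing?
  fi <- status$label == "F" & !status$lad_early
  cls <- calls$calls
  callv <- cls$call[match(status$key, cls$key)]
  defined <- fi & !is.na(callv) & callv != "undefined"
  to_lad <- status$lad_late[defined]
  is_mix <- callv[defined] == "mix"
  tab <- matrix(c(sum(to_lad & is_mix), sum(to_lad & !is_mix),
                  sum(!to_lad & is_mix), sum(!to_lad & !is_mix)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("iLAD->LAD", "iLAD->iLAD"),
                                c("mix", "not_mix")))
  fisher <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    stats::fisher.test(tab) else NULL
  switch_keys <- status$key[fi & status$lad_late]
  de <- ve[switch_keys]
  dl <- vl[switch_keys]
  tt <- if (sum(is.finite(de)) >= 2 && sum(is.finite(dl)) >= 2)
    stats::t.test(de[is.finite(de)], dl[is.finite(dl)]) else NULL
  list(status = status, welch_prairie = welch, fisher_table = tab,
       fisher = fisher, ilad_to_lad_ttest = tt)
}
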