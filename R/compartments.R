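# A/B compartment calling (PC1 of the contact correlation matrix), the
# compartment index, strict compartments, forest/prairie-by-compartment
# composition, prairie compartment dynamics across stages, transition
# composition, and bedGraph-style signal aggregation.

#' Call A/B compartments from a distance-normalized contact matrix
#'
#' PC1 is the leading eigenvector of the Pearson correlation matrix of the
#' distance-normalized contact matrix (masked bins removed, then re-inserted
#' as `NA`). The sign is oriented so bins with above-median CpG density have a
#' positive mean PC1 (compartment A is the CpG-rich, active compartment);
#' `delta` is 1 (A) where PC1 > 0 and 0 (B) elsewhere.
#'
#' @param m a distance-normalized [contact_matrix] with at least 20 unmasked
#'   bins.
#' @param cpg_density numeric per-bin CpG density used to orient the sign.
#' @return data.frame of class `compartment_track` with columns `chrom`,
#'   `bin` (0-based), `start`, `end`, `pc1`, `delta`, `cindex` (NA until
#'   [compute_cindex()]), `strict`; resolution kept as an attribute.
#' @export
call_compartments <- function(m, cpg_density) {
  if (m$norm_state != "distance")
    warning("compartment calling expects a distance-normalized matrix")
  stopifnot(length(cpg_density) == m$n_bins)
  um <- unmasked_bins(m)
  if (length(um) < 20) stop("need at least 20 unmasked bins")
  cc <- suppressWarnings(stats::cor(m$values[um, um, drop = FALSE]))
  if (any(!is.finite(cc)))
    stop("degenerate correlation matrix (constant contact profiles)")
  ev <- eigen(cc, symmetric = TRUE)
  pc1u <- ev$vectors[, 1]
  cpg <- cpg_density[um]
  # orient so PC1 increases with CpG density (A = CpG-rich); covariance is
  # the tie-robust form of "above-median CpG bins have positive mean PC1"
  ori <- stats::cov(pc1u, cpg)
  if (ori == 0) {
    hi <- cpg > stats::median(cpg)
    ori <- if (any(hi)) mean(pc1u[hi]) else 1
  }
  if (ori < 0) pc1u <- -pc1u
  pc1 <- rep(NA_real_, m$n_bins)
  pc1[um] <- pc1u
  track <- data.frame(
    chrom = m$chrom, bin = seq_len(m$n_bins) - 1L,
    start = (seq_len(m$n_bins) - 1L) * m$resolution_bp,
    end = seq_len(m$n_bins) * m$resolution_bp,
    pc1 = pc1,
    delta = ifelse(is.na(pc1), NA_integer_, as.integer(pc1 > 0)),
    cindex = NA_real_, strict = NA_character_, stringsAsFactors = FALSE)
  attr(track, "resolution_bp") <- m$resolution_bp
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Compartment index (C-index)
#'
#' For each bin i, the log ratio of its mean distance-normalized contact with
#' all A bins over its mean contact with all B bins:
#' `I_i = ln[(sum_j C_ij delta_j / N_A) / (sum_j C_ij (1 - delta_j) / N_B)]`.
#' Higher values indicate a more A-like (active) spatial environment. Bins
#' with zero contact to either class get `NA`.
#'
#' @param m a distance-normalized [contact_matrix].
#' @param track a `compartment_track` with `delta` assigned.
#' @return The track with the `cindex` column filled.
#' @export
compute_cindex <- function(m, track) {
  stopifnot(nrow(track) == m$n_bins)
  delta <- track$delta
  um <- which(!is.na(delta))
  um <- setdiff(um, m$mask)
  n_a <- sum(delta[um] == 1)
  n_b <- sum(delta[um] == 0)
  if (n_a == 0 || n_b == 0)
    stop("both compartments must be non-empty for the C-index")
  a_bins <- um[delta[um] == 1]
  b_bins <- um[delta[um] == 0]
  cindex <- rep(NA_real_, m$n_bins)
  for (i in um) {
    sa <- sum(m$values[i, a_bins])
    sb <- sum(m$values[i, b_bins])
    if (sa == 0 || sb == 0) next
    cindex[i] <- log((sa / n_a) / (sb / n_b))
  }
  track$cindex <- cindex
  attr(track, "n_a") <- n_a
  attr(track, "n_b") <- n_b
  track
}

#' Strict compartments and their forest/prairie genome lengths
#'
#' A bins with a positive C-index are strict A (`sA`); B bins with a negative
#' C-index are strict B (`sB`); everything else is `none` and dropped from the
#' strict analysis. Genome lengths are reported for the four classes sAf, sAp,
#' sBf, sBp (strict compartment x forest/prairie).
#'
#' @param track a `compartment_track` with `delta` and `cindex` filled.
#' @param bin_fp_labels per-bin `"F"`/`"P"`/`NA` labels from [label_bins()].
#' @return A list with the updated `track` (strict column filled) and
#'   `lengths_bp`, a named vector (sAf, sAp, sBf, sBp).
#' @export
strict_compartments <- function(track, bin_fp_labels) {
  stopifnot(length(bin_fp_labels) == nrow(track))
  strict <- rep("none", nrow(track))
  strict[!is.na(track$delta) & track$delta == 1 &
           !is.na(track$cindex) & track$cindex > 0] <- "sA"
  strict[!is.na(track$delta) & track$delta == 0 &
           !is.na(track$cindex) & track$cindex < 0] <- "sB"
  track$strict <- strict
  res <- attr(track, "resolution_bp")
  if (is.null(res)) res <- track$end[1] - track$start[1]
  fp <- bin_fp_labels
  lengths <- c(
    sAf = sum(strict == "sA" & !is.na(fp) & fp == "F"),
    sAp = sum(strict == "sA" & !is.na(fp) & fp == "P"),
    sBf = sum(strict == "sB" & !is.na(fp) & fp == "F"),
    sBp = sum(strict == "sB" & !is.na(fp) & fp == "P")) * res
  list(track = track, lengths_bp = lengths)
}

#' Forest/prairie by compartment composition (Af, Bf, Ap, Bp)
#'
#' Genome-length fractions of the four classes among bins carrying both an
#' A/B call and an F/P label; the first letter denotes the compartment, the
#' second the domain type. The four fractions sum to 1.
#'
#' @param track a `compartment_track`.
#' @param bin_fp_labels per-bin `"F"`/`"P"`/`NA` labels.
#' @return Named numeric vector (Af, Bf, Ap, Bp).
#' @export
fp_compartment_composition <- function(track, bin_fp_labels) {
  stopifnot(length(bin_fp_labels) == nrow(track))
  ok <- !is.na(track$delta) & !is.na(bin_fp_labels)
  if (!any(ok)) stop("no bins with both compartment and domain labels")
  a <- track$delta[ok] == 1
  f <- bin_fp_labels[ok] == "F"
  n <- sum(ok)
  c(Af = sum(a & f), Bf = sum(!a & f), Ap = sum(a & !f),
    Bp = sum(!a & !f)) / n
}

# Majority-vote compartment of each domain from its member bins' delta;
# ties go to B (the repressive default).
domain_compartments <- function(track, domains) {
  res <- attr(track, "resolution_bp")
  if (is.null(res)) res <- track$end[1] - track$start[1]
  rows <- bin_domain_rows(domains, res, chrom = domains$chrom[1],
                          n_bins = nrow(track))
  vapply(seq_len(nrow(domains)), function(r) {
    d <- track$delta[which(rows == r)]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_character_)
    if (sum(d == 1) > length(d) / 2) "A" else "B"
  }, character(1))
}

#' Classify prairie domains by compartment dynamics across stages
#'
#' Each prairie domain is assigned one compartment per stage by the majority
#' of its member bins' A/B calls (ties to B). Domains in A at every stage are
#' `stable_Ap`, in B at every stage `stable_Bp`, and `switchable_p` otherwise.
#' For every stage the distance from each B-prairie domain midpoint to the
#' nearest A-B boundary is also reported, to compare switch-prone and stable
#' regions.
#'
#' @param tracks named list of `compartment_track`s, one per stage, on a
#'   common grid.
#' @param domains an [fp_domains] object (single chromosome).
#' @return A list with `classes` (data.frame `key`, `label`, per-stage
#'   compartments, `class`) and `boundary_distance` (data.frame `stage`,
#'   `key`, `compartment`, `dist_bp` for prairie domains).
#' @export
classify_prairie_dynamics <- function(tracks, domains) {
  stopifnot(length(tracks) >= 2)
  nb <- vapply(tracks, nrow, integer(1))
  if (length(unique(nb)) != 1) stop("stage grids mismatch")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- paste0("stage", seq_along(tracks))
  per_stage <- vapply(tracks, domain_compartments, character(nrow(domains)),
                      domains = domains)
  per_stage <- matrix(per_stage, nrow = nrow(domains),
                      dimnames = list(NULL, names(tracks)))
  keys <- domain_key(domains)
  cls <- apply(per_stage, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_character_)
    if (all(x == "A")) "stable_Ap" else if (all(x == "B")) "stable_Bp"
    else "switchable_p"
  })
  classes <- data.frame(key = keys, label = domains$label,
                        per_stage, class = cls,
                        row.names = NULL, stringsAsFactors = FALSE)
  classes$class[classes$label != "P"] <- NA_character_
  res <- attr(tracks[[1]], "resolution_bp")
  if (is.null(res)) res <- tracks[[1]]$end[1] - tracks[[1]]$start[1]
  bd <- do.call(rbind, lapply(names(tracks), function(st) {
    tr <- tracks[[st]]
    d <- tr$delta
    ok <- which(!is.na(d))
    flips <- ok[-1][d[ok[-1]] != d[ok[-length(ok)]]]
    if (length(flips) == 0) return(NULL)
    bounds_bp <- tr$start[flips]
    p <- which(domains$label == "P")
    mid <- (domains$start[p] + domains$end[p]) / 2
    data.frame(stage = st, key = keys[p],
               compartment = per_stage[p, st],
               dist_bp = vapply(mid, function(x) min(abs(x - bounds_bp)),
                                numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(classes = classes, boundary_distance = bd)
}

#' Compartment transition composition between two stages
#'
#' Joint per-bin classification of two compartment tracks into AA, AB, BA, BB
#' (stage-1 state then stage-2 state), reported as genome-length ratios over
#' bins classified in both stages. Ratios sum to 1.
#'
#' @param track_stage1,track_stage2 `compartment_track`s on the same grid.
#' @return Named numeric vector (AA, AB, BA, BB).
#' @export
transition_composition <- function(track_stage1, track_stage2) {
  if (nrow(track_stage1) != nrow(track_stage2)) stop("stage grids mismatch")
  d1 <- track_stage1$delta
  d2 <- track_stage2$delta
  ok <- !is.na(d1) & !is.na(d2)
  if (!any(ok)) stop("no bins classified in both stages")
  n <- sum(ok)
  c(AA = sum(d1[ok] == 1 & d2[ok] == 1),
    AB = sum(d1[ok] == 1 & d2[ok] == 0),
    BA = sum(d1[ok] == 0 & d2[ok] == 1),
    BB = sum(d1[ok] == 0 & d2[ok] == 0)) / n
}

#' Aggregate an interval signal over regions
#'
#' Base-pair-weighted mean of a bedGraph-style signal over each region.
#' Uncovered base pairs contribute 0 to the mean and the covered fraction is
#' reported alongside.
#'
#' @param signal data.frame (`chrom`, `start`, `end`, `value`), sorted and
#'   non-overlapping per chromosome.
#' @param regions data.frame (`chrom`, `start`, `end`).
#' @return `regions` with `mean_signal` and `coverage` columns added.
#' @export
aggregate_signal <- function(signal, regions) {
  if (any(signal$end <= signal$start) || any(regions$end <= regions$start))
    stop("malformed intervals")
  for (ch in unique(signal$chrom)) {
    s <- signal[signal$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("malformed intervals: signal overlaps on ", ch)
  }
  gs <- GenomicRanges::GRanges(signal$chrom,
                               IRanges::IRanges(signal$start + 1, signal$end))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1,
                                                regions$end))
  hits <- GenomicRanges::findOverlaps(gr, gs)
  ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                  gs[S4Vectors::subjectHits(hits)])
  w <- IRanges::width(ov)
  qh <- S4Vectors::queryHits(hits)
  val <- signal$value[S4Vectors::subjectHits(hits)]
  wsum <- tapply(w * val, qh, sum)
  cov <- tapply(w, qh, sum)
  width <- regions$end - regions$start
  mean_signal <- rep(0, nrow(regions))
  coverage <- rep(0, nrow(regions))
  idx <- as.integer(names(wsum))
  mean_signal[idx] <- as.numeric(wsum) / width[idx]
  coverage[idx] <- as.numeric(cov) / width[idx]
  out <- regions
  out$mean_signal <- mean_signal
  out$coverage <- coverage
  out
}
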