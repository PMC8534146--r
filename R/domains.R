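# Forest/prairie domain partitioning from CGI density, bin labelling, and
# CpG x SINE bin classification. Coordinates are 0-based half-open (BED
# convention) throughout; bins are 0-based in all files, 1-based as R indices.

#' Construct a forest/prairie domain set
#'
#' A domain set is an ordered, non-overlapping tiling of each chromosome into
#' forest (`"F"`, CGI-rich) and prairie (`"P"`, CGI-poor) domains.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open coordinates in bp.
#' @param label character vector, `"F"` or `"P"`.
#' @return A `data.frame` of class `fp_domains` with columns `chrom`, `start`,
#'   `end`, `label`, `id` (ordinal within chromosome) and `length_bp`.
#' @export
fp_domains <- function(chrom, start, end, label) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(end) == length(label))
  if (!all(label %in% c("F", "P"))) stop("labels must be 'F' or 'P'")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (any(df$end <= df$start)) stop("domains must have positive length")
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop("domains overlap on chromosome ", ch)
  }
  df$id <- stats::ave(seq_len(nrow(df)), df$chrom, FUN = seq_along)
  df$length_bp <- df$end - df$start
  rownames(df) <- NULL
  class(df) <- c("fp_domains", "data.frame")
  df
}

#' @export
print.fp_domains <- function(x, ...) {
  cat(sprintf("fp_domains: %d domains on %d chromosome(s) (%d F, %d P)\n",
              nrow(x), length(unique(x$chrom)),
              sum(x$label == "F"), sum(x$label == "P")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

domain_key <- function(domains) paste0(domains$chrom, ":", domains$id)

#' Partition a genome into forest and prairie domains from CGI intervals
#'
#' Runs of CpG islands whose inter-CGI gaps are all shorter than
#' `gap_threshold_bp` are merged (with their flanks) into forest domains; the
#' remaining genome is prairie. Domains shorter than `min_domain_bp` are then
#' absorbed into their longer neighbor until none remain, so the resulting
#' domains are megabase-scale, as expected for this partition (average lengths
#' on the order of 1-3 Mb in mammalian genomes).
#'
#' @param cgi data.frame with columns `chrom`, `start`, `end`: sorted,
#'   non-overlapping CGI intervals.
#' @param chrom_sizes named numeric vector, chromosome name -> length in bp.
#' @param gap_threshold_bp maximum inter-CGI gap inside a forest (default 50 kb).
#' @param min_domain_bp minimum domain length kept (default 1 Mb).
#' @return An [fp_domains] tiling of every chromosome in `chrom_sizes`.
#' @export
partition_forest_prairie <- function(cgi, chrom_sizes,
                                     gap_threshold_bp = 50000L,
                                     min_domain_bp = 1000000L) {
  stopifnot(gap_threshold_bp > 0, min_domain_bp > 0)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (nrow(cgi) > 0) {
    bad <- !(cgi$chrom %in% names(chrom_sizes)) | cgi$start < 0 |
      cgi$end > unname(chrom_sizes[cgi$chrom])
    if (any(is.na(bad)) || any(bad))
      stop("CGI interval outside chromosome bounds")
  } else {
    warning("empty CGI set: entire genome labeled prairie")
  }
  out <- list()
  for (ch in names(chrom_sizes)) {
    size <- as.integer(chrom_sizes[[ch]])
    g <- cgi[cgi$chrom == ch, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)]))
      stop("CGI intervals overlap on chromosome ", ch)
    if (nrow(g) == 0) {
      out[[ch]] <- data.frame(chrom = ch, start = 0L, end = size, label = "P")
      next
    }
    # forest runs: consecutive CGIs closer than the gap threshold
    run <- cumsum(c(0L, as.integer(g$start[-1] - g$end[-nrow(g)] >=
                                     gap_threshold_bp)))
    fstart <- tapply(g$start, run, min)
    fend <- tapply(g$end, run, max)
    seg <- data.frame(start = as.integer(fstart), end = as.integer(fend),
                      label = "F")
    # prairie fills the complement
    edges <- c(0L, as.vector(rbind(seg$start, seg$end)), size)
    pstart <- edges[seq(1, length(edges), by = 2)]
    pend <- edges[seq(2, length(edges), by = 2)]
    keep <- pend > pstart
    seg <- rbind(seg, data.frame(start = pstart[keep], end = pend[keep],
                                 label = "P"))
    seg <- seg[order(seg$start), , drop = FALSE]
    seg <- merge_short_domains(seg, min_domain_bp)
    out[[ch]] <- data.frame(chrom = ch, start = seg$start, end = seg$end,
                            label = seg$label)
  }
  res <- do.call(rbind, out)
  fp_domains(res$chrom, res$start, res$end, res$label)
}

# Absorb sub-threshold segments into the longer neighbor (ties -> left),
# collapsing same-label neighbors after every merge.
merge_short_domains <- function(seg, min_domain_bp) {
  collapse <- function(s) {
    if (nrow(s) < 2) return(s)
    grp <- cumsum(c(1L, as.integer(s$label[-1] != s$label[-nrow(s)])))
    data.frame(start = as.integer(tapply(s$start, grp, min)),
               end = as.integer(tapply(s$end, grp, max)),
               label = as.character(tapply(s$label, grp, `[`, 1)))
  }
  seg <- collapse(seg)
  repeat {
    len <- seg$end - seg$start
    short <- which(len < min_domain_bp)
    if (length(short) == 0 || nrow(seg) == 1) break
    i <- short[which.min(len[short])]
    left <- if (i > 1) len[i - 1] else -1L
    right <- if (i < nrow(seg)) len[i + 1] else -1L
    j <- if (left >= right) i - 1L else i + 1L
    seg$start[j] <- min(seg$start[i], seg$start[j])
    seg$end[j] <- max(seg$end[i], seg$end[j])
    seg <- collapse(seg[-i, , drop = FALSE])
  }
  seg
}

#' Read forest/prairie domains from a BED4 file
#'
#' @param path BED file with columns chrom, start, end, name where name is
#'   `F` or `P`.
#' @return An [fp_domains] object.
#' @export
read_domains_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "label"))
  fp_domains(df$chrom, df$start, df$end, df$label)
}

#' Write forest/prairie domains as BED4
#'
#' @param domains an [fp_domains] object.
#' @param path output file.
#' @export
write_domains_bed <- function(domains, path) {
  df <- data.frame(domains$chrom, as.integer(domains$start),
                   as.integer(domains$end), domains$label)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Internal: map each bin (1-based index over a fixed grid) to a domain row of
# `domains` on one chromosome, by majority base-pair overlap. A bin is assigned
# only when the winning domain covers at least half of it; exact half/half ties
# between two domains go to the domain containing the bin start.
bin_domain_rows <- function(domains, resolution_bp, chrom = NULL,
                            n_bins = NULL) {
  stopifnot(resolution_bp > 0)
  if (is.null(chrom)) chrom <- domains$chrom[1]
  d <- domains[domains$chrom == chrom, , drop = FALSE]
  if (is.null(n_bins)) {
    if (nrow(d) == 0) stop("n_bins is required when no domains cover ", chrom)
    n_bins <- as.integer(ceiling(max(d$end) / resolution_bp))
  }
  assign <- rep(NA_integer_, n_bins)
  if (nrow(d) == 0) return(assign)
  for (b in seq_len(n_bins)) {
    b0 <- (b - 1) * resolution_bp
    b1 <- b0 + resolution_bp
    ov <- pmin(d$end, b1) - pmax(d$start, b0)
    ov[ov < 0] <- 0
    o <- max(ov)
    if (o == 0 || 2 * o < resolution_bp) next
    cand <- which(ov == o)
    if (length(cand) > 1L) {
      holds <- cand[d$start[cand] <= b0 & d$end[cand] > b0]
      if (length(holds) > 0) cand <- holds
    }
    assign[b] <- cand[1]
  }
  attr(assign, "rows") <- d
  assign
}

#' Label bins on a fixed grid by their covering domain
#'
#' Each bin of width `resolution_bp` is labelled `"F"` or `"P"` by the domain
#' covering the majority of the bin; exact 50/50 ties go to the domain
#' containing the bin start. Bins not majority-covered are `NA` (unassigned)
#' and excluded from all downstream statistics.
#'
#' @param domains an [fp_domains] object.
#' @param resolution_bp bin width in bp.
#' @param chrom chromosome to label (default: first chromosome in `domains`).
#' @param n_bins number of bins on the grid (default: up to the last domain end).
#' @return Character vector of length `n_bins` with values `"F"`, `"P"` or `NA`.
#' @export
label_bins <- function(domains, resolution_bp, chrom = NULL, n_bins = NULL) {
  rows <- bin_domain_rows(domains, resolution_bp, chrom, n_bins)
  d <- attr(rows, "rows")
  out <- rep(NA_character_, length(rows))
  ok <- !is.na(rows)
  out[ok] <- d$label[rows[ok]]
  out
}

#' Classify 40-kb bins by CpG and SINE density median splits
#'
#' Bins with density strictly above the genome-wide median are "high"; bins at
#' or below the median are "low". The two splits are combined into four
#' classes: `hChS`, `hClS`, `lChS`, `lClS` (high/low CpG x high/low SINE).
#'
#' @param cpg_density numeric vector, CpG density per bin (per bp).
#' @param sine_density numeric vector of the same length, SINE-covered fraction.
#' @return data.frame with columns `bin` (0-based), `cpg`, `sine`, `cls`.
#' @export
classify_bins_cpg_sine <- function(cpg_density, sine_density) {
  if (length(cpg_density) != length(sine_density))
    stop("density tracks must share the 40-kb grid")
  if (length(unique(cpg_density)) == 1L)
    stop("degenerate CpG density track: all values equal, no median split")
  if (length(unique(sine_density)) == 1L)
    stop("degenerate SINE density track: all values equal, no median split")
  hc <- cpg_density > stats::median(cpg_density)
  hs <- sine_density > stats::median(sine_density)
  data.frame(bin = seq_along(cpg_density) - 1L,
             cpg = cpg_density, sine = sine_density,
             cls = paste0(ifelse(hc, "h", "l"), "C",
                          ifelse(hs, "h", "l"), "S"),
             stringsAsFactors = FALSE)
}
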