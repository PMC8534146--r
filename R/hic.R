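# Hi-C contact-matrix container, text I/O, ICE and distance normalization,
# and aggregation into per-domain contact tables.

#' Construct a contact matrix
#'
#' A per-chromosome symmetric binned Hi-C matrix. `norm_state` records the
#' normalization applied so far and only moves forward: raw -> ICE -> distance.
#' Masked bins (zero-coverage) have all-zero rows and are excluded from every
#' downstream sum.
#'
#' @param values symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param resolution_bp bin width in bp.
#' @param norm_state one of `"raw"`, `"ICE"`, `"distance"`.
#' @param mask integer vector of masked bin indices (1-based).
#' @return A list of class `contact_matrix` with fields `chrom`,
#'   `resolution_bp`, `n_bins`, `values`, `norm_state`, `mask`.
#' @export
contact_matrix <- function(values, chrom = "chr1", resolution_bp = 40000L,
                           norm_state = c("raw", "ICE", "distance"),
                           mask = integer(0)) {
  norm_state <- match.arg(norm_state)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("contact matrix must be square")
  if (any(values < 0)) stop("negative contact counts")
  if (max(abs(values - t(values))) > 1e-9)
    stop("contact matrix asymmetric beyond tolerance 1e-9")
  values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  m <- list(chrom = as.character(chrom),
            resolution_bp = as.integer(resolution_bp),
            n_bins = nrow(values), values = values,
            norm_state = norm_state, mask = sort(unique(as.integer(mask))))
  class(m) <- "contact_matrix"
  m
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins @ %d bp, norm=%s, %d masked\n",
              x$chrom, x$n_bins, x$resolution_bp, x$norm_state,
              length(x$mask)))
  invisible(x)
}

unmasked_bins <- function(m) setdiff(seq_len(m$n_bins), m$mask)

#' Read a contact matrix from text
#'
#' Supports 3-column sparse text (`bin_i bin_j count`, 0-based bins, any
#' triangle; entries are mirrored) and dense whitespace-separated text.
#'
#' @param path input file.
#' @param chrom chromosome name for the container.
#' @param resolution_bp bin width in bp.
#' @param n_bins number of bins (sparse input only; default: max bin + 1).
#' @param format `"auto"` (by column count), `"sparse"`, or `"dense"`.
#' @return A [contact_matrix] with `norm_state = "raw"`.
#' @export
read_contact_matrix <- function(path, chrom = "chr1", resolution_bp = 40000L,
                                n_bins = NULL,
                                format = c("auto", "sparse", "dense")) {
  format <- match.arg(format)
  tab <- utils::read.table(path, header = FALSE)
  if (format == "auto") format <- if (ncol(tab) == 3) "sparse" else "dense"
  if (format == "sparse") {
    if (ncol(tab) != 3) stop("sparse matrix text must have 3 columns")
    i <- as.integer(tab[[1]]) + 1L
    j <- as.integer(tab[[2]]) + 1L
    v <- as.numeric(tab[[3]])
    if (any(v < 0)) stop("negative contact counts")
    if (is.null(n_bins)) n_bins <- max(i, j)
    vals <- matrix(0, n_bins, n_bins)
    for (k in seq_along(i)) {
      if (vals[i[k], j[k]] != 0 && abs(vals[i[k], j[k]] - v[k]) > 1e-9)
        stop("conflicting duplicate entries for bin pair ",
             i[k] - 1L, ",", j[k] - 1L)
      vals[i[k], j[k]] <- v[k]
      vals[j[k], i[k]] <- v[k]
    }
  } else {
    vals <- as.matrix(tab)
  }
  contact_matrix(vals, chrom = chrom, resolution_bp = resolution_bp)
}

#' Write a contact matrix as text
#'
#' @param m a [contact_matrix].
#' @param path output file.
#' @param format `"sparse"` (upper triangle, 0-based bins) or `"dense"`.
#' @export
write_contact_matrix <- function(m, path, format = c("sparse", "dense")) {
  format <- match.arg(format)
  if (format == "sparse") {
    idx <- which(upper.tri(m$values, diag = TRUE) & m$values != 0,
                 arr.ind = TRUE)
    df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                     v = m$values[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(m$values, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' ICE-normalize a contact matrix
#'
#' Iterative correction: bin biases are updated from row sums until all
#' unmasked row sums agree to within `tol` (maximum relative deviation from
#' their mean), then the matrix is rescaled so the mean unmasked row sum is 1.
#' Bins whose raw marginal is zero are masked before balancing.
#'
#' @param m a raw [contact_matrix].
#' @param tol convergence tolerance on the row-sum relative deviation.
#' @param max_iter iteration cap; non-convergence returns with a warning and
#'   `converged = FALSE`.
#' @return An ICE-normalized [contact_matrix] with attributes `converged` and
#'   `iterations` stored as fields.
#' @export
ice_normalize <- function(m, tol = 1e-5, max_iter = 200L) {
  if (m$norm_state != "raw") stop("ICE requires a raw matrix")
  v <- m$values
  if (all(v == 0)) stop("all-zero matrix cannot be balanced")
  mask <- m$mask
  # iteratively mask bins with zero marginal (a row can lose all its partners)
  repeat {
    um <- setdiff(seq_len(nrow(v)), mask)
    rs <- rowSums(v[um, um, drop = FALSE])
    zero <- um[rs == 0]
    if (length(zero) == 0) break
    mask <- sort(union(mask, zero))
    if (length(mask) == nrow(v)) stop("all-zero matrix cannot be balanced")
  }
  w <- v[um, um, drop = FALSE]
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    s <- rowSums(w)
    shat <- s / mean(s)
    if (max(abs(shat - 1)) < tol) {
      converged <- TRUE
      break
    }
    w <- w / outer(shat, shat)
    iter <- iter + 1L
  }
  if (!converged) {
    s <- rowSums(w)
    if (max(abs(s / mean(s) - 1)) < tol) converged <- TRUE
    else warning("ICE did not converge in ", max_iter, " iterations")
  }
  w <- w / mean(rowSums(w))
  out <- matrix(0, nrow(v), ncol(v))
  out[um, um] <- w
  res <- contact_matrix(out, chrom = m$chrom, resolution_bp = m$resolution_bp,
                        norm_state = "ICE", mask = mask)
  res$converged <- converged
  res$iterations <- iter
  res
}

#' Distance-normalize a contact matrix (observed over expected)
#'
#' Every entry is divided by the mean contact at its genomic distance
#' (diagonal), computed over unmasked bin pairs. Diagonals with zero mean are
#' left at zero. Applying the operation twice is a no-op.
#'
#' @param m a [contact_matrix].
#' @return A [contact_matrix] with `norm_state = "distance"`.
#' @export
distance_normalize <- function(m) {
  n <- m$n_bins
  v <- m$values
  um <- unmasked_bins(m)
  keep <- rep(FALSE, n)
  keep[um] <- TRUE
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- keep[i] & keep[j]
    if (!any(ok)) next
    vals <- v[cbind(i[ok], j[ok])]
    mu <- mean(vals)
    if (mu == 0) next
    v[cbind(i[ok], j[ok])] <- vals / mu
    if (d > 0) v[cbind(j[ok], i[ok])] <- vals / mu
  }
  res <- contact_matrix(v, chrom = m$chrom, resolution_bp = m$resolution_bp,
                        norm_state = "distance", mask = m$mask)
  res
}

#' Aggregate bin-level contacts into a per-domain contact table
#'
#' For every pair of domains i, j the entry `D` is the sum of contacts between
#' their member bins divided by the product of domain lengths counted in bins
#' (so `D` is a mean per-bin-pair contact). Bins that are unassigned on the
#' domain grid or masked in the matrix are excluded from both sums and
#' lengths; domains left with zero usable bins are dropped with a warning.
#' Intra-domain entries are kept but flagged `intra` and excluded from all
#' segregation ratios.
#'
#' @param m a [contact_matrix] (ICE-normalized for segregation statistics).
#' @param domains an [fp_domains] object.
#' @return data.frame of class `domain_contacts` with one row per unordered
#'   domain pair: `chrom`, `id_i`, `id_j`, `key_i`, `key_j`, `label_i`,
#'   `label_j`, `n_bins_i`, `n_bins_j`, `D`, `intra`.
#' @export
aggregate_domain_contacts <- function(m, domains) {
  rows <- bin_domain_rows(domains, m$resolution_bp, chrom = m$chrom,
                          n_bins = m$n_bins)
  d <- attr(rows, "rows")
  assign <- as.integer(rows)
  assign[m$mask] <- NA_integer_
  members <- split(seq_len(m$n_bins)[!is.na(assign)],
                   assign[!is.na(assign)])
  dom_rows <- as.integer(names(members))
  dropped <- setdiff(seq_len(nrow(d)), dom_rows)
  if (length(dropped) > 0)
    warning("domain(s) with zero unmasked bins excluded: ",
            paste(domain_key(d)[dropped], collapse = ", "))
  nd <- length(dom_rows)
  if (nd == 0) stop("no domain has usable bins on ", m$chrom)
  res <- vector("list", nd * (nd + 1) / 2)
  k <- 0L
  for (a in seq_len(nd)) {
    for (b in a:nd) {
      bi <- members[[a]]
      bj <- members[[b]]
      D <- sum(m$values[bi, bj, drop = FALSE]) /
        (length(bi) * length(bj))
      k <- k + 1L
      res[[k]] <- data.frame(
        chrom = m$chrom,
        id_i = d$id[dom_rows[a]], id_j = d$id[dom_rows[b]],
        label_i = d$label[dom_rows[a]], label_j = d$label[dom_rows[b]],
        n_bins_i = length(bi), n_bins_j = length(bj),
        D = D, intra = a == b, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$key_i <- paste0(out$chrom, ":", out$id_i)
  out$key_j <- paste0(out$chrom, ":", out$id_j)
  class(out) <- c("domain_contacts", "data.frame")
  out
}

#' Write a domain contact table as TSV
#' @param dct a `domain_contacts` table.
#' @param path output file.
#' @export
write_domain_contacts <- function(dct, path) {
  utils::write.table(as.data.frame(dct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a domain contact table from TSV
#' @param path file written by [write_domain_contacts()].
#' @return A `domain_contacts` data.frame.
#' @export
read_domain_contacts <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("domain_contacts", "data.frame")
  out
}
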