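# Synthetic data with the statistical structure the analysis assumes:
# alternating forest/prairie genomes with CGI and SINE tracks, two-type
# block-structured Hi-C matrices with power-law distance decay and a tunable
# same-type affinity, stage series with compartment flips, open-sea
# methylomes with a forest-prairie offset, and expression tables with planted
# sample-specific genes. Every generator is deterministic given (spec, seed).

#' Specification for the synthetic-data generators
#'
#' @param n_domains number of alternating F/P domains (>= 2).
#' @param domain_length_bins two-element range; per-domain lengths in bins are
#'   drawn uniformly from it.
#' @param resolution_bp Hi-C bin width in bp.
#' @param alpha contact decay exponent (> 0): expected contact at bin distance
#'   d scales as `(d + 1)^-alpha`.
#' @param affinity same-type affinity s (>= 0): same-type bin pairs have their
#'   expected contact multiplied by `1 + s`.
#' @param dispersion negative-binomial dispersion of the sampled counts
#'   (variance `mu + dispersion * mu^2`); Hi-C counts are overdispersed
#'   relative to Poisson.
#' @param depth target total contact count (sum over the upper triangle).
#' @param sine_cor correlation rho between SINE density and forest membership.
#' @param stages data.frame (`name`, `s`) of per-stage affinities for the
#'   stage series; `flips` (list column or separate argument of
#'   [generate_stage_series()]) marks domains whose effective type is swapped.
#' @param m_f,m_p open-sea methylation levels of forest and prairie domains.
#' @param beta_concentration concentration of the per-CpG Beta noise around
#'   `m_f`/`m_p` (larger = tighter).
#' @param coverage_lambda Poisson mean of per-CpG sequencing coverage.
#' @param cpg_spacing_bp distance between consecutive synthetic CpGs.
#' @param n_samples,n_genes expression table dimensions.
#' @param specific_frac fraction of genes planted as sample-specific.
#' @param effect_multiplier fold enrichment of a specific gene in its target
#'   sample (and fold depletion elsewhere).
#' @param forest_gene_frac fraction of genes placed in forest domains.
#' @return A list of class `fp_sim_spec`.
#' @export
synthetic_spec <- function(n_domains = 20L,
                           domain_length_bins = c(5L, 15L),
                           resolution_bp = 40000L,
                           alpha = 1.0,
                           affinity = 1.0,
                           dispersion = 0.1,
                           depth = 1e6,
                           sine_cor = 0.8,
                           stages = NULL,
                           m_f = 0.75,
                           m_p = 0.55,
                           beta_concentration = 50,
                           coverage_lambda = 30,
                           cpg_spacing_bp = 500L,
                           n_samples = 8L,
                           n_genes = 400L,
                           specific_frac = 0.1,
                           effect_multiplier = 10,
                           forest_gene_frac = 0.785) {
  stopifnot(n_domains >= 2, length(domain_length_bins) == 2,
            all(domain_length_bins >= 1), resolution_bp > 0, alpha > 0,
            affinity >= 0, dispersion >= 0, depth > 0,
            sine_cor >= 0, sine_cor <= 1,
            m_f >= 0, m_f <= 1, m_p >= 0, m_p <= 1,
            beta_concentration > 0, coverage_lambda > 0, cpg_spacing_bp > 0,
            n_samples >= 2, n_genes >= 1,
            specific_frac >= 0, specific_frac <= 1, effect_multiplier >= 1,
            forest_gene_frac >= 0, forest_gene_frac <= 1)
  spec <- as.list(environment())
  class(spec) <- "fp_sim_spec"
  spec
}

#' Generate a synthetic genome: domains, CGIs, SINE density, chromosome sizes
#'
#' Alternating F/P domains with lengths drawn uniformly from
#' `spec$domain_length_bins`. CGIs (200 bp) are placed every 20 kb in forests
#' and every 500 kb in prairies; per-bin CpG density is the CGI base-pair
#' fraction. SINE density is a bin-level Gaussian mixture correlated with
#' forest membership with correlation `spec$sine_cor` (at `sine_cor = 1` it is
#' a deterministic two-level track).
#'
#' @param spec an [synthetic_spec()] object.
#' @param seed integer seed.
#' @return A list with `domains` ([fp_domains]), `cgi`, `chrom_sizes`, and
#'   `bins` (data.frame `bin`, `start`, `end`, `label`, `cpg_density`,
#'   `sine_density`).
#' @export
generate_genome <- function(spec, seed = 1L) {
  if (spec$n_domains < 2) stop("n_domains must be >= 2")
  withr::with_seed(seed, {
    res <- spec$resolution_bp
    lens <- seq(spec$domain_length_bins[1], spec$domain_length_bins[2])
    len_bins <- lens[sample.int(length(lens), spec$n_domains, replace = TRUE)]
    label <- rep(c("F", "P"), length.out = spec$n_domains)
    end <- cumsum(len_bins) * res
    start <- c(0, end[-length(end)])
    chrom <- "chrS"
    domains <- fp_domains(rep(chrom, spec$n_domains), start, end, label)
    size <- max(end)
    # CGIs: dense in forests (one per 20 kb), sparse in prairies (per 500 kb)
    cgi <- do.call(rbind, lapply(seq_len(nrow(domains)), function(r) {
      spacing <- if (domains$label[r] == "F") 20000 else 500000
      pos <- seq(domains$start[r], domains$end[r] - 200, by = spacing)
      if (length(pos) == 0) return(NULL)
      data.frame(chrom = chrom, start = as.integer(pos),
                 end = as.integer(pos + 200))
    }))
    n_bins <- size / res
    bl <- label_bins(domains, res, chrom = chrom, n_bins = n_bins)
    cpg <- vapply(seq_len(n_bins), function(b) {
      b0 <- (b - 1) * res
      b1 <- b0 + res
      sum(pmax(0, pmin(cgi$end, b1) - pmax(cgi$start, b0))) / res
    }, numeric(1))
    is_f <- as.numeric(bl == "F")
    rho <- spec$sine_cor
    noise <- stats::rnorm(n_bins, 0, 0.5)
    sine <- rho * (is_f - 0.5) + sqrt(max(0, 1 - rho^2)) * noise
    bins <- data.frame(bin = seq_len(n_bins) - 1L,
                       start = (seq_len(n_bins) - 1L) * res,
                       end = seq_len(n_bins) * res,
                       label = bl, cpg_density = cpg, sine_density = sine,
                       stringsAsFactors = FALSE)
    sizes <- stats::setNames(size, chrom)
    list(domains = domains, cgi = cgi, chrom_sizes = sizes, bins = bins)
  })
}

# Expected contact surface for a label vector: c * (d+1)^-alpha * (1 + s*same),
# with c set so the upper-triangle sum equals the target depth.
expected_contacts <- function(bin_labels, spec, s = spec$affinity) {
  n <- length(bin_labels)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(bin_labels, bin_labels, "==")
  same[is.na(same)] <- FALSE
  base <- (d + 1)^(-spec$alpha) * (1 + s * same)
  base * (spec$depth / sum(base[upper.tri(base, diag = TRUE)]))
}

#' Generate a synthetic Hi-C contact matrix
#'
#' Expected contact between bins i and j is
#' `mu_ij = c (|i - j| + 1)^-alpha (1 + s [same_type(i, j)])` with `c` scaled
#' so the expected upper-triangle total equals `spec$depth`. Counts are drawn
#' independently per bin pair as negative binomial with mean `mu_ij` and
#' dispersion `spec$dispersion`, then symmetrized.
#'
#' @param domains an [fp_domains] object (typically from [generate_genome()]).
#' @param spec an [synthetic_spec()] object.
#' @param seed integer seed.
#' @param s same-type affinity; defaults to `spec$affinity`.
#' @param noise `"nb"` for negative-binomial counts, `"none"` for the exact
#'   expected surface (useful as ground truth).
#' @return A raw [contact_matrix] with the per-bin type stored in the
#'   `truth_labels` field.
#' @export
generate_hic <- function(domains, spec, seed = 1L, s = spec$affinity,
                         noise = c("nb", "none")) {
  noise <- match.arg(noise)
  res <- spec$resolution_bp
  chrom <- domains$chrom[1]
  n_bins <- as.integer(max(domains$end[domains$chrom == chrom]) / res)
  bl <- label_bins(domains, res, chrom = chrom, n_bins = n_bins)
  mu <- expected_contacts(bl, spec, s = s)
  if (noise == "none") {
    vals <- mu
  } else {
    vals <- withr::with_seed(seed, {
      ut <- upper.tri(mu, diag = TRUE)
      v <- matrix(0, n_bins, n_bins)
      if (spec$dispersion > 0) {
        v[ut] <- stats::rnbinom(sum(ut), mu = mu[ut],
                                size = 1 / spec$dispersion)
      } else {
        v[ut] <- stats::rpois(sum(ut), lambda = mu[ut])
      }
      v[lower.tri(v)] <- t(v)[lower.tri(v)]
      v
    })
  }
  m <- contact_matrix(vals, chrom = chrom, resolution_bp = res,
                      norm_state = "raw")
  m$truth_labels <- bl
  m
}

#' Generate a stage series of Hi-C matrices with compartment flips
#'
#' One matrix per stage, each with its own same-type affinity. Domains listed
#' in `flips[[stage]]` have their effective type swapped at that stage (a
#' prairie behaving as forest models a compartment-switching prairie), which
#' is recorded in the returned ground truth.
#'
#' @param domains an [fp_domains] object.
#' @param spec an [synthetic_spec()] object; `spec$stages` (data.frame
#'   `name`, `s`) defines the schedule.
#' @param seed integer seed.
#' @param flips named list (stage name -> integer domain ids with swapped
#'   effective type).
#' @param noise passed to [generate_hic()].
#' @return A list with `matrices` (named list of [contact_matrix]) and
#'   `truth` (data.frame `stage`, `key`, `label`, `effective`).
#' @export
generate_stage_series <- function(domains, spec, seed = 1L, flips = list(),
                                  noise = c("nb", "none")) {
  noise <- match.arg(noise)
  stages <- spec$stages
  if (is.null(stages)) stop("spec$stages is required for a stage series")
  res <- spec$resolution_bp
  chrom <- domains$chrom[1]
  n_bins <- as.integer(max(domains$end) / res)
  rows <- bin_domain_rows(domains, res, chrom = chrom, n_bins = n_bins)
  matrices <- list()
  truth <- list()
  for (k in seq_len(nrow(stages))) {
    st <- stages$name[k]
    eff <- domains$label
    fl <- flips[[st]]
    if (!is.null(fl)) {
      swap <- domains$id %in% fl
      eff[swap] <- ifelse(eff[swap] == "F", "P", "F")
    }
    bl <- rep(NA_character_, n_bins)
    ok <- !is.na(rows)
    bl[ok] <- eff[as.integer(rows)[ok]]
    mu <- expected_contacts(bl, spec, s = stages$s[k])
    if (noise == "none") {
      vals <- mu
    } else {
      vals <- withr::with_seed(seed + k, {
        ut <- upper.tri(mu, diag = TRUE)
        v <- matrix(0, n_bins, n_bins)
        v[ut] <- stats::rnbinom(sum(ut), mu = mu[ut],
                                size = 1 / spec$dispersion)
        v[lower.tri(v)] <- t(v)[lower.tri(v)]
        v
      })
    }
    m <- contact_matrix(vals, chrom = chrom, resolution_bp = res,
                        norm_state = "raw")
    m$truth_labels <- bl
    matrices[[st]] <- m
    truth[[st]] <- data.frame(stage = st, key = domain_key(domains),
                              label = domains$label, effective = eff,
                              stringsAsFactors = FALSE)
  }
  list(matrices = matrices, truth = do.call(rbind, truth))
}

#' Generate a synthetic methylome
#'
#' CpGs are placed every `spec$cpg_spacing_bp` along the genome; each CpG's
#' methylation fraction is Beta-distributed around the forest level `m_f` or
#' prairie level `m_p` of its host domain, with coverage drawn from
#' `Poisson(coverage_lambda)`.
#'
#' @param domains an [fp_domains] object.
#' @param spec an [synthetic_spec()] object.
#' @param seed integer seed.
#' @param m_f,m_p methylation levels; default from `spec`.
#' @return data.frame (`chrom`, `pos`, `meth_fraction`, `coverage`).
#' @export
generate_methylome <- function(domains, spec, seed = 1L, m_f = spec$m_f,
                               m_p = spec$m_p) {
  withr::with_seed(seed, {
    chrom <- domains$chrom[1]
    size <- max(domains$end)
    pos <- seq(0L, size - 1L, by = spec$cpg_spacing_bp)
    dom <- findInterval(pos, domains$start)
    level <- ifelse(domains$label[dom] == "F", m_f, m_p)
    kappa <- spec$beta_concentration
    a <- pmax(level * kappa, 1e-6)
    b <- pmax((1 - level) * kappa, 1e-6)
    meth <- stats::rbeta(length(pos), a, b)
    data.frame(chrom = chrom, pos = as.integer(pos), meth_fraction = meth,
               coverage = stats::rpois(length(pos), spec$coverage_lambda),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic expression table with planted specific genes
#'
#' Background genes have FPKM ~ Uniform(0.5, 2) in every sample. A fraction
#' `spec$specific_frac` of genes is planted as sample-specific: their FPKM is
#' multiplied by `effect_multiplier` in one (round-robin) target sample and
#' divided by it elsewhere, emulating tissue-restricted expression. Gene TSSs
#' are placed inside forest domains with probability `forest_gene_frac`.
#'
#' @param spec an [synthetic_spec()] object.
#' @param domains an [fp_domains] object for gene placement.
#' @param seed integer seed.
#' @return A list with `fpkm` (genes x samples matrix), `genes` (data.frame
#'   `gene`, `chrom`, `tss`), and `truth` (data.frame `gene`, `specific`,
#'   `target_sample`, `label`).
#' @export
generate_expression <- function(spec, domains, seed = 1L) {
  withr::with_seed(seed, {
    ns <- spec$n_samples
    ng <- spec$n_genes
    samples <- paste0("S", seq_len(ns))
    gene <- sprintf("g%04d", seq_len(ng))
    fpkm <- matrix(stats::runif(ng * ns, 0.5, 2), ng, ns,
                   dimnames = list(gene, samples))
    n_spec <- round(spec$specific_frac * ng)
    specific <- rep(FALSE, ng)
    target <- rep(NA_character_, ng)
    if (n_spec > 0) {
      idx <- sample(ng, n_spec)
      specific[idx] <- TRUE
      target[idx] <- samples[(seq_len(n_spec) - 1) %% ns + 1]
      for (g in idx) {
        fpkm[g, ] <- fpkm[g, ] / spec$effect_multiplier
        fpkm[g, target[g]] <- fpkm[g, target[g]] * spec$effect_multiplier^2
      }
    }
    # TSS placement: forest with probability forest_gene_frac
    in_f <- stats::runif(ng) < spec$forest_gene_frac
    fdom <- which(domains$label == "F")
    pdom <- which(domains$label == "P")
    if (length(fdom) == 0) in_f[] <- FALSE
    if (length(pdom) == 0) in_f[] <- TRUE
    host <- integer(ng)
    host[in_f] <- sample(fdom, sum(in_f), replace = TRUE)
    host[!in_f] <- sample(pdom, sum(!in_f), replace = TRUE)
    tss <- domains$start[host] +
      floor(stats::runif(ng) * domains$length_bp[host])
    genes <- data.frame(gene = gene, chrom = domains$chrom[host],
                        tss = as.integer(tss), stringsAsFactors = FALSE)
    truth <- data.frame(gene = gene, specific = specific,
                        target_sample = target,
                        label = domains$label[host],
                        domain_key = domain_key(domains)[host],
                        stringsAsFactors = FALSE)
    list(fpkm = fpkm, genes = genes, truth = truth)
  })
}
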