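# Shared fixtures built in code.

# Three domains of 2 bins each (F1, F2, P1) on a 6-bin / 40-kb grid, with
# cross-domain contact sums F1-F2 = 4, F1-P1 = 1, F2-P1 = 1, so that
# D(F1,F2) = 1, D(F1,P1) = D(F2,P1) = 0.25.
fixture_three_domains <- function() {
  domains <- fp_domains(rep("chr1", 3),
                        start = c(0, 80000, 160000),
                        end = c(80000, 160000, 240000),
                        label = c("F", "F", "P"))
  v <- matrix(0, 6, 6)
  v[1, 3] <- v[1, 4] <- v[2, 3] <- v[2, 4] <- 1  # F1-F2 sums to 4
  v[1, 5] <- 1                                   # F1-P1 sums to 1
  v[3, 5] <- 1                                   # F2-P1 sums to 1
  v <- v + t(v)
  m <- contact_matrix(v, chrom = "chr1", resolution_bp = 40000L)
  list(domains = domains, m = m)
}

# A random symmetric strictly positive matrix with a random 40-domain genome
# on 100-300 bins; returns everything the oracles need.
random_genome_matrix <- function(seed, n_domains = 40) {
  withr::with_seed(seed, {
    len <- sample(2:7, n_domains, replace = TRUE)
    end <- cumsum(len) * 40000
    start <- c(0, end[-n_domains])
    label <- rep(c("F", "P"), length.out = n_domains)
    if (runif(1) < 0.5) label <- rev(label)
    domains <- fp_domains(rep("chrT", n_domains), start, end, label)
    n <- sum(len)
    v <- matrix(runif(n * n, 0.05, 1), n, n)
    v <- (v + t(v)) / 2
    m <- contact_matrix(v, chrom = "chrT", resolution_bp = 40000L)
    list(domains = domains, m = m, n = n)
  })
}
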