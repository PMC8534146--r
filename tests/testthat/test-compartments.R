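# Compartment calling, C-index, strict compartments, composition, dynamics,
# transitions, and signal aggregation.

# two-block matrix: within-block w, cross-block x, flagged distance-normalized
two_block <- function(n_half = 15, w = 2, x = 0.5) {
  n <- 2 * n_half
  v <- matrix(x, n, n)
  v[1:n_half, 1:n_half] <- w
  v[(n_half + 1):n, (n_half + 1):n] <- w
  contact_matrix(v, "c", 200000, norm_state = "distance")
}

test_that("PC1 separates a two-block checkerboard and CpG orients the sign", {
  m <- two_block()
  cpg <- c(rep(1, 15), rep(0, 15))  # block 1 is CpG-rich
  tr <- call_compartments(m, cpg)
  expect_true(all(tr$delta[1:15] == 1))
  expect_true(all(tr$delta[16:30] == 0))
  # swapping which block is CpG-rich keeps A on the CpG-rich block
  tr2 <- call_compartments(m, rev(cpg))
  expect_true(all(tr2$delta[1:15] == 0))
  expect_true(all(tr2$delta[16:30] == 1))
})

test_that("a uniform matrix is rejected as degenerate", {
  u <- contact_matrix(matrix(1, 25, 25), "c", 200000,
                      norm_state = "distance")
  expect_error(call_compartments(u, runif(25)), "degenerate")
})

test_that("C-index matches direct arithmetic and the naive oracle", {
  # bin 1 with sum 8 to the 4 A bins and sum 2 to the 2 B bins -> ln 2
  n <- 6
  v <- matrix(0, n, n)
  v[1, 2:5] <- 2
  v[1, 6] <- 2
  v <- v + t(v)
  v[2:6, 2:6] <- 1
  diag(v) <- 0
  m <- contact_matrix(v, "c", 200000, norm_state = "distance")
  tr <- data.frame(chrom = "c", bin = 0:(n - 1), start = (0:(n - 1)) * 2e5,
                   end = (1:n) * 2e5, pc1 = NA_real_,
                   delta = c(0L, 1L, 1L, 1L, 1L, 0L),
                   cindex = NA_real_, strict = NA_character_)
  attr(tr, "resolution_bp") <- 200000L
  tr <- compute_cindex(m, tr)
  expect_equal(tr$cindex[1], log(2))
  expect_equal(tr$cindex, oracle_cindex(v, tr$delta))
  # scaling the matrix leaves the C-index unchanged
  m2 <- contact_matrix(5 * v, "c", 200000, norm_state = "distance")
  tr2 <- compute_cindex(m2, tr)
  expect_equal(tr2$cindex, tr$cindex)
  # equal mean contact to both classes gives exactly zero
  u <- contact_matrix(matrix(1, n, n), "c", 200000, norm_state = "distance")
  tru <- compute_cindex(u, tr)
  expect_equal(tru$cindex[1], 0)
  # a one-compartment track errors
  tr$delta <- rep(1L, n)
  expect_error(compute_cindex(m, tr), "non-empty")
})

test_that("strict compartments drop sign-inconsistent bins and count lengths", {
  tr <- data.frame(chrom = "c", bin = 0:9, start = (0:9) * 2e5,
                   end = (1:10) * 2e5, pc1 = NA_real_,
                   delta = c(rep(1L, 6), rep(0L, 4)),
                   cindex = c(rep(0.5, 6), rep(-0.5, 4)),
                   strict = NA_character_)
  attr(tr, "resolution_bp") <- 200000L
  fp <- c(rep("F", 4), rep("P", 2), "F", rep("P", 3))
  res <- strict_compartments(tr, fp)
  expect_equal(unname(res$lengths_bp),
               c(0.8e6, 0.4e6, 0.2e6, 0.6e6))  # sAf, sAp, sBf, sBp
  # an A bin with negative C-index is dropped from the strict analysis
  tr$cindex[1] <- -0.1
  res2 <- strict_compartments(tr, fp)
  expect_equal(res2$track$strict[1], "none")
  expect_equal(unname(res2$lengths_bp["sAf"]), 0.6e6)
})

test_that("compartment composition fractions sum to one and match counts", {
  tr <- data.frame(chrom = "c", bin = 0:9, start = (0:9) * 2e5,
                   end = (1:10) * 2e5, pc1 = NA_real_,
                   delta = c(rep(1L, 6), rep(0L, 4)),
                   cindex = NA_real_, strict = NA_character_)
  fp <- c(rep("F", 4), rep("P", 2), "F", rep("P", 3))
  comp <- fp_compartment_composition(tr, fp)
  expect_equal(sum(comp), 1)
  expect_equal(unname(comp), c(4, 1, 2, 3) / 10)  # Af, Bf, Ap, Bp
  # all F in A, all P in B
  comp2 <- fp_compartment_composition(tr, c(rep("F", 6), rep("P", 4)))
  expect_equal(unname(comp2), c(0.6, 0, 0, 0.4))
})

make_track <- function(delta, res = 200000L) {
  n <- length(delta)
  tr <- data.frame(chrom = "c", bin = 0:(n - 1), start = (0:(n - 1)) * res,
                   end = (1:n) * res, pc1 = NA_real_,
                   delta = as.integer(delta),
                   cindex = NA_real_, strict = NA_character_)
  attr(tr, "resolution_bp") <- res
  class(tr) <- c("compartment_track", "data.frame")
  tr
}

test_that("prairie dynamics recover planted stable and switchable classes", {
  # 4 domains x 2 bins at 200 kb: F, P, P, P
  dom <- fp_domains(rep("c", 4), (0:3) * 4e5, (1:4) * 4e5,
                    c("F", "P", "P", "P"))
  d_a <- c(1, 1)
  d_b <- c(0, 0)
  tracks <- list(
    s1 = make_track(c(d_a, d_a, d_b, d_b)),
    s2 = make_track(c(d_a, d_a, d_b, d_a)),  # domain 4 switches to A
    s3 = make_track(c(d_a, d_a, d_b, d_b)))
  res <- classify_prairie_dynamics(tracks, dom)
  cls <- setNames(res$classes$class, res$classes$key)
  expect_true(is.na(cls["c:1"]))  # forests are not classified
  expect_equal(unname(cls["c:2"]), "stable_Ap")
  expect_equal(unname(cls["c:3"]), "stable_Bp")
  expect_equal(unname(cls["c:4"]), "switchable_p")
  # the three classes partition prairie domains
  expect_equal(sum(!is.na(cls)), 3)
  # boundary distances are reported for prairie domains
  expect_true(all(res$boundary_distance$key %in% paste0("c:", 2:4)))
  expect_error(classify_prairie_dynamics(
    list(s1 = tracks$s1, s2 = make_track(c(1, 0))), dom), "mismatch")
})

test_that("majority vote with ties to B assigns domain compartments", {
  dom <- fp_domains(rep("c", 2), c(0, 4e5), c(4e5, 8e5), c("P", "P"))
  tr1 <- make_track(c(1, 0, 0, 0))  # domain 1 tied -> B; domain 2 B
  tr2 <- make_track(c(1, 1, 0, 0))  # domain 1 A; domain 2 B
  res <- classify_prairie_dynamics(list(a = tr1, b = tr2), dom)
  expect_equal(res$classes$class, c("switchable_p", "stable_Bp"))
})

test_that("transition composition counts joint states and sums to one", {
  t1 <- make_track(c(1, 1, 1, 0, 0, 0, 1, 0))
  t2 <- make_track(c(1, 0, 1, 1, 0, 0, 0, 0))
  tc <- transition_composition(t1, t2)
  expect_equal(sum(tc), 1)
  expect_equal(unname(tc), c(2, 2, 1, 3) / 8)
  expect_equal(unname(transition_composition(t1, t1)[c("AB", "BA")]), c(0, 0))
  # a full A -> B flip moves all of stage-1 A into AB
  t3 <- make_track(rep(0, 8))
  expect_equal(unname(transition_composition(t1, t3)["AB"]), 0.5)
})

test_that("signal aggregation computes bp-weighted means with coverage", {
  sig <- data.frame(chrom = "c", start = c(0, 50), end = c(50, 100),
                    value = c(1, 3))
  reg <- data.frame(chrom = "c", start = c(0, 0, 200),
                    end = c(100, 50, 300))
  out <- aggregate_signal(sig, reg)
  expect_equal(out$mean_signal, c(2, 1, 0))
  expect_equal(out$coverage, c(1, 1, 0))
  # constant signal gives its value for any covered region
  sig2 <- data.frame(chrom = "c", start = 0, end = 1000, value = 2)
  expect_equal(aggregate_signal(sig2, reg[1:2, ])$mean_signal, c(2, 2))
  # overlapping signal intervals are malformed
  bad <- data.frame(chrom = "c", start = c(0, 25), end = c(50, 75),
                    value = 1:2)
  expect_error(aggregate_signal(bad, reg), "malformed")
})
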