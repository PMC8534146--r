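# ORs, DRs, Rs(d), TC10, threshold calibration, seg/mix calls, Ror,
# segregation extent, and LAD overlap.

test_that("ORs follows the ordered/unordered pair convention", {
  fx <- fixture_three_domains()
  dct <- aggregate_domain_contacts(fx$m, fx$domains)
  # ordered F-F pairs count D(F1,F2) twice: 2.0 / (0.25 + 0.25) = 4
  expect_equal(compute_ors(dct, "F"), 4.0)
  # 2 F + 2 P domains with equal D everywhere: 2 ordered same pairs over 4
  # cross pairs
  dom4 <- fp_domains(rep("c", 4), (0:3) * 80000, (1:4) * 80000,
                     c("F", "F", "P", "P"))
  v <- matrix(1, 8, 8)
  dct4 <- aggregate_domain_contacts(contact_matrix(v, "c", 40000), dom4)
  expect_equal(compute_ors(dct4, "F"), 0.5)
  expect_equal(compute_ors(dct4, "P"), 0.5)
})

test_that("ORs errors when there is no cross-type contact", {
  fx <- fixture_three_domains()
  v <- fx$m$values
  v[1:4, 5:6] <- 0
  v[5:6, 1:4] <- 0
  m <- contact_matrix(v, "chr1", 40000)
  dct <- aggregate_domain_contacts(m, fx$domains)
  expect_error(compute_ors(dct, "F"), "no cross-type contact")
})

test_that("DRs handles defined, zero and undefined denominators", {
  fx <- fixture_three_domains()
  dct <- aggregate_domain_contacts(fx$m, fx$domains)
  drs <- compute_drs(dct)
  expect_equal(drs$drs[drs$id == 1], 4.0)   # 1.0 / 0.25
  expect_equal(drs$drs[drs$id == 3], 0.0)   # sole prairie: numerator 0
  # a domain with no cross-type contact is undefined
  v <- fx$m$values
  v[1:2, 5:6] <- 0
  v[5:6, 1:2] <- 0
  dct2 <- aggregate_domain_contacts(contact_matrix(v, "chr1", 40000),
                                    fx$domains)
  expect_true(is.na(compute_drs(dct2)$drs[1]))
})

test_that("Rs(d) matches hand enumeration on [F, F, P, P]", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 2
  v[2, 3] <- v[3, 2] <- 1
  v[3, 4] <- v[4, 3] <- 2
  m <- contact_matrix(v, "c", 40000)
  bl <- c("F", "F", "P", "P")
  expect_equal(compute_rs_distance(m, bl, "F", offsets = 1)$rs, 4.0)
  expect_equal(compute_rs_distance(m, bl, "P", offsets = 1)$rs, 4.0)
  # one-type genome: denominator zero everywhere -> undefined
  rsf <- compute_rs_distance(m, rep("F", 4), "F")
  expect_true(all(is.na(rsf$rs)))
})

test_that("TC10 selects the top decile with deterministic ties", {
  # diagonal d = 1 of a 11-bin matrix has 10 entries valued 1..10; the top
  # 10% is the single value-10 pair, whose endpoints are F and P
  n <- 11
  v <- matrix(0, n, n)
  for (i in 1:10) v[i, i + 1] <- v[i + 1, i] <- i
  diag(v) <- 1
  bl <- rep("F", n)
  bl[n] <- "P"  # pair (10, 11) holds value 10 and is F-P
  m <- contact_matrix(v, "c", 40000)
  tc <- compute_tc10(m, bl)
  expect_equal(unlist(tc$table[tc$table$d == 1, c("p_ff", "p_fp", "p_pp")]),
               c(p_ff = 0, p_fp = 1, p_pp = 0))
  # an all-zero diagonal gets the (0,0,0) composition
  expect_equal(sum(unlist(tc$table[tc$table$d == 5, c("p_ff", "p_fp", "p_pp")])),
               0)
})

test_that("strictly positive matrices reach the maximal critical distance", {
  set.seed(5)
  n <- 40
  v <- matrix(runif(n * n, 0.1, 1), n, n)
  v <- v + t(v)
  m <- contact_matrix(v, "c", 40000)
  bl <- rep(c("F", "P"), length.out = n)
  tc <- compute_tc10(m, bl)
  expect_equal(tc$critical_distance_bp, (n - 1) * 40000)
  expect_false(tc$interleaved)
})

test_that("threshold calibration is exact on identical replicates and errors
           on insufficient support", {
  drs <- setNames(runif(50, 0.5, 2), paste0("d", 1:50))
  expect_equal(calibrate_threshold(drs, drs), 0)
  expect_error(calibrate_threshold(drs[1:20], drs[1:20]),
               "insufficient replicate support")
})

test_that("calibrated threshold tracks the 1.96-sigma quantile", {
  withr::with_seed(101, {
    r <- rnorm(2000, 0, 0.075)
    T <- calibrate_threshold(setNames(exp(r), paste0("d", 1:2000)),
                             setNames(rep(1, 2000), paste0("d", 1:2000)))
    expect_gt(T, 0.132)
    expect_lt(T, 0.162)
  })
})

test_that("seg/mix calls apply the symmetric threshold and partition domains", {
  e <- setNames(c(2.0, 1.0, 0.0, 1.0), paste0("d", 1:4))
  l <- setNames(c(1.0, 1.0, 1.0, 1.5), paste0("d", 1:4))
  res <- call_seg_mix(e, l, 0.1469)
  calls <- setNames(res$calls$call, res$calls$key)
  expect_equal(unname(calls["d1"]), "mix")      # ln(0.5) < -0.1469
  expect_equal(unname(calls["d2"]), "neutral")  # unchanged
  expect_equal(unname(calls["d3"]), "undefined")  # DRs_early = 0
  expect_equal(unname(calls["d4"]), "seg")      # ln(1.5) > 0.1469
  expect_equal(sum(table(res$calls$call)), 4)
})

test_that("Ror is antisymmetric and matches direct arithmetic", {
  a <- setNames(c(rep(2, 20), rep(1, 10), 5), paste0("d", 1:31))
  b <- setNames(c(rep(1, 20), rep(2, 10), 5), paste0("d", 1:31))
  r <- compute_ror(a, b)
  expect_equal(r$n_ij, 20)
  expect_equal(r$n_ji, 10)
  expect_equal(r$ror, log(2))
  r2 <- compute_ror(b, a)
  expect_equal(r2$ror, -r$ror)
  expect_equal(compute_ror(a, a * 0 + a)$ror |> suppressWarnings(), NaN)
  expect_warning(compute_ror(a, a / 2), "infinite")
})

test_that("segregation extent recovers planted block structure", {
  n <- 8
  cls <- data.frame(bin = 0:(n - 1),
                    cls = rep(c("hChS", "hClS"), each = 4))
  u <- contact_matrix(matrix(1, n, n), "c", 40000)
  expect_equal(unname(segregation_extent(u, cls, "hChS", "hClS")), c(1, 1))
  v <- matrix(1, n, n)
  v[1:4, 1:4] <- 2
  v[5:8, 5:8] <- 2
  m <- contact_matrix(v, "c", 40000)
  expect_equal(unname(segregation_extent(m, cls, "hChS", "hClS")), c(2, 2))
  expect_error(segregation_extent(m, cls, "hChS", "lClS"), "empty")
})

test_that("segregation statistics are invariant under global matrix scaling", {
  fx <- random_genome_matrix(33, n_domains = 12)
  m2 <- contact_matrix(7.3 * fx$m$values, fx$m$chrom, fx$m$resolution_bp)
  dct1 <- aggregate_domain_contacts(fx$m, fx$domains)
  dct2 <- aggregate_domain_contacts(m2, fx$domains)
  expect_equal(compute_ors(dct2, "F"), compute_ors(dct1, "F"))
  expect_equal(compute_drs(dct2)$drs, compute_drs(dct1)$drs)
  bl <- label_bins(fx$domains, 40000, n_bins = fx$n)
  expect_equal(compute_rs_distance(m2, bl, "P", offsets = 1:5)$rs,
               compute_rs_distance(fx$m, bl, "P", offsets = 1:5)$rs)
})

test_that("LAD overlap analysis classifies domains and runs the tests", {
  dom <- fp_domains(rep("c", 8), (0:7) * 1e6, (1:8) * 1e6,
                    rep(c("F", "P"), 4))
  # LADs cover domains 2, 4, 6, 8 fully at the early stage; at the late stage
  # domain 1 (forest, previously iLAD) joins
  lad_e <- data.frame(chrom = "c", start = c(1, 3, 5, 7) * 1e6,
                      end = c(2, 4, 6, 8) * 1e6)
  lad_l <- rbind(lad_e, data.frame(chrom = "c", start = 0, end = 1e6))
  ks <- paste0("c:", 1:8)
  drs_e <- data.frame(key = ks, chrom = "c", id = 1:8,
                      label = dom$label, drs = c(2, 1.5, 2, 1.4, 2, 1.6, 2, 1.5))
  drs_l <- drs_e
  drs_l$drs[1] <- 1.2  # the iLAD->LAD forest becomes more mixed
  calls <- call_seg_mix(drs_e, drs_l, 0.1469)
  rep <- lad_overlap_analysis(dom, lad_e, lad_l, drs_e, drs_l, calls)
  expect_true(all(rep$status$lad_early == c(F, T, F, T, F, T, F, T)))
  expect_equal(rep$status$transition[1], "iLAD->LAD")
  expect_equal(rep$fisher_table["iLAD->LAD", "mix"], 1)
  expect_warning(
    empty <- lad_overlap_analysis(dom, NULL, NULL, drs_e, drs_l, calls),
    "empty report")
  expect_null(empty$status)
})

test_that("Fisher p-value matches exact hypergeometric enumeration", {
  tab <- matrix(c(8, 2, 2, 8), 2, 2, byrow = TRUE)
  p_pkg <- stats::fisher.test(tab)$p.value
  # independent oracle: enumerate all tables with the same margins
  m <- 10; n <- 10; k <- 10
  probs <- dhyper(0:10, m, n, k)
  p_oracle <- sum(probs[probs <= dhyper(8, m, n, k) * (1 + 1e-7)])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-9)
  expect_equal(round(p_pkg, 3), 0.023)
})
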