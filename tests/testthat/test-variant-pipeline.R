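test_that("precision filters partition variants with strict boundaries", {
  fits <- data.frame(
    variant_id = sprintf("v%02d", 1:10),
    dg = c(rep(-10, 7), -7.0, -10, -6.0),       # v08 fails dg, v10 fails all
    dg_err = c(0.2, 0.2, 1.5, rep(0.2, 6), 2.0),  # v03 fails err
    n_clusters = c(6, 6, 6, 3, rep(6, 5), 2))     # v04 fails clusters
  out <- filter_variants(fits)
  expect_equal(nrow(out$kept), 6L)
  expect_equal(nrow(out$kept) + nrow(out$dropped), 10L)
  expect_equal(unname(out$counts["kept"]), 6L)
  expect_false(any(out$kept$variant_id %in% c("v03", "v04", "v08", "v10")))
  # boundary: dg_err exactly 1.0 is dropped (strict <)
  b <- filter_variants(data.frame(variant_id = "b", dg = -10, dg_err = 1.0,
                                  n_clusters = 10))
  expect_equal(nrow(b$kept), 0L)
  # empty input
  e <- filter_variants(fits[0, ])
  expect_equal(nrow(e$kept), 0L)
  expect_equal(unname(e$counts["dropped"]), 0L)
})

test_that("replicate combination applies the error-weighted mean", {
  # equal-sigma limit: arithmetic mean, sigma / sqrt(2)
  eqA <- data.frame(variant_id = c("x", "y"), dg = c(-12, -10), sigma = 0.3)
  eqB <- data.frame(variant_id = c("x", "y"), dg = c(-12, -10), sigma = 0.3)
  eq <- combine_replicates(eqA, eqB)
  expect_equal(eq$combined$dg, c(-12, -10))
  expect_equal(eq$combined$sigma, rep(0.3 / sqrt(2), 2))
  # sigma falls back to dg_err / 2 when absent
  dA <- data.frame(variant_id = "x", dg = -12, dg_err = 0.6)
  dB <- data.frame(variant_id = "x", dg = -12, dg_err = 0.6)
  expect_equal(combine_replicates(dA, dB)$combined$sigma, 0.3 / sqrt(2))
})

test_that("weighted-mean worked example is exact once the offset is removed", {
  # two variants with identical replicate shift so the offset correction
  # leaves the documented (-10.0, 0.2) vs (-10.4, 0.4) pair intact
  a <- data.frame(variant_id = c("ref", "v1"), dg = c(-13.0, -10.0),
                  sigma = c(0.2, 0.2))
  b <- data.frame(variant_id = c("ref", "v1"), dg = c(-13.0, -10.4),
                  sigma = c(0.4, 0.4))
  cr <- combine_replicates(a, b, tight_quantile = 0.4)  # offset from ref only
  expect_equal(cr$offset, 0)
  v1 <- cr$combined[cr$combined$variant_id == "v1", ]
  expect_equal(v1$dg, -10.08)
  expect_equal(v1$sigma, 0.17889, tolerance = 1e-4)
})

test_that("a constructed 0.1 kcal/mol shift is recovered and corrected", {
  set.seed(30)
  a <- data.frame(variant_id = sprintf("v%02d", 1:40),
                  dg = runif(40, -13, -8), sigma = 0.2)
  b <- a
  b$dg <- a$dg - 0.1  # replicate B reads tighter by 0.1
  cr <- combine_replicates(a, b)
  expect_equal(cr$offset, 0.1, tolerance = 1e-9)
  expect_equal(cr$combined$dg[match(a$variant_id, cr$combined$variant_id)],
               a$dg)
  # information never lost; symmetry of the weights
  expect_true(all(cr$combined$sigma <= 0.2))
  # variants present in only one replicate pass through
  a2 <- rbind(a, data.frame(variant_id = "only_a", dg = -9, sigma = 0.5))
  cr2 <- combine_replicates(a2, b)
  expect_true("only_a" %in% cr2$combined$variant_id)
  expect_equal(cr2$combined$n_replicates[cr2$combined$variant_id == "only_a"],
               1L)
  expect_error(combine_replicates(a, data.frame(variant_id = "zz", dg = -9,
                                                sigma = 1)), "share")
})

test_that("relative affinities are taken against the reference median", {
  fits <- data.frame(
    variant_id = c("r1", "r2", "r3", "m1"),
    sequence = c(rep("UGUAUAUAU", 3), "AGUAUAUAU"),
    dg = c(-12.0, -12.2, -12.4, -10.2),
    dg_fold = c(0, 0, 0, 0))
  out <- reference_ddg(fits)
  expect_equal(out$dg_ref, -12.2)
  expect_equal(out$n_ref, 3L)
  expect_equal(out$fits$ddg_obs[4], 2.0)
  expect_equal(out$fits$ddg_obs[2], 0)
  # even occurrence count: midpoint median
  out2 <- reference_ddg(fits[c(1, 2, 4), ])
  expect_equal(out2$dg_ref, -12.1)
  # the stricter reference structure cutoff excludes folded occurrences
  fits$dg_fold <- c(-0.3, 0, 0, 0)
  expect_equal(reference_ddg(fits)$n_ref, 2L)
  fits$dg_fold <- c(-0.3, -0.25, -0.21, 0)
  expect_error(reference_ddg(fits), "no qualifying")
})

test_that("structure filter drops variants below the fold cutoff", {
  oracle <- mock_fold_oracle(c(UUAAGGCC = -0.6, GGGGCCCC = -0.5))
  a <- assess_structure("UUAAGGCC", oracle = oracle)
  expect_equal(a$dg_fold, -0.6)
  expect_false(a$keep)                      # below -0.5, dropped
  b <- assess_structure("GGGGCCCC", oracle = oracle)
  expect_true(b$keep)                       # exactly -0.5 kept (strict <)
  c0 <- assess_structure("UUUUUUUU", oracle = oracle)
  expect_equal(c0$dg_fold, 0)               # unstructured
  expect_true(c0$keep)
})

test_that("the RNAfold oracle reports a destabilizing constraint", {
  oracle <- vienna_fold_oracle()
  hairpin <- "GGGGGAAAACCCCC"
  a <- assess_structure(hairpin, var_region = 1:14, oracle = oracle)
  expect_lt(a$dg_fold, -0.5)  # strong stem, forced open
  expect_false(a$keep)
  open_seq <- assess_structure("AAAACAAACAAAAC", var_region = 1:14,
                               oracle = oracle)
  expect_gt(open_seq$dg_fold, -0.1)
  expect_true(open_seq$keep)
})
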