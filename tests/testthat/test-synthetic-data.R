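m <- puf4_model()

test_that("library design enumerates the documented classes deterministically", {
  lib <- design_library(seed = 1)
  # 9 positions x 3 non-consensus bases x 4 scaffolds, in each frame
  expect_equal(sum(lib$class == "single_mutant"), 108L)
  expect_equal(sum(lib$class == "single_mutant_linear"), 108L)
  expect_equal(sum(lib$class == "consensus"), 4L)
  expect_equal(sum(lib$class == "flip_consensus"), 4L)
  expect_setequal(unique(lib$scaffold), c("S1a", "S1b", "S2a", "S2b"))
  expect_false(any(duplicated(paste(lib$scaffold, lib$varreg))))
  # every single-base insertion at every junction is represented (some
  # insertion strings coincide across junctions and are deduplicated)
  cons <- "UGUAUAUAU"
  s1a <- lib$varreg[lib$scaffold == "S1a"]
  for (j in 1:8) for (b in c("A", "C", "G", "U")) {
    v <- paste0(substr(cons, 1, j), b, substr(cons, j + 1, 9))
    expect_true(v %in% s1a)
  }
  # determinism and seed sensitivity
  expect_identical(design_library(seed = 1), lib)
  lib2 <- design_library(seed = 2)
  expect_false(identical(lib2$varreg, lib$varreg))
  # seed only affects the sampled classes
  expect_identical(lib2$varreg[lib2$class == "single_mutant"],
                   lib$varreg[lib$class == "single_mutant"])
})

test_that("ground truth is referenced to the in-scaffold consensus", {
  lib <- design_library(n_multi = c("2" = 10, "3" = 0, "4" = 0),
                        n_insert_pairs = 1, n_insert_long = 1, n_flank = 2,
                        seed = 4)
  truth <- simulate_true_affinities(lib, m)
  expect_true(all(truth$ddg_true[truth$class == "consensus"] == 0))
  # the flipped consensus lands near its dominant flip term
  fc <- truth$ddg_true[truth$class == "flip_consensus"]
  expect_true(all(abs(fc - (-1.34)) < 0.05))
  expect_equal(truth$dg_true, -12.35 + truth$ddg_true)
  expect_equal(truth$kd_true_nM, dg_to_kd(truth$dg_true) * 1e9)
  # deep mutants above the detection limit are flagged unmeasurable
  expect_true(all((truth$dg_true < -7.69) == truth$measurable))
  expect_true(any(!truth$measurable))
})

test_that("cluster simulation follows the isotherm exactly at zero noise", {
  gl <- sim_globals(fmax_shape = 1e6, fmax_scale = 1e-6)  # f_max ~ 1 exactly
  truth <- data.frame(variant_id = c("a", "b"), kd_true_nM = c(1, 50))
  conc <- default_concentrations()
  cd <- simulate_cluster_data(truth, gl, conc, n_clusters_min = 5,
                              n_clusters_lambda = 3, sigma_f = 0, seed = 2)
  # every cluster lies on the exact curve
  for (v in truth$variant_id) {
    sub <- cd[cd$variant_id == v, ]
    expect_gte(length(unique(sub$cluster_id)), 5L)  # floor respected
    f_expect <- binding_signal(sub$concentration_nM, gl$f_min, 1,
                               truth$kd_true_nM[truth$variant_id == v],
                               gl$kd_ns_nM)
    expect_equal(sub$normalized_fluorescence, f_expect, tolerance = 1e-3)
  }
  # reproducibility under seed
  expect_identical(cd, simulate_cluster_data(truth, gl, conc, 5, 3, 0, 2))
})

test_that("replicate pairs carry the constructed systematic offset", {
  gl <- sim_globals()
  truth <- data.frame(variant_id = sprintf("v%02d", 1:12),
                      dg_true = seq(-12.5, -9, length.out = 12))
  truth$kd_true_nM <- dg_to_kd(truth$dg_true) * 1e9
  pair <- simulate_replicate_pair(truth, gl, sigma_f = 0.02, offset = 0.1,
                                  n_clusters_min = 8, n_clusters_lambda = 0,
                                  seeds = c(11, 12))
  fits <- lapply(pair, function(tbl) {
    gl_fit <- estimate_global_params(fit_clusters(tbl))
    refit_all_variants(tbl, gl_fit, n_boot = 30, seed = 1)
  })
  fits <- lapply(fits, function(f) { f$sigma <- pmax(f$dg_err / 2, 0.01); f })
  cr <- combine_replicates(fits[[1]], fits[[2]], tight_quantile = 0.25)
  expect_lt(abs(cr$offset - 0.1), 0.06)
  # zero offset: replicates differ only by noise
  pair0 <- simulate_replicate_pair(truth[1:6, ], gl, sigma_f = 0.02,
                                   offset = 0, n_clusters_min = 8,
                                   n_clusters_lambda = 0, seeds = c(3, 4))
  d <- merge(aggregate(normalized_fluorescence ~ variant_id, pair0$repA, mean),
             aggregate(normalized_fluorescence ~ variant_id, pair0$repB, mean),
             by = "variant_id")
  # per-variant means differ only through f_max draws and noise
  expect_lt(mean(abs(d[[2]] - d[[3]])), 0.05)
})

test_that("the pipeline round-trips a consensus variant within its CI", {
  gl <- sim_globals()
  truth <- data.frame(variant_id = "cons", kd_true_nM = 0.88)
  cd <- simulate_cluster_data(truth, gl, n_clusters_min = 15,
                              n_clusters_lambda = 0, sigma_f = 0.05, seed = 6)
  rv <- refit_variant(cd, gl, n_boot = 50, seed = 7)
  true_dg <- kd_to_dg(0.88e-9)
  expect_true(rv$dg_lower <= true_dg && true_dg <= rv$dg_upper)
})
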