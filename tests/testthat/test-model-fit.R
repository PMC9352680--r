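m <- puf4_model()

test_that("goodness-of-fit report computes RMSE, R2 and z-scores", {
  obs <- c(-1, 0, 1, 2)
  r <- evaluate_fit(obs, obs, rep(0.2, 4))
  expect_equal(r$rmse, 0)
  expect_equal(r$r_squared, 1)
  expect_equal(r$n_outliers, 0L)
  # z exactly 3 is not an outlier (strict >), display cap applies to z only
  r2 <- evaluate_fit(-2.0, -1.25, 0.25)
  expect_equal(r2$z, 3)
  expect_equal(r2$n_outliers, 0L)
  r3 <- evaluate_fit(-2.01, -1.4, 0.2)
  expect_equal(r3$n_outliers, 1L)
  expect_equal(r3$z_display, 3)
  expect_gt(r3$z, 3)
  # seeded noise around the line recovers the noise RMSE
  set.seed(5)
  pred <- runif(100, -2, 4)
  obs_n <- pred + rnorm(100, 0, 0.3)
  r4 <- evaluate_fit(pred, obs_n, rep(0.3, 100))
  expect_equal(r4$rmse, 0.3, tolerance = 0.1)
  # permutation invariance
  idx <- sample(100)
  expect_equal(evaluate_fit(pred[idx], obs_n[idx], rep(0.3, 100))$rmse,
               r4$rmse)
  # non-finite predictions excluded with a count
  r5 <- evaluate_fit(c(pred, Inf), c(obs_n, 1), rep(0.3, 101))
  expect_equal(r5$n_excluded, 1L)
  expect_equal(r5$rmse, r4$rmse)
  expect_error(evaluate_fit(numeric(0), numeric(0), numeric(0)), "empty")
})

lib_small <- design_library(n_multi = c("2" = 0, "3" = 0, "4" = 0),
                            n_insert_pairs = 2, n_insert_long = 2,
                            n_flank = 4, seed = 3)
truth_small <- simulate_true_affinities(lib_small, m)

test_that("single-mutant table reproduces the generator's bound terms", {
  set.seed(8)
  d <- truth_small
  d$ddg_obs <- d$ddg_true + rnorm(nrow(d), 0, 0.1)
  d <- d[d$measurable, ]
  smt <- single_mutant_table(d)
  # consensus rows are zero by construction
  expect_true(all(smt$ddg[mapply(function(p, b)
    substr(m$consensus, p, p) == b, smt$position, smt$base)] == 0))
  # non-consensus rows track the generating bound terms; position 7 is
  # frame-ambiguous in the flipped consensus (which is why fitting excludes
  # it from initialization) and is exempt here
  for (i in which(smt$n > 0 & smt$position != 7)) {
    truth_term <- m$bound[smt$position[i], smt$base[i]]
    expect_lt(abs(smt$ddg[i] - truth_term), 0.5)
  }
  # a mutation present in one scaffold still yields a value with n = 1
  d1 <- d[d$class != "single_mutant" | d$scaffold == "S1a", ]
  smt1 <- single_mutant_table(d1)
  expect_true(all(smt1$n[!is.na(smt1$n) & smt1$n > 0] == 1L))
  # absent mutations are marked unavailable
  d2 <- d[!(d$class == "single_mutant" & d$mut_position == 3), ]
  smt2 <- single_mutant_table(d2)
  expect_false(any(smt2$available[smt2$position == 3 & smt2$base == "A"]))
})

test_that("flip refit improves SSE and leaves a self-consistent model alone", {
  d <- truth_small[truth_small$measurable, ]
  # data generated exactly from the model: flips stay near their init
  # obs carry the small in-scaffold consensus reference shift, which no
  # parameter can absorb; the residual floor reflects it
  ff <- fit_flip_terms(d$ddg_true, d$sequence_scored, m, n_start = 1)
  expect_lte(ff$sse, ff$sse_init + 1e-9)
  expect_lt(ff$sse / nrow(d), 1e-3)
  th <- pufbind:::theta_from_model(ff$model)
  expect_equal(unname(th["f6/7.U"]), -1.34, tolerance = 0.02)
  # wrong-flip base model: refit recovers the favorable 6/7 flips
  base <- puf_model(m$bound, matrix(1.5, 4, 5), name = "unfavorable-flips")
  set.seed(14)
  obs <- d$ddg_true + rnorm(nrow(d), 0, 0.3)
  ff2 <- fit_flip_terms(obs, d$sequence_scored, base, n_start = 1)
  th2 <- pufbind:::theta_from_model(ff2$model)
  expect_lt(ff2$sse, ff2$sse_init)
  expect_true(all(th2[c("f6/7.A", "f6/7.C", "f6/7.U", "f6/7.G")] < 0))
  expect_equal(unname(th2["f6/7.U"]), -1.34, tolerance = 0.2)
})

test_that("full-model fit recovers a zero-noise dataset near-exactly", {
  lib <- design_library(n_multi = c("2" = 120, "3" = 0, "4" = 0),
                        n_insert_pairs = 2, n_insert_long = 2, n_flank = 4,
                        seed = 6)
  truth <- simulate_true_affinities(lib, m)
  d <- truth[truth$measurable, ]
  # exact ensemble observations (no reference shift): the model family can
  # represent them exactly, so recovery is near-exact
  d$ddg_obs <- predict_dataset(m, d$sequence_scored)
  smt <- single_mutant_table(d)
  fit <- fit_full_model(d$ddg_obs, d$sequence_scored, init_table = smt,
                        seed = 2, n_start = 1)
  expect_lt(fit$report_all$rmse, 1e-3)
  th <- pufbind:::theta_from_model(fit$model)
  tt <- pufbind:::theta_from_model(m)
  # the well-exercised 6/7 flip row is recovered essentially exactly;
  # censored terms elsewhere are barely exercised and only loosely pinned
  f67 <- paste0("f6/7.", c("A", "C", "G", "U", "NN"))
  expect_lt(max(abs(th[f67] - tt[f67])), 0.05)
  expect_lt(max(abs(th[37:56] - tt[37:56])), 0.3)
  # terms never leave their declared windows
  for (i in seq_len(nrow(smt))) {
    p <- smt$position[i]; b <- smt$base[i]
    if (substr(m$consensus, p, p) == b || p == 7) next
    idx <- paste0("b", p, ".", b)
    win <- max(0.75, ifelse(is.finite(smt$ci_halfwidth[i]),
                            smt$ci_halfwidth[i], 0))
    expect_gte(th[idx], smt$ddg[i] - win - 1e-8)
    expect_lte(th[idx], smt$ddg[i] + win + 1e-8)
  }
  # train and test halves agree on well-specified data
  expect_lt(abs(fit$report_train$rmse - fit$report_test$rmse), 0.05)
})

test_that("sensitivity scan finds the optimum and applies the plateau rule", {
  d <- truth_small[truth_small$measurable, ]
  set.seed(31)
  obs <- d$ddg_true + rnorm(nrow(d), 0, 0.1)
  grid <- seq(-2.5, 0.5, by = 0.1)
  sc <- sensitivity_scan(m, obs, d$sequence_scored, "f6/7.U", grid)
  expect_true(sc$distinct_minimum)
  expect_lt(abs(sc$best_value - (-1.34)), 0.1 + 1e-9)  # within one grid step
  # grid excluding the optimum: argmin lands on the nearest boundary
  sc2 <- sensitivity_scan(m, obs, d$sequence_scored, "f6/7.U",
                          seq(0, 2, by = 0.5))
  expect_equal(sc2$best_value, 0)
  # a large deleterious term is asymmetric: the RMSE rises less above the
  # optimum (ensemble alternatives cap the penalty) than below it
  sc3 <- sensitivity_scan(m, obs, d$sequence_scored, "b2.C",
                          seq(2.4, 6.4, by = 0.25))
  rise_up <- sc3$rmse[length(sc3$rmse)] - min(sc3$rmse)
  rise_down <- sc3$rmse[1] - min(sc3$rmse)
  expect_lt(rise_up, rise_down)
  # a term never exercised by the data gives a flat curve; the plateau rule
  # reports the onset grid point
  cons_only <- d[d$class == "consensus", ]
  sc4 <- sensitivity_scan(m, cons_only$ddg_true, cons_only$sequence_scored,
                          "b2.C", seq(3, 6, by = 0.5))
  expect_false(sc4$distinct_minimum)
  expect_equal(sc4$plateau_value, 3)
  expect_error(sensitivity_scan(m, obs, d$sequence_scored, "b0.X", grid),
               "unknown term")
})
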