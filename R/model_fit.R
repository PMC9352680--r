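# Fitting the additive non-consecutive model ----------------------------------
#
# Every configuration's energy is a 0/1 combination of the 56 parameters
# (36 bound + 20 flip terms), so a dataset's configurations form a sparse
# design matrix A with ddG_config = A theta. The ensemble prediction is the
# softmin -RT log sum exp(-A theta / RT) grouped by variant, which gives an
# analytic gradient for bounded quasi-Newton fitting.

param_names <- function() {
  c(paste0("b", rep(1:9, each = 4), ".", rep(.BASES, 9)),
    paste0("f", rep(.JUNCTIONS, each = 5), ".", rep(.PAYLOADS, 4)))
}

# 56-vector of parameter values in canonical order.
theta_from_model <- function(model) {
  th <- c(as.vector(t(model$bound)), as.vector(t(model$flips)))
  names(th) <- param_names()
  th
}

# Rebuild a model from a 56-vector, keeping the base model's limit flags.
model_from_theta <- function(theta, base_model, name = NULL) {
  bound <- matrix(theta[1:36], 9, 4, byrow = TRUE,
                  dimnames = list(as.character(1:9), .BASES))
  flips <- matrix(theta[37:56], 4, 5, byrow = TRUE,
                  dimnames = list(.JUNCTIONS, .PAYLOADS))
  # fitted models hold the consensus at 0 but may place another base
  # marginally below it, so the strict normalization check is waived
  puf_model(bound, flips, base_model$flip_limits,
            coupling = base_model$coupling,
            name = if (is.null(name)) base_model$name else name,
            enforce_normalization = FALSE)
}

#' Build the sparse configuration design for a set of sequences
#'
#' Enumerates every register and flip mode for each sequence (unextended
#' 9-position models) and encodes each configuration as a 0/1 row over the
#' 56 canonical parameters. Configurations through ambiguous bases are
#' dropped; sequences too short or fully ambiguous yield no rows and are
#' reported in `unbindable`.
#'
#' @param sequences character vector of RNA sequences.
#' @param policy a [mode_policy()].
#' @return List of class `config_design`: sparse `A` (configs x 56),
#'   `variant` (config-to-sequence index), `n_variants`, `unbindable`
#'   (indices with no configuration).
#' @export
build_design <- function(sequences, policy = mode_policy()) {
  tpls <- mode_templates(policy, extended = FALSE)
  # per-template slot offsets and parameter geometry
  geom <- lapply(tpls, function(tpl) {
    s <- tpl$slots
    bnd <- which(s$kind == "bound")
    flp <- which(s$kind == "flip")
    jidx <- match(s$junction[flp], .JUNCTIONS)
    list(fp = tpl$footprint, b_off = bnd, b_pos = as.integer(s$pos[bnd]),
         f_off = flp, f_j = jidx, nn = tpl$mode == "double_flip_NN")
  })
  ii <- list(); jj <- list(); vv <- list()
  cfg_total <- 0L
  for (v in seq_along(sequences)) {
    codes <- encode_rna(sequences[v])
    n <- length(codes)
    for (g in geom) {
      if (n < g$fp) next
      regs <- 0:(n - g$fp)
      # configs x slots residue codes
      bmat <- matrix(codes[outer(regs, g$b_off, "+")], nrow = length(regs))
      fmat <- if (length(g$f_off)) {
        matrix(codes[outer(regs, g$f_off, "+")], nrow = length(regs))
      } else matrix(integer(0), nrow = length(regs), ncol = 0)
      keep <- !apply(cbind(is.na(bmat), is.na(fmat)), 1, any)
      if (!any(keep)) next
      bmat <- bmat[keep, , drop = FALSE]; fmat <- fmat[keep, , drop = FALSE]
      ncfg <- nrow(bmat)
      cfg_id <- cfg_total + seq_len(ncfg)
      # bound params: (pos-1)*4 + base
      bj <- sweep(bmat, 2, (g$b_pos - 1L) * 4L, "+")
      ii[[length(ii) + 1L]] <- rep(cfg_id, times = ncol(bj))
      jj[[length(jj) + 1L]] <- as.vector(bj)
      if (length(g$f_off)) {
        if (g$nn) {
          # one NN term per junction regardless of the two flipped bases
          jun <- unique(g$f_j)
          fj <- matrix(rep(36L + (jun - 1L) * 5L + 5L, each = ncfg),
                       nrow = ncfg)
        } else {
          fj <- sweep(fmat, 2, 36L + (g$f_j - 1L) * 5L, "+")
        }
        ii[[length(ii) + 1L]] <- rep(cfg_id, times = ncol(fj))
        jj[[length(jj) + 1L]] <- as.vector(fj)
      }
      vv[[length(vv) + 1L]] <- rep(v, ncfg)
      cfg_total <- cfg_total + ncfg
    }
  }
  variant <- unlist(vv, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(cfg_total, 56L),
                            dimnames = list(NULL, param_names()))
  structure(list(A = A, variant = if (is.null(variant)) integer(0) else variant,
                 n_variants = length(sequences),
                 unbindable = setdiff(seq_along(sequences), unique(variant))),
            class = "config_design")
}

# Ensemble predictions (and optionally the SSE gradient) from a design.
# Configuration energies are bounded well away from exp() overflow for any
# physically sensible parameter set, so the Boltzmann sum needs no shift.
predict_design <- function(design, theta, RT = energy_convention()$RT,
                           obs = NULL) {
  s <- as.numeric(design$A %*% theta)
  v <- design$variant
  pred <- rep(Inf, design$n_variants)
  w <- Zv <- NULL
  if (length(s)) {
    w <- exp(-s / RT)
    Z <- rowsum(w, v)
    vids <- as.integer(rownames(Z))
    pred[vids] <- -RT * log(as.numeric(Z))
    Zv <- as.numeric(Z)[match(v, vids)]
  }
  if (is.null(obs)) return(pred)
  # SSE over variants with finite prediction and observation
  use <- is.finite(pred) & is.finite(obs)
  resid <- ifelse(use, pred - obs, 0)
  sse <- sum(resid^2)
  coef_cfg <- (w / Zv) * (2 * resid[v])
  grad <- as.numeric(Matrix::crossprod(design$A, coef_cfg))
  list(pred = pred, sse = sse, grad = grad)
}

#' Predict ensemble affinities for a variant table
#'
#' Deterministic ensemble relative free energy per variant sequence. For
#' hairpin-stem scaffolds supply the loop-region sequence (column
#' `sequence_scored` when present, else `sequence`). Unbindable variants
#' (no valid configuration) receive `Inf`.
#'
#' @param model a [puf_model()] (unextended, no coupling; use
#'   [ensemble_ddg()] directly otherwise).
#' @param variants data.frame with a `sequence` (or `sequence_scored`)
#'   column, or a character vector of sequences.
#' @param policy a [mode_policy()].
#' @return Numeric vector of predicted relative free energies (kcal/mol).
#' @export
predict_dataset <- function(model, variants, policy = mode_policy()) {
  seqs <- if (is.character(variants)) variants
          else if ("sequence_scored" %in% names(variants)) variants$sequence_scored
          else variants$sequence
  if (!is.null(model$extension) || !is.null(model$coupling)) {
    return(vapply(seqs, function(s) ensemble_ddg(s, model, policy),
                  numeric(1), USE.NAMES = FALSE))
  }
  design <- build_design(seqs, policy)
  theta <- theta_from_model(model)
  if (policy$censored_limit_handling == "infinite") {
    lim <- c(rep(FALSE, 36), as.vector(t(model$flip_limits)))
    theta[lim] <- Inf
  }
  predict_design(design, theta)
}

#' Goodness-of-fit report against x = y
#'
#' RMSE of predicted versus observed relative affinities, R-squared from an
#' ordinary least-squares regression of observed on predicted, per-variant
#' z-scores |pred - obs| / sigma_obs (capped at 3 in `z_display` for
#' plotting only), and the number of outliers with uncapped z > 3 (strict).
#' Variants with non-finite predictions are excluded and counted.
#'
#' @param pred,obs numeric vectors of predicted and observed ddG (kcal/mol).
#' @param sigma_obs per-variant observed uncertainties (> 0).
#' @return List of class `fit_report`: `rmse`, `r_squared`, `z`,
#'   `z_display`, `n_outliers`, `n_variants`, `n_excluded`.
#' @export
evaluate_fit <- function(pred, obs, sigma_obs) {
  stopifnot(length(pred) == length(obs), length(obs) == length(sigma_obs))
  if (!length(pred)) stop("empty input")
  use <- is.finite(pred) & is.finite(obs)
  n_exc <- sum(!use)
  pred <- pred[use]; obs <- obs[use]; sigma_obs <- sigma_obs[use]
  if (!length(pred)) stop("no finite predictions to evaluate")
  rmse <- sqrt(mean((pred - obs)^2))
  r2 <- if (length(pred) > 1 && stats::var(pred) > 0) {
    # a perfect fit triggers a harmless precision warning from summary.lm
    suppressWarnings(summary(stats::lm(obs ~ pred))$r.squared)
  } else NA_real_
  z <- abs(pred - obs) / sigma_obs
  structure(list(rmse = rmse, r_squared = r2, z = z,
                 z_display = pmin(z, 3), n_outliers = sum(z > 3),
                 n_variants = length(pred), n_excluded = n_exc),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: RMSE %.3f kcal/mol, R^2 %.3f, %d/%d outliers (z > 3)\n",
              x$rmse, x$r_squared, x$n_outliers, x$n_variants))
  invisible(x)
}

#' Single-mutant penalty table
#'
#' Aggregates observed single-mutant penalties across scaffolds: per
#' (position, base) the median with its dispersion. Single-mutant probes
#' live in the flipped frame (mutants of the flipped 10-mer consensus, in
#' which the favorable 6/7 flip is part of the designed register), so each
#' probe's penalty is its `ddg_obs` minus the same scaffold's
#' flipped-consensus `ddg_obs` — this isolates the bound term from the
#' flip energetics. When no `flip_consensus` rows are present, raw
#' `ddg_obs` is used. Mutations absent from the dataset are marked
#' unavailable (`n = 0`).
#'
#' @param fits variant-fit data.frame with `ddg_obs` and library metadata
#'   columns `class` (rows with `"single_mutant"`, and per-scaffold
#'   `"flip_consensus"` references when available), `scaffold`,
#'   `mut_position`, `mut_base`.
#' @param consensus consensus sequence (rows for consensus bases are 0 by
#'   construction).
#' @return data.frame: `position`, `base`, `ddg`, `n`, `sd`,
#'   `ci_halfwidth` (normal-approximation 95% half-width; `NA` if n < 2),
#'   `available`.
#' @export
single_mutant_table <- function(fits, consensus = "UGUAUAUAU") {
  cons <- strsplit(consensus, "")[[1]]
  sm <- fits[fits$class == "single_mutant", , drop = FALSE]
  fc <- fits[fits$class == "flip_consensus", , drop = FALSE]
  ref <- if (nrow(fc) && "scaffold" %in% names(fc)) {
    stats::setNames(fc$ddg_obs, fc$scaffold)
  } else NULL
  penalty <- sm$ddg_obs
  if (!is.null(ref) && "scaffold" %in% names(sm)) {
    penalty <- sm$ddg_obs - as.numeric(ref[sm$scaffold])
  }
  out <- expand.grid(position = 1:9, base = .BASES, stringsAsFactors = FALSE)
  out <- out[order(out$position, match(out$base, .BASES)), ]
  res <- lapply(seq_len(nrow(out)), function(i) {
    p <- out$position[i]; b <- out$base[i]
    if (cons[p] == b) {
      return(data.frame(position = p, base = b, ddg = 0, n = NA_integer_,
                        sd = 0, ci_halfwidth = 0, available = TRUE))
    }
    hits <- penalty[sm$mut_position == p & sm$mut_base == b]
    hits <- hits[is.finite(hits)]
    n <- length(hits)
    data.frame(position = p, base = b,
               ddg = if (n) stats::median(hits) else NA_real_,
               n = n, sd = if (n > 1) stats::sd(hits) else NA_real_,
               ci_halfwidth = if (n > 1) 1.96 * stats::sd(hits) / sqrt(n)
                              else NA_real_,
               available = n > 0)
  })
  do.call(rbind, res)
}

# Bounded L-BFGS-B minimization of the ensemble SSE over a free subset of
# the 56 parameters, with jittered multi-starts.
fit_terms <- function(design, obs, theta0, free, lower, upper,
                      RT = energy_convention()$RT, n_start = 3L, seed = 1L) {
  fn <- function(p) {
    th <- theta0; th[free] <- p
    predict_design(design, th, RT, obs)$sse
  }
  gr <- function(p) {
    th <- theta0; th[free] <- p
    predict_design(design, th, RT, obs)$grad[free]
  }
  inits <- list(theta0[free])
  if (n_start > 1L) {
    jit <- with_seed(seed, lapply(seq_len(n_start - 1L), function(i) {
      p <- theta0[free] + stats::rnorm(sum(free), 0, 0.1)
      pmin(pmax(p, lower[free]), upper[free])
    }))
    inits <- c(inits, jit)
  }
  best <- NULL
  for (p0 in inits) {
    fit <- tryCatch(
      stats::optim(p0, fn, gr, method = "L-BFGS-B",
                   lower = lower[free], upper = upper[free],
                   control = list(maxit = 3000, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- theta0; theta[free] <- best$par
  # optimizer contract: never worse than the initialization
  if (best$value > fn(theta0[free]) + 1e-9) theta <- theta0
  list(theta = theta, sse = min(best$value, fn(theta0[free])),
       sse_init = fn(theta0[free]))
}

#' Fit flip terms with bound terms fixed
#'
#' Optimizes the 20 flip parameters by bounded quasi-Newton minimization of
#' the sum of squared ensemble-prediction errors, with the 36 bound terms
#' held at the base model's values. Flips are initialized at the base
#' model's flip values and constrained to [-4, 4] kcal/mol. The final SSE
#' never exceeds the initialization's.
#'
#' @param obs_ddg observed relative affinities (kcal/mol), one per sequence.
#' @param sequences RNA sequences (scored region).
#' @param base_model a [puf_model()] supplying bound terms and flip
#'   initialization.
#' @param flip_bound symmetric flip bound in kcal/mol (default 4).
#' @param seed seed for jittered multi-starts.
#' @param n_start optimizer starts (1 = the base-model initialization).
#' @return List: `model` (fitted), `sse`, `sse_init`.
#' @export
fit_flip_terms <- function(obs_ddg, sequences, base_model, flip_bound = 4,
                           seed = 1L, n_start = 3L) {
  stopifnot(length(obs_ddg) == length(sequences))
  design <- build_design(sequences)
  theta0 <- theta_from_model(base_model)
  free <- c(rep(FALSE, 36), rep(TRUE, 20))
  lower <- rep(-Inf, 56); upper <- rep(Inf, 56)
  lower[37:56] <- -flip_bound; upper[37:56] <- flip_bound
  theta0[37:56] <- pmin(pmax(theta0[37:56], -flip_bound), flip_bound)
  res <- fit_terms(design, obs_ddg, theta0, free, lower, upper, seed = seed,
                   n_start = n_start)
  list(model = model_from_theta(res$theta, base_model,
                                paste0(base_model$name, "_flipfit")),
       sse = res$sse, sse_init = res$sse_init)
}

#' Fit all model terms from observed affinities
#'
#' Full optimization of the 53 free parameters (consensus bases are held at
#' 0). Bound terms are initialized at their single-mutant penalties
#' (position 7 initializes at 0) and restricted to the larger of their 95%
#' CI half-width or +/-`bound_window` kcal/mol around the initialization;
#' mutations unavailable in the data initialize at 0 with the wider
#' +/-`wide_window` bound. Flip terms initialize at 0 with +/-`flip_bound`.
#' Variants are split 50/50 into seeded random training and testing halves;
#' the model is fit on the training half and evaluated on both.
#'
#' @param obs_ddg observed relative affinities (kcal/mol).
#' @param sequences RNA sequences (scored region), same length.
#' @param sigma_obs per-variant uncertainties for z-scores.
#' @param init_table single-mutant table from [single_mutant_table()].
#' @param train_fraction fraction of variants in the training half.
#' @param bound_window,wide_window,flip_bound bound windows in kcal/mol.
#' @param seed seed controlling the split and optimizer multi-starts.
#' @param consensus consensus sequence fixed at 0.
#' @return List: `model`, `report_train`, `report_test`, `report_all`,
#'   `train_idx`, `sse`.
#' @export
fit_full_model <- function(obs_ddg, sequences, sigma_obs = NULL,
                           init_table, train_fraction = 0.5,
                           bound_window = 0.75, wide_window = 2.5,
                           flip_bound = 4, seed = 1L, n_start = 3L,
                           consensus = "UGUAUAUAU") {
  n <- length(obs_ddg)
  stopifnot(length(sequences) == n)
  if (is.null(sigma_obs)) sigma_obs <- rep(0.3, n)
  cons <- strsplit(consensus, "")[[1]]
  theta0 <- stats::setNames(rep(0, 56), param_names())
  lower <- rep(0, 56); upper <- rep(0, 56)
  free <- rep(FALSE, 56)
  missing_terms <- character(0)
  for (i in seq_len(nrow(init_table))) {
    p <- init_table$position[i]; b <- init_table$base[i]
    idx <- (p - 1L) * 4L + match(b, .BASES)
    if (cons[p] == b) next  # consensus term: fixed at 0
    free[idx] <- TRUE
    if (isTRUE(init_table$available[i]) && p != 7L) {
      init <- init_table$ddg[i]
      hw <- init_table$ci_halfwidth[i]
      win <- max(bound_window, if (is.finite(hw)) hw else 0)
      theta0[idx] <- init
      lower[idx] <- init - win; upper[idx] <- init + win
    } else if (isTRUE(init_table$available[i]) && p == 7L) {
      # position 7 initializes at 0 but keeps data-derived bounds
      init <- init_table$ddg[i]
      hw <- init_table$ci_halfwidth[i]
      win <- max(bound_window, if (is.finite(hw)) hw else 0)
      theta0[idx] <- 0
      lower[idx] <- min(0, init - win); upper[idx] <- max(0, init + win)
    } else {
      missing_terms <- c(missing_terms, paste0("b", p, ".", b))
      theta0[idx] <- 0
      lower[idx] <- -wide_window; upper[idx] <- wide_window
    }
  }
  free[37:56] <- TRUE
  lower[37:56] <- -flip_bound; upper[37:56] <- flip_bound
  split <- with_seed(seed, sample(n, size = round(train_fraction * n)))
  design_train <- build_design(sequences[split])
  res <- fit_terms(design_train, obs_ddg[split], theta0, free, lower, upper,
                   seed = seed, n_start = n_start)
  flim <- matrix(FALSE, 4, 5, dimnames = list(.JUNCTIONS, .PAYLOADS))
  base <- list(flip_limits = flim, coupling = NULL, name = "fitted")
  model <- model_from_theta(res$theta, base, "fitted")
  pred_all <- predict_dataset(model, sequences)
  rep_train <- evaluate_fit(pred_all[split], obs_ddg[split], sigma_obs[split])
  rep_test <- evaluate_fit(pred_all[-split], obs_ddg[-split], sigma_obs[-split])
  rep_all <- evaluate_fit(pred_all, obs_ddg, sigma_obs)
  list(model = model, report_train = rep_train, report_test = rep_test,
       report_all = rep_all, train_idx = sort(split), sse = res$sse,
       missing_init_terms = missing_terms)
}

#' Parameter sensitivity scan
#'
#' Varies a single term over a grid with all other terms fixed and records
#' the RMSE of the ensemble predictions against the observations. The best
#' value is the grid argmin; when the curve has no distinct minimum (the
#' RMSE stays within `plateau_tol` of its minimum out to a grid edge), the
#' reported `plateau_value` is the onset of that plateau — the grid point
#' nearest the rising side at which the RMSE first comes within
#' `plateau_tol` of the minimum.
#'
#' @param model a [puf_model()].
#' @param obs_ddg,sequences observed affinities and scored sequences.
#' @param term parameter name, e.g. `"b1.A"` or `"f6/7.U"`.
#' @param grid numeric grid of trial values (kcal/mol), sorted ascending.
#' @param plateau_tol RMSE tolerance defining the plateau (default 0.005).
#' @return data.frame-backed list of class `sensitivity_curve`: `term`,
#'   `grid`, `rmse`, `best_value`, `plateau_value`, `distinct_minimum`.
#' @export
sensitivity_scan <- function(model, obs_ddg, sequences, term, grid,
                             plateau_tol = 0.005) {
  theta <- theta_from_model(model)
  if (!term %in% names(theta)) stop("unknown term: ", term)
  grid <- sort(grid)
  design <- build_design(sequences)
  RT <- energy_convention()$RT
  rmse <- vapply(grid, function(v) {
    th <- theta; th[term] <- v
    pred <- predict_design(design, th, RT)
    use <- is.finite(pred) & is.finite(obs_ddg)
    sqrt(mean((pred[use] - obs_ddg[use])^2))
  }, numeric(1))
  k <- which.min(rmse)
  rmin <- rmse[k]
  flat <- rmse <= rmin + plateau_tol
  distinct <- !flat[1] && !flat[length(flat)]
  plateau_value <- grid[k]
  if (!distinct) {
    run <- flat
    if (flat[length(flat)] && !flat[1]) {
      plateau_value <- grid[min(which(run))]       # flat to the right
    } else if (flat[1] && !flat[length(flat)]) {
      plateau_value <- grid[max(which(run))]       # flat to the left
    } else {
      plateau_value <- grid[min(which(run))]       # flat throughout
    }
  }
  structure(list(term = term, grid = grid, rmse = rmse,
                 best_value = grid[k], plateau_value = plateau_value,
                 distinct_minimum = distinct),
            class = "sensitivity_curve")
}
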