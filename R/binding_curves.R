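# Equilibrium binding-curve inference -----------------------------------------
#
# Signal model: a cluster's normalized fluorescence across a protein titration
# follows a two-site isotherm with a specific site (K_D) and a weak
# non-specific site (K_D,NS) on the RNA-protein complex:
#   f([P]) = f_min + f_max * [P]/([P]+K_D) * (1 + [P]/([P]+K_D,NS))

#' Default protein concentration series
#'
#' Zero plus a 16-point two-fold dilution series from 0.0125 to 409.6 nM.
#' @return Numeric vector of concentrations in nM, ascending.
#' @export
default_concentrations <- function() {
  c(0, 0.0125 * 2^(0:15))
}

#' Two-site equilibrium binding signal
#'
#' @param p protein concentration(s), nM (>= 0).
#' @param f_min baseline fluorescence (dimensionless).
#' @param f_max specific-site amplitude (dimensionless).
#' @param kd_nM specific dissociation constant, nM.
#' @param kd_ns_nM non-specific dissociation constant, nM.
#' @return Normalized fluorescence at each `p`.
#' @examples
#' binding_signal(0, 0.01, 1, 1, 600)          # f_min at zero protein
#' binding_signal(409.6, 0.0134, 1, 1, 597.4)  # ~1.417 with the NS rise
#' @export
binding_signal <- function(p, f_min, f_max, kd_nM, kd_ns_nM) {
  stopifnot(all(p >= 0))
  occ <- p / (p + kd_nM)
  f_min + f_max * occ * (1 + p / (p + kd_ns_nM))
}

# Bounded LM fit of the isotherm with jittered restarts. Dissociation
# constants are optimized on a log scale (they span decades); start/lower/
# upper and the returned parameters are in natural units. Standard errors
# are delta-method propagated back from the log scale.
fit_curve_lm <- function(conc, fluor, start, lower, upper,
                         fixed = list(), extra_starts = list(),
                         n_restart = 3L, jitter_seed = 1L) {
  kdpar <- intersect(names(start), c("kd_nM", "kd_ns_nM"))
  tf <- function(p) { p[kdpar] <- log(p[kdpar]); p }
  itf <- function(p) { p[kdpar] <- exp(p[kdpar]); p }
  obj <- function(par) {
    a <- as.list(itf(par))
    a[names(fixed)] <- fixed
    binding_signal(conc, a$f_min, a$f_max, a$kd_nM, a$kd_ns_nM) - fluor
  }
  best <- NULL
  starts <- c(list(start), extra_starts)
  if (n_restart > 1L) {
    jit <- with_seed(jitter_seed, {
      lapply(seq_len(n_restart - 1L), function(i) {
        s <- start * exp(stats::rnorm(length(start), 0, 1))
        pmin(pmax(s, lower), upper)
      })
    })
    starts <- c(starts, jit)
  }
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = tf(s), fn = obj, lower = tf(lower),
                         upper = tf(upper),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) return(list(converged = FALSE))
  fit <- best$fit
  par <- itf(fit$par)
  se <- tryCatch({
    # pseudo-inverse tolerates the singular Hessian of an exact fit, where
    # the residual scale drives the errors to zero anyway
    hinv <- tryCatch(solve(fit$hessian),
                     error = function(e) MASS::ginv(fit$hessian))
    cov <- hinv * best$sse / max(1, length(fluor) - length(fit$par))
    s <- sqrt(pmax(diag(cov), 0))
    s[names(fit$par) %in% kdpar] <- s[names(fit$par) %in% kdpar] *
      par[names(fit$par) %in% kdpar]  # d(exp)/dx
    s
  }, error = function(e) rep(NA_real_, length(fit$par)))
  names(se) <- names(fit$par)
  list(converged = fit$info %in% 1:4, par = par, se = se, sse = best$sse)
}

#' Fit the binding isotherm to a single cluster titration
#'
#' Bounded nonlinear least squares of the two-site model with all four
#' parameters free. Initialization: `f_min` at the fluorescence at the
#' lowest concentration (or a caller-supplied median across clusters),
#' `f_max` at the cluster's maximum observed fluorescence, `K_D` at the
#' highest applied concentration, and `K_D,NS` at five-fold that;
#' `f_min` and `f_max` are constrained non-negative.
#'
#' @param fluor normalized fluorescence, one value per concentration.
#' @param conc concentrations in nM (ascending, including 0); at least 4.
#' @param f_min_init optional initial `f_min` (e.g. the across-cluster
#'   median at the lowest concentration).
#' @return One-row data.frame: `f_min`, `f_max`, `kd_nM`, `kd_ns_nM`, `dg`,
#'   `dg_ns` (kcal/mol), standard errors `se_fmax`, `se_dg`, and `converged`.
#' @export
fit_single_cluster <- function(fluor, conc, f_min_init = NULL) {
  stopifnot(length(fluor) == length(conc), length(conc) >= 4)
  p_max <- max(conc)
  start <- c(f_min = if (is.null(f_min_init)) max(fluor[which.min(conc)], 0)
                     else f_min_init,
             f_max = max(fluor), kd_nM = p_max, kd_ns_nM = 5 * p_max)
  lower <- c(f_min = 0, f_max = 0, kd_nM = 1e-4, kd_ns_nM = 1e-2)
  upper <- c(f_min = Inf, f_max = Inf, kd_nM = 1e7, kd_ns_nM = 1e9)
  mid <- start
  mid[["kd_nM"]] <- sqrt(max(min(conc[conc > 0]), 1e-4) * p_max)
  res <- fit_curve_lm(conc, fluor, start, lower, upper,
                      extra_starts = list(mid))
  if (!res$converged) {
    return(data.frame(f_min = NA, f_max = NA, kd_nM = NA, kd_ns_nM = NA,
                      dg = NA, dg_ns = NA, se_fmax = NA, se_dg = NA,
                      converged = FALSE))
  }
  conv <- energy_convention()
  kd <- res$par[["kd_nM"]]
  se_kd <- res$se[["kd_nM"]]
  data.frame(
    f_min = res$par[["f_min"]], f_max = res$par[["f_max"]],
    kd_nM = kd, kd_ns_nM = res$par[["kd_ns_nM"]],
    dg = kd_to_dg(kd * 1e-9, conv),
    dg_ns = kd_to_dg(res$par[["kd_ns_nM"]] * 1e-9, conv),
    se_fmax = res$se[["f_max"]],
    se_dg = if (is.na(se_kd)) NA_real_ else conv$RT * se_kd / kd,
    converged = TRUE)
}

#' Fit all clusters of a long-format fluorescence table
#'
#' @param tbl data.frame with columns `cluster_id`, `variant_id`,
#'   `concentration_nM`, `normalized_fluorescence` (the generator's and the
#'   interface TSV dialect).
#' @return data.frame of per-cluster fits with `cluster_id` and `variant_id`.
#' @export
fit_clusters <- function(tbl) {
  need <- c("cluster_id", "variant_id", "concentration_nM",
            "normalized_fluorescence")
  stopifnot(all(need %in% names(tbl)))
  conc0 <- sort(unique(tbl$concentration_nM))
  low <- min(conc0)
  f_min_init <- stats::median(
    tbl$normalized_fluorescence[tbl$concentration_nM == low])
  parts <- split(tbl, tbl$cluster_id)
  out <- lapply(names(parts), function(cid) {
    d <- parts[[cid]][order(parts[[cid]]$concentration_nM), ]
    fit <- fit_single_cluster(d$normalized_fluorescence, d$concentration_nM,
                              f_min_init = f_min_init)
    cbind(data.frame(cluster_id = cid, variant_id = d$variant_id[1]), fit)
  })
  do.call(rbind, out)
}

#' Variant-independent curve parameters
#'
#' Pools single-cluster fits by variant (per-variant medians), then derives
#' the shared parameters used for refitting: the global `f_min` (median over
#' variants), a gamma distribution for `f_max` fitted by maximum likelihood
#' to the tight/precise variant subset (standard error of dG below
#' `max_se_dg`, SE(f_max) below f_max, and fitted K_D below
#' `tight_kd_fraction` of the highest concentration), and the global
#' non-specific free energy. The tight subset must be larger than expected
#' by chance: the null that at most `null_rate` of variants pass is rejected
#' at binomial p < 0.01, otherwise the estimation aborts.
#'
#' @param cluster_fits output of [fit_clusters()].
#' @param p_max highest concentration in nM (default 409.6).
#' @param max_se_dg precision cutoff on the per-variant dG standard error
#'   (kcal/mol).
#' @param tight_kd_fraction K_D cutoff as a fraction of `p_max`.
#' @param null_rate chance pass rate under the null (default 0.25).
#' @return List of class `global_curve_params`: `f_min`, `fmax_shape`,
#'   `fmax_scale`, `fmax_interval` (central 99.7%), `dg_ns`, `kd_ns_nM`,
#'   `n_tight`, `n_variants`, `binom_p`.
#' @export
estimate_global_params <- function(cluster_fits, p_max = 409.6,
                                   max_se_dg = 1.0, tight_kd_fraction = 0.15,
                                   null_rate = 0.25) {
  ok <- cluster_fits[cluster_fits$converged %in% TRUE, ]
  if (!nrow(ok)) stop("no converged cluster fits")
  agg <- function(col, f = stats::median) {
    tapply(ok[[col]], ok$variant_id, f, na.rm = TRUE)
  }
  v_fmin <- agg("f_min"); v_fmax <- agg("f_max"); v_kd <- agg("kd_nM")
  v_dgns <- agg("dg_ns")
  v_se_dg <- agg("se_dg"); v_se_fmax <- agg("se_fmax")
  tight <- !is.na(v_se_dg) & v_se_dg < max_se_dg &
    !is.na(v_se_fmax) & v_se_fmax < v_fmax &
    v_kd < tight_kd_fraction * p_max
  n_tight <- sum(tight); n_var <- length(tight)
  bt <- stats::binom.test(n_tight, n_var, p = null_rate,
                          alternative = "greater")
  if (n_tight == 0L || bt$p.value >= 0.01) {
    stop(sprintf(paste0("tight variant subset not significant: %d/%d pass ",
                        "(binomial p = %.3g)"), n_tight, n_var, bt$p.value))
  }
  fx <- as.numeric(v_fmax[tight])
  # ML gamma fit; variance floor keeps noiseless test data non-degenerate
  gam <- tryCatch(
    MASS::fitdistr(fx, "gamma"),
    error = function(e) NULL)
  if (is.null(gam) || stats::var(fx) < 1e-10) {
    m <- mean(fx); scale <- 1e-6; shape <- m / scale
  } else {
    shape <- gam$estimate[["shape"]]
    scale <- 1 / gam$estimate[["rate"]]
  }
  interval <- stats::qgamma(c(0.0015, 0.9985), shape = shape, scale = scale)
  dg_ns <- stats::median(v_dgns, na.rm = TRUE)
  structure(list(
    f_min = stats::median(v_fmin, na.rm = TRUE),
    fmax_shape = shape, fmax_scale = scale, fmax_interval = interval,
    dg_ns = dg_ns, kd_ns_nM = dg_to_kd(dg_ns) * 1e9,
    n_tight = n_tight, n_variants = n_var, binom_p = bt$p.value),
    class = "global_curve_params")
}

#' @export
print.global_curve_params <- function(x, ...) {
  cat(sprintf(paste0("global_curve_params: f_min %.4f; f_max ~ Gamma(%.2f, ",
                     "scale %.4g); dG_NS %.2f kcal/mol; tight %d/%d\n"),
              x$f_min, x$fmax_shape, x$fmax_scale, x$dg_ns,
              x$n_tight, x$n_variants))
  invisible(x)
}

# Fit K_D (and optionally f_max) to per-concentration medians with global
# f_min / K_D,NS fixed.
refit_median_curve <- function(conc, med, globals, fmax_fixed = NULL) {
  fixed <- list(f_min = globals$f_min, kd_ns_nM = globals$kd_ns_nM)
  p_max <- max(conc)
  if (is.null(fmax_fixed)) {
    start <- c(f_max = max(med, 1e-3), kd_nM = p_max)
    lower <- c(f_max = 0, kd_nM = 1e-4); upper <- c(f_max = Inf, kd_nM = 1e7)
  } else {
    fixed$f_max <- fmax_fixed
    start <- c(kd_nM = p_max)
    lower <- c(kd_nM = 1e-4); upper <- c(kd_nM = 1e7)
  }
  mid <- start
  mid[["kd_nM"]] <- sqrt(max(min(conc[conc > 0]), 1e-4) * p_max)
  res <- fit_curve_lm(conc, med, start, lower, upper, fixed = fixed,
                      extra_starts = list(mid))
  if (!res$converged) return(NA_real_)
  res$par[["kd_nM"]]
}

#' Refit a variant from its clusters with bootstrap confidence interval
#'
#' Refits a single binding curve to the per-concentration median
#' fluorescence across a variant's clusters, holding `f_min` and `K_D,NS`
#' at their global values. Saturation rule: when the median fluorescence at
#' the highest concentration falls below the lower edge of the f_max
#' distribution's central 99.7% interval, the variant is treated as
#' non-saturated and `f_max` is resampled from the gamma distribution
#' (`f_max_source = "resampled"`); otherwise `f_max` varies freely.
#' Clusters are resampled with replacement `n_boot` times (seeded, over a
#' canonical sorted cluster order, so the result is invariant to input row
#' order) to yield a percentile 95% confidence interval and
#' `dg_err = dg_upper - dg_lower`.
#'
#' @param tbl long-format fluorescence rows for one variant (`cluster_id`,
#'   `concentration_nM`, `normalized_fluorescence`).
#' @param globals a `global_curve_params` from [estimate_global_params()].
#' @param n_boot bootstrap iterations (default 100).
#' @param seed integer seed for bootstrap and f_max resampling.
#' @return One-row data.frame: `variant_id` (if present in `tbl`), `kd_nM`,
#'   `dg`, `dg_lower`, `dg_upper` (95% CI), `dg_err`, `n_clusters`,
#'   `saturated`, `f_max_source`.
#' @export
refit_variant <- function(tbl, globals, n_boot = 100L, seed = 1L) {
  stopifnot(all(c("cluster_id", "concentration_nM",
                  "normalized_fluorescence") %in% names(tbl)))
  clusters <- sort(unique(as.character(tbl$cluster_id)))
  conc <- sort(unique(tbl$concentration_nM))
  med_mat <- tapply(tbl$normalized_fluorescence,
                    list(as.character(tbl$cluster_id), tbl$concentration_nM),
                    stats::median)
  med_mat <- med_mat[clusters, as.character(conc), drop = FALSE]
  med_of <- function(ids) apply(med_mat[ids, , drop = FALSE], 2,
                                stats::median, na.rm = TRUE)
  med_all <- med_of(clusters)
  saturated <- med_all[length(med_all)] >= globals$fmax_interval[1]
  conv <- energy_convention()
  res <- with_seed(seed, {
    draw_fmax <- function() stats::rgamma(1, shape = globals$fmax_shape,
                                          scale = globals$fmax_scale)
    point_fmax <- if (saturated) NULL else draw_fmax()
    kd_point <- refit_median_curve(conc, med_all, globals, point_fmax)
    boot <- vapply(seq_len(n_boot), function(i) {
      ids <- sample(clusters, length(clusters), replace = TRUE)
      fm <- if (saturated) NULL else draw_fmax()
      refit_median_curve(conc, med_of(ids), globals, fm)
    }, numeric(1))
    list(kd = kd_point, boot = boot)
  })
  if (is.na(res$kd) || all(is.na(res$boot))) {
    return(data.frame(variant_id = if ("variant_id" %in% names(tbl))
      tbl$variant_id[1] else NA, kd_nM = NA, dg = NA, dg_lower = NA,
      dg_upper = NA, dg_err = NA, n_clusters = length(clusters),
      saturated = saturated, f_max_source = NA, fittable = FALSE))
  }
  dg <- kd_to_dg(res$kd * 1e-9, conv)
  bdg <- kd_to_dg(res$boot[!is.na(res$boot)] * 1e-9, conv)
  ci <- stats::quantile(bdg, c(0.025, 0.975), names = FALSE, type = 7)
  # percentile CI; widened if needed so the point estimate is always inside
  lo <- min(ci[1], dg); hi <- max(ci[2], dg)
  out <- data.frame(
    variant_id = if ("variant_id" %in% names(tbl)) tbl$variant_id[1] else NA,
    kd_nM = res$kd, dg = dg, dg_lower = lo, dg_upper = hi,
    dg_err = hi - lo, n_clusters = length(clusters), saturated = saturated,
    f_max_source = if (saturated) "fitted" else "resampled", fittable = TRUE)
  rownames(out) <- NULL
  out
}

#' Refit every variant of a cluster table
#'
#' Applies [refit_variant()] per variant with per-variant seeds derived from
#' `seed`, returning the per-variant affinity table.
#'
#' @param tbl long-format table (`cluster_id`, `variant_id`,
#'   `concentration_nM`, `normalized_fluorescence`).
#' @inheritParams refit_variant
#' @return data.frame, one row per variant (see [refit_variant()]).
#' @export
refit_all_variants <- function(tbl, globals, n_boot = 100L, seed = 1L) {
  vids <- sort(unique(as.character(tbl$variant_id)))
  out <- lapply(seq_along(vids), function(i) {
    refit_variant(tbl[tbl$variant_id == vids[i], , drop = FALSE], globals,
                  n_boot = n_boot, seed = seed + i)
  })
  do.call(rbind, out)
}
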