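# Variant-level filtering and replicate combination ---------------------------

#' Apply the affinity-precision filters to variant fits
#'
#' Keeps variants with `dg_err` strictly below `max_dg_err`, at least
#' `min_clusters` clusters, and `dg` strictly below the measurability limit
#' `dg_limit`. Per-rule violation counts are non-exclusive.
#'
#' @param fits data.frame of variant fits (needs `dg`, `dg_err`,
#'   `n_clusters`).
#' @param max_dg_err precision cutoff in kcal/mol (default 1.0).
#' @param min_clusters minimum clusters per variant (default 5).
#' @param dg_limit measurability threshold in kcal/mol (default -7.69).
#' @return List: `kept`, `dropped` (partition of `fits`) and `counts`
#'   (violations per rule plus totals).
#' @export
filter_variants <- function(fits, max_dg_err = 1.0, min_clusters = 5L,
                            dg_limit = -7.69) {
  if (!nrow(fits)) {
    return(list(kept = fits, dropped = fits,
                counts = c(dg_err = 0L, n_clusters = 0L, dg_limit = 0L,
                           kept = 0L, dropped = 0L)))
  }
  bad_err <- !(fits$dg_err < max_dg_err) | is.na(fits$dg_err)
  bad_n <- !(fits$n_clusters >= min_clusters)
  bad_dg <- !(fits$dg < dg_limit) | is.na(fits$dg)
  keep <- !(bad_err | bad_n | bad_dg)
  list(kept = fits[keep, , drop = FALSE],
       dropped = fits[!keep, , drop = FALSE],
       counts = c(dg_err = sum(bad_err), n_clusters = sum(bad_n),
                  dg_limit = sum(bad_dg), kept = sum(keep),
                  dropped = sum(!keep)))
}

#' Combine two replicate datasets by the error-weighted mean
#'
#' A systematic offset between replicates is estimated as the mean
#' difference `dg_A - dg_B` over the tightest-binding shared variants
#' (lowest `tight_quantile` of replicate A's dG) and added to replicate B.
#' Shared variants are then combined by the inverse-variance weighted mean,
#' \eqn{\Delta G_{comb} = (\Delta G_1/\sigma_1^2 + \Delta G_2/\sigma_2^2) /
#' (1/\sigma_1^2 + 1/\sigma_2^2)}, with
#' \eqn{\sigma_{comb} = (1/\sigma_1^2 + 1/\sigma_2^2)^{-1/2}}. Variants
#' present in only one replicate pass through unchanged.
#'
#' The per-variant uncertainty entering the weights is `sigma = dg_err / 2`
#' if no `sigma` column is present (half the 95% CI width is close to
#' 2 standard errors; the constant cancels in the weighted mean).
#'
#' @param repA,repB variant-fit data.frames with `variant_id`, `dg` and
#'   `sigma` (or `dg_err`).
#' @param tight_quantile fraction of tightest shared variants used for the
#'   offset (default 0.05).
#' @return List: `combined` data.frame (`variant_id`, `dg`, `sigma`,
#'   `n_replicates`) and `offset` (kcal/mol added to replicate B).
#' @export
combine_replicates <- function(repA, repB, tight_quantile = 0.05) {
  getsig <- function(d) if ("sigma" %in% names(d)) d$sigma else d$dg_err / 2
  a <- data.frame(variant_id = repA$variant_id, dg = repA$dg,
                  sigma = getsig(repA))
  b <- data.frame(variant_id = repB$variant_id, dg = repB$dg,
                  sigma = getsig(repB))
  shared <- intersect(a$variant_id, b$variant_id)
  if (!length(shared)) stop("replicates share no variants")
  ai <- match(shared, a$variant_id); bi <- match(shared, b$variant_id)
  cut <- stats::quantile(a$dg[ai], tight_quantile, names = FALSE)
  tight <- a$dg[ai] <= cut
  offset <- mean(a$dg[ai][tight] - b$dg[bi][tight])
  b$dg <- b$dg + offset
  w1 <- 1 / a$sigma[ai]^2; w2 <- 1 / b$sigma[bi]^2
  comb <- data.frame(
    variant_id = shared,
    dg = (a$dg[ai] * w1 + b$dg[bi] * w2) / (w1 + w2),
    sigma = sqrt(1 / (w1 + w2)),
    n_replicates = 2L)
  only_a <- a[!a$variant_id %in% shared, , drop = FALSE]
  only_b <- b[!b$variant_id %in% shared, , drop = FALSE]
  pass <- rbind(only_a, only_b)
  if (nrow(pass)) pass$n_replicates <- 1L
  list(combined = rbind(comb, pass), offset = offset)
}

#' Relative affinities versus the reference sequence
#'
#' Annotates each variant with \eqn{\Delta\Delta G_{obs} = \Delta G -
#' \Delta G_{ref,median}}, where the reference free energy is the median
#' over all library occurrences of the reference sequence that pass a
#' stricter structure cutoff (`dg_fold > ref_fold_cutoff`, strict).
#'
#' @param fits variant-fit data.frame with `dg`; reference occurrences are
#'   the rows whose `sequence_varreg` (or `sequence`) equals
#'   `reference_seq`, or rows flagged by a logical `is_reference` column.
#' @param reference_seq reference RNA (default consensus `"UGUAUAUAU"`).
#' @param ref_fold_cutoff structure cutoff for reference occurrences
#'   (kcal/mol, default -0.2); ignored when no `dg_fold` column exists.
#' @return List: `fits` with a `ddg_obs` column, `dg_ref` (median reference
#'   dG), `n_ref` (qualifying occurrences).
#' @export
reference_ddg <- function(fits, reference_seq = "UGUAUAUAU",
                          ref_fold_cutoff = -0.2) {
  is_ref <- if ("is_reference" %in% names(fits)) {
    fits$is_reference
  } else {
    seqcol <- if ("sequence_varreg" %in% names(fits)) "sequence_varreg"
              else "sequence"
    if (!seqcol %in% names(fits)) stop("no sequence or is_reference column")
    toupper(gsub("T", "U", fits[[seqcol]])) == reference_seq
  }
  qual <- is_ref
  if ("dg_fold" %in% names(fits)) {
    qual <- qual & fits$dg_fold > ref_fold_cutoff  # stricter reference cutoff
  }
  if (!sum(qual, na.rm = TRUE)) stop("no qualifying reference occurrences")
  dg_ref <- stats::median(fits$dg[which(qual)])
  fits$ddg_obs <- fits$dg - dg_ref
  list(fits = fits, dg_ref = dg_ref, n_ref = sum(qual, na.rm = TRUE))
}

# Folding oracles --------------------------------------------------------------
#
# Contract: a folding oracle is a function(sequence, constraint) returning the
# ensemble free energy (kcal/mol) at 25 C, where `constraint` is a string the
# length of `sequence` with '.' for unconstrained and 'x' for bases forced
# single-stranded. A NULL constraint means fully unconstrained.

#' Deterministic mock folding oracle
#'
#' Returns fixed fold penalties for testing the structure filter without a
#' folding engine: the unconstrained energy of sequence `s` is
#' `penalties[[s]]` (0 when absent) and the constrained energy is always 0,
#' so `dg_fold = penalties[[s]]`.
#'
#' @param penalties named numeric vector/list of fold free energies keyed by
#'   sequence.
#' @return A folding-oracle function.
#' @export
mock_fold_oracle <- function(penalties = c()) {
  force(penalties)
  function(sequence, constraint = NULL) {
    if (!is.null(constraint) && grepl("x", constraint, fixed = TRUE)) return(0)
    if (!sequence %in% names(penalties)) return(0)
    as.numeric(penalties[[sequence]])
  }
}

#' ViennaRNA folding oracle (RNAfold command line)
#'
#' Wraps `RNAfold -p0 -T25` (with `-C` when a constraint is given) and
#' parses the ensemble free energy. Requires the `RNAfold` executable on
#' `PATH`.
#'
#' @return A folding-oracle function, or an error if RNAfold is missing.
#' @export
vienna_fold_oracle <- function() {
  if (Sys.which("RNAfold") == "") stop("RNAfold executable not found on PATH")
  function(sequence, constraint = NULL) {
    input <- if (is.null(constraint)) sequence
             else paste(sequence, constraint, sep = "\n")
    args <- c("-p0", "-T25", "--noPS")
    if (!is.null(constraint)) args <- c(args, "-C")
    out <- system2("RNAfold", args, input = input, stdout = TRUE,
                   stderr = FALSE)
    line <- grep("free energy of ensemble", out, value = TRUE)
    if (!length(line)) stop("could not parse RNAfold output")
    as.numeric(sub(".*=\\s*(-?[0-9.]+).*", "\\1", line[1]))
  }
}

#' Assess a variant's secondary-structure penalty
#'
#' Folds the sequence unconstrained and with the designed variant region
#' forced single-stranded ('x' marks), and computes
#' \eqn{\Delta G_{fold} = \Delta G_{unconstrained} - \Delta G_{constrained}}
#' (always <= 0: a constraint can only destabilize the ensemble). The
#' variant is dropped iff `dg_fold < cutoff` (strict). For hairpin-stem
#' scaffolds, pass the already-truncated loop-region sequence.
#'
#' @param sequence RNA sequence in scaffold context (loop region only for
#'   stem scaffolds).
#' @param var_region integer positions (1-based) of the designed variant
#'   region within `sequence`; default all positions.
#' @param oracle folding oracle function (see [mock_fold_oracle()],
#'   [vienna_fold_oracle()]).
#' @param cutoff drop threshold in kcal/mol (default -0.5).
#' @return List: `dg_unconstrained`, `dg_constrained`, `dg_fold`, `keep`.
#' @export
assess_structure <- function(sequence, var_region = seq_len(nchar(sequence)),
                             oracle, cutoff = -0.5) {
  constraint <- rep(".", nchar(sequence))
  constraint[var_region] <- "x"
  constraint <- paste(constraint, collapse = "")
  dg_u <- oracle(sequence, NULL)
  dg_c <- oracle(sequence, constraint)
  dg_fold <- min(dg_u - dg_c, 0)  # numeric guard; constraint cannot stabilize
  list(dg_unconstrained = dg_u, dg_constrained = dg_c, dg_fold = dg_fold,
       keep = !(dg_fold < cutoff))
}
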