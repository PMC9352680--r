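# Synthetic RNA-MaP-like data with known ground truth --------------------------
#
# The generator emulates the designed-library regime: a variable region
# derived from the consensus by mutation, insertion, or flanking variation,
# embedded in one of four scaffolds (two linear, two hairpin-stem whose loop
# is the scored region), measured as cluster-level fluorescence titrations.

#' Scaffold contexts used by the library generator
#'
#' Four sequence contexts mirroring the designed-library layout: S1a/S1b
#' are linear, S2a/S2b embed the variable region in a hairpin loop whose
#' stem is dropped from the scored sequence. Scored flanks are cytidine
#' runs: C is the most uniformly penalized base across recognition
#' positions, so flanks neither complete cheap alternative registers for
#' mutants nor perturb the consensus ensemble, and the designed register
#' dominates by construction.
#'
#' @return Named list of scaffolds, each with `left`, `right` (scored
#'   flanks) and `stem_left`, `stem_right` (empty for linear scaffolds).
#' @export
library_scaffolds <- function() {
  list(
    S1a = list(left = "CCCCCCCC", right = "CCCCCCCC",
               stem_left = "", stem_right = ""),
    S1b = list(left = "CCCCCC", right = "CCCCCC",
               stem_left = "", stem_right = ""),
    S2a = list(left = "CCCCC", right = "CCCCC",
               stem_left = "GGAUGC", stem_right = "GCAUCC"),
    S2b = list(left = "CCCC", right = "CCCC",
               stem_left = "GCCAGU", stem_right = "ACUGGC"))
}

rand_bases <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

#' Design a synthetic variant library
#'
#' Deterministic under `seed`. Contains, in every scaffold: the consensus;
#' all single mutants (9 positions x 3 non-consensus bases); sampled
#' higher-order mutants (2-4 mutations); insertion variants of 1-5 nt at
#' every junction (all four bases singly at each junction, sampled pairs
#' and longer runs); and flanking-variation variants (0-3 extra nt between
#' scaffold flank and variable region). The table is deduplicated on
#' (scaffold, variable-region) pairs.
#'
#' @param consensus linear consensus sequence (default `"UGUAUAUAU"`).
#' @param flip_consensus the flipped-frame consensus (the linear consensus
#'   with the preferred residue flipped between positions 6 and 7; default
#'   `"UGUAUAUUAU"`). Single-mutant penalty probes mutate the nine bound
#'   positions of this 10-mer, so the favorable flip stays in frame and the
#'   observed penalty isolates the bound term.
#' @param scaffolds scaffold list as from [library_scaffolds()].
#' @param n_multi named vector: higher-order mutants per depth per
#'   scaffold. All distinct double mutants are enumerated when `"2"` meets
#'   or exceeds their count (324); depths 3-4 are sampled.
#' @param n_insert_pairs sampled 2-nt insertions per junction per scaffold.
#' @param n_insert_long sampled 3-5 nt insertions per scaffold.
#' @param n_flank flanking variants per scaffold.
#' @param seed integer seed.
#' @return data.frame (one row per deduplicated variant): `variant_id`,
#'   `scaffold`, `class`, `varreg`,
#'   `sequence` (full), `sequence_scored` (loop only for stem scaffolds),
#'   `mut_position`, `mut_base` (single mutants only), `insert_junction`,
#'   `insert_len`.
#' @export
design_library <- function(consensus = "UGUAUAUAU",
                           flip_consensus = "UGUAUAUUAU",
                           scaffolds = library_scaffolds(),
                           n_multi = c("2" = 324, "3" = 600, "4" = 150),
                           n_insert_pairs = 8, n_insert_long = 10,
                           n_flank = 24, seed = 1L) {
  cons <- strsplit(consensus, "")[[1]]
  fcons <- strsplit(flip_consensus, "")[[1]]
  np <- length(cons)
  # bound position -> character index in the flipped 10-mer (char 7 is the
  # flipped residue and is not a bound position)
  fmap <- c(1:6, 8:10)
  rows <- list()
  add <- function(scaffold, class, varreg, mut_position = NA, mut_base = NA,
                  insert_junction = NA, insert_len = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scaffold = scaffold, class = class, varreg = varreg,
      mut_position = mut_position, mut_base = mut_base,
      insert_junction = insert_junction, insert_len = insert_len)
  }
  with_seed(seed, {
    for (sc in names(scaffolds)) {
      add(sc, "consensus", consensus)
      add(sc, "flip_consensus", flip_consensus)
      # single mutants in the flipped frame (bound-term probes)
      for (p in seq_len(np)) for (b in setdiff(.BASES, cons[p])) {
        v <- fcons; v[fmap[p]] <- b
        add(sc, "single_mutant", paste(v, collapse = ""),
            mut_position = p, mut_base = b)
      }
      # single mutants of the linear consensus (register analyses)
      for (p in seq_len(np)) for (b in setdiff(.BASES, cons[p])) {
        v <- cons; v[p] <- b
        add(sc, "single_mutant_linear", paste(v, collapse = ""),
            mut_position = p, mut_base = b)
      }
      for (depth in names(n_multi)) {
        d <- as.integer(depth)
        n_all_pairs <- choose(np, 2) * 9L
        if (d == 2L && n_multi[[depth]] >= n_all_pairs) {
          # all distinct double mutants
          for (p1 in seq_len(np - 1L)) for (p2 in (p1 + 1L):np) {
            for (b1 in setdiff(.BASES, cons[p1])) {
              for (b2 in setdiff(.BASES, cons[p2])) {
                v <- cons; v[p1] <- b1; v[p2] <- b2
                add(sc, "mutant_2", paste(v, collapse = ""))
              }
            }
          }
        } else {
          for (i in seq_len(n_multi[[depth]])) {
            pos <- sort(sample(np, d))
            v <- cons
            for (p in pos) v[p] <- sample(setdiff(.BASES, cons[p]), 1)
            add(sc, paste0("mutant_", depth), paste(v, collapse = ""))
          }
        }
      }
      for (j in seq_len(np - 1L)) {
        for (b in .BASES) {
          v <- paste0(substr(consensus, 1, j), b,
                      substr(consensus, j + 1, np))
          add(sc, "insertion", v, insert_junction = j, insert_len = 1L)
        }
        for (i in seq_len(n_insert_pairs)) {
          v <- paste0(substr(consensus, 1, j), rand_bases(2),
                      substr(consensus, j + 1, np))
          add(sc, "insertion", v, insert_junction = j, insert_len = 2L)
        }
      }
      for (i in seq_len(n_insert_long)) {
        len <- sample(3:5, 1)
        j <- sample(np - 1L, 1)
        v <- paste0(substr(consensus, 1, j), rand_bases(len),
                    substr(consensus, j + 1, np))
        add(sc, "insertion", v, insert_junction = j, insert_len = len)
      }
      for (i in seq_len(n_flank)) {
        nl <- sample(0:3, 1); nr <- sample(0:3, 1)
        v <- paste0(rand_bases(nl), consensus, rand_bases(nr))
        add(sc, "flank", v)
      }
    }
  })
  lib <- do.call(rbind, rows)
  lib <- lib[!duplicated(paste(lib$scaffold, lib$varreg)), , drop = FALSE]
  sc <- scaffolds[lib$scaffold]
  left <- vapply(sc, `[[`, "", "left")
  right <- vapply(sc, `[[`, "", "right")
  stem_l <- vapply(sc, `[[`, "", "stem_left")
  stem_r <- vapply(sc, `[[`, "", "stem_right")
  lib$sequence_scored <- paste0(left, lib$varreg, right)
  lib$sequence <- paste0(stem_l, lib$sequence_scored, stem_r)
  lib$variant_id <- sprintf("v%05d", seq_len(nrow(lib)))
  rownames(lib) <- NULL
  lib[, c("variant_id", "scaffold", "class", "varreg", "sequence",
          "sequence_scored", "mut_position", "mut_base",
          "insert_junction", "insert_len")]
}

#' Simulate ground-truth affinities from a generator model
#'
#' True relative affinity of each variant is the ensemble free energy of
#' its scored sequence minus that of the consensus in the same scaffold
#' (so consensus variants have exactly ddG = 0); the true absolute free
#' energy is `ref_dg + ddG`. Variants whose true dG falls at or above the
#' measurability limit are flagged unmeasurable.
#'
#' @param library data.frame from [design_library()].
#' @param generator a [puf_model()] acting as the generative truth.
#' @param ref_dg reference (consensus) free energy in kcal/mol; the default
#'   -12.35 corresponds to a 0.88 nM consensus K_D.
#' @param policy a [mode_policy()].
#' @param dg_limit measurability threshold in kcal/mol.
#' @return `library` with `ddg_true`, `dg_true`, `kd_true_nM`,
#'   `measurable` columns.
#' @export
simulate_true_affinities <- function(library, generator, ref_dg = -12.35,
                                     policy = mode_policy(),
                                     dg_limit = -7.69) {
  pred <- predict_dataset(generator, library$sequence_scored, policy)
  cons_rows <- which(library$class == "consensus")
  cons_ddg <- stats::setNames(pred[cons_rows], library$scaffold[cons_rows])
  library$ddg_true <- pred - as.numeric(cons_ddg[library$scaffold])
  library$dg_true <- ref_dg + library$ddg_true
  library$kd_true_nM <- dg_to_kd(library$dg_true) * 1e9
  library$measurable <- library$dg_true < dg_limit
  library
}

#' Generator defaults for cluster-level simulation
#'
#' The variant-independent parameters the titration simulator draws from:
#' baseline `f_min`, non-specific binding free energy, and the gamma
#' distribution of cluster `f_max` (mean 1, CV 10%).
#'
#' @param f_min baseline fluorescence (default 0.0134).
#' @param dg_ns non-specific free energy in kcal/mol (default -8.49).
#' @param fmax_shape,fmax_scale gamma parameters for cluster f_max.
#' @return List with the same fields as the fitted `global_curve_params`
#'   that the estimation stage produces.
#' @export
sim_globals <- function(f_min = 0.0134, dg_ns = -8.49,
                        fmax_shape = 100, fmax_scale = 0.01) {
  structure(list(
    f_min = f_min, fmax_shape = fmax_shape, fmax_scale = fmax_scale,
    fmax_interval = stats::qgamma(c(0.0015, 0.9985), shape = fmax_shape,
                                  scale = fmax_scale),
    dg_ns = dg_ns, kd_ns_nM = dg_to_kd(dg_ns) * 1e9),
    class = "global_curve_params")
}

#' Simulate cluster-level fluorescence titrations
#'
#' For each variant, draws a cluster count (`n_clusters_min` plus a Poisson
#' excess), a per-cluster f_max from the gamma distribution, and evaluates
#' the two-site isotherm at each concentration with additive Gaussian noise
#' `sigma_f`. Fully reproducible under `seed`.
#'
#' @param truth data.frame from [simulate_true_affinities()] (needs
#'   `variant_id`, `kd_true_nM`).
#' @param globals list from [sim_globals()] (or fitted globals).
#' @param conc concentration series in nM.
#' @param n_clusters_min floor on clusters per variant (default 5).
#' @param n_clusters_lambda Poisson mean of the excess (default 15).
#' @param sigma_f fluorescence noise standard deviation.
#' @param seed integer seed.
#' @return Long-format data.frame: `cluster_id`, `variant_id`,
#'   `concentration_nM`, `normalized_fluorescence`.
#' @export
simulate_cluster_data <- function(truth, globals = sim_globals(),
                                  conc = default_concentrations(),
                                  n_clusters_min = 5L,
                                  n_clusters_lambda = 15,
                                  sigma_f = 0.05, seed = 1L) {
  stopifnot(sigma_f >= 0)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      nc <- n_clusters_min + stats::rpois(1, n_clusters_lambda)
      kd <- truth$kd_true_nM[i]
      fmax <- stats::rgamma(nc, shape = globals$fmax_shape,
                            scale = globals$fmax_scale)
      f <- vapply(seq_len(nc), function(k) {
        binding_signal(conc, globals$f_min, fmax[k], kd, globals$kd_ns_nM) +
          stats::rnorm(length(conc), 0, sigma_f)
      }, numeric(length(conc)))
      data.frame(
        cluster_id = rep(paste0(truth$variant_id[i], "_c", seq_len(nc)),
                         each = length(conc)),
        variant_id = truth$variant_id[i],
        concentration_nM = rep(conc, nc),
        normalized_fluorescence = as.vector(f))
    })
    do.call(rbind, out)
  })
}

#' Simulate a replicate pair with a systematic affinity offset
#'
#' Replicate A simulates the truth as given; replicate B simulates the same
#' variants with every true dG made tighter (more negative) by `offset`
#' before simulation, with independent noise. [combine_replicates()]
#' applied to the two fitted datasets recovers approximately `offset`.
#'
#' @inheritParams simulate_cluster_data
#' @param offset systematic shift in kcal/mol (default 0.1).
#' @param seeds two integers, one per replicate.
#' @return List of two long-format tables, `repA` and `repB`.
#' @export
simulate_replicate_pair <- function(truth, globals = sim_globals(),
                                    conc = default_concentrations(),
                                    offset = 0.1, sigma_f = 0.05,
                                    n_clusters_min = 5L,
                                    n_clusters_lambda = 15,
                                    seeds = c(1L, 2L)) {
  truth_b <- truth
  truth_b$dg_true <- truth$dg_true - offset
  truth_b$kd_true_nM <- dg_to_kd(truth_b$dg_true) * 1e9
  list(
    repA = simulate_cluster_data(truth, globals, conc, n_clusters_min,
                                 n_clusters_lambda, sigma_f, seeds[1]),
    repB = simulate_cluster_data(truth_b, globals, conc, n_clusters_min,
                                 n_clusters_lambda, sigma_f, seeds[2]))
}
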