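# Configuration geometry ------------------------------------------------------
#
# A binding configuration places the model's bound positions (1..9, plus -2/-1
# for 5'-extended models) consecutively on the RNA except where flip junctions
# extrude one (single flip) or two (NN flip) residues between adjacent
# positions. A configuration "template" captures the mode geometry only; a
# register offsets the template along the query.

# Slot table for one template: data.frame(kind, pos, junction) with one row per
# consumed residue, 5' to 3'. kind: "ext", "bound", "flip".
template_slots <- function(junctions, widths, extended) {
  kind <- character(0); pos <- character(0); junc <- character(0)
  if (extended) {
    kind <- c(kind, "ext", "ext"); pos <- c(pos, "-2", "-1")
    junc <- c(junc, NA, NA)
  }
  for (p in 1:9) {
    kind <- c(kind, "bound"); pos <- c(pos, as.character(p)); junc <- c(junc, NA)
    hit <- which(junctions == p)
    if (length(hit)) {
      for (h in hit) {
        w <- widths[h]
        j <- paste0(p, "/", p + 1L)
        kind <- c(kind, rep("flip", w)); pos <- c(pos, rep(NA, w))
        junc <- c(junc, rep(j, w))
      }
    }
  }
  data.frame(kind = kind, pos = pos, junction = junc,
             stringsAsFactors = FALSE)
}

# All templates allowed by a policy, in deterministic mode order.
mode_templates <- function(policy, extended) {
  js <- 3:6  # junctions 3/4..6/7; others carry no term by construction
  tpl <- list()
  add <- function(mode, junctions, widths, label) {
    slots <- template_slots(junctions, widths, extended)
    tpl[[length(tpl) + 1L]] <<- list(mode = mode, slots = slots,
                                     footprint = nrow(slots), label = label)
  }
  if ("consecutive" %in% policy$modes) {
    add("consecutive", integer(0), integer(0), "")
  }
  if ("single_flip" %in% policy$modes) {
    for (j in js) add("single_flip", j, 1L, paste0(j, "/", j + 1L))
  }
  if ("double_flip_NN" %in% policy$modes) {
    for (j in js) add("double_flip_NN", j, 2L, paste0(j, "/", j + 1L))
  }
  if ("two_single_flips" %in% policy$modes) {
    for (a in js) for (b in js) if (a < b) {
      add("two_single_flips", c(a, b), c(1L, 1L),
          paste0(a, "/", a + 1L, "+", b, "/", b + 1L))
    }
  }
  tpl
}

# Score one placed template on integer-coded residues. Returns the total
# ddG (Inf if a censored-as-infinite term is hit, NA if an ambiguous base is
# consumed) and the flipped payload string.
score_template <- function(codes_window, tpl, model, flips_eff) {
  if (anyNA(codes_window)) return(list(ddg = NA_real_, payload = NA_character_))
  slots <- tpl$slots
  total <- 0
  payload <- character(0)
  bound_bases <- character(0)
  nn_seen <- character(0)
  for (i in seq_len(nrow(slots))) {
    b <- codes_window[i]
    if (slots$kind[i] == "bound") {
      total <- total + model$bound[slots$pos[i], b]
      bound_bases[slots$pos[i]] <- .BASES[b]
    } else if (slots$kind[i] == "ext") {
      total <- total + model$extension[slots$pos[i], b]
    } else {  # flip
      j <- slots$junction[i]
      if (tpl$mode == "double_flip_NN") {
        if (!j %in% nn_seen) {  # NN term charged once per junction
          total <- total + flips_eff[j, "NN"]
          nn_seen <- c(nn_seen, j)
        }
        payload <- c(payload, .BASES[b])
      } else {
        total <- total + flips_eff[j, .BASES[b]]
        payload <- c(payload, .BASES[b])
      }
    }
  }
  if (!is.null(model$coupling) && is.finite(total)) {
    for (k in seq_len(nrow(model$coupling))) {
      pp <- trimws(strsplit(model$coupling$positions[k], ",")[[1]])
      bb <- trimws(strsplit(model$coupling$bases[k], ",")[[1]])
      if (all(bound_bases[pp] == bb, na.rm = FALSE) && !anyNA(bound_bases[pp])) {
        total <- total + model$coupling$value[k]
      }
    }
  }
  list(ddg = total, payload = paste(payload, collapse = ""))
}

#' Score a consecutive window under the additive model
#'
#' Sum of the bound terms for the residues of a single consecutive window
#' (length 9, or 11 for a 5'-extended model). The consensus scores 0.
#'
#' @param window RNA string of exactly the model footprint length
#'   (T is accepted and read as U).
#' @param model a [puf_model()].
#' @param ambiguous how to treat non-ACGU bases: `"error"` (default) or
#'   `"unbindable"` (returns `Inf`).
#' @return Predicted relative free energy in kcal/mol.
#' @export
score_consecutive <- function(window, model,
                              ambiguous = c("error", "unbindable")) {
  ambiguous <- match.arg(ambiguous)
  fp <- model_footprint(model)
  codes <- encode_rna(window)
  if (length(codes) != fp) {
    stop(sprintf("window must be exactly %d bases, got %d", fp, length(codes)))
  }
  if (anyNA(codes)) {
    if (ambiguous == "error") stop("window contains non-ACGU bases")
    return(Inf)
  }
  total <- 0
  if (!is.null(model$extension)) {
    total <- model$extension["-2", codes[1]] + model$extension["-1", codes[2]]
    codes <- codes[-(1:2)]
  }
  total + sum(model$bound[cbind(1:9, codes)])
}

#' Enumerate all binding configurations of a sequence
#'
#' Every geometrically valid placement of the model on the query: each
#' consecutive register, each register x enabled single-flip junction, each
#' register x NN two-residue flip, and each register x pair of distinct
#' single-flip junctions. Configurations through censored-as-infinite terms
#' or ambiguous bases are omitted. Ordering is deterministic: register, then
#' mode (consecutive, single flips 3/4..6/7, NN flips, junction pairs).
#'
#' @param seq RNA string, length at least the model footprint.
#' @param model a [puf_model()].
#' @param policy a [mode_policy()].
#' @return data.frame with columns `register` (0-based offset of the first
#'   consumed residue), `mode`, `junctions`, `flipped`, `footprint`, `ddg`.
#' @export
enumerate_configurations <- function(seq, model, policy = mode_policy()) {
  codes <- encode_rna(seq)
  n <- length(codes)
  fp0 <- model_footprint(model)
  empty <- data.frame(register = integer(0), mode = character(0),
                      junctions = character(0), flipped = character(0),
                      footprint = integer(0), ddg = numeric(0))
  if (n < fp0) {
    warning(sprintf("sequence length %d below minimal footprint %d", n, fp0))
    return(empty)
  }
  if (anyNA(codes) && policy$ambiguous == "error") {
    stop("sequence contains non-ACGU bases")
  }
  flips_eff <- effective_flips(model, policy)
  tpls <- mode_templates(policy, !is.null(model$extension))
  rows <- vector("list", 64L)
  k <- 0L
  for (r in 0:(n - fp0)) {
    for (tpl in tpls) {
      fp <- tpl$footprint
      if (r + fp > n) next
      sc <- score_template(codes[(r + 1):(r + fp)], tpl, model, flips_eff)
      if (is.na(sc$ddg) || !is.finite(sc$ddg)) next
      k <- k + 1L
      rows[[k]] <- data.frame(register = r, mode = tpl$mode,
                              junctions = tpl$label, flipped = sc$payload,
                              footprint = fp, ddg = sc$ddg)
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, rows[seq_len(k)])
}

# -RT ln sum exp(-x/RT), numerically shifted.
neg_rt_logsumexp <- function(ddg, RT) {
  if (!length(ddg)) return(Inf)
  m <- min(ddg)
  m - RT * log(sum(exp(-(ddg - m) / RT)))
}

#' Ensemble (partition-function) relative binding free energy
#'
#' \eqn{\Delta\Delta G_{ens} = -RT \ln \sum_r e^{-\Delta\Delta G_r / RT}}
#' over all configurations from [enumerate_configurations()]. Always at most
#' the best single configuration's value; equals it when only one
#' configuration exists; `Inf` (no measurable binding) when none does.
#'
#' @inheritParams enumerate_configurations
#' @param convention an [energy_convention()].
#' @return Ensemble relative free energy in kcal/mol.
#' @examples
#' m <- puf4_model()
#' ensemble_ddg("UGUAUAUAU", m)    # 0: single consensus configuration
#' ensemble_ddg("UGUAUAUUAU", m)   # ~ -1.34: dominant favorable 6/7 U flip
#' @export
ensemble_ddg <- function(seq, model, policy = mode_policy(),
                         convention = energy_convention()) {
  cfg <- suppressWarnings(enumerate_configurations(seq, model, policy))
  neg_rt_logsumexp(cfg$ddg, convention$RT)
}

#' Best consecutive binding register of a sequence
#'
#' Splits the query into overlapping windows of the model footprint shifted
#' by one base, scores each under the additive consecutive model, and
#' returns the lowest-energy window (ties broken by the smallest offset).
#' When the designed register offset is supplied, flags whether the best
#' register differs from it.
#'
#' @inheritParams score_consecutive
#' @param seq RNA string of length at least the footprint.
#' @param designed_offset optional 0-based offset of the designed register.
#' @return List with `window`, `ddg`, `offset` (0-based) and
#'   `shifted` (logical, `NA` when no designed offset given).
#' @export
best_register <- function(seq, model, designed_offset = NULL) {
  fp <- model_footprint(model)
  codes <- encode_rna(seq)
  n <- length(codes)
  if (n < fp) stop("sequence shorter than model footprint")
  offs <- 0:(n - fp)
  scores <- vapply(offs, function(r) {
    w <- codes[(r + 1):(r + fp)]
    if (anyNA(w)) return(Inf)
    score_consecutive(decode_rna(w), model)
  }, numeric(1))
  best <- offs[which.min(scores)]  # which.min takes the first = smallest offset
  list(window = decode_rna(codes[(best + 1):(best + fp)]),
       ddg = min(scores), offset = best,
       shifted = if (is.null(designed_offset)) NA else best != designed_offset)
}
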