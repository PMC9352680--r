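# Internal base alphabet; all sequence handling is uppercase RNA with T -> U.
.BASES <- c("A", "C", "G", "U")
.JUNCTIONS <- c("3/4", "4/5", "5/6", "6/7")
.PAYLOADS <- c(.BASES, "NN")

# Normalize a character string to uppercase RNA; returns integer codes 1..4
# (A,C,G,U) with NA for anything else (N and other ambiguity codes).
encode_rna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "T"] <- "U"
  match(chars, .BASES)
}

decode_rna <- function(codes) paste(.BASES[codes], collapse = "")

#' Construct a Pumilio energy model
#'
#' An additive non-consecutive model is a set of free-energy penalties
#' (kcal/mol, relative to the consensus sequence): `bound` terms for each
#' base at each of the nine recognition positions, `flip` terms for residues
#' extruded between adjacent positions (junctions 3/4, 4/5, 5/6 and 6/7; the
#' remaining junctions carry no term and never contribute configurations),
#' optional `coupling` corrections for specific residue combinations, and an
#' optional 5' `extension` adding recognition positions -2 and -1.
#'
#' Every position's minimum bound term must be 0 and is attained by the
#' consensus base, so the consensus sequence scores exactly 0.
#'
#' @param bound 9 x 4 numeric matrix of bound terms; rows are positions 1-9,
#'   columns A, C, G, U.
#' @param flips 4 x 5 numeric matrix of flip terms; rows `3/4`, `4/5`, `5/6`,
#'   `6/7`; columns A, C, G, U, NN (NN = any two adjacent residues flipped).
#' @param flip_limits logical matrix like `flips`; `TRUE` marks a censored
#'   lower limit (the true penalty is at least the stated value).
#' @param coupling optional data.frame with columns `positions`
#'   (comma-separated position list), `bases` (residues required at those
#'   positions, same order) and `value` (kcal/mol).
#' @param extension optional 2 x 4 numeric matrix of 5'-extension terms;
#'   rows `-2`, `-1`; columns A, C, G, U.
#' @param name model name used in printing and output tables.
#' @param enforce_normalization require each position's minimum bound term
#'   to be exactly 0 (the convention of canonical parameter tables). Fitted
#'   models hold the consensus at 0 but may assign a marginally negative
#'   term to another base; they are constructed with `FALSE` and their
#'   consensus is the per-position argmin.
#' @return An object of class `puf_model`.
#' @seealso [puf4_model()], [read_energy_model()], [extend_model_5prime()]
#' @export
puf_model <- function(bound, flips, flip_limits = NULL, coupling = NULL,
                      extension = NULL, name = "model",
                      enforce_normalization = TRUE) {
  bound <- as.matrix(bound)
  flips <- as.matrix(flips)
  stopifnot(nrow(bound) == 9, ncol(bound) == 4,
            nrow(flips) == 4, ncol(flips) == 5)
  dimnames(bound) <- list(as.character(1:9), .BASES)
  dimnames(flips) <- list(.JUNCTIONS, .PAYLOADS)
  if (is.null(flip_limits)) {
    flip_limits <- matrix(FALSE, 4, 5, dimnames = dimnames(flips))
  }
  flip_limits <- as.matrix(flip_limits)
  dimnames(flip_limits) <- dimnames(flips)
  if (any(!is.finite(bound))) stop("bound terms must be finite")
  if (any(!is.finite(flips))) stop("flip terms must be finite")
  if (enforce_normalization) {
    mins <- apply(bound, 1, min)
    if (any(abs(mins) > 1e-9)) {
      stop("each position's minimum bound term must be 0 (consensus normalization)")
    }
  }
  if (!is.null(extension)) {
    extension <- as.matrix(extension)
    stopifnot(nrow(extension) == 2, ncol(extension) == 4)
    dimnames(extension) <- list(c("-2", "-1"), .BASES)
  }
  consensus <- paste(.BASES[apply(bound, 1, which.min)], collapse = "")
  structure(
    list(name = name, bound = bound, flips = flips,
         flip_limits = flip_limits, coupling = coupling,
         extension = extension, consensus = consensus),
    class = "puf_model"
  )
}

#' @export
print.puf_model <- function(x, ...) {
  cat(sprintf("puf_model '%s': consensus %s; %d bound + %d flip terms%s%s\n",
              x$name, x$consensus, sum(x$bound != 0) + 9L, length(x$flips),
              if (!is.null(x$coupling)) sprintf("; %d coupling", nrow(x$coupling)) else "",
              if (!is.null(x$extension)) "; 5' extended (-2/-1)" else ""))
  invisible(x)
}

#' Footprint geometry of a model
#'
#' Number of bound positions (9, or 11 with a 5' extension) consumed by a
#' consecutive configuration; flipped modes consume one or two more residues.
#' @param model a [puf_model()].
#' @return Integer footprint length of the consecutive mode.
#' @export
model_footprint <- function(model) {
  9L + if (!is.null(model$extension)) 2L else 0L
}

#' Policy for configuration enumeration
#'
#' Controls how censored flip limits enter the partition function and which
#' binding modes are enumerated. Junctions without a term (1/2, 2/3, 7/8,
#' 8/9) always yield excluded configurations.
#'
#' @param censored_limit_handling `"point_value"` uses a censored limit at
#'   its stated value (keeps the partition function finite and
#'   conservative); `"infinite"` removes such configurations.
#' @param modes subset of `c("consecutive", "single_flip", "double_flip_NN",
#'   "two_single_flips")` to enumerate.
#' @param ambiguous `"unbindable"` treats windows containing non-ACGU bases
#'   as contributing nothing (genome scans skip N-runs); `"error"` rejects.
#' @return An object of class `mode_policy`.
#' @export
mode_policy <- function(censored_limit_handling = c("point_value", "infinite"),
                        modes = c("consecutive", "single_flip",
                                  "double_flip_NN", "two_single_flips"),
                        ambiguous = c("unbindable", "error")) {
  censored_limit_handling <- match.arg(censored_limit_handling)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(censored_limit_handling = censored_limit_handling,
                 modes = modes, ambiguous = match.arg(ambiguous)),
            class = "mode_policy")
}

# Flip matrix with the policy applied (censored limits -> Inf if requested).
effective_flips <- function(model, policy) {
  fl <- model$flips
  if (policy$censored_limit_handling == "infinite") {
    fl[model$flip_limits] <- Inf
  }
  fl
}

#' Read an energy parameter table
#'
#' Tab-separated with columns `term_class` (`bound`, `flip`, `coupling`,
#' `extension`), `position` (1-9 for bound; junction such as `6/7` for
#' flips; `-2`/`-1` for extension; comma-separated list for coupling),
#' `base` (A/C/G/U, `NN`, or a residue combination for coupling),
#' `value_kcal_mol`, and `is_lower_limit` (0/1, flips only).
#'
#' @param path TSV file path.
#' @param name model name; defaults to the file name.
#' @return A [puf_model()].
#' @export
read_energy_model <- function(path, name = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("term_class", "position", "base", "value_kcal_mol")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  val <- as.numeric(tab$value_kcal_mol)
  lim <- if ("is_lower_limit" %in% names(tab)) {
    as.integer(tab$is_lower_limit) == 1L
  } else rep(FALSE, nrow(tab))
  lim[is.na(lim)] <- FALSE

  bound <- matrix(NA_real_, 9, 4, dimnames = list(as.character(1:9), .BASES))
  flips <- matrix(NA_real_, 4, 5, dimnames = list(.JUNCTIONS, .PAYLOADS))
  flim <- matrix(FALSE, 4, 5, dimnames = dimnames(flips))
  ext <- NULL
  coup <- NULL
  for (i in seq_len(nrow(tab))) {
    cls <- tab$term_class[i]
    if (cls == "bound") {
      bound[tab$position[i], tab$base[i]] <- val[i]
    } else if (cls == "flip") {
      flips[tab$position[i], tab$base[i]] <- val[i]
      flim[tab$position[i], tab$base[i]] <- lim[i]
    } else if (cls == "extension") {
      if (is.null(ext)) {
        ext <- matrix(0, 2, 4, dimnames = list(c("-2", "-1"), .BASES))
      }
      ext[tab$position[i], tab$base[i]] <- val[i]
    } else if (cls == "coupling") {
      coup <- rbind(coup, data.frame(positions = tab$position[i],
                                     bases = tab$base[i], value = val[i]))
    } else {
      stop("unknown term_class: ", cls)
    }
  }
  if (any(is.na(bound))) stop("incomplete bound term table")
  if (any(is.na(flips))) stop("incomplete flip term table")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  puf_model(bound, flips, flim, coupling = coup, extension = ext, name = name)
}

#' Write an energy parameter table
#'
#' Inverse of [read_energy_model()].
#' @param model a [puf_model()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_energy_model <- function(model, path) {
  rows <- list()
  for (b in rownames(model$bound)) for (x in .BASES) {
    rows[[length(rows) + 1L]] <- data.frame(
      term_class = "bound", position = b, base = x,
      value_kcal_mol = model$bound[b, x], is_lower_limit = 0L)
  }
  for (j in .JUNCTIONS) for (y in .PAYLOADS) {
    rows[[length(rows) + 1L]] <- data.frame(
      term_class = "flip", position = j, base = y,
      value_kcal_mol = model$flips[j, y],
      is_lower_limit = as.integer(model$flip_limits[j, y]))
  }
  if (!is.null(model$extension)) {
    for (p in rownames(model$extension)) for (x in .BASES) {
      rows[[length(rows) + 1L]] <- data.frame(
        term_class = "extension", position = p, base = x,
        value_kcal_mol = model$extension[p, x], is_lower_limit = 0L)
    }
  }
  if (!is.null(model$coupling)) {
    for (i in seq_len(nrow(model$coupling))) {
      rows[[length(rows) + 1L]] <- data.frame(
        term_class = "coupling", position = model$coupling$positions[i],
        base = model$coupling$bases[i],
        value_kcal_mol = model$coupling$value[i], is_lower_limit = 0L)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged PUF4 energy model
#'
#' The 56-term PUF4 additive non-consecutive model (36 bound terms, 20 flip
#' terms; censored limits flagged). Consensus UGUAUAUAU; the single-residue
#' 6/7 flips are favorable (negative), the hallmark of PUF4 specificity.
#'
#' @return A [puf_model()].
#' @examples
#' m <- puf4_model()
#' score_consecutive("UGUAUAUAU", m)  # 0
#' @export
puf4_model <- function() {
  read_energy_model(system.file("extdata", "puf4_model.tsv",
                                package = "pufbind", mustWork = TRUE),
                    name = "PUF4")
}

#' Extend a model with 5' recognition positions -2 and -1
#'
#' Adds two upstream positions to the bound footprint (9 -> 11 residues)
#' with user-supplied penalties. A PUF3-style model is obtained from a
#' PUM2-like core by setting C at position -2 to -2 kcal/mol and all other
#' extension terms to 0; an all-zero extension reproduces the unextended
#' model's scores on any window that provides the two upstream residues.
#'
#' @param model a [puf_model()] without an extension.
#' @param extension 2 x 4 numeric matrix (rows `-2`, `-1`; columns
#'   A, C, G, U), or a named list like `list("-2" = c(C = -2))` filling
#'   unnamed entries with 0.
#' @return An extended [puf_model()].
#' @export
extend_model_5prime <- function(model, extension) {
  if (!is.null(model$extension)) stop("model is already 5'-extended")
  if (is.list(extension) && !is.matrix(extension)) {
    ext <- matrix(0, 2, 4, dimnames = list(c("-2", "-1"), .BASES))
    for (p in names(extension)) {
      if (!p %in% c("-2", "-1")) stop("extension positions must be -2 or -1")
      v <- extension[[p]]
      ext[p, names(v)] <- v
    }
    extension <- ext
  }
  extension <- as.matrix(extension)
  stopifnot(nrow(extension) == 2, ncol(extension) == 4)
  puf_model(model$bound, model$flips, model$flip_limits,
            coupling = model$coupling, extension = extension,
            name = paste0(model$name, "+5prime"))
}
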