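# Genome-wide occupancy prediction ---------------------------------------------

# Vectorized per-contig, per-strand window scan. `codes` are integer residue
# codes for the scanned strand read 5'->3'. Returns ddG per window start
# (1-based in the scanned strand) and a logical `skipped` for windows that
# contain ambiguous bases.
scan_codes <- function(codes, model, policy, window_len, RT) {
  L <- length(codes)
  nwin <- L - window_len + 1L
  if (nwin < 1L) return(list(ddg = numeric(0), skipped = logical(0)))
  tpls <- mode_templates(policy, extended = !is.null(model$extension))
  flips_eff <- effective_flips(model, policy)
  Z <- numeric(nwin)
  isna <- is.na(codes)
  for (tpl in tpls) {
    fp <- tpl$footprint
    if (fp > window_len) next
    nst <- L - fp + 1L
    starts <- seq_len(nst)
    S <- numeric(nst)
    nn_seen <- character(0)
    slots <- tpl$slots
    for (i in seq_len(nrow(slots))) {
      res <- codes[starts + i - 1L]
      if (slots$kind[i] == "bound") {
        S <- S + model$bound[slots$pos[i], ][res]
      } else if (slots$kind[i] == "ext") {
        S <- S + model$extension[slots$pos[i], ][res]
      } else {
        j <- slots$junction[i]
        if (tpl$mode == "double_flip_NN") {
          if (!j %in% nn_seen) {
            S <- S + flips_eff[j, "NN"]
            nn_seen <- c(nn_seen, j)
          }
          S <- S + ifelse(is.na(res), NA_real_, 0)  # consume residue, any base
        } else {
          S <- S + flips_eff[j, 1:4][res]
        }
      }
    }
    if (!is.null(model$coupling)) {
      bnd <- which(slots$kind == "bound")
      off_of_pos <- stats::setNames(bnd, slots$pos[bnd])
      for (k in seq_len(nrow(model$coupling))) {
        pp <- trimws(strsplit(model$coupling$positions[k], ",")[[1]])
        bb <- match(trimws(strsplit(model$coupling$bases[k], ",")[[1]]), .BASES)
        hit <- rep(TRUE, nst)
        for (q in seq_along(pp)) {
          res <- codes[starts + off_of_pos[[pp[q]]] - 1L]
          hit <- hit & !is.na(res) & res == bb[q]
        }
        S <- S + ifelse(hit, model$coupling$value[k], 0)
      }
    }
    B <- exp(-S / RT)
    B[is.na(B)] <- 0
    K <- window_len - fp + 1L  # registers of this mode inside one window
    cs <- c(0, cumsum(B))
    Z <- Z + (cs[seq_len(nwin) + K] - cs[seq_len(nwin)])
  }
  nacum <- c(0L, cumsum(isna))
  skipped <- (nacum[seq_len(nwin) + window_len] - nacum[seq_len(nwin)]) > 0L
  ddg <- ifelse(Z > 0, -RT * log(Z), Inf)
  list(ddg = ddg, skipped = skipped)
}

#' Scan a genome with sliding windows on both strands
#'
#' Divides each contig into `window_len`-nt windows shifted by a single
#' base, on both strands, and scores each window's ensemble relative
#' affinity (partition function over every register and enabled flip mode
#' inside the window). Minus-strand windows are scored on the reverse
#' complement read 5' to 3'. Windows containing non-ACGU characters are
#' skipped and counted.
#'
#' @param genome named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet` (see [load_genome()]).
#' @param model a [puf_model()]; use 11-nt windows for 9-position models
#'   and 13-nt for 5'-extended models.
#' @param window_len window length in nt (>= the maximal footprint,
#'   typically 11 or 13).
#' @param policy a [mode_policy()].
#' @param convention an [energy_convention()].
#' @return data.frame: `chrom`, `strand`, `start`, `end` (0-based
#'   half-open genomic), `ddg` (kcal/mol). The number of skipped windows is
#'   attached as attribute `n_skipped`.
#' @export
scan_sequence <- function(genome, model, window_len = 11L,
                          policy = mode_policy(),
                          convention = energy_convention()) {
  if (inherits(genome, "XStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!length(genome) || any(!nzchar(genome))) {
    stop("empty genome or contig")
  }
  if (is.null(names(genome)) || anyNA(names(genome))) {
    stop("genome contigs must be named")
  }
  if (window_len < model_footprint(model)) {
    stop("window_len below the model footprint")
  }
  RT <- convention$RT
  out <- list(); n_skipped <- 0L
  for (chrom in names(genome)) {
    codes <- encode_rna(genome[[chrom]])
    L <- length(codes)
    for (strand in c("+", "-")) {
      sc_codes <- if (strand == "+") codes else rev(5L - codes)
      res <- scan_codes(sc_codes, model, policy, window_len, RT)
      if (!length(res$ddg)) next
      keep <- !res$skipped
      n_skipped <- n_skipped + sum(res$skipped)
      if (!any(keep)) next
      i1 <- which(keep)  # 1-based start on the scanned strand
      start0 <- if (strand == "+") i1 - 1L else L - (i1 - 1L) - window_len
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, strand = strand, start = start0,
        end = start0 + window_len, ddg = res$ddg[keep])
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0),
                         ddg = numeric(0))
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Greedy non-overlapping site selection
#'
#' Sorts windows from highest to lowest affinity (ascending ddG; ties by
#' genomic coordinate, then strand) and removes any window overlapping a
#' window higher on the list. Only windows with `ddg < ddg_max` (strict)
#' are retained. Overlap is strand-agnostic on genomic coordinates by
#' default.
#'
#' @param windows data.frame from [scan_sequence()].
#' @param ddg_max retention threshold in kcal/mol (default 4.0).
#' @param ignore_strand if `TRUE` (default), windows on opposite strands
#'   sharing genomic bases are considered overlapping.
#' @return The selected subset of `windows` (coordinate-sorted), with zero
#'   pairwise overlaps; re-running selection on its own output is the
#'   identity.
#' @export
select_top_sites <- function(windows, ddg_max = 4.0, ignore_strand = TRUE) {
  w <- windows[is.finite(windows$ddg) & windows$ddg < ddg_max, , drop = FALSE]
  if (!nrow(w)) return(w)
  ord <- order(w$ddg, w$chrom, w$start, w$strand)
  gr <- GenomicRanges::GRanges(
    w$chrom, IRanges::IRanges(w$start + 1L, w$end), strand = w$strand)
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = ignore_strand)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  nbr <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  rank <- integer(nrow(w)); rank[ord] <- seq_along(ord)
  keep <- logical(nrow(w))
  for (i in ord) {
    ov <- nbr[[as.character(i)]]
    keep[i] <- !length(ov) || !any(keep[ov])
  }
  out <- w[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best predicted site per 3'UTR
#'
#' Assigns selected windows to 3'UTRs when fully contained within the UTR
#' interval on the matching strand, and reports each gene's best (lowest
#' ddG) site and site count. Genes without an assigned site are reported
#' with `NA` ddG and a zero count.
#'
#' @param sites data.frame from [select_top_sites()].
#' @param utrs data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open; see [load_utr_bed()]).
#' @param require_containment if `FALSE`, partial overlap assigns a window.
#' @return data.frame: `gene_id`, `best_ddg`, `best_start`, `best_end`,
#'   `strand`, `n_sites`.
#' @export
utr_best_sites <- function(sites, utrs, require_containment = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(utrs)))
  if (nrow(sites)) {
    sgr <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$start + 1L, sites$end),
      strand = sites$strand)
    ugr <- GenomicRanges::GRanges(
      utrs$chrom, IRanges::IRanges(utrs$start + 1L, utrs$end),
      strand = utrs$strand)
    hits <- GenomicRanges::findOverlaps(
      sgr, ugr, type = if (require_containment) "within" else "any",
      ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  } else {
    qh <- sh <- integer(0)
  }
  res <- lapply(seq_len(nrow(utrs)), function(u) {
    idx <- qh[sh == u]
    if (!length(idx)) {
      return(data.frame(gene_id = utrs$gene_id[u], best_ddg = NA_real_,
                        best_start = NA_integer_, best_end = NA_integer_,
                        strand = utrs$strand[u], n_sites = 0L))
    }
    s <- sites[idx, , drop = FALSE]
    best <- s[order(s$ddg, s$start), ][1, ]
    data.frame(gene_id = utrs$gene_id[u], best_ddg = best$ddg,
               best_start = best$start, best_end = best$end,
               strand = utrs$strand[u], n_sites = length(idx))
  })
  do.call(rbind, res)
}

#' Pair two models' site affinities into a landscape
#'
#' Joins per-window or per-gene-best affinities under two models into the
#' paired points of an affinity-specificity landscape.
#'
#' @param sites_a,sites_b window tables from the same genome scan
#'   (`by_window`) or per-gene tables from [utr_best_sites()]
#'   (`by_gene_best`).
#' @param join `"by_window"` matches identical coordinates and strand;
#'   `"by_gene_best"` matches gene ids (each model's best site may be a
#'   different window).
#' @return data.frame: `key`, `ddg_a`, `ddg_b` (finite values only).
#' @export
pair_landscape <- function(sites_a, sites_b,
                           join = c("by_window", "by_gene_best")) {
  join <- match.arg(join)
  if (join == "by_window") {
    key_a <- paste(sites_a$chrom, sites_a$strand, sites_a$start, sites_a$end)
    key_b <- paste(sites_b$chrom, sites_b$strand, sites_b$start, sites_b$end)
    shared <- intersect(key_a, key_b)
    if (!length(shared)) {
      stop("no shared windows: disjoint coordinate systems or window lengths")
    }
    out <- data.frame(key = shared,
                      ddg_a = sites_a$ddg[match(shared, key_a)],
                      ddg_b = sites_b$ddg[match(shared, key_b)])
  } else {
    shared <- intersect(sites_a$gene_id, sites_b$gene_id)
    if (!length(shared)) stop("no shared genes")
    out <- data.frame(key = shared,
                      ddg_a = sites_a$best_ddg[match(shared, sites_a$gene_id)],
                      ddg_b = sites_b$best_ddg[match(shared, sites_b$gene_id)])
  }
  out[is.finite(out$ddg_a) & is.finite(out$ddg_b), , drop = FALSE]
}

#' Bin enrichment values by predicted affinity
#'
#' Left-closed bins of width `bin_width` anchored at the minimum predicted
#' ddG; per-bin mean enrichment with a normal-approximation 95% CI of the
#' mean. Genes predicted to bind (`ddg < ddg_max`) but missing an
#' enrichment value receive `default_enrichment`; unpredicted missing genes
#' are dropped. Empty bins are omitted.
#'
#' @param ddg predicted per-gene ddG (kcal/mol).
#' @param enrichment per-gene enrichment (e.g. log2 RIP ratio); `NA`
#'   allowed.
#' @param bin_width bin width in kcal/mol (default 0.5).
#' @param default_enrichment value substituted for predicted-but-unlisted
#'   genes (default 0).
#' @param ddg_max prediction threshold for the substitution (default 4).
#' @return data.frame: `bin_left`, `bin_right`, `mean`, `ci_lower`,
#'   `ci_upper`, `n`.
#' @export
bin_enrichment <- function(ddg, enrichment, bin_width = 0.5,
                           default_enrichment = 0, ddg_max = 4.0) {
  stopifnot(bin_width > 0, length(ddg) == length(enrichment))
  fill <- is.na(enrichment) & ddg < ddg_max
  enrichment[fill] <- default_enrichment
  use <- is.finite(ddg) & !is.na(enrichment)
  ddg <- ddg[use]; enrichment <- enrichment[use]
  if (!length(ddg)) {
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      mean = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0), n = integer(0)))
  }
  lo <- min(ddg)
  idx <- floor((ddg - lo) / bin_width)
  res <- lapply(sort(unique(idx)), function(k) {
    e <- enrichment[idx == k]
    n <- length(e)
    se <- if (n > 1) stats::sd(e) / sqrt(n) else 0
    data.frame(bin_left = lo + k * bin_width,
               bin_right = lo + (k + 1) * bin_width,
               mean = mean(e), ci_lower = mean(e) - 1.96 * se,
               ci_upper = mean(e) + 1.96 * se, n = n)
  })
  do.call(rbind, res)
}
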