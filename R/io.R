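# File formats -----------------------------------------------------------------
#
# TSV (tab-delimited, header row, '.' for missing) is the tabular dialect
# throughout; concentrations are nM at the interface; energies kcal/mol.

#' Load a genome FASTA
#'
#' Reads a (optionally gzipped) multi-contig FASTA, uppercases sequences,
#' and optionally normalizes U/T.
#'
#' @param path FASTA file path.
#' @param as how to normalize the alphabet: `"dna"` (U -> T), `"rna"`
#'   (T -> U), or `"asis"`.
#' @return Named character vector of contig sequences.
#' @export
load_genome <- function(path, as = c("asis", "dna", "rna")) {
  as <- match.arg(as)
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  seqs <- toupper(as.character(ss))
  if (as == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (as == "rna") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(as.character(seqs), names(seqs))),
    path)
  invisible(path)
}

#' Load 3'UTR annotations from a BED6 file
#'
#' Parses BED6 (0-based half-open, name = gene id, strand column honored),
#' rejecting malformed rows (start >= end, unknown strand) with a logged
#' count, and deduplicates by keeping each gene's longest annotated
#' interval.
#'
#' @param path BED6 file path.
#' @return data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`, with
#'   attribute `n_rejected`.
#' @export
load_utr_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "")
  if (ncol(raw) < 6) stop("BED6 requires 6 columns, got ", ncol(raw))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  ok <- !is.na(start) & !is.na(end) & start < end & raw[[6]] %in% c("+", "-")
  n_rejected <- sum(!ok)
  if (n_rejected) {
    message(n_rejected, " malformed BED row(s) rejected")
  }
  d <- data.frame(gene_id = raw[[4]][ok], chrom = raw[[1]][ok],
                  strand = raw[[6]][ok], start = start[ok], end = end[ok])
  # longest interval per gene
  d$len <- d$end - d$start
  d <- d[order(d$gene_id, -d$len, d$chrom, d$start), ]
  d <- d[!duplicated(d$gene_id), , drop = FALSE]
  d$len <- NULL
  rownames(d) <- NULL
  attr(d, "n_rejected") <- n_rejected
  d
}

#' Write predicted sites as BED6 plus a ddG column
#'
#' @param sites data.frame from [select_top_sites()] or [scan_sequence()].
#' @param path output path.
#' @param name_prefix site name prefix.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, name_prefix = "site") {
  bed <- data.frame(
    chrom = sites$chrom, start = sites$start, end = sites$end,
    name = sprintf("%s_%05d", name_prefix, seq_len(nrow(sites))),
    score = 0L, strand = sites$strand,
    ddg_kcal_mol = round(sites$ddg, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write the long-format cluster fluorescence TSV
#'
#' Columns: `cluster_id`, `variant_id`, `concentration_nM`,
#' `normalized_fluorescence`.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cluster_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".")
  need <- c("cluster_id", "variant_id", "concentration_nM",
            "normalized_fluorescence")
  if (!all(need %in% names(d))) {
    stop("cluster table must have columns: ", paste(need, collapse = ", "))
  }
  d
}

#' @rdname read_cluster_table
#' @param tbl data.frame to write.
#' @export
write_cluster_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write a per-variant affinity TSV
#'
#' @param fits variant-fit data.frame (e.g. from [refit_all_variants()]).
#' @param path output path.
#' @export
write_variant_table <- function(fits, path) {
  utils::write.table(fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
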