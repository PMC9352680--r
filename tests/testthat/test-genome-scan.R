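m <- puf4_model()

rc <- function(s) chartr("ACGTU", "UGCAA",
                         paste(rev(strsplit(s, "")[[1]]), collapse = ""))

test_that("window scan matches the per-window ensemble oracle on both strands", {
  set.seed(91)
  g <- c(chrA = paste0("AAAA", "TGTATATAT", "AAAAAA"),
         chrB = random_rna(80))
  sc <- scan_sequence(g, m, window_len = 11)
  expect_true(all(sc$end - sc$start == 11))
  for (i in seq_len(nrow(sc))) {
    w <- substr(g[[sc$chrom[i]]], sc$start[i] + 1, sc$end[i])
    if (sc$strand[i] == "-") w <- rc(w)
    expect_equal(sc$ddg[i], oracle_ensemble(w, m), tolerance = 1e-9)
  }
  # the consensus-centred window attains the minimum
  best <- sc[which.min(sc$ddg), ]
  expect_equal(best$chrom, "chrA")
  expect_true(best$start <= 4 && best$end >= 13)
})

test_that("scanning is strand-symmetric under reverse complement", {
  set.seed(12)
  g <- c(c1 = random_rna(120))
  g_rc <- c(c1 = rc(g[["c1"]]))
  s1 <- scan_sequence(g, m, 11)
  s2 <- scan_sequence(g_rc, m, 11)
  expect_equal(sort(s1$ddg), sort(s2$ddg), tolerance = 1e-12)
  # strand labels swap at mirrored coordinates
  L <- nchar(g[["c1"]])
  plus1 <- s1[s1$strand == "+", ]
  minus2 <- s2[s2$strand == "-", ]
  minus2_mirror <- data.frame(start = L - minus2$end, ddg = minus2$ddg)
  minus2_mirror <- minus2_mirror[order(minus2_mirror$start), ]
  expect_equal(plus1$ddg, minus2_mirror$ddg, tolerance = 1e-12)
})

test_that("ambiguous windows are skipped and counted", {
  g <- c(nn = paste0(strrep("N", 30)))
  sc <- scan_sequence(g, m, 11)
  expect_equal(nrow(sc), 0L)
  expect_equal(attr(sc, "n_skipped"), 2 * (30 - 11 + 1))
  g2 <- c(x = paste0("AAAA", "N", strrep("A", 20)))
  sc2 <- scan_sequence(g2, m, 11)
  expect_true(all(sc2$start > 4 | sc2$end <= 4))
  expect_error(scan_sequence(c(x = ""), m, 11), "empty")
})

test_that("greedy selection is overlap-free, idempotent and strict at 4", {
  w <- data.frame(
    chrom = "c", strand = c("+", "+", "+", "-", "+"),
    start = c(0, 5, 40, 42, 100), end = c(11, 16, 51, 53, 111),
    ddg = c(0.0, 1.0, 2.0, 1.5, 4.0))
  sel <- select_top_sites(w)
  # overlapping pair: only the better survives; strand-agnostic overlap
  expect_true(any(sel$start == 0))
  expect_false(any(sel$start == 5))
  expect_true(any(sel$start == 42))   # beats the + strand window it overlaps
  expect_false(any(sel$start == 40))
  expect_false(any(sel$ddg >= 4.0))   # 4.0 exactly is dropped
  # idempotence
  expect_equal(select_top_sites(sel), sel)
  # zero pairwise overlaps
  gr <- GenomicRanges::GRanges(sel$chrom,
                               IRanges::IRanges(sel$start + 1, sel$end))
  hits <- GenomicRanges::findOverlaps(gr, ignore.strand = TRUE)
  expect_equal(length(hits), nrow(sel))  # self-hits only
  # strand-aware option keeps opposite-strand overlaps
  sel2 <- select_top_sites(w, ignore_strand = FALSE)
  expect_true(all(c(40, 42) %in% sel2$start))
})

test_that("UTR assignment requires containment and reports per-gene bests", {
  sites <- data.frame(
    chrom = "c", strand = "+",
    start = c(10, 30, 95), end = c(21, 41, 106),
    ddg = c(0.5, 2.0, 1.0))
  utrs <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                     strand = c("+", "+"), start = c(0, 90), end = c(50, 100))
  out <- utr_best_sites(sites, utrs)
  expect_equal(out$best_ddg[out$gene_id == "g1"], 0.5)
  expect_equal(out$n_sites[out$gene_id == "g1"], 2L)
  # the site straddling g2's boundary is not assigned
  expect_equal(out$n_sites[out$gene_id == "g2"], 0L)
  expect_true(is.na(out$best_ddg[out$gene_id == "g2"]))
  # best never exceeds any assigned site
  expect_true(all(out$best_ddg[out$n_sites > 0] <= 2.0))
  # strand mismatch blocks assignment
  utrs_m <- utrs; utrs_m$strand <- "-"
  out_m <- utr_best_sites(sites, utrs_m)
  expect_true(all(out_m$n_sites == 0L))
})

test_that("landscapes join by window or per-gene best site", {
  set.seed(5)
  g <- c(c1 = random_rna(150))
  sA <- scan_sequence(g, m, 11)
  expect_equal(pair_landscape(sA, sA)$ddg_a, pair_landscape(sA, sA)$ddg_b)
  # a model with a more favorable 6/7 U flip pulls flip sites below diagonal
  fl2 <- m$flips
  fl2["6/7", "U"] <- fl2["6/7", "U"] - 1
  m2 <- puf_model(m$bound, fl2, name = "fav")
  sB <- scan_sequence(g, m2, 11)
  pl <- pair_landscape(sA, sB)
  expect_true(all(pl$ddg_b <= pl$ddg_a + 1e-6))
  # mismatched window lengths give disjoint coordinates
  sC <- scan_sequence(g, m, 12)
  expect_error(pair_landscape(sA, sC), "no shared windows")
  # per-gene join
  gA <- data.frame(gene_id = c("g1", "g2"), best_ddg = c(0.1, 2))
  gB <- data.frame(gene_id = c("g2", "g3"), best_ddg = c(1, 5))
  pg <- pair_landscape(gA, gB, join = "by_gene_best")
  expect_equal(pg$key, "g2")
})

test_that("13-nt scans with a 5'-extended model honor the upstream terms", {
  ext <- extend_model_5prime(m, list("-2" = c(C = -2)))
  # identical core site, with and without the upstream C at -2
  g <- c(withC = paste0("AAAA", "CA", "UGUAUAUAU", "AAAA"),
         noC  = paste0("AAAA", "AA", "UGUAUAUAU", "AAAA"))
  sc <- scan_sequence(g, ext, window_len = 13)
  best_withC <- min(sc$ddg[sc$chrom == "withC" & sc$strand == "+"])
  best_noC <- min(sc$ddg[sc$chrom == "noC" & sc$strand == "+"])
  # the upstream C is worth its -2 kcal/mol term for the best window, up to
  # the small Boltzmann weight of alternative configurations
  expect_equal(best_withC, best_noC - 2, tolerance = 0.005)
  # per-window values agree with direct enumeration of the extended model
  i <- which.min(sc$ddg)
  w <- substr(g[[sc$chrom[i]]], sc$start[i] + 1, sc$end[i])
  expect_equal(sc$ddg[i], ensemble_ddg(w, ext), tolerance = 1e-9)
  expect_error(scan_sequence(g, ext, window_len = 10), "footprint")
})

test_that("enrichment binning averages within half-kcal bins", {
  expect_equal(bin_enrichment(c(1.1, 1.3), c(2, 4))$mean, 3)
  cb <- bin_enrichment(runif(200, 0, 3), rep(1, 200))
  expect_true(all(cb$mean == 1))
  expect_true(all(cb$ci_upper - cb$ci_lower < 0.01))
  # predicted-but-unlisted genes default to zero enrichment
  be <- bin_enrichment(c(0.1, 0.2, 5), c(NA, 2, NA))
  expect_equal(sum(be$n), 2L)  # the ddg=5 NA row is dropped, 0.1 filled as 0
  expect_equal(be$mean[1], 1)  # (0 + 2) / 2 in the first bin
  # monotone trend is preserved through binning
  set.seed(2)
  dd <- runif(400, 0, 4)
  en <- -dd + rnorm(400, 0, 0.2)
  bm <- bin_enrichment(dd, en)
  expect_true(all(diff(bm$mean) < 0))
})
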