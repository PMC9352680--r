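# Independent brute-force oracle for the register/flip partition function.
# Deliberately written by direct string indexing, sharing no code with the
# package's template machinery.

RT_REF <- 1.9872e-3 * 298.15

oracle_terms <- function(model) {
  list(B = model$bound, F1 = model$flips[, 1:4, drop = FALSE],
       FNN = model$flips[, "NN"])
}

# All configuration energies of `seq` under point-value censoring, all modes.
oracle_config_ddgs <- function(seq, model) {
  ch <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(ch)
  tm <- oracle_terms(model)
  jn <- c("3/4", "4/5", "5/6", "6/7")
  bsum <- function(idx) {
    if (any(!ch[idx] %in% c("A", "C", "G", "U"))) return(NA_real_)
    sum(vapply(1:9, function(p) tm$B[p, ch[idx[p]]], numeric(1)))
  }
  res <- numeric(0)
  if (n >= 9) {
    for (r in 0:(n - 9)) res <- c(res, bsum(r + 1:9))
  }
  if (n >= 10) {
    for (j in 3:6) for (r in 0:(n - 10)) {
      bound <- r + c(1:j, (j + 2):10)
      fch <- ch[r + j + 1]
      if (!fch %in% c("A", "C", "G", "U")) next
      res <- c(res, bsum(bound) + tm$F1[jn[j - 2], fch])
    }
  }
  if (n >= 11) {
    for (j in 3:6) for (r in 0:(n - 11)) {
      bound <- r + c(1:j, (j + 3):11)
      if (any(!ch[r + j + 1:2] %in% c("A", "C", "G", "U"))) next
      res <- c(res, bsum(bound) + tm$FNN[jn[j - 2]])
    }
    for (j1 in 3:5) for (j2 in (j1 + 1):6) for (r in 0:(n - 11)) {
      bound <- r + setdiff(1:11, c(j1 + 1, j2 + 2))
      f1 <- ch[r + j1 + 1]; f2 <- ch[r + j2 + 2]
      if (!all(c(f1, f2) %in% c("A", "C", "G", "U"))) next
      res <- c(res, bsum(bound) + tm$F1[jn[j1 - 2], f1] + tm$F1[jn[j2 - 2], f2])
    }
  }
  res[!is.na(res)]
}

oracle_ensemble <- function(seq, model) {
  d <- oracle_config_ddgs(seq, model)
  if (!length(d)) return(Inf)
  -RT_REF * log(sum(exp(-d / RT_REF)))
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
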