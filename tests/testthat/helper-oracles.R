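# Independent oracles used across the suite. These deliberately take a
# different computational route than the package implementation.

# Exhaustive-enumeration minimum pairing energy: plain recursion over all
# nested structures (no memoization, no DP table). Feasible for n <= 12.
bf_pair_energy <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)[key]
  if (is.na(e)) 0 else unname(e)
}

bf_mfe <- function(seq, min_loop = 3) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i, j - 1)  # j unpaired
    for (k in i:(j - min_loop - 1)) {
      e <- bf_pair_energy(b[k], b[j])
      if (e < 0) {
        left <- if (k > i) rec(i, k - 1) else 0
        best <- min(best, left + rec(k + 1, j - 1) + e)
      }
    }
    best
  }
  if (length(b) < 2) 0 else rec(1, length(b))
}

# Brute-force uORF enumerator: tests every (start, stop) coordinate pair
# directly instead of walking codons from each AUG.
bf_uorfs <- function(utr5, min_codons = 2) {
  s <- toupper(chartr("T", "U", utr5))
  n <- nchar(s)
  stops <- c("UAA", "UAG", "UGA")
  out <- list()
  if (n < min_codons * 3) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  for (a in 1:(n - 2)) {
    if (substr(s, a, a + 2) != "AUG") next
    if (a + 3 > n - 2) next
    for (e in seq(a + 3, n - 2, by = 3)) {
      if (e + 2 > n) break
      cod <- substr(s, e, e + 2)
      inner_ok <- TRUE
      if (e > a + 3) {
        for (m in seq(a + 3, e - 3, by = 3)) {
          if (substr(s, m, m + 2) %in% stops) { inner_ok <- FALSE; break }
        }
      }
      if (!inner_ok) break
      if (cod %in% stops) {
        if ((e + 3 - a) / 3 >= min_codons)
          out[[length(out) + 1]] <- data.frame(start = a - 1L, end = e + 2L)
        break
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# Character-walk TOP check.
bf_top <- function(seq, min_run = 4) {
  ch <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  if (!length(ch) || ch[1] != "C") return(FALSE)
  run <- 0
  for (i in seq_along(ch)[-1]) {
    if (ch[i] %in% c("C", "U")) run <- run + 1 else break
  }
  run >= min_run
}

# Direct sums-of-squares one-way ANOVA F.
oracle_anova1 <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  lev <- unique(groups)
  ssb <- sum(sapply(lev, function(g) {
    sum(groups == g) * (mean(values[groups == g]) - gm)^2
  }))
  ssw <- sum(sapply(lev, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }))
  df1 <- length(lev) - 1
  df2 <- length(values) - length(lev)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2)
}

# Direct sums-of-squares two-way additive ANOVA on a balanced table
# (one observation per cell): response y with factors fa, fb.
oracle_anova2 <- function(y, fa, fb) {
  fa <- as.character(fa); fb <- as.character(fb)
  gm <- mean(y)
  na <- length(unique(fa)); nb <- length(unique(fb))
  ssa <- nb * sum((tapply(y, fa, mean) - gm)^2)
  ssb <- na * sum((tapply(y, fb, mean) - gm)^2)
  sst <- sum((y - gm)^2)
  sse <- sst - ssa - ssb
  dfa <- na - 1; dfb <- nb - 1; dfe <- dfa * dfb
  list(Fa = (ssa / dfa) / (sse / dfe), Fb = (ssb / dfb) / (sse / dfe),
       dfa = dfa, dfb = dfb, dfe = dfe)
}

# Spectral power via explicit cosine/sine sums (no complex arithmetic).
oracle_periodicity <- function(profile, periods = 2:6) {
  x <- profile - mean(profile)
  t <- seq_along(x) - 1
  pw <- sapply(periods, function(p) {
    sum(x * cos(2 * pi * t / p))^2 + sum(x * sin(2 * pi * t / p))^2
  })
  pw[periods == 3] / sum(pw)
}

random_rna_str <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

small_sim <- function(n_genes = 200, seed = 7, ...) {
  sim_config(n_genes = n_genes, seed = seed, library_size = 2e5, ...)
}
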