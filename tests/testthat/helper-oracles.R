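# Independent brute-force oracles: explicit loops over individuals, markers
# and pairs, written directly from the definitions of each statistic. They
# share no code with the package implementations they check.

bruteAlleleFreq <- function(gc12) {
  # gc12: list(a1, a2) markers x individuals allele matrices
  vapply(seq_len(nrow(gc12$a1)), function(m) {
    calls <- c(gc12$a1[m, ], gc12$a2[m, ])
    calls <- calls[!is.na(calls)]
    sum(calls == 1) / length(calls)
  }, numeric(1))
}

bruteHo <- function(a1, a2) {
  vapply(seq_len(nrow(a1)), function(m) {
    ok <- !is.na(a1[m, ]) & !is.na(a2[m, ])
    mean(a1[m, ok] != a2[m, ok])
  }, numeric(1))
}

bruteFis <- function(a1, a2, min_he = 0.05) {
  p <- bruteAlleleFreq(list(a1 = a1, a2 = a2))
  he <- 2 * p * (1 - p)
  ho <- bruteHo(a1, a2)
  keep <- he >= min_he
  1 - mean(ho[keep]) / mean(he[keep])
}

# David et al. multilocus g2 by explicit double loops (pairwise-complete
# individuals per locus pair; unordered pairs, which cancels in the ratio).
bruteG2 <- function(gc) {
  H <- t(gc == 1L)  # individuals x loci, NA for missing
  L <- ncol(H)
  num <- 0
  den <- 0
  for (l in seq_len(L - 1)) {
    for (m in (l + 1):L) {
      comp <- !is.na(H[, l]) & !is.na(H[, m])
      np <- sum(comp)
      if (np < 2) next
      hl <- as.numeric(H[comp, l])
      hm <- as.numeric(H[comp, m])
      s11 <- sum(hl * hm)
      cross <- 0
      for (i in seq_len(np)) {
        for (j in seq_len(np)) {
          if (i != j) cross <- cross + hl[i] * hm[j]
        }
      }
      num <- num + s11 / np
      den <- den + cross / (np * (np - 1))
    }
  }
  num / den - 1
}

# r2 for one marker pair from the 2x2 gamete table
bruteR2pair <- function(g1, g2) {
  # g1, g2: gamete allele vectors (0/1) at the two markers
  n <- length(g1)
  p11 <- sum(g1 == 1 & g2 == 1) / n
  p1 <- mean(g1)
  p2 <- mean(g2)
  D <- p11 - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# windowed effective haplotype number, direct tabulation
bruteWindowHe <- function(a1, a2, widx) {
  s1 <- apply(a1[widx, , drop = FALSE], 2, paste, collapse = "")
  s2 <- apply(a2[widx, , drop = FALSE], 2, paste, collapse = "")
  k <- table(c(s1, s2)) / (2 * ncol(a1))
  1 / sum(k^2)
}

# product-limit estimator by explicit risk-set bookkeeping
bruteKM <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  S <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    S <- S * (1 - d / n_risk)
    out$surv[i] <- S
  }
  out
}
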