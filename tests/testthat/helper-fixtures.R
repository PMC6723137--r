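# Programmatic fixtures: small PhasedGenotypes objects built in code.

# PhasedGenotypes from a character matrix of calls like "0|1"
# (markers x individuals); map defaults to one 50 cM chromosome.
pgFromCalls <- function(calls, map = NULL, phased = TRUE) {
  sp <- if (phased) "|" else "/"
  a1 <- apply(calls, c(1, 2), function(s) {
    v <- substr(s, 1, 1); if (v == ".") NA_integer_ else as.integer(v)
  })
  a2 <- apply(calls, c(1, 2), function(s) {
    v <- substr(s, 3, 3); if (v == ".") NA_integer_ else as.integer(v)
  })
  if (is.null(map)) {
    map <- generateMap(chromosomes = 1, markers_per_chromosome = nrow(calls),
                       length_cm = 50)
  }
  PhasedGenotypes(a1, a2, map, phased = phased)
}

# random phased genotypes, independent alleles at frequency p_alt
randomPG <- function(n_ind, n_markers, chromosomes = 1, p_alt = 0.4,
                     miss = 0, seed = 1) {
  set.seed(seed)
  stopifnot(n_markers %% chromosomes == 0)
  map <- generateMap(chromosomes, n_markers / chromosomes, 50)
  a1 <- matrix(rbinom(n_markers * n_ind, 1, p_alt), n_markers, n_ind)
  a2 <- matrix(rbinom(n_markers * n_ind, 1, p_alt), n_markers, n_ind)
  if (miss > 0) {
    a1[runif(length(a1)) < miss] <- NA
    a2[runif(length(a2)) < miss] <- NA
  }
  PhasedGenotypes(a1, a2, map)
}

# genotypes with exact ALT-allele counts per marker: p must be multiples of
# 1/(2 * n_ind); ALT alleles are laid down deterministically
pgFromFreqs <- function(p, n_ind = 10) {
  n_all <- 2 * n_ind
  stopifnot(all(abs(p * n_all - round(p * n_all)) < 1e-9))
  a1 <- matrix(0L, length(p), n_ind)
  a2 <- matrix(0L, length(p), n_ind)
  for (m in seq_along(p)) {
    k <- round(p[m] * n_all)
    alleles <- c(rep(1L, k), rep(0L, n_all - k))
    a1[m, ] <- alleles[seq_len(n_ind)]
    a2[m, ] <- alleles[n_ind + seq_len(n_ind)]
  }
  map <- generateMap(1, length(p), 50)
  PhasedGenotypes(a1, a2, map)
}

# Hardy-Weinberg sample: alleles drawn independently at given frequencies
hwPG <- function(n_ind, p_vec, seed = 1) {
  set.seed(seed)
  L <- length(p_vec)
  a1 <- matrix(rbinom(L * n_ind, 1, rep(p_vec, n_ind)), L, n_ind)
  a2 <- matrix(rbinom(L * n_ind, 1, rep(p_vec, n_ind)), L, n_ind)
  PhasedGenotypes(a1, a2, generateMap(1, L, 50))
}

# every individual heterozygous at every marker
fullyHetPG <- function(n_ind, chromosomes = 6, markers_per_chromosome = 20) {
  map <- generateMap(chromosomes, markers_per_chromosome, 50)
  L <- nrow(map)
  PhasedGenotypes(matrix(0L, L, n_ind), matrix(1L, L, n_ind), map)
}
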