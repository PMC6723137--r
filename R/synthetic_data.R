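## Synthetic-data generators: genetic maps, populations evolved under a
## chosen selfing rate (with optional viability selection), inbred-line
## panels, and line-extinction records. These give every pipeline stage a
## test surface with known ground truth, emulating the motivating design:
## ~743 SNPs on 6 chromosomes of 50 cM, 16-individual phased samples, and
## line assays of 13-16 generations.

#' Generate an evenly spaced genetic map
#'
#' Markers are placed evenly in cM on each chromosome over
#' `[0, length_cm]`; with one marker per chromosome the position is 0.
#'
#' @param chromosomes Number of chromosomes (default 6).
#' @param markers_per_chromosome Markers on each chromosome.
#' @param length_cm Chromosome map length in cM (default 50, an F2-scale
#'   map).
#' @return Map `data.frame` (`marker_id`, `chromosome`, `position_cM`).
#' @export
generateMap <- function(chromosomes = 6, markers_per_chromosome = 124,
                        length_cm = 50) {
  out <- lapply(seq_len(chromosomes), function(ch) {
    n <- markers_per_chromosome
    pos <- if (n == 1) 0 else seq(0, length_cm, length.out = n)
    data.frame(
      marker_id = sprintf("chr%d_m%03d", ch, seq_len(n)),
      chromosome = paste0("chr", ch),
      position_cM = pos,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Specify viability selection for the synthetic generators
#'
#' Multiplicative viability over the given loci. Writing the selection
#' coefficient as `s'` (the plain `s` is reserved for the selfing rate):
#' `recessive_deleterious` gives genotype fitness `1`, `1 - h s'`, `1 - s'`
#' for 0/1/2 copies of the ALT allele; `overdominant` gives heterozygote
#' fitness 1 and both homozygotes `1 - s'`; `repulsion_lethals` is recessive
#' lethality (`s' = 1, h = 0`) at pairs of loci whose founder alleles are
#' arranged in repulsion phase, which behaves as effective overdominance
#' across the pair.
#'
#' @param mode One of `"neutral"`, `"recessive_deleterious"`,
#'   `"overdominant"`, `"repulsion_lethals"`.
#' @param loci Global marker indices under selection (pairs, in order, for
#'   `repulsion_lethals`).
#' @param s_coef Selection coefficient(s) `s'` in `[0, 1]`, recycled over loci.
#' @param h Dominance coefficient for `recessive_deleterious` (default 0).
#' @return A `selectionSpec` list.
#' @export
selectionSpec <- function(mode = c("neutral", "recessive_deleterious",
                                   "overdominant", "repulsion_lethals"),
                          loci = integer(), s_coef = 0, h = 0) {
  mode <- match.arg(mode)
  if (mode == "repulsion_lethals") {
    if (length(loci) %% 2 != 0) stop("repulsion_lethals needs pairs of loci")
    s_coef <- 1
    h <- 0
  }
  stopifnot(all(s_coef >= 0), all(s_coef <= 1), h >= 0, h <= 1)
  structure(list(mode = mode, loci = as.integer(loci),
                 s_coef = rep_len(s_coef, max(length(loci), 1L)), h = h),
            class = "selectionSpec")
}

## Viability of offspring given stacked haplotype lists and a selectionSpec.
## Returns a numeric vector of fitness values in [0, 1], one per column.
.viability <- function(hapsA, hapsB, idx, sel) {
  ncols <- ncol(hapsA[[1]])
  w <- rep(1, ncols)
  if (is.null(sel) || sel$mode == "neutral" || !length(sel$loci)) return(w)
  ## locate each selected locus: chromosome and row within it
  for (k in seq_along(sel$loci)) {
    loc <- sel$loci[k]
    ch <- which(vapply(idx, function(i) loc %in% i, logical(1)))[1]
    row <- match(loc, idx[[ch]])
    g <- hapsA[[ch]][row, ] + hapsB[[ch]][row, ]
    sc <- sel$s_coef[k]
    wl <- if (sel$mode == "overdominant") {
      ifelse(g == 1L, 1, 1 - sc)
    } else {  # recessive_deleterious / repulsion_lethals
      ifelse(g == 2L, 1 - sc, ifelse(g == 1L, 1 - sel$h * sc, 1))
    }
    w <- w * wl
  }
  w
}

## Founder haplotype pool: markers x n_hap 0/1 matrix with every marker
## polymorphic; repulsion pairs arranged in opposite phase when requested.
.founderPool <- function(n_markers, n_hap, sel = NULL) {
  pool <- matrix(stats::rbinom(n_markers * n_hap, 1, 0.5), n_markers, n_hap)
  mono <- rowSums(pool) %in% c(0L, n_hap)
  if (any(mono)) {
    flip <- sample.int(n_hap, sum(mono), replace = TRUE)
    pool[cbind(which(mono), flip)] <- 1L - pool[cbind(which(mono), flip)]
  }
  if (!is.null(sel) && sel$mode == "repulsion_lethals") {
    odd <- seq_len(n_hap) %% 2 == 1
    for (pr in seq_len(length(sel$loci) / 2)) {
      l1 <- sel$loci[2 * pr - 1]
      l2 <- sel$loci[2 * pr]
      pool[l1, ] <- as.integer(odd)    # lethal 1 on odd haplotypes
      pool[l2, ] <- as.integer(!odd)   # lethal 2 on even: repulsion phase
    }
  }
  storage.mode(pool) <- "integer"
  pool
}

#' Evolve a population under a chosen selfing rate
#'
#' Forward simulation of a population with mixed mating: each offspring is
#' produced by selfing with probability `s` and by outcrossing between two
#' distinct random parents otherwise, with meiosis under complete crossover
#' interference ([meiosis()]). Optional multiplicative viability selection
#' ([selectionSpec()]) is applied by rejection: candidate offspring survive
#' with probability equal to their fitness. Founders are assembled from a
#' pool of distinct haplotypes (default 16) so the starting sample carries
#' realistic polymorphism and linkage.
#'
#' At neutral mixed-mating equilibrium the inbreeding coefficient converges
#' to `Fis = s / (2 - s)` (0 at `s = 0`, 1/3 at `s = 0.5`, 1 at `s = 1`), and
#' identity disequilibrium g2 is positive only for intermediate `s`.
#'
#' @param s Selfing rate in `[0, 1]`.
#' @param N Population size.
#' @param generations Generations to evolve.
#' @param map Genetic map `data.frame` (see [generateMap()]).
#' @param founder_haplotypes Number of distinct founder haplotypes, or an
#'   explicit markers x haplotypes 0/1 matrix.
#' @param selection Optional [selectionSpec()].
#' @param sample_size Individuals in the returned phased sample (default 16).
#' @param seed Optional integer seed.
#' @return List with `sample` (a [PhasedGenotypes-class] of `sample_size`
#'   individuals) and `truth` (selfing rate, full-population allele
#'   frequencies, realized Fis and Ho/He of the full population).
#' @export
evolvePopulation <- function(s, N, generations, map, founder_haplotypes = 16,
                             selection = NULL, sample_size = 16, seed = NULL) {
  stopifnot(s >= 0, s <= 1, N >= 2)
  if (!is.null(seed)) set.seed(seed)
  idx <- .chromosomeIndex(map)
  posl <- lapply(idx, function(i) map$position_cM[i])
  L <- nrow(map)
  pool <- if (is.matrix(founder_haplotypes)) {
    storage.mode(founder_haplotypes) <- "integer"
    founder_haplotypes
  } else {
    .founderPool(L, founder_haplotypes, selection)
  }
  hA <- pool[, sample.int(ncol(pool), N, replace = TRUE), drop = FALSE]
  hB <- pool[, sample.int(ncol(pool), N, replace = TRUE), drop = FALSE]
  hapsA <- lapply(idx, function(i) hA[i, , drop = FALSE])
  hapsB <- lapply(idx, function(i) hB[i, , drop = FALSE])
  for (g in seq_len(generations)) {
    accA <- lapply(idx, function(i) matrix(0L, length(i), 0))
    accB <- accA
    got <- 0L
    tries <- 0L
    while (got < N) {
      tries <- tries + 1L
      if (tries > 50L) {
        stop("population went effectively extinct under selection; ",
             "use weaker selection coefficients")
      }
      nb <- N
      selfer <- stats::runif(nb) < s
      p1 <- sample.int(N, nb, replace = TRUE)
      p2 <- sample.int(N, nb, replace = TRUE)
      clash <- !selfer & p2 == p1
      while (any(clash)) {   # outcrossing needs two distinct parents
        p2[clash] <- sample.int(N, sum(clash), replace = TRUE)
        clash <- !selfer & p2 == p1
      }
      p2[selfer] <- p1[selfer]
      offA <- vector("list", length(idx))
      offB <- vector("list", length(idx))
      for (ch in seq_along(idx)) {
        offA[[ch]] <- .meiosisStack(hapsA[[ch]][, p1, drop = FALSE],
                                    hapsB[[ch]][, p1, drop = FALSE],
                                    posl[[ch]])
        offB[[ch]] <- .meiosisStack(hapsA[[ch]][, p2, drop = FALSE],
                                    hapsB[[ch]][, p2, drop = FALSE],
                                    posl[[ch]])
      }
      w <- .viability(offA, offB, idx, selection)
      keep <- stats::runif(nb) < w
      if (any(keep)) {
        for (ch in seq_along(idx)) {
          accA[[ch]] <- cbind(accA[[ch]], offA[[ch]][, keep, drop = FALSE])
          accB[[ch]] <- cbind(accB[[ch]], offB[[ch]][, keep, drop = FALSE])
        }
        got <- got + sum(keep)
      }
    }
    hapsA <- lapply(accA, function(m) m[, seq_len(N), drop = FALSE])
    hapsB <- lapply(accB, function(m) m[, seq_len(N), drop = FALSE])
  }
  ## full-population truth
  fullA <- do.call(rbind, hapsA)[order(unlist(idx)), , drop = FALSE]
  fullB <- do.call(rbind, hapsB)[order(unlist(idx)), , drop = FALSE]
  p <- (rowSums(fullA) + rowSums(fullB)) / (2 * N)
  he <- 2 * p * (1 - p)
  ho <- rowMeans(fullA != fullB)
  fis <- if (mean(he) > 0) 1 - mean(ho) / mean(he) else NA_real_
  samp <- sample.int(N, min(sample_size, N))
  sp <- list(idx = idx, map = map)
  pg <- .assemblePG(lapply(seq_along(idx), function(ch) hapsA[[ch]][, samp, drop = FALSE]),
                    lapply(seq_along(idx), function(ch) hapsB[[ch]][, samp, drop = FALSE]),
                    sp, ids = sprintf("ind%03d", seq_along(samp)))
  list(
    sample = pg,
    truth = list(selfing_rate = s, N = N, generations = generations,
                 allele_freq = p, mean_He = mean(he), mean_Ho = mean(ho),
                 Fis = fis)
  )
}

#' Derive inbred lines from a population sample
#'
#' Samples `n_lines` founders with replacement from the individuals of `x`
#' and selfs each independently for `generations` generations. With a
#' [selectionSpec()], viability selection acts within each line's brood:
#' every generation, `brood_size` candidate offspring are produced per line
#' and one is kept with probability proportional to its viability (uniformly
#' if the whole brood has viability zero, mirroring the practice of rescuing
#' a failing line from backup offspring). Because survival within a brood
#' depends on relative viability, loci fixed homozygous in a line no longer
#' influence which of its offspring continues, while segregating
#' deleterious-recessive or overdominant loci are selected against --
#' the returned panel represents surviving, viability-filtered lines.
#'
#' @param x A phased [PhasedGenotypes-class] population sample.
#' @param generations Selfing generations.
#' @param n_lines Number of lines to derive.
#' @param selection Optional [selectionSpec()].
#' @param brood_size Candidate offspring per line and generation under
#'   selection (default 25); ignored for neutral derivation.
#' @param seed Optional integer seed.
#' @return A [PhasedGenotypes-class] object with `n_lines` individuals.
#' @export
deriveInbredLines <- function(x, generations, n_lines, selection = NULL,
                              brood_size = 25, seed = NULL) {
  .stopIfUnphased(x, "deriveInbredLines")
  if (!is.null(seed)) set.seed(seed)
  sp <- .splitHaps(x)
  f <- sample.int(nIndividuals(x), n_lines, replace = TRUE)
  hapsA <- lapply(sp$A, function(m) m[, f, drop = FALSE])
  hapsB <- lapply(sp$B, function(m) m[, f, drop = FALSE])
  neutral <- is.null(selection) || selection$mode == "neutral" ||
    !length(selection$loci)
  K <- if (neutral) 1L else as.integer(brood_size)
  par_cols <- rep(seq_len(n_lines), each = K)
  for (g in seq_len(generations)) {
    offA <- vector("list", length(hapsA))
    offB <- vector("list", length(hapsA))
    for (ch in seq_along(hapsA)) {
      pa <- hapsA[[ch]][, par_cols, drop = FALSE]
      pb <- hapsB[[ch]][, par_cols, drop = FALSE]
      offA[[ch]] <- .meiosisStack(pa, pb, sp$pos[[ch]])
      offB[[ch]] <- .meiosisStack(pa, pb, sp$pos[[ch]])
    }
    if (neutral) {
      hapsA <- offA
      hapsB <- offB
    } else {
      w <- .viability(offA, offB, sp$idx, selection)
      pick <- vapply(seq_len(n_lines), function(l) {
        wl <- w[(l - 1L) * K + seq_len(K)]
        if (sum(wl) == 0) wl <- rep(1, K)
        (l - 1L) * K + sample.int(K, 1L, prob = wl)
      }, integer(1))
      for (ch in seq_along(hapsA)) {
        hapsA[[ch]] <- offA[[ch]][, pick, drop = FALSE]
        hapsB[[ch]] <- offB[[ch]][, pick, drop = FALSE]
      }
    }
  }
  .assemblePG(hapsA, hapsB, sp, ids = sprintf("line%03d", seq_len(n_lines)))
}

#' Generate synthetic line-extinction records
#'
#' Extinction times are geometric with the given per-generation hazard,
#' truncated at `assay_length`; lines surviving the assay are censored at
#' `assay_length`.
#'
#' @param n_lines Number of lines.
#' @param hazard Per-generation extinction probability in `[0, 1]`.
#' @param assay_length Assay length in generations (16 for ancestral-style
#'   assays, 13 otherwise).
#' @param population,block Labels for the records.
#' @param seed Optional integer seed.
#' @return Line-record `data.frame` (see [readLineRecords()]).
#' @export
generateLineExtinctions <- function(n_lines, hazard, assay_length,
                                    population = "pop", block = "block1",
                                    seed = NULL) {
  stopifnot(hazard >= 0, hazard <= 1, assay_length >= 1)
  if (!is.null(seed)) set.seed(seed)
  time <- if (hazard == 0) {
    rep(Inf, n_lines)
  } else {
    stats::rgeom(n_lines, hazard) + 1
  }
  extinct <- time <= assay_length
  data.frame(
    line_id = sprintf("%s_L%04d", population, seq_len(n_lines)),
    population = population,
    block = block,
    generations_survived = as.integer(ifelse(extinct, time, assay_length)),
    status = ifelse(extinct, "extinct", "censored"),
    stringsAsFactors = FALSE
  )
}
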