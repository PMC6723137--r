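#' Per-marker ALT allele frequencies
#'
#' Frequencies are computed over non-missing allele calls only; a marker
#' where every call is missing gets `NA` (and is flagged with a warning).
#'
#' @param x A [PhasedGenotypes-class] object.
#' @return Named numeric vector, one ALT frequency per marker.
#' @export
alleleFrequencies <- function(x) {
  a1 <- hapAlleles(x, 1)
  a2 <- hapAlleles(x, 2)
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  tot <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  p <- alt / tot
  if (any(tot == 0)) {
    p[tot == 0] <- NA_real_
    warning(sum(tot == 0), " marker(s) with all calls missing; frequency undefined")
  }
  names(p) <- rownames(x)
  p
}

## per-chromosome means averaged across chromosomes (default), or flat mean
.genomeMean <- function(values, map, average) {
  if (average == "flat") return(mean(values, na.rm = TRUE))
  chr <- factor(map$chromosome, levels = unique(map$chromosome))
  mean(tapply(values, chr, mean, na.rm = TRUE), na.rm = TRUE)
}

#' Expected heterozygosity (He)
#'
#' `He = 2pq = 1 - (p^2 + q^2)` per biallelic marker. The genome-wide value
#' averages per-chromosome means across chromosomes by default
#' (`average = "flat"` gives the unweighted mean over all markers).
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param per_marker Return the per-marker vector instead of the mean.
#' @param average `"chromosome"` or `"flat"`.
#' @return Numeric scalar, or per-marker vector.
#' @export
expectedHet <- function(x, per_marker = FALSE, average = c("chromosome", "flat")) {
  average <- match.arg(average)
  p <- alleleFrequencies(x)
  he <- 2 * p * (1 - p)
  if (per_marker) return(he)
  .genomeMean(he, geneticMap(x), average)
}

#' Observed heterozygosity (Ho)
#'
#' Per marker, the proportion of heterozygous individuals among individuals
#' with complete (both-allele) calls at that marker.
#'
#' @inheritParams expectedHet
#' @return Numeric scalar, or per-marker vector.
#' @export
observedHet <- function(x, per_marker = FALSE, average = c("chromosome", "flat")) {
  average <- match.arg(average)
  gc <- genotypeCodes(x)
  ho <- rowMeans(gc == 1L, na.rm = TRUE)
  if (per_marker) return(ho)
  .genomeMean(ho, geneticMap(x), average)
}

#' Multilocus inbreeding coefficient (Fis)
#'
#' `Fis = 1 - Ho/He` in the multilocus ratio-of-means form: one minus the
#' ratio of the mean observed to the mean expected heterozygosity over
#' markers passing the He filter. Markers with `He < min_he` are removed
#' before the calculation, which avoids the instability of per-locus ratios
#' at nearly monomorphic SNPs.
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param min_he Minimum per-marker He for inclusion (default 0.05).
#' @return Numeric scalar in `(-Inf, 1]`; `Fis = 1` iff no heterozygotes at
#'   the retained markers.
#' @export
inbreedingCoefficient <- function(x, min_he = 0.05) {
  he <- expectedHet(x, per_marker = TRUE)
  keep <- !is.na(he) & he >= min_he
  if (!any(keep)) {
    stop("no markers pass the He >= ", min_he, " filter; Fis is undefined")
  }
  ho <- observedHet(x, per_marker = TRUE)[keep]
  1 - mean(ho, na.rm = TRUE) / mean(he[keep])
}

#' Identity disequilibrium (g2)
#'
#' The standardized excess of two-locus heterozygosity,
#' `g2 = E[h_i h_j] / (E[h_i] E[h_j]) - 1` averaged over marker pairs, where
#' `h` is the per-individual heterozygosity indicator. Uses the finite-sample
#' multilocus estimator of David et al. (2007): a ratio of sums over marker
#' pairs, with the cross-product term estimated from ordered pairs of
#' distinct individuals. Missing data are handled per marker pair using
#' individuals with complete calls at both markers. Phase is not used.
#'
#' g2 is positive when individuals vary in their realized inbreeding (as
#' under partial selfing) and zero under random mating or when all
#' individuals are equally heterozygous. It is undefined when no individual
#' is heterozygous anywhere (e.g. fully selfing populations).
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param n_boot Bootstrap replicates (over individuals) for the SE; 0 skips.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `g2`, `se`, `n_boot`, `boot` (replicate values).
#' @references David P., Pujol B., Viard F., Castella V., Goudet J. (2007)
#'   Reliable selfing rate estimates from imperfect population genetic data.
#'   Molecular Ecology 16:2474-2487.
#' @export
identityDisequilibrium <- function(x, n_boot = 100, seed = NULL) {
  gc <- genotypeCodes(x)
  if (nrow(gc) < 2) stop("g2 needs at least 2 markers")
  if (ncol(gc) < 2) stop("g2 needs at least 2 individuals")
  H <- t(gc == 1L)              # individuals x loci, NA where missing
  g2 <- .g2FromHet(H)
  if (is.na(g2)) {
    stop("g2 is undefined: no heterozygotes (or no informative marker pairs)")
  }
  boot <- numeric(0)
  se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(H)
    boot <- vapply(seq_len(n_boot), function(b) {
      .g2FromHet(H[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    se <- stats::sd(boot, na.rm = TRUE)
  }
  list(g2 = g2, se = se, n_boot = n_boot, boot = boot)
}

## H: individuals x loci logical heterozygosity indicators (NA = missing).
## Ratio-of-sums estimator over ordered pairs of distinct loci; returns NA
## when the denominator is zero (no heterozygotes anywhere).
.g2FromHet <- function(H) {
  M <- !is.na(H)
  H0 <- H
  H0[!M] <- FALSE
  H0 <- matrix(as.numeric(H0), nrow(H), ncol(H))
  Mn <- matrix(as.numeric(M), nrow(H), ncol(H))
  S11 <- crossprod(H0)              # sum_i h_il h_im (complete at both)
  S1 <- crossprod(H0, Mn)           # S1[l,m] = sum over C_lm of h_il
  Np <- crossprod(Mn)               # individuals complete at both loci
  cross <- S1 * t(S1) - S11         # ordered pairs i != j within C_lm
  use <- Np >= 2
  diag(use) <- FALSE
  if (!any(use)) return(NA_real_)
  num <- sum(S11[use] / Np[use])
  den <- sum(cross[use] / (Np[use] * (Np[use] - 1)))
  if (den == 0) return(NA_real_)
  num / den - 1
}

#' Effective number of haplotypes (he) in SNP windows
#'
#' Haplotypes are defined in non-overlapping windows of `window` consecutive
#' SNPs tiling each chromosome left to right (a trailing remainder shorter
#' than `window` is dropped). Within a window each phased individual
#' contributes its two window haplotypes (`unit = "haploid"`, the default);
#' `unit = "diploid"` counts the unordered pair of window haplotypes as one
#' unit per individual. Individuals with any missing call in a window are
#' dropped from that window only. For haplotype proportions `k_i`,
#' `he = 1 / sum(k_i^2)` -- the number of equally frequent haplotypes giving
#' the observed haplotype homozygosity.
#'
#' @param x A phased [PhasedGenotypes-class] object.
#' @param window Window size in SNPs (default 10).
#' @param unit `"haploid"` or `"diploid"` counting unit.
#' @param average `"chromosome"` (per-chromosome window means averaged) or
#'   `"flat"` (mean over all windows).
#' @return List with `mean_he` and `windows` (a `data.frame` with one row per
#'   window: chromosome, first/last marker, number of units, distinct
#'   haplotypes, `he`).
#' @export
effectiveHaplotypeNumber <- function(x, window = 10,
                                     unit = c("haploid", "diploid"),
                                     average = c("chromosome", "flat")) {
  unit <- match.arg(unit)
  average <- match.arg(average)
  .stopIfUnphased(x, "effectiveHaplotypeNumber")
  map <- geneticMap(x)
  a1 <- hapAlleles(x, 1)
  a2 <- hapAlleles(x, 2)
  out <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    nwin <- length(idx) %/% window
    if (nwin == 0) next
    for (w in seq_len(nwin)) {
      widx <- idx[((w - 1) * window + 1):(w * window)]
      h1 <- a1[widx, , drop = FALSE]
      h2 <- a2[widx, , drop = FALSE]
      complete <- colSums(is.na(h1)) == 0 & colSums(is.na(h2)) == 0
      if (!any(complete)) next
      s1 <- apply(h1[, complete, drop = FALSE], 2, paste, collapse = "")
      s2 <- apply(h2[, complete, drop = FALSE], 2, paste, collapse = "")
      units <- if (unit == "haploid") {
        c(s1, s2)
      } else {
        paste(pmin(s1, s2), pmax(s1, s2), sep = "/")
      }
      k <- table(units) / length(units)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr,
        first_marker = map$marker_id[widx[1]],
        last_marker = map$marker_id[widx[window]],
        n_units = length(units),
        n_haplotypes = length(k),
        he = 1 / sum(k^2),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    stop("no chromosome has at least ", window, " markers; cannot form windows")
  }
  windows <- do.call(rbind, out)
  mean_he <- if (average == "flat") {
    mean(windows$he)
  } else {
    mean(tapply(windows$he, factor(windows$chromosome,
                                   levels = unique(windows$chromosome)), mean))
  }
  list(mean_he = mean_he, windows = windows)
}

#' Average a metric over subsets of fixed size (sample-size matching)
#'
#' Evaluates `metric` on subsets of exactly `subset_size` individuals and
#' returns the average -- delete-d jackknife resampling used to compare a
#' large panel of inbred lines against a fixed-size population sample on an
#' equal footing. All subsets are enumerated when there are no more than
#' `n_subsets` of them; otherwise `n_subsets` distinct random subsets are
#' drawn.
#'
#' @param metric Function taking a [PhasedGenotypes-class] object and
#'   returning a numeric scalar.
#' @param x A [PhasedGenotypes-class] object.
#' @param subset_size Individuals per subset (default 16).
#' @param n_subsets Maximum number of subsets (default 100).
#' @param seed Optional seed for random subset draws.
#' @return List with `mean`, `values` (per-subset), and `n_subsets`.
#' @export
jackknifeMatch <- function(metric, x, subset_size = 16, n_subsets = 100,
                           seed = NULL) {
  n <- nIndividuals(x)
  if (n < subset_size) {
    warning("only ", n, " individuals (< subset_size = ", subset_size,
            "); metric computed on the full sample")
    v <- metric(x)
    return(list(mean = v, values = v, n_subsets = 1L))
  }
  if (n == subset_size) {
    v <- metric(x)
    return(list(mean = v, values = v, n_subsets = 1L))
  }
  ncomb <- choose(n, subset_size)
  if (ncomb <= n_subsets) {
    subs <- utils::combn(n, subset_size, simplify = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    subs <- replicate(n_subsets, sort(sample.int(n, subset_size)),
                      simplify = FALSE)
  }
  vals <- vapply(subs, function(s) metric(x[, s]), numeric(1))
  list(mean = mean(vals), values = vals, n_subsets = length(vals))
}

#' Correlation of allele-frequency changes across two episodes
#'
#' For matched marker sets in an ancestral sample `gA`, an evolved sample
#' `gB` and derived inbred lines `gC`, computes per-marker changes
#' `d1 = p_B - p_A` (experimental evolution) and `d2 = p_C - p_B`
#' (inbreeding), and returns their Pearson correlation over markers
#' polymorphic in `gA`. A strong negative correlation indicates that
#' inbreeding reverses the frequency changes seen during evolution --
#' a signature of balancing selection during the evolution phase.
#'
#' @param gA,gB,gC [PhasedGenotypes-class] objects with identical marker sets.
#' @return Pearson correlation coefficient.
#' @export
frequencyChangeCorrelation <- function(gA, gB, gC) {
  if (!identical(rownames(gA), rownames(gB)) ||
      !identical(rownames(gA), rownames(gC))) {
    stop("the three genotype sets must share an identical marker set")
  }
  pA <- alleleFrequencies(gA)
  pB <- alleleFrequencies(gB)
  pC <- alleleFrequencies(gC)
  poly <- !is.na(pA) & pA > 0 & pA < 1 & !is.na(pB) & !is.na(pC)
  if (sum(poly) < 3) {
    stop("fewer than 3 shared markers polymorphic in the ancestral sample")
  }
  d1 <- pB[poly] - pA[poly]
  d2 <- pC[poly] - pB[poly]
  stats::cor(d1, d2, method = "pearson")
}

#' Per-population diversity report
#'
#' One-stop summary: genome-wide mean He, Ho, multilocus Fis (after the
#' He filter), identity disequilibrium g2 with bootstrap SE, and windowed
#' effective haplotype number. g2 is reported as `NA` where undefined (no
#' heterozygotes); he is `NA` for unphased input.
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param population Population label for the report row.
#' @param min_he He filter for Fis (default 0.05).
#' @param window Window size in SNPs for he (default 10).
#' @param n_boot Bootstrap replicates for the g2 SE.
#' @param seed Optional seed (g2 bootstrap).
#' @param average Genome-wide averaging mode, see [expectedHet()].
#' @return One-row `data.frame`.
#' @export
diversityReport <- function(x, population = "pop", min_he = 0.05, window = 10,
                            n_boot = 100, seed = NULL,
                            average = c("chromosome", "flat")) {
  average <- match.arg(average)
  he_m <- expectedHet(x, per_marker = TRUE)
  n_used <- sum(!is.na(he_m) & he_m >= min_he)
  fis <- tryCatch(inbreedingCoefficient(x, min_he = min_he),
                  error = function(e) NA_real_)
  g2res <- tryCatch(identityDisequilibrium(x, n_boot = n_boot, seed = seed),
                    error = function(e) list(g2 = NA_real_, se = NA_real_))
  hap <- if (isPhased(x)) {
    tryCatch(effectiveHaplotypeNumber(x, window = window, average = average)$mean_he,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  data.frame(
    population = population,
    mean_He = expectedHet(x, average = average),
    mean_Ho = observedHet(x, average = average),
    Fis = fis,
    g2 = g2res$g2,
    g2_se = g2res$se,
    mean_he = hap,
    n_markers_used = n_used,
    filters_applied = sprintf("He>=%g for Fis; %d-SNP windows for he", min_he, window),
    stringsAsFactors = FALSE
  )
}
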