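## Neutral forward simulation of inbred-line derivation by selfing.
##
## Meiosis model: complete crossover interference -- at most one crossover
## per chromosome per meiosis. The crossover probability equals the map
## length in Morgans (capped at 1; 0.5 for a 50 cM chromosome) and, given a
## crossover, its position falls between two consecutive SNPs with
## probability proportional to the cM length of that interval.

## A, B: markers x lineages matrices (the two haplotypes of each lineage on
## one chromosome); pos: cM positions. One independent meiosis per lineage.
.meiosisStack <- function(A, B, pos) {
  L <- nrow(A)
  M <- ncol(A)
  startA <- stats::runif(M) < 0.5
  S <- A
  S[, !startA] <- B[, !startA, drop = FALSE]
  if (L >= 2) {
    lens <- diff(pos)
    tot <- sum(lens)
    if (tot > 0) {
      pco <- min(tot / 100, 1)           # cM -> Morgans, capped
      co <- stats::runif(M) < pco
      if (any(co)) {
        O <- B
        O[, !startA] <- A[, !startA, drop = FALSE]
        k <- sample.int(L - 1L, sum(co), replace = TRUE, prob = lens)
        cols <- which(co)
        take <- outer(seq_len(L), k, ">")  # markers after the cut come from O
        Sc <- S[, cols, drop = FALSE]
        Oc <- O[, cols, drop = FALSE]
        Sc[take] <- Oc[take]
        S[, cols] <- Sc
      }
    }
  }
  S
}

#' Simulate one meiosis on a single chromosome
#'
#' Produces one gamete from a phased diploid parent under complete crossover
#' interference: with probability equal to the chromosome's map length in
#' Morgans (capped at 1) a single crossover is placed between two consecutive
#' markers with probability proportional to the interval's cM length;
#' otherwise an unrecombined parental haplotype is returned (each with
#' probability 1/2). A one-marker or zero-length chromosome can never
#' recombine.
#'
#' @param h1,h2 Parental haplotypes: equal-length vectors of 0/1 (or `NA`)
#'   allele calls on one chromosome, in map order.
#' @param pos cM positions of the markers (non-decreasing).
#' @return Gamete haplotype vector.
#' @export
meiosis <- function(h1, h2, pos) {
  stopifnot(length(h1) == length(h2), length(h1) == length(pos))
  drop(.meiosisStack(matrix(h1, ncol = 1), matrix(h2, ncol = 1), pos))
}

## hapsA/hapsB: lists per chromosome of markers x lineages matrices.
.selfStack <- function(hapsA, hapsB, posl, generations) {
  for (g in seq_len(generations)) {
    for (ch in seq_along(hapsA)) {
      g1 <- .meiosisStack(hapsA[[ch]], hapsB[[ch]], posl[[ch]])
      g2 <- .meiosisStack(hapsA[[ch]], hapsB[[ch]], posl[[ch]])
      hapsA[[ch]] <- g1
      hapsB[[ch]] <- g2
    }
  }
  list(A = hapsA, B = hapsB)
}

.splitHaps <- function(x) {
  map <- geneticMap(x)
  idx <- .chromosomeIndex(map)
  a1 <- hapAlleles(x, 1)
  a2 <- hapAlleles(x, 2)
  list(
    A = lapply(idx, function(i) a1[i, , drop = FALSE]),
    B = lapply(idx, function(i) a2[i, , drop = FALSE]),
    pos = lapply(idx, function(i) map$position_cM[i]),
    idx = idx,
    map = map
  )
}

.assemblePG <- function(hapsA, hapsB, sp, ids = NULL, phased = TRUE) {
  a1 <- do.call(rbind, hapsA)
  a2 <- do.call(rbind, hapsB)
  ord <- order(unlist(sp$idx))
  a1 <- a1[ord, , drop = FALSE]
  a2 <- a2[ord, , drop = FALSE]
  if (!is.null(ids)) colnames(a1) <- colnames(a2) <- ids
  PhasedGenotypes(a1, a2, sp$map, phased = phased)
}

#' Self a lineage for a number of generations
#'
#' Iterates generations of self-fertilization at population size one: each
#' generation, two independent gametes from the current individual are joined
#' into the next. Each heterozygous site has probability 1/2 of remaining
#' heterozygous per generation, so heterozygosity halves in expectation every
#' generation regardless of linkage.
#'
#' @param x A phased [PhasedGenotypes-class] object.
#' @param generations Number of selfing generations (0 returns the founder).
#' @param individual Column index of the founder individual in `x`.
#' @return A [PhasedGenotypes-class] object with one individual.
#' @export
selfLineage <- function(x, generations, individual = 1) {
  .stopIfUnphased(x, "selfLineage")
  sp <- .splitHaps(x[, individual])
  res <- .selfStack(sp$A, sp$B, sp$pos, generations)
  .assemblePG(res$A, res$B, sp, ids = colnames(x)[individual])
}

#' NeutralSimResult: drift-only distribution of a diversity metric
#'
#' Result of [neutralInbreedingSim()] for one metric: the per-simulation
#' values, their mean (point expectation) and the empirical 2.5/97.5
#' percentile 95% credible interval.
#'
#' @slot metric Metric name ("He", "he" or "Ho").
#' @slot values Per-simulation metric values.
#' @slot expectation Mean over simulations.
#' @slot ci Length-2 numeric, the 95% interval.
#' @slot generations Selfing generations simulated.
#' @export
setClass("NeutralSimResult",
  representation(metric = "character", values = "numeric",
                 expectation = "numeric", ci = "numeric",
                 generations = "integer")
)

setValidity("NeutralSimResult", function(object) {
  if (length(object@ci) != 2) return("ci must have length 2")
  if (object@ci[1] > object@ci[2]) return("ci must be (low, high)")
  TRUE
})

setMethod("show", "NeutralSimResult", function(object) {
  cat(sprintf(
    "NeutralSimResult '%s': %d sims, %d generations of selfing\n  expectation %.4f, 95%% CI [%.4f, %.4f]\n",
    object@metric, length(object@values), object@generations,
    object@expectation, object@ci[1], object@ci[2]))
  invisible(object)
})

#' Position of an observed value relative to the neutral interval
#'
#' @param result A [NeutralSimResult-class] object.
#' @param observed Observed metric value among real inbred lines.
#' @return `"inside"`, `"above"` or `"below"`.
#' @export
scoreObserved <- function(result, observed) {
  if (observed > result@ci[2]) "above"
  else if (observed < result@ci[1]) "below"
  else "inside"
}

#' Neutral credible intervals for post-inbreeding diversity
#'
#' Forward-simulates inbred-line derivation by selfing, conditional on an
#' observed phased population sample, to obtain the drift-only distribution
#' of diversity among surviving lines. Each of `n_sims` replicates (i)
#' samples `n_lines` founders with replacement from the individuals of `x`,
#' (ii) selfs each founder independently for `generations` generations under
#' complete crossover interference, and (iii) computes the diversity metrics
#' among the resulting lines, matched to the population sample size by
#' averaging over subsets of `subset_size` lines (see [jackknifeMatch()]).
#' Chromosomes are analyzed separately and metrics averaged across
#' chromosomes. The empirical 2.5 and 97.5 percentiles over simulations give
#' a 95% credible interval against which an observed value among real lines
#' can be scored with [scoreObserved()]: observed diversity above the
#' interval indicates balancing (e.g. overdominant) selection during
#' inbreeding, below it purifying selection.
#'
#' @param x A phased [PhasedGenotypes-class] population sample (typically 16
#'   individuals).
#' @param generations Selfing generations (13 or 16 in the motivating
#'   experimental design).
#' @param n_sims Number of simulation replicates (default 1000).
#' @param n_lines Lines sampled per replicate (match the number of surviving
#'   real lines, typically > 50).
#' @param subset_size Sample-size matching subset (default 16).
#' @param n_subsets Subsets per replicate for the jackknife average.
#' @param window SNP window for the effective haplotype number.
#' @param metrics Which metrics to return ("He", "he", "Ho").
#' @param seed Optional integer seed; fixing it reproduces the result
#'   bit-identically.
#' @return Named list of [NeutralSimResult-class] objects, one per metric.
#' @export
neutralInbreedingSim <- function(x, generations, n_sims = 1000, n_lines = 50,
                                 subset_size = 16, n_subsets = 10,
                                 window = 10, metrics = c("He", "he", "Ho"),
                                 seed = NULL) {
  .stopIfUnphased(x, "neutralInbreedingSim")
  stopifnot(generations >= 1, n_sims >= 1, n_lines >= 1)
  metrics <- match.arg(metrics, c("He", "he", "Ho"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sp <- .splitHaps(x)
  nf <- nIndividuals(x)
  founders <- sample.int(nf, n_sims * n_lines, replace = TRUE)
  hapsA <- lapply(sp$A, function(m) m[, founders, drop = FALSE])
  hapsB <- lapply(sp$B, function(m) m[, founders, drop = FALSE])
  res <- .selfStack(hapsA, hapsB, sp$pos, generations)
  subs <- .drawSubsets(n_sims, n_lines, subset_size, n_subsets)
  vals <- .simMetrics(res$A, res$B, sp$pos, n_sims, n_lines, subs, metrics,
                      window)
  out <- lapply(metrics, function(m) {
    v <- vals[, m]
    methods::new("NeutralSimResult", metric = m, values = v,
                 expectation = mean(v),
                 ci = unname(stats::quantile(v, c(0.025, 0.975))),
                 generations = as.integer(generations))
  })
  names(out) <- metrics
  out
}

## list over sims of list of within-sim column subsets
.drawSubsets <- function(n_sims, n_lines, subset_size, n_subsets) {
  lapply(seq_len(n_sims), function(s) {
    if (n_lines <= subset_size) {
      list(seq_len(n_lines))
    } else {
      replicate(n_subsets, sample.int(n_lines, subset_size), simplify = FALSE)
    }
  })
}

## Metrics per simulation, chromosome-averaged, jackknife-averaged over the
## supplied subsets. hapsA/hapsB columns are sims stacked contiguously.
.simMetrics <- function(hapsA, hapsB, posl, n_sims, n_lines, subs, metrics,
                        window) {
  nchr <- length(hapsA)
  want_he <- "he" %in% metrics
  if (want_he) {
    codes <- .windowCodes(hapsA, hapsB, window)
    if (want_he && is.null(codes)) {
      stop("no chromosome has at least ", window,
           " markers; cannot compute he")
    }
  }
  vals <- matrix(NA_real_, n_sims, length(metrics),
                 dimnames = list(NULL, metrics))
  for (s in seq_len(n_sims)) {
    base <- (s - 1L) * n_lines
    acc <- stats::setNames(numeric(length(metrics)), metrics)
    for (sub in subs[[s]]) {
      cols <- base + sub
      perchr <- matrix(NA_real_, nchr, length(metrics),
                       dimnames = list(NULL, metrics))
      for (ch in seq_len(nchr)) {
        A <- hapsA[[ch]][, cols, drop = FALSE]
        B <- hapsB[[ch]][, cols, drop = FALSE]
        if ("He" %in% metrics) {
          alt <- rowSums(A, na.rm = TRUE) + rowSums(B, na.rm = TRUE)
          tot <- rowSums(!is.na(A)) + rowSums(!is.na(B))
          p <- alt / tot
          perchr[ch, "He"] <- mean(2 * p * (1 - p), na.rm = TRUE)
        }
        if ("Ho" %in% metrics) {
          perchr[ch, "Ho"] <- mean(A != B, na.rm = TRUE)
        }
        if (want_he && !is.null(codes[[ch]])) {
          cw <- codes[[ch]]
          hev <- vapply(seq_len(nrow(cw$A)), function(w) {
            u <- c(cw$A[w, cols], cw$B[w, cols])
            u <- u[!is.na(u)]
            if (!length(u)) return(NA_real_)
            k <- tabulate(match(u, unique(u))) / length(u)
            1 / sum(k^2)
          }, numeric(1))
          perchr[ch, "he"] <- mean(hev, na.rm = TRUE)
        }
      }
      acc <- acc + colMeans(perchr, na.rm = TRUE)
    }
    vals[s, ] <- acc / length(subs[[s]])
  }
  vals
}

## Binary window codes per chromosome: windows x columns matrices of window
## haplotype identities (NA when any call in the window is missing).
.windowCodes <- function(hapsA, hapsB, window) {
  any_win <- FALSE
  codes <- vector("list", length(hapsA))
  w2 <- 2^(seq_len(window) - 1)
  for (ch in seq_along(hapsA)) {
    L <- nrow(hapsA[[ch]])
    nwin <- L %/% window
    if (nwin == 0) next
    any_win <- TRUE
    cA <- matrix(NA_real_, nwin, ncol(hapsA[[ch]]))
    cB <- cA
    for (w in seq_len(nwin)) {
      ridx <- ((w - 1) * window + 1):(w * window)
      cA[w, ] <- drop(w2 %*% hapsA[[ch]][ridx, , drop = FALSE])
      cB[w, ] <- drop(w2 %*% hapsB[[ch]][ridx, , drop = FALSE])
    }
    codes[[ch]] <- list(A = cA, B = cB)
  }
  if (!any_win) return(NULL)
  codes
}

#' Diversity metrics among inbred lines, sample-size matched
#'
#' Computes He, he and Ho among a panel of lines with the same chromosome
#' averaging and subset-jackknife machinery as [neutralInbreedingSim()], so
#' observed values are directly comparable to the simulated intervals.
#'
#' @param x A phased [PhasedGenotypes-class] object of inbred lines.
#' @inheritParams neutralInbreedingSim
#' @return Named numeric vector with elements `He`, `he`, `Ho`.
#' @export
lineDiversityMetrics <- function(x, subset_size = 16, n_subsets = 10,
                                 window = 10, metrics = c("He", "he", "Ho"),
                                 seed = NULL) {
  .stopIfUnphased(x, "lineDiversityMetrics")
  metrics <- match.arg(metrics, c("He", "he", "Ho"), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  sp <- .splitHaps(x)
  n <- nIndividuals(x)
  subs <- .drawSubsets(1L, n, subset_size, n_subsets)
  drop(.simMetrics(sp$A, sp$B, sp$pos, 1L, n, subs, metrics, window)[1, ])
}

## NA x NA comparison in Ho: A != B gives NA, excluded by na.rm -- an
## individual with a missing call at a marker is excluded at that marker.
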