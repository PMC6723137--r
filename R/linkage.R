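#' Pairwise linkage disequilibrium within chromosomes
#'
#' For every within-chromosome pair of markers segregating inside
#' `maf_range`, computes the gametic disequilibrium `D` and
#' `r2 = D^2 / (p_i (1 - p_i) p_j (1 - p_j))`, together with the genetic
#' distance `c` (cM) between the pair.
#'
#' With phased data, `D = P(11 haplotype) - p_i p_j` from observed gametes.
#' With unphased data the Burrows composite estimator is used
#' (`method = "composite"`): `D = mean(X Y)/2 - 2 p_i p_j` over genotype
#' dosages `X`, `Y`, which requires no haplotype inference. `method = "auto"`
#' picks by the phased flag; `method = "phased"` refuses unphased input.
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param maf_range Allele-frequency inclusion range (default `c(0.05, 0.95)`).
#' @param max_cm Optional cap on pair distance in cM.
#' @param method `"auto"`, `"phased"` or `"composite"`.
#' @return `data.frame` with columns `marker_i`, `marker_j`, `chromosome`,
#'   `c` (cM), `D`, `r2`.
#' @export
pairwiseLD <- function(x, maf_range = c(0.05, 0.95), max_cm = NULL,
                       method = c("auto", "phased", "composite")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (isPhased(x)) "phased" else "composite"
  if (method == "phased") .stopIfUnphased(x, "pairwiseLD(method = 'phased')")
  map <- geneticMap(x)
  p <- alleleFrequencies(x)
  keep <- !is.na(p) & p >= maf_range[1] & p <= maf_range[2]
  res <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr & keep)
    if (length(idx) < 2) next
    if (method == "phased") {
      hap <- cbind(hapAlleles(x, 1)[idx, , drop = FALSE],
                   hapAlleles(x, 2)[idx, , drop = FALSE])
      Dmat <- .gameticD(hap)
    } else {
      Dmat <- .burrowsD(genotypeCodes(x)[idx, , drop = FALSE])
    }
    pl <- Dmat$p
    denom <- outer(pl * (1 - pl), pl * (1 - pl))
    r2 <- Dmat$D^2 / denom
    pos <- map$position_cM[idx]
    pairs <- which(upper.tri(r2), arr.ind = TRUE)
    cdist <- abs(pos[pairs[, 2]] - pos[pairs[, 1]])
    if (!is.null(max_cm)) {
      ok <- cdist <= max_cm
      pairs <- pairs[ok, , drop = FALSE]
      cdist <- cdist[ok]
    }
    if (!nrow(pairs)) next
    res[[chr]] <- data.frame(
      marker_i = map$marker_id[idx[pairs[, 1]]],
      marker_j = map$marker_id[idx[pairs[, 2]]],
      chromosome = chr,
      c = cdist,
      D = Dmat$D[pairs],
      r2 = r2[pairs],
      stringsAsFactors = FALSE
    )
  }
  if (!length(res)) stop("fewer than 2 markers pass the frequency filter on every chromosome")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## hap: loci x gametes 0/1 matrix (may contain NA); D from pairwise-complete
## gametes. Returns list(D = loci x loci matrix, p = loci ALT freqs).
.gameticD <- function(hap) {
  M <- !is.na(hap)
  H0 <- hap
  H0[!M] <- 0
  P11n <- H0 %*% t(H0)                 # joint 11 counts over complete gametes
  Nn <- M %*% t(M) * 1
  p1n <- H0 %*% t(M)                   # ALT count at row locus among complete
  P11 <- P11n / Nn
  pi_ <- p1n / Nn                      # pairwise allele freq at locus i
  pj_ <- t(p1n) / Nn
  D <- P11 - pi_ * pj_
  p <- rowSums(H0) / rowSums(M)
  list(D = D, p = p)
}

## gc: loci x individuals dosage 0/1/2 (may contain NA); Burrows composite.
.burrowsD <- function(gc) {
  M <- !is.na(gc)
  G0 <- gc
  G0[!M] <- 0
  XY <- G0 %*% t(G0)
  Nn <- M %*% t(M) * 1
  sx <- G0 %*% t(M)
  px <- sx / (2 * Nn)
  py <- t(sx) / (2 * Nn)
  D <- XY / (2 * Nn) - 2 * px * py
  p <- rowSums(G0) / (2 * rowSums(M))
  list(D = D, p = p)
}

#' Fit the decay of linkage disequilibrium with genetic distance
#'
#' Nonlinear least squares fit of the Sved expectation
#' `E[r2] = 1 / (1 + 4 x c)` to an LD table, with `c` in centimorgans as
#' produced by [pairwiseLD()]. The decay-rate parameter `x` is estimated on
#' the log scale so the fit can never leave the positive domain; the reported
#' SE is delta-method transformed back. Given a list of LD tables (replicate
#' populations), each replicate is fitted separately and the population-level
#' estimate pools replicates by inverse-variance weighting.
#'
#' @param ld An LD `data.frame` from [pairwiseLD()] (needs columns `c`, `r2`),
#'   or a list of such tables, one per replicate.
#' @param population Label for the fit.
#' @return `data.frame` with `population`, `x_hat`, `x_se`, `n_pairs`,
#'   `model`; for replicate input, an attribute `"replicates"` holds the
#'   per-replicate fits.
#' @references Sved J.A. (1971) Linkage disequilibrium and homozygosity of
#'   chromosome segments in finite populations. Theor. Popul. Biol. 2:125-141.
#' @export
fitLDDecay <- function(ld, population = "pop") {
  if (is.data.frame(ld)) {
    fit <- .fitOneLD(ld)
    return(data.frame(population = population, x_hat = fit$x, x_se = fit$se,
                      n_pairs = fit$n, model = "E[r2]=1/(1+4*x*c)",
                      stringsAsFactors = FALSE))
  }
  fits <- lapply(ld, .fitOneLD)
  reps <- data.frame(
    replicate = if (!is.null(names(ld))) names(ld) else seq_along(ld),
    x_hat = vapply(fits, `[[`, numeric(1), "x"),
    x_se = vapply(fits, `[[`, numeric(1), "se"),
    n_pairs = vapply(fits, `[[`, numeric(1), "n")
  )
  w <- 1 / reps$x_se^2
  x_pool <- sum(w * reps$x_hat) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  out <- data.frame(population = population, x_hat = x_pool, x_se = se_pool,
                    n_pairs = sum(reps$n_pairs),
                    model = "E[r2]=1/(1+4*x*c)", stringsAsFactors = FALSE)
  attr(out, "replicates") <- reps
  out
}

.fitOneLD <- function(ld) {
  ld <- ld[is.finite(ld$r2) & is.finite(ld$c), ]
  if (nrow(ld) < 10) stop("need at least 10 (c, r2) pairs to fit LD decay")
  if (diff(range(ld$c)) <= 0) stop("LD pairs span no range of genetic distance")
  ## moment start: invert E[r2] at the median informative pair
  pos <- ld$r2 > 0 & ld$r2 < 1 & ld$c > 0
  x0 <- if (any(pos)) {
    stats::median((1 / ld$r2[pos] - 1) / (4 * ld$c[pos]))
  } else 1
  x0 <- max(x0, 1e-6)
  fit <- minpack.lm::nlsLM(
    r2 ~ 1 / (1 + 4 * exp(ltheta) * c),
    data = ld,
    start = list(ltheta = log(x0)),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  lth <- stats::coef(fit)[["ltheta"]]
  se_l <- sqrt(stats::vcov(fit)[1, 1])
  list(x = exp(lth), se = exp(lth) * se_l, n = nrow(ld))
}

#' Sved decay curve
#'
#' Predicted `r2` at genetic distance `c` (cM) for decay parameter `x`:
#' `1 / (1 + 4 x c)`; equals 1 at `c = 0` for any `x`.
#'
#' @param c Genetic distances (cM).
#' @param x Decay-rate parameter.
#' @return Predicted `r2` values.
#' @export
ldDecayCurve <- function(c, x) 1 / (1 + 4 * x * c)
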