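#' PhasedGenotypes: biallelic SNP genotypes with a genetic map
#'
#' An S4 container for diploid biallelic SNP genotype matrices, built on
#' [SummarizedExperiment::SummarizedExperiment]. The two allele calls of each
#' individual are stored as two assays (`hap1`, `hap2`), each a
#' markers-by-individuals integer matrix with values 0 (REF), 1 (ALT) or `NA`
#' (missing). The genetic map (chromosome and position in centimorgans per
#' marker) lives in `rowData`, so that subsetting by marker or by individual
#' keeps genotypes and map in register.
#'
#' When `phased = FALSE` the assignment of calls to `hap1`/`hap2` within an
#' individual carries no information; operations that require phase (window
#' haplotypes, the selfing simulator) refuse unphased input rather than
#' silently pseudo-phasing.
#'
#' @slot phased Logical scalar; whether haplotype assignment is meaningful.
#'
#' @seealso [readGenotypes()], [geneticMap()], [hapAlleles()],
#'   [genotypeCodes()]
#' @export
setClass("PhasedGenotypes",
  contains = "SummarizedExperiment",
  representation(phased = "logical")
)

.validPhasedGenotypes <- function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("hap1", "hap2") %in% an)) {
    msg <- c(msg, "assays 'hap1' and 'hap2' are required")
  } else {
    for (a in c("hap1", "hap2")) {
      v <- SummarizedExperiment::assay(object, a)
      bad <- !(v %in% c(0L, 1L) | is.na(v))
      if (any(bad)) {
        msg <- c(msg, sprintf("assay '%s' contains values other than 0, 1, NA", a))
      }
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chromosome", "position_cM") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'chromosome' and 'position_cM'")
  } else {
    map <- data.frame(
      marker_id = rownames(object),
      chromosome = as.character(rd$chromosome),
      position_cM = as.numeric(rd$position_cM)
    )
    mmsg <- .checkGeneticMap(map)
    msg <- c(msg, mmsg)
  }
  if (length(object@phased) != 1L || is.na(object@phased)) {
    msg <- c(msg, "'phased' must be TRUE or FALSE")
  }
  if (length(msg)) msg else TRUE
}

setValidity("PhasedGenotypes", .validPhasedGenotypes)

## Returns character vector of problems (empty if fine); shared with
## readGeneticMap() so files and in-memory maps are held to the same contract.
.checkGeneticMap <- function(map) {
  msg <- character()
  if (anyDuplicated(map$marker_id)) {
    msg <- c(msg, "marker ids are not unique")
  }
  if (any(is.na(map$position_cM)) || any(map$position_cM < 0)) {
    msg <- c(msg, "cM positions must be non-negative")
  } else {
    for (chr in unique(map$chromosome)) {
      p <- map$position_cM[map$chromosome == chr]
      if (is.unsorted(p)) {
        msg <- c(msg, sprintf("cM positions are not non-decreasing on chromosome %s", chr))
      }
    }
  }
  msg
}

#' Construct a PhasedGenotypes object
#'
#' @param hap1,hap2 Integer matrices (markers x individuals) of allele calls,
#'   0 = REF, 1 = ALT, `NA` = missing. Row names are marker ids; column names
#'   are individual ids (generated if absent).
#' @param map A genetic map `data.frame` with columns `marker_id`,
#'   `chromosome`, `position_cM`, one row per marker, in the same order as the
#'   rows of `hap1`.
#' @param phased Logical; whether the split into `hap1`/`hap2` reflects true
#'   haplotypes.
#'
#' @return A [PhasedGenotypes-class] object.
#' @examples
#' map <- generateMap(chromosomes = 1, markers_per_chromosome = 3)
#' h <- matrix(0L, 3, 2, dimnames = list(map$marker_id, c("i1", "i2")))
#' pg <- PhasedGenotypes(h, h, map)
#' nMarkers(pg)
#' @export
PhasedGenotypes <- function(hap1, hap2, map, phased = TRUE) {
  hap1 <- as.matrix(hap1)
  hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"
  storage.mode(hap2) <- "integer"
  stopifnot(identical(dim(hap1), dim(hap2)))
  if (nrow(hap1) != nrow(map)) {
    stop("number of markers (", nrow(hap1), ") does not match map length (",
         nrow(map), ")")
  }
  if (is.null(colnames(hap1))) {
    colnames(hap1) <- sprintf("ind%03d", seq_len(ncol(hap1)))
  }
  colnames(hap2) <- colnames(hap1)
  rownames(hap1) <- rownames(hap2) <- map$marker_id
  rd <- S4Vectors::DataFrame(
    chromosome = as.character(map$chromosome),
    position_cM = as.numeric(map$position_cM),
    row.names = map$marker_id
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(hap1 = hap1, hap2 = hap2),
    rowData = rd
  )
  methods::new("PhasedGenotypes", se, phased = isTRUE(phased))
}

#' @describeIn PhasedGenotypes Number of individuals (samples).
#' @param x A `PhasedGenotypes` object.
#' @export
nIndividuals <- function(x) ncol(x)

#' @describeIn PhasedGenotypes Number of markers.
#' @export
nMarkers <- function(x) nrow(x)

#' @describeIn PhasedGenotypes Whether the object is phased.
#' @export
isPhased <- function(x) x@phased

#' Extract one haplotype assay
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param which 1 or 2.
#' @return Integer matrix, markers x individuals.
#' @export
hapAlleles <- function(x, which = 1) {
  SummarizedExperiment::assay(x, if (which == 1) "hap1" else "hap2")
}

#' Genetic map of a PhasedGenotypes object
#'
#' @param x A [PhasedGenotypes-class] object.
#' @return `data.frame` with columns `marker_id`, `chromosome`, `position_cM`.
#' @export
geneticMap <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(
    marker_id = rownames(x),
    chromosome = as.character(rd$chromosome),
    position_cM = as.numeric(rd$position_cM),
    stringsAsFactors = FALSE
  )
}

#' Genotype dosage codes
#'
#' Collapses the two allele calls to ALT-allele dosage 0/1/2 per individual
#' and marker; any missing allele call gives `NA`. Phase-free, so valid for
#' unphased objects.
#'
#' @param x A [PhasedGenotypes-class] object.
#' @return Integer matrix, markers x individuals, values 0, 1, 2 or `NA`.
#' @export
genotypeCodes <- function(x) {
  hapAlleles(x, 1) + hapAlleles(x, 2)
}

setMethod("show", "PhasedGenotypes", function(object) {
  map <- geneticMap(object)
  cat("PhasedGenotypes:", nrow(object), "markers x", ncol(object),
      "individuals\n")
  cat("  phased:", object@phased, "\n")
  cat("  chromosomes:", length(unique(map$chromosome)),
      sprintf("(%s)", paste(utils::head(unique(map$chromosome), 6),
                            collapse = ", ")), "\n")
  nmiss <- sum(is.na(hapAlleles(object, 1))) + sum(is.na(hapAlleles(object, 2)))
  cat("  missing allele calls:", nmiss, "\n")
  invisible(object)
})

## internal: split marker indices by chromosome, preserving map order
.chromosomeIndex <- function(map) {
  split(seq_len(nrow(map)), factor(map$chromosome, levels = unique(map$chromosome)))
}

.stopIfUnphased <- function(x, what) {
  if (!isPhased(x)) {
    stop(what, " requires phased genotypes; this object is unphased. ",
         "Re-read the data with phased calls ('|' separators) or supply ",
         "phased = TRUE only if haplotype assignment is real.", call. = FALSE)
  }
  invisible(TRUE)
}
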