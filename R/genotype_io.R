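## Readers and writers for genotype matrices, genetic maps and line records.
## All writers emit a "# selfdiv <version>" header comment and deterministic
## column order; readers skip comment lines.

.toolHeader <- function() {
  sprintf("# selfdiv %s", as.character(utils::packageVersion("selfdiv")))
}

#' Read a genetic map TSV
#'
#' Expects columns `marker_id`, `chromosome`, `position_cM` (tab-separated,
#' `#` comment lines ignored). Positions are absolute within chromosome, in
#' centimorgans, 0-based at the chromosome start.
#'
#' @param path File path.
#' @return Validated map `data.frame`.
#' @export
readGeneticMap <- function(path) {
  map <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% colnames(map))) {
    stop("map file ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  map <- map[, need]
  map$marker_id <- as.character(map$marker_id)
  map$chromosome <- as.character(map$chromosome)
  map$position_cM <- as.numeric(map$position_cM)
  msg <- .checkGeneticMap(map)
  if (length(msg)) stop("invalid genetic map: ", paste(msg, collapse = "; "))
  map
}

#' @rdname readGeneticMap
#' @param map Map `data.frame`.
#' @export
writeGeneticMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  utils::write.table(map[, c("marker_id", "chromosome", "position_cM")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP genotypes from VCF or TSV
#'
#' Builds a [PhasedGenotypes-class] object from a VCF 4.x file (GT field
#' only) or from the package's genotype TSV dialect (one row per individual,
#' one column per marker, cells like `"0|1"`). The phased flag is set from the
#' allele separator: `|` phased, `/` unphased; mixing the two within a file is
#' rejected. Multi-allelic sites are rejected. The genetic map travels in a
#' separate TSV (see [readGeneticMap()]); every genotyped marker must be
#' present in the map.
#'
#' @param path Genotype file path.
#' @param map Genetic map: a `data.frame` or a path for [readGeneticMap()].
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [PhasedGenotypes-class] object; markers ordered as in the map.
#' @export
readGenotypes <- function(path, map, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (is.character(map)) map <- readGeneticMap(map)
  gt <- switch(format,
    vcf = .readGenotypesVCF(path),
    tsv = .readGenotypesTSV(path)
  )
  missing_in_map <- setdiff(rownames(gt$hap1), map$marker_id)
  if (length(missing_in_map)) {
    stop("markers present in genotypes but not in map: ",
         paste(utils::head(missing_in_map, 5), collapse = ", "),
         if (length(missing_in_map) > 5) " ...")
  }
  map <- map[map$marker_id %in% rownames(gt$hap1), , drop = FALSE]
  ord <- match(map$marker_id, rownames(gt$hap1))
  PhasedGenotypes(gt$hap1[ord, , drop = FALSE], gt$hap2[ord, , drop = FALSE],
                  map, phased = gt$phased)
}

.parseGTStrings <- function(gtmat, context) {
  gtv <- as.vector(gtmat)
  gtv[is.na(gtv)] <- ".|."
  gtv <- sub(":.*$", "", gtv)          # drop any trailing FORMAT subfields
  gtv[gtv == "."] <- ".|."
  sep <- unique(c(
    if (any(grepl("\\|", gtv))) "|",
    if (any(grepl("/", gtv))) "/"
  ))
  if (length(sep) > 1) {
    stop("mixed phase separators ('|' and '/') in ", context,
         "; phase must be consistent per file")
  }
  if (length(sep) == 0) sep <- "|"
  ok <- grepl(paste0("^[01.]\\", sep, "[01.]$"), gtv)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    row <- (bad - 1L) %% nrow(gtmat) + 1L
    stop("malformed genotype call '", as.vector(gtmat)[bad], "' at record ",
         row, " in ", context)
  }
  a1 <- substr(gtv, 1, 1)
  a2 <- substr(gtv, 3, 3)
  num <- function(a) {
    v <- suppressWarnings(as.integer(a))
    matrix(v, nrow(gtmat), ncol(gtmat), dimnames = dimnames(gtmat))
  }
  list(hap1 = num(a1), hap2 = num(a2), phased = (sep == "|"))
}

.readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic sites are not supported: ",
         paste(utils::head(fix[multi, "ID"], 5), collapse = ", "))
  }
  gtmat <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  rownames(gtmat) <- ids
  .parseGTStrings(gtmat, basename(path))
}

.readGenotypesTSV <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (colnames(d)[1] != "individual") {
    stop("genotype TSV must have 'individual' as its first column")
  }
  inds <- as.character(d$individual)
  gtmat <- t(as.matrix(d[, -1, drop = FALSE]))  # markers x individuals
  colnames(gtmat) <- inds
  .parseGTStrings(gtmat, basename(path))
}

#' Write SNP genotypes
#'
#' Writes a [PhasedGenotypes-class] object as genotype TSV (individuals in
#' rows) or as a minimal VCF 4.2 with a GT-only FORMAT. The separator encodes
#' the phased flag. The genetic map is not embedded; use [writeGeneticMap()].
#'
#' @param x A [PhasedGenotypes-class] object.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  sep <- if (isPhased(x)) "|" else "/"
  a1 <- hapAlleles(x, 1)
  a2 <- hapAlleles(x, 2)
  chr <- function(m) {
    v <- as.character(m)
    v[is.na(v)] <- "."
    v
  }
  cells <- matrix(paste0(chr(a1), sep, chr(a2)), nrow(a1), ncol(a1),
                  dimnames = dimnames(a1))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(.toolHeader(), con)
    d <- data.frame(individual = colnames(cells), t(cells),
                    check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    map <- geneticMap(x)
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##source=", sub("^# ", "", .toolHeader())),
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", colnames(cells)), collapse = "\t")
    ), con)
    ## POS: cM scaled to an integer coordinate (VCF stores bp; positions here
    ## are only placeholders -- the map TSV is authoritative for distance)
    pos <- as.integer(round(map$position_cM * 1e4)) + 1L
    body <- cbind(map$chromosome, pos, map$marker_id, "A", "T", ".", "PASS",
                  ".", "GT", cells)
    utils::write.table(body, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read inbred-line derivation records
#'
#' TSV with header `line_id`, `population`, `block`, `generations_survived`,
#' `status`. Status must be `extinct` or `censored`. Censored lines must have
#' `generations_survived` equal to the assay length (16 for ancestral-style
#' assays, 13 otherwise) when `assay_length` is given.
#'
#' @param path File path.
#' @param assay_length Optional integer; when supplied, records are checked
#'   against it.
#' @return `data.frame` of validated line records.
#' @export
readLineRecords <- function(path, assay_length = NULL) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("line_id", "population", "block", "generations_survived", "status")
  if (!all(need %in% colnames(d))) {
    stop("line-record file must have columns: ", paste(need, collapse = ", "))
  }
  d <- d[, need]
  bad <- !d$status %in% c("extinct", "censored")
  if (any(bad)) {
    stop("unknown status token(s): ",
         paste(unique(d$status[bad]), collapse = ", "),
         " (expected 'extinct' or 'censored')")
  }
  g <- d$generations_survived
  if (!is.numeric(g) || any(is.na(g)) || any(g != round(g)) || any(g < 1)) {
    stop("generations_survived must be positive integers")
  }
  d$generations_survived <- as.integer(g)
  if (!is.null(assay_length)) {
    if (any(d$generations_survived > assay_length)) {
      stop("generations_survived exceeds assay length ", assay_length)
    }
    cen <- d$status == "censored"
    if (any(d$generations_survived[cen] != assay_length)) {
      stop("censored lines must have generations_survived == assay length")
    }
  }
  counts <- table(d$population)
  message("read ", nrow(d), " line records (",
          paste(names(counts), counts, sep = ": ", collapse = ", "), ")")
  d
}

#' @rdname readLineRecords
#' @param records Line-record `data.frame`.
#' @export
writeLineRecords <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.toolHeader(), con)
  utils::write.table(
    records[, c("line_id", "population", "block", "generations_survived", "status")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
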