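# Readers and writers for the package's tab-delimited interchange formats.
# Coordinate conventions: BED files are 0-based half-open; VCF-like variant
# tables are 1-based; conversion happens here and only here.

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

parseError <- function(path, line, what) {
  stop(sprintf("%s:%d: %s", path, line, what), call. = FALSE)
}

#' Read a genetic map (TSV: marker, chrom, cm)
#' @param path TSV path.
#' @return A [GeneticMap-class].
#' @export
readMap <- function(path) {
  d <- readTsv(path)
  need <- c("marker", "chrom", "cm")
  if (!all(need %in% names(d)))
    stop(path, ": map needs columns ", paste(need, collapse = ", "))
  bad <- which(is.na(suppressWarnings(as.numeric(d$cm))))
  if (length(bad)) parseError(path, bad[1] + 1L, "non-numeric cm position")
  geneticMap(d$marker, d$chrom, as.numeric(d$cm))
}

#' Read a genotype matrix (TSV: marker rows, individual columns, QQ/Qq/qq/NA)
#' @param path TSV path; first column \code{marker}.
#' @param map a [GeneticMap-class] covering the markers.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, map) {
  d <- readTsv(path)
  if (names(d)[1] != "marker") stop(path, ": first column must be 'marker'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$marker
  ok <- is.na(m) | m %in% c("QQ", "Qq", "qq")
  if (!all(ok)) {
    w <- which(!ok, arr.ind = TRUE)[1, ]
    parseError(path, w[1] + 1L,
               sprintf("genotype call outside {QQ,Qq,qq,NA}: '%s'", m[!ok][1]))
  }
  genotypeMatrix(m, map)
}

#' Write a genotype matrix as TSV (QQ/Qq/qq/NA coding)
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output path.
#' @export
writeGenotypes <- function(genotypes, path) {
  g <- genotypeCalls(genotypes)
  lab <- matrix(c("qq", "Qq", "QQ")[g + 1L], nrow(g), dimnames = dimnames(g))
  utils::write.table(data.frame(marker = rownames(lab), lab, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a phenotype table (TSV with header; id column required)
#' @param path TSV path.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  d <- readTsv(path)
  if (!("id" %in% names(d))) stop(path, ": phenotype table needs an 'id' column")
  d
}

#' Read a BED file (0-based half-open)
#' @param path BED path (3+ columns, tab-separated, no header).
#' @return [GenomicRanges::GRanges] (1-based internally).
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) parseError(path, i, "BED needs >= 3 columns")
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e)) parseError(path, i, "non-numeric BED coordinates")
    if (e <= s) parseError(path, i, sprintf("end (%s) must exceed start (%s)", p[3], p[2]))
  }
  chrom <- vapply(parts, `[`, "", 1)
  s0 <- as.numeric(vapply(parts, `[`, "", 2))
  e0 <- as.numeric(vapply(parts, `[`, "", 3))
  gr <- GRanges(chrom, IRanges(s0 + 1, e0))
  if (all(lengths(parts) >= 4)) names(gr) <- vapply(parts, `[`, "", 4)
  gr
}

#' Write a GRanges as BED (0-based half-open)
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr))
  if (!is.null(names(gr))) d$name <- names(gr)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a minimal VCF into the package's variant table
#'
#' Parses an uncompressed VCF with INFO \code{DP} depth, optional INFO
#' \code{FDR}, and exactly two sample columns whose GT fields give the
#' per-strain zygosity (0/0 hom_ref, 0/1 het, 1/1 hom_alt, ./. missing).
#'
#' @param path VCF path.
#' @return data.frame(chrom, pos, depth, fdr, gtA, gtB).
#' @export
readVcfMinimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  hdr <- lines[startsWith(lines, "#CHROM")]
  if (!length(hdr)) stop(path, ": missing #CHROM header line")
  cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (length(cols) < 11) stop(path, ": need FORMAT plus two sample columns")
  gtOf <- function(fmt, smp, ln) {
    fk <- strsplit(fmt, ":", fixed = TRUE)[[1]]
    gi <- match("GT", fk)
    if (is.na(gi)) parseError(path, ln, "FORMAT lacks GT")
    gt <- strsplit(smp, ":", fixed = TRUE)[[1]][gi]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    switch(gt, "0/0" = "hom_ref", "0/1" = "het", "1/0" = "het",
           "1/1" = "hom_alt", "./." = "missing",
           parseError(path, ln, paste("unsupported GT:", gt)))
  }
  rows <- lapply(seq_along(body), function(i) {
    p <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    ln <- which(lines == body[i])[1]
    if (length(p) < 11) parseError(path, ln, "truncated VCF record")
    info <- strsplit(p[8], ";", fixed = TRUE)[[1]]
    kv <- strsplit(info, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, function(x) x[2], ""),
                            vapply(kv, function(x) x[1], ""))
    data.frame(chrom = p[1], pos = as.numeric(p[2]),
               depth = as.numeric(vals[["DP"]]),
               fdr = if ("FDR" %in% names(vals)) as.numeric(vals[["FDR"]]) else 0,
               gtA = gtOf(p[9], p[10], ln), gtB = gtOf(p[9], p[11], ln),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a scored edge list (TSV: geneA, geneB, score)
#' @param path TSV path.
#' @return data.frame(geneA, geneB, score).
#' @export
readEdges <- function(path) {
  d <- readTsv(path)
  need <- c("geneA", "geneB", "score")
  if (!all(need %in% names(d)))
    stop(path, ": edge list needs columns ", paste(need, collapse = ", "))
  bad <- which(d$score < 0 | d$score > 1000)
  if (length(bad)) parseError(path, bad[1] + 1L, "score outside 0-1000")
  d
}

#' Read an expression count matrix (TSV: gene column + sample columns)
#' @param path TSV path.
#' @return Integer matrix, genes x samples.
#' @export
readCounts <- function(path) {
  d <- readTsv(path)
  if (names(d)[1] != "gene") stop(path, ": first column must be 'gene'")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0)) stop(path, ": counts must be non-negative")
  rownames(m) <- d$gene
  storage.mode(m) <- "integer"
  m
}

# diff-able float formatting for TSV outputs (6 significant digits)
writeTsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 6))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a LOD curve as TSV (chrom, cm, lod)
#' @param curve a [LodCurve-class] or list of them.
#' @param path output path.
#' @export
writeLodCurve <- function(curve, path) {
  if (is(curve, "LodCurve")) curve <- list(curve)
  d <- do.call(rbind, lapply(curve, function(cv)
    data.frame(chrom = cv@chrom, cm = cv@pos, lod = cv@lod)))
  writeTsv(d, path)
}
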