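#' @import methods
#' @importFrom stats setNames
NULL

#' AIL breeding design
#'
#' Describes a two-strain advanced intercross line (AIL) maintained by
#' cascade mating: a constant number of breeding pairs per generation, each
#' pair contributing exactly one male and one female to the next generation,
#' with the female of one cage mated to the male of the next cage (the ring
#' wraps). The terminal generation index uses the convention F2 = 2.
#'
#' @slot nPairs number of breeding pairs (cages) per generation; at least 2,
#'   since the mating ring is undefined for a single cage.
#' @slot tFinal terminal generation index (>= 2).
#' @slot offspringPerPair litter contribution to the next breeding
#'   generation; fixed at 2 (one of each sex) by the design.
#' @slot finalCohortSize number of individuals in the terminal generation.
#'   Defaults to \code{2 * nPairs}; may be larger (terminal litters are
#'   expanded across the same pairings) to emulate a large phenotyping
#'   cohort bred from the final pairs.
#' @slot seed integer seed from which all randomness of a simulated cohort
#'   is derived.
#'
#' @seealso [AILDesign()], [simulatePedigree()]
#' @export
setClass("AILDesign", representation(
  nPairs = "integer",
  tFinal = "integer",
  offspringPerPair = "integer",
  finalCohortSize = "integer",
  seed = "integer"
))

setValidity("AILDesign", function(object) {
  msg <- character()
  if (length(object@nPairs) != 1L || is.na(object@nPairs) || object@nPairs < 2L)
    msg <- c(msg, "nPairs must be a single integer >= 2 (mating ring undefined otherwise)")
  if (length(object@tFinal) != 1L || is.na(object@tFinal) || object@tFinal < 2L)
    msg <- c(msg, "tFinal must be a single integer >= 2 (F2 = 2)")
  if (object@offspringPerPair != 2L)
    msg <- c(msg, "offspringPerPair is fixed at 2 (one male + one female) by the design")
  if (length(object@finalCohortSize) != 1L || is.na(object@finalCohortSize) ||
      object@finalCohortSize < 2L)
    msg <- c(msg, "finalCohortSize must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct an AIL breeding design
#'
#' @param nPairs breeding pairs per generation (the study design uses 48).
#' @param tFinal terminal generation (F2 = 2; the study design uses 14).
#' @param offspringPerPair fixed at 2.
#' @param finalCohortSize size of the terminal generation; default
#'   \code{2 * nPairs}.
#' @param seed integer seed.
#' @return An [AILDesign-class] object.
#' @examples
#' AILDesign(nPairs = 48, tFinal = 14, seed = 1)
#' @export
AILDesign <- function(nPairs = 48L, tFinal = 14L, offspringPerPair = 2L,
                      finalCohortSize = 2L * nPairs, seed = 1L) {
  new("AILDesign", nPairs = as.integer(nPairs), tFinal = as.integer(tFinal),
      offspringPerPair = as.integer(offspringPerPair),
      finalCohortSize = as.integer(finalCohortSize), seed = as.integer(seed))
}

setMethod("show", "AILDesign", function(object) {
  cat(sprintf("AILDesign: %d pairs, F2..F%d, %d offspring/pair, terminal cohort %d, seed %d\n",
              object@nPairs, object@tFinal, object@offspringPerPair,
              object@finalCohortSize, object@seed))
})

#' Genetic map
#'
#' Ordered marker positions (centimorgan) per chromosome, with the map
#' function used to translate genetic distance into recombination fractions.
#' Only the Haldane map function (no crossover interference, Poisson
#' crossover counts) is implemented.
#'
#' @slot markers data.frame with columns \code{marker}, \code{chrom},
#'   \code{cm}; positions non-decreasing within chromosome, names unique.
#' @slot mapFunction map function tag, currently \code{"haldane"}.
#' @export
setClass("GeneticMap", representation(
  markers = "data.frame",
  mapFunction = "character"
))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  msg <- character()
  need <- c("marker", "chrom", "cm")
  if (!all(need %in% names(m)))
    return(sprintf("markers must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(m$marker))
    msg <- c(msg, "marker names must be unique")
  if (!is.numeric(m$cm) || anyNA(m$cm))
    msg <- c(msg, "cm positions must be numeric and non-missing")
  else {
    bad <- vapply(split(m$cm, m$chrom), is.unsorted, logical(1))
    if (any(bad))
      msg <- c(msg, sprintf("positions must be non-decreasing within chromosome (%s)",
                            paste(names(bad)[bad], collapse = ", ")))
  }
  if (!identical(object@mapFunction, "haldane"))
    msg <- c(msg, "only the haldane map function is supported")
  if (length(msg)) msg else TRUE
})

#' Construct a genetic map
#'
#' @param marker character vector of unique marker names.
#' @param chrom chromosome of each marker.
#' @param cm position in centimorgan, non-decreasing within chromosome.
#' @param mapFunction map function tag; only \code{"haldane"}.
#' @return A [GeneticMap-class] object.
#' @examples
#' geneticMap(paste0("m", 1:5), "1", seq(0, 8, by = 2))
#' @export
geneticMap <- function(marker, chrom, cm, mapFunction = "haldane") {
  m <- data.frame(marker = as.character(marker), chrom = as.character(chrom),
                  cm = as.numeric(cm), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$cm), , drop = FALSE]
  rownames(m) <- m$marker
  new("GeneticMap", markers = m, mapFunction = mapFunction)
}

#' @describeIn GeneticMap-class marker table accessor
#' @param x,object a \code{GeneticMap}
#' @export
mapMarkers <- function(x) x@markers

#' @describeIn GeneticMap-class chromosome names
#' @export
mapChromosomes <- function(x) unique(x@markers$chrom)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat(sprintf("GeneticMap: %d markers on %d chromosome(s) [%s], %s map function\n",
              nrow(m), length(unique(m$chrom)),
              paste(utils::head(unique(m$chrom), 5), collapse = ","),
              object@mapFunction))
})

#' Genotype matrix coded by parental-strain origin
#'
#' Marker-by-individual genotype calls for an intercross of two inbred
#' strains, coded as the number of copies of the Q (first-strain) allele:
#' 0 = qq, 1 = Qq, 2 = QQ, NA = missing. Text I/O uses the QQ/Qq/qq/NA
#' coding.
#'
#' @slot calls integer matrix, markers in rows (named), individuals in
#'   columns.
#' @slot map the [GeneticMap-class] the markers belong to.
#' @export
setClass("GenotypeMatrix", representation(
  calls = "matrix",
  map = "GeneticMap"
))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  g <- object@calls
  if (is.null(rownames(g)))
    return("calls must have marker rownames")
  if (!all(rownames(g) %in% object@map@markers$marker))
    msg <- c(msg, "all row markers must exist in the map")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msg <- c(msg, "calls must be 0 (qq), 1 (Qq), 2 (QQ) or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix (markers x individuals) in 0/1/2/NA coding,
#'   or character matrix in qq/Qq/QQ/NA coding.
#' @param map a [GeneticMap-class].
#' @return A [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(calls, map) {
  if (is.character(calls)) {
    code <- c(qq = 0L, Qq = 1L, qQ = 1L, QQ = 2L)
    bad <- !is.na(calls) & !(calls %in% names(code))
    if (any(bad))
      stop("genotype call outside {QQ,Qq,qq,NA}: ", calls[which(bad)[1]])
    dm <- dim(calls); dn <- dimnames(calls)
    calls <- code[calls]
    dim(calls) <- dm; dimnames(calls) <- dn
  }
  storage.mode(calls) <- "integer"
  new("GenotypeMatrix", calls = calls, map = map)
}

#' @describeIn GenotypeMatrix-class integer call matrix accessor (0/1/2/NA)
#' @param x,object a \code{GenotypeMatrix}
#' @export
genotypeCalls <- function(x) x@calls

#' @describeIn GenotypeMatrix-class the genetic map of the markers
#' @export
genotypeMap <- function(x) x@map

setMethod("show", "GenotypeMatrix", function(object) {
  g <- object@calls
  cat(sprintf("GenotypeMatrix: %d markers x %d individuals (%.1f%% missing)\n",
              nrow(g), ncol(g), 100 * mean(is.na(g))))
})

#' LOD curve from an interval-mapping scan
#'
#' LOD profile over a scan grid on one chromosome. LOD is defined as the
#' log10 likelihood ratio of the single-QTL model at the test position
#' against the no-QTL null, so it is non-negative by construction.
#'
#' @slot chrom chromosome scanned.
#' @slot pos scan positions (cM), marker positions included exactly.
#' @slot lod LOD at each position.
#' @slot model \code{"quantitative"}, \code{"binary"} or
#'   \code{"fixed-term"}.
#' @slot fixedMarker marker included as additive+dominance covariate in both
#'   null and alternative fits (fixed-term scans), otherwise \code{NA}.
#' @slot t AIL generation used for the recombination model.
#' @slot flags character flags per position ("" if clean; "noconv" for EM
#'   non-convergence, "separation" for capped logistic fits).
#' @export
setClass("LodCurve", representation(
  chrom = "character",
  pos = "numeric",
  lod = "numeric",
  model = "character",
  fixedMarker = "character",
  t = "integer",
  flags = "character"
))

setValidity("LodCurve", function(object) {
  msg <- character()
  if (length(object@pos) != length(object@lod))
    msg <- c(msg, "pos and lod must have equal length")
  if (any(!is.finite(object@lod)))
    msg <- c(msg, "LOD values must be finite")
  if (any(object@lod < -1e-8))
    msg <- c(msg, "LOD must be non-negative (likelihood-ratio definition)")
  if (is.unsorted(object@pos, strictly = TRUE))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @describeIn LodCurve-class scan positions (cM)
#' @param x,object a \code{LodCurve}
#' @export
lodPositions <- function(x) x@pos

#' @describeIn LodCurve-class LOD values
#' @export
lodValues <- function(x) x@lod

setMethod("show", "LodCurve", function(object) {
  cat(sprintf("LodCurve [%s scan]: chr %s, %d positions (%.2f..%.2f cM), max LOD %.2f at %.2f cM%s\n",
              object@model, object@chrom, length(object@pos),
              min(object@pos), max(object@pos), max(object@lod),
              object@pos[which.max(object@lod)],
              if (!is.na(object@fixedMarker))
                sprintf(", fixed term %s", object@fixedMarker) else ""))
})
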