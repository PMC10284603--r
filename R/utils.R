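# Shared numerical helpers: map-function conversions, AIL map expansion,
# and deterministic sub-seed derivation.

#' Haldane conversion between centimorgan distance and recombination fraction
#'
#' @param cm genetic distance in centimorgan.
#' @return Per-meiosis recombination fraction in [0, 0.5).
#' @examples
#' haldaneR(2)    # ~0.0196
#' @export
haldaneR <- function(cm) {
  if (any(cm < 0)) stop("genetic distance must be non-negative")
  0.5 * (1 - exp(-2 * cm / 100))
}

#' Expected recombinant fraction after t generations of intercrossing
#'
#' For two loci with per-meiosis recombination fraction \code{r}, the
#' fraction of recombinant haplotypes in generation \code{t} of a random
#' mating advanced intercross (F2 = 2) is
#' \deqn{R_t = \frac{1}{2}\left[1 - (1 - 2r)(1 - r)^{t-2}\right]}
#' which follows from the decay of linkage disequilibrium at rate (1 - r)
#' per generation from the F2 value. It reduces to \code{r} at t = 2 and,
#' for small r, grows approximately as \code{r * t / 2} - the map expansion
#' that shrinks AIL confidence intervals roughly t/2-fold relative to an F2.
#'
#' @param r per-meiosis recombination fraction(s), in [0, 0.5].
#' @param t generation index (>= 2); F2 = 2.
#' @return Expected recombinant haplotype fraction, bounded by 0.5.
#' @examples
#' expectedRecombinantFraction(0.01, 2)   # 0.01
#' expectedRecombinantFraction(0.01, 14)  # ~0.0657
#' @export
expectedRecombinantFraction <- function(r, t) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  if (any(t < 2)) stop("t must be >= 2 (F2 = 2)")
  0.5 * (1 - (1 - 2 * r) * (1 - r)^(t - 2))
}

#' Standardized difference between two group means
#'
#' Difference between two means expressed in units of a common standard
#' deviation, as used to express the divergence between parental strains
#' for a trait (e.g. flap valve length).
#'
#' @param meanA,meanB group means.
#' @param sd common standard deviation (> 0).
#' @return (meanA - meanB) / sd.
#' @examples
#' standardizedDifference(1.13, 0.60, 0.11)  # ~4.8
#' @export
standardizedDifference <- function(meanA, meanB, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  (meanA - meanB) / sd
}

# Deterministic 32-bit sub-seed from a global seed and a stage label, so all
# stochastic stages of the pipeline draw from one explicit seed.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# messages used for dropped-record accounting; kept quiet-able via suppressMessages
logCount <- function(fmt, n) {
  if (n > 0) message(sprintf(fmt, n))
  invisible(n)
}
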