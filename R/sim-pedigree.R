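# Breeding-scheme simulator: cascade-mating AIL pedigree.

#' Simulate a cascade-mating AIL pedigree
#'
#' Builds the pedigree of a two-strain advanced intercross line. Two inbred
#' founders (generation 0) produce \code{nPairs} F1 pairs; each pair of every
#' breeding generation contributes exactly one male and one female to the
#' next generation; breeding pairs of generation g+1 are formed by the
#' cascade rule: the female raised in cage c is mated with the male raised in
#' cage c+1 (the ring wraps at the last cage). The population is therefore
#' constant at \code{2 * nPairs} in every generation from F2 onwards, a
#' doubled-effective-size design that limits drift. The terminal generation
#' may be expanded to \code{finalCohortSize} individuals drawn from the same
#' terminal pairings (litters enlarged round-robin), emulating the large
#' phenotyping cohort bred from the final pairs.
#'
#' @param design an [AILDesign-class].
#' @return data.frame with columns \code{id}, \code{generation}, \code{cage},
#'   \code{sex} ("M"/"F"), \code{sire}, \code{dam} (ids; NA for founders).
#'   Generation 0 holds the two founder strains, generation 1 the F1s.
#' @examples
#' ped <- simulatePedigree(AILDesign(nPairs = 4, tFinal = 5, seed = 1))
#' table(ped$generation)
#' @export
simulatePedigree <- function(design) {
  stopifnot(is(design, "AILDesign"))
  validObject(design)
  nP <- design@nPairs
  tF <- design@tFinal

  # founders: strain Q sire, strain q dam
  ped <- data.frame(
    id = c("Q_founder", "q_founder"),
    generation = 0L, cage = NA_integer_,
    sex = c("M", "F"), sire = NA_character_, dam = NA_character_,
    stringsAsFactors = FALSE
  )

  mk <- function(gen, cage, sex, sire, dam) {
    data.frame(id = sprintf("F%d_c%02d_%s", gen, cage, sex),
               generation = gen, cage = cage, sex = sex,
               sire = sire, dam = dam, stringsAsFactors = FALSE)
  }

  # F1: one pair per cage, all offspring of the founder pair
  for (c in seq_len(nP))
    ped <- rbind(ped, mk(1L, c, "M", "Q_founder", "q_founder"),
                 mk(1L, c, "F", "Q_founder", "q_founder"))

  # pairs of generation g live in cages; offspring raised in the dam's cage
  pairs <- data.frame(cage = seq_len(nP),
                      sire = sprintf("F1_c%02d_M", seq_len(nP)),
                      dam = sprintf("F1_c%02d_F", seq_len(nP)),
                      stringsAsFactors = FALSE)

  for (g in 2:tF) {
    nOff <- if (g == tF) design@finalCohortSize else 2L * nP
    cage <- sort(rep(seq_len(nP), length.out = nOff))
    k <- stats::ave(seq_along(cage), cage, FUN = seq_along)
    # within each litter: alternate M, F so every pair contributes one of each
    sex <- ifelse(k %% 2L == 1L, "M", "F")
    off <- data.frame(cage = cage, sex = sex, litterIdx = k,
                      sire = pairs$sire[match(cage, pairs$cage)],
                      dam = pairs$dam[match(cage, pairs$cage)],
                      stringsAsFactors = FALSE)
    off$id <- sprintf("F%d_c%02d_%s%02d", g, off$cage, off$sex,
                      (off$litterIdx + 1L) %/% 2L)
    ped <- rbind(ped, data.frame(id = off$id, generation = g, cage = off$cage,
                                 sex = off$sex, sire = off$sire, dam = off$dam,
                                 stringsAsFactors = FALSE))
    if (g < tF) {
      # cascade: female of cage c x male of cage c+1 (wrap)
      fem <- off$id[off$sex == "F"][match(seq_len(nP), off$cage[off$sex == "F"])]
      mal <- off$id[off$sex == "M"][match(seq_len(nP), off$cage[off$sex == "M"])]
      nxt <- c(seq_len(nP)[-1], 1L)
      pairs <- data.frame(cage = seq_len(nP), sire = mal[nxt], dam = fem,
                          stringsAsFactors = FALSE)
    }
  }
  rownames(ped) <- ped$id
  ped
}
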