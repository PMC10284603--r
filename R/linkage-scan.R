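# Interval-mapping scans: EM on the three-component Gaussian mixture for
# quantitative traits, logistic likelihood-ratio scans for binary traits.
# A fixed marker (composite-interval-mapping style) enters BOTH the null
# and the alternative fit so the likelihood ratio isolates the test
# position.

#' Covariate-adjust a phenotype
#'
#' Fits a least-squares linear model of the trait on the given covariates
#' and returns the residuals re-centred at the trait mean, the standard
#' pre-scan normalization (e.g. heart weight adjusted for age, sex and body
#' weight). Individuals with missing trait or covariate values are dropped
#' with a logged count.
#'
#' @param phenotypes data.frame with an \code{id} column, the trait column
#'   and the covariate columns.
#' @param trait trait column name.
#' @param covariates character vector of covariate column names (must be
#'   non-empty: with nothing to adjust for, the call is an error).
#' @return data.frame(id, value) of adjusted values for retained rows.
#' @export
normalizePhenotype <- function(phenotypes, trait, covariates) {
  if (length(covariates) == 0L) stop("no covariates to adjust for")
  stopifnot(trait %in% names(phenotypes), all(covariates %in% names(phenotypes)))
  d <- phenotypes[, c("id", trait, covariates), drop = FALSE]
  ok <- stats::complete.cases(d)
  logCount("normalizePhenotype: dropped %d individual(s) with missing values", sum(!ok))
  d <- d[ok, , drop = FALSE]
  y <- d[[trait]]
  X <- stats::model.matrix(~ ., data = d[, covariates, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  data.frame(id = d$id, value = fit$residuals + mean(y), stringsAsFactors = FALSE)
}

#' Convert genetic-map positions between maps by linear interpolation
#'
#' Piecewise-linear interpolation between anchor markers with known
#' positions on both the old and the new map (the standard way to port
#' legacy cM positions onto a current map). No extrapolation: queries
#' outside the anchor span are an error.
#'
#' @param oldPos numeric query positions on the old scale.
#' @param anchorsOld,anchorsNew anchor positions, strictly increasing on
#'   both scales, equal length >= 2.
#' @return Positions on the new scale.
#' @examples
#' convertMap(20, c(10, 30), c(20, 40))  # 30
#' @export
convertMap <- function(oldPos, anchorsOld, anchorsNew) {
  if (length(anchorsOld) != length(anchorsNew) || length(anchorsOld) < 2)
    stop("need >= 2 anchors of equal length")
  if (is.unsorted(anchorsOld, strictly = TRUE) ||
      is.unsorted(anchorsNew, strictly = TRUE))
    stop("anchors must be strictly increasing on both scales")
  if (any(oldPos < min(anchorsOld) | oldPos > max(anchorsOld)))
    stop("query outside the anchor span (no extrapolation)")
  stats::approx(anchorsOld, anchorsNew, xout = oldPos)$y
}

# ---- EM machinery -------------------------------------------------------

# Gaussian log-likelihood of the null linear model y ~ X (X includes
# intercept), MLE sigma.
nullGaussianLogLik <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / length(y)
  list(logLik = -length(y) / 2 * (log(2 * pi * s2) + 1), coef = fit$coefficients,
       sigma = sqrt(s2))
}

# EM fit of the 3-component mixture y_i ~ sum_g P_ig N(mu_g + X_i beta,
# sigma) against prior genotype probabilities P (n x 3). X may be NULL or a
# matrix WITHOUT intercept (absorbed into mu). Returns logLik, mu, beta,
# sigma, converged.
emMixtureFit <- function(y, P, X = NULL, tol = 1e-8, maxit = 200L) {
  n <- length(y)
  k <- if (is.null(X)) 0L else ncol(X)
  # Haley-Knott start: regression on expected dosage
  add <- P[, 3] - P[, 1]
  dom <- P[, 2]
  D <- cbind(1, add, dom, X)
  hk <- stats::lm.fit(D, y)
  cf <- ifelse(is.na(hk$coefficients), 0, hk$coefficients)
  mu <- cf[1] + c(-cf[2], cf[3], cf[2])
  beta <- if (k) cf[-(1:3)] else numeric(0)
  sigma <- max(sqrt(sum(hk$residuals^2) / n), 1e-6)

  if (k) Xs <- rbind(cbind(1, 0, 0, X), cbind(0, 1, 0, X), cbind(0, 0, 1, X))
  ll <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- if (k) drop(X %*% beta) else 0
    dens <- vapply(1:3, function(g)
      P[, g] * stats::dnorm(y, eta + mu[g], sigma), numeric(n))
    rs <- rowSums(dens)
    rs[rs < 1e-300] <- 1e-300
    newll <- sum(log(rs))
    if (is.finite(newll) && abs(newll - ll) < tol * (abs(newll) + 1)) {
      ll <- newll; converged <- TRUE; break
    }
    ll <- newll
    W <- dens / rs
    if (!k) {
      cs <- colSums(W)
      mu <- colSums(W * y) / pmax(cs, 1e-12)
      sigma <- sqrt(sum(W * (outer(y, mu, "-"))^2) / n)
    } else {
      w <- c(W[, 1], W[, 2], W[, 3])
      fit <- stats::lm.wfit(Xs, rep(y, 3), w)
      cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      mu <- cf[1:3]
      beta <- cf[-(1:3)]
      sigma <- sqrt(sum(w * fit$residuals^2) / n)
    }
    sigma <- max(sigma, 1e-8)
  }
  list(logLik = ll, mu = mu, beta = beta, sigma = sigma, converged = converged)
}

# scan grid: step-spaced positions snapped to include every marker exactly
scanGrid <- function(cm, step) {
  g <- seq(min(cm), max(cm), by = step)
  sort(unique(round(c(g, cm), 6)))
}

# fixed-term covariate columns (expected additive dosage and dominance
# probability at the fixed marker), used in both null and alternative fits
fixedTermX <- function(genotypes, fixedMarker, t) {
  mk <- mapMarkers(genotypeMap(genotypes))
  row <- mk[mk$marker == fixedMarker, , drop = FALSE]
  if (!nrow(row)) stop("fixed marker not on the map: ", fixedMarker)
  Pf <- qtlGenotypeProbs(genotypes, row$chrom, row$cm, t)
  cbind(fmAdd = Pf[, 3] - Pf[, 1], fmDom = Pf[, 2])
}

#' Quantitative interval-mapping scan (maximum likelihood / EM)
#'
#' At each grid position the trait is modelled as a three-component Gaussian
#' mixture with genotype-class means and a common residual SD, mixed by the
#' conditional genotype probabilities of [qtlGenotypeProbs()]; the mixture
#' is maximised by EM and compared with the no-QTL single-Gaussian null.
#' LOD = log10 of the likelihood ratio. With a fixed marker, its expected
#' additive dosage and dominance probability enter both null and
#' alternative fits (simplified composite interval mapping), so the LOD
#' isolates the test position.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param trait numeric trait values in genotype-column order (no NAs).
#' @param t AIL generation (2 = F2).
#' @param step scan step in cM (default 0.25); marker positions are always
#'   included exactly.
#' @param fixedMarker optional marker name included as a fixed term.
#' @param chrom chromosomes to scan (default: all on the map).
#' @param tol,maxit EM convergence controls (relative log-likelihood change
#'   and iteration cap; non-convergent positions keep the best-so-far LOD
#'   and are flagged).
#' @return Named list of [LodCurve-class], one per scanned chromosome.
#' @export
scanQuantitative <- function(genotypes, trait, t = 2L, step = 0.25,
                             fixedMarker = NULL, chrom = NULL,
                             tol = 1e-8, maxit = 200L) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  y <- as.numeric(trait)
  if (anyNA(y) || any(!is.finite(y))) stop("trait values must be finite")
  if (stats::var(y) == 0) stop("trait is monomorphic (zero variance)")
  if (length(y) != ncol(genotypeCalls(genotypes)))
    stop("trait length must match the number of individuals")

  X <- if (is.null(fixedMarker)) NULL else fixedTermX(genotypes, fixedMarker, t)
  null <- nullGaussianLogLik(y, cbind(rep(1, length(y)), X))
  mk <- mapMarkers(genotypeMap(genotypes))
  if (is.null(chrom)) chrom <- unique(mk$chrom)

  out <- list()
  for (ch in chrom) {
    cm <- mk$cm[mk$chrom == ch]
    grid <- scanGrid(cm, step)
    lod <- numeric(length(grid))
    flags <- character(length(grid))
    for (j in seq_along(grid)) {
      P <- qtlGenotypeProbs(genotypes, ch, grid[j], t)
      fit <- emMixtureFit(y, P, X, tol = tol, maxit = maxit)
      lod[j] <- max(0, (fit$logLik - null$logLik) / log(10))
      flags[j] <- if (fit$converged) "" else "noconv"
    }
    out[[ch]] <- new("LodCurve", chrom = as.character(ch), pos = grid,
                     lod = lod,
                     model = if (is.null(fixedMarker)) "quantitative" else "fixed-term",
                     fixedMarker = if (is.null(fixedMarker)) NA_character_ else fixedMarker,
                     t = as.integer(t), flags = flags)
  }
  out
}

#' Binary-trait interval-mapping scan (logistic likelihood ratio)
#'
#' Logistic regression of a 0/1 trait on the expected additive dosage and
#' dominance probability at each grid position (from [qtlGenotypeProbs()]),
#' against the null without the position terms;
#' LOD = (deviance_null - deviance_alt) / (2 ln 10). Optionally the hard
#' genotype calls at typed positions can be used instead of dosages. Fits
#' with complete separation are capped at the saturated-model bound and
#' flagged.
#'
#' @inheritParams scanQuantitative
#' @param trait binary 0/1 trait values; both classes must be present.
#' @param useDosage if FALSE, hard calls (additive -1/0/1 and heterozygote
#'   indicator) are used at typed markers; dosages elsewhere.
#' @return Named list of [LodCurve-class].
#' @export
scanBinary <- function(genotypes, trait, t = 2L, step = 0.25,
                       fixedMarker = NULL, chrom = NULL, useDosage = TRUE) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  y <- as.integer(trait)
  if (anyNA(y) || !all(y %in% 0:1)) stop("binary trait must be 0/1 with no NAs")
  if (length(unique(y)) < 2L) stop("binary trait has a single class")

  X <- if (is.null(fixedMarker)) NULL else fixedTermX(genotypes, fixedMarker, t)
  nullFit <- suppressWarnings(stats::glm.fit(cbind(rep(1, length(y)), X), y,
                                             family = stats::binomial()))
  dev0 <- nullFit$deviance
  mk <- mapMarkers(genotypeMap(genotypes))
  if (is.null(chrom)) chrom <- unique(mk$chrom)
  calls <- genotypeCalls(genotypes)

  out <- list()
  for (ch in chrom) {
    onChr <- mk[mk$chrom == ch, , drop = FALSE]
    grid <- scanGrid(onChr$cm, step)
    lod <- numeric(length(grid))
    flags <- character(length(grid))
    for (j in seq_along(grid)) {
      P <- qtlGenotypeProbs(genotypes, ch, grid[j], t)
      add <- P[, 3] - P[, 1]
      dom <- P[, 2]
      if (!useDosage) {
        hit <- which(abs(onChr$cm - grid[j]) < 1e-9)
        if (length(hit)) {
          g <- calls[onChr$marker[hit[1]], ]
          add <- ifelse(is.na(g), add, g - 1L)
          dom <- ifelse(is.na(g), dom, as.integer(g == 1L))
        }
      }
      D <- cbind(1, add, dom, X)
      fit <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
      sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
      dev1 <- if (sep) 0 else fit$deviance       # saturated-bound cap
      lod[j] <- max(0, (dev0 - dev1) / (2 * log(10)))
      flags[j] <- if (sep) "separation" else ""
    }
    out[[ch]] <- new("LodCurve", chrom = as.character(ch), pos = grid,
                     lod = lod, model = "binary",
                     fixedMarker = if (is.null(fixedMarker)) NA_character_ else fixedMarker,
                     t = as.integer(t), flags = flags)
  }
  out
}
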