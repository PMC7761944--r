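# Validation analytics: per-technique trueness/precision versus the gold
# standard, Bland-Altman reproducibility, repeated-scan error, and the
# nonparametric comparisons (Friedman, Wilcoxon signed rank with Bonferroni
# adjustment, Mann-Whitney, Kruskal-Wallis) as a thin harness over the
# standard routines.

#' Measure a benchmark with a set of techniques
#'
#' Runs \code{\link{measureWear}} on every case for every technique and
#' returns the per-case wear volumes plus differences from the gold
#' standard.
#'
#' @param cases list of \linkS4class{WearCase}.
#' @param techniques technique ids (must include "GS" for differences).
#' @param seed integer seed.
#' @param ... passed to \code{\link{measureWear}}.
#' @return data.frame with caseId, techniqueId, wear, trueVolume, diffGS and
#'   case covariates.
#' @export
measureBenchmark <- function(cases, techniques = c("GS", "CC_C"), seed = 1L,
                             ...) {
  rows <- list()
  for (case in cases) {
    wears <- vapply(techniques, function(tech) {
      wearVolume(measureCaseWear(case, tech, seed = seed, ...))
    }, numeric(1))
    gs <- if ("GS" %in% techniques) wears[["GS"]] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      caseId = case@id, techniqueId = techniques, wear = as.numeric(wears),
      trueVolume = case@trueRemovedVolume, diffGS = as.numeric(wears) - gs,
      toothType = case@info$toothType, loss = case@info$verticalLoss,
      pattern = case@info$pattern, crowding = isTRUE(case@info$crowding),
      row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Measure one case with one technique
#'
#' @param case a \linkS4class{WearCase}.
#' @param technique technique id or \linkS4class{TechniqueSpec}.
#' @param seed integer seed.
#' @param landmarkJitterSd optional sd (mm) of Gaussian jitter added to the
#'   coarse-alignment landmarks: the in-silico analog of the operator's
#'   manual approximation varying between repeated sessions.
#' @param ... passed to \code{\link{measureWear}}.
#' @return a \linkS4class{WearMeasurement}.
#' @export
measureCaseWear <- function(case, technique, seed = 1L, landmarkJitterSd = 0,
                            ...) {
  lm <- list(t0 = case@t0Landmarks, t1 = case@t1Landmarks)
  if (landmarkJitterSd > 0) {
    rng <- localSeed(seed, 67L)
    lm$t1 <- lm$t1 + matrix(rng$rnorm(12, sd = landmarkJitterSd), 4, 3)
  }
  measureWear(case@t0, case@t1, case@t0Labels, case@t1Labels, technique,
              lm, seed = seed, ...)
}

#' Trueness and precision summaries per technique
#'
#' Trueness is the median difference from the gold standard (zero = perfect);
#' precision is the spread of the individual deviations (range and IQR).
#'
#' @param diffs data.frame with columns techniqueId and diff (mm^3), e.g.
#'   \code{diffGS} from \code{\link{measureBenchmark}}.
#' @return data.frame: techniqueId, n, median, min, max, iqr, maxAbs.
#' @export
truenessPrecision <- function(diffs) {
  if (!nrow(diffs)) stop("empty difference table")
  sp <- split(diffs$diff, diffs$techniqueId)
  out <- do.call(rbind, lapply(names(sp), function(id) {
    x <- sp[[id]]
    if (!length(x)) stop("empty group: ", id)
    data.frame(techniqueId = id, n = length(x), median = median(x),
               min = min(x), max = max(x), iqr = IQR(x), maxAbs = max(abs(x)))
  }))
  out[order(out$techniqueId), , drop = FALSE]
}

#' Bland-Altman agreement of repeated measurements
#'
#' @param pairs data.frame with columns measurement1 and measurement2 (mm^3)
#'   and optionally caseId / techniqueId.
#' @return list with per-pair differences, mean difference, sd, and 95\%
#'   limits of agreement (mean +- 1.96 sd).
#' @export
blandAltman <- function(pairs) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  d <- pairs$measurement1 - pairs$measurement2
  m <- (pairs$measurement1 + pairs$measurement2) / 2
  mu <- mean(d)
  s <- sd(d)
  list(differences = d, means = m, meanDifference = mu, sd = s,
       loa = c(lower = mu - 1.96 * s, upper = mu + 1.96 * s),
       maxAbsDifference = max(abs(d)))
}

#' Nonparametric technique comparisons
#'
#' Friedman's test over the complete blocks of per-case differences, pairwise
#' Wilcoxon signed-rank tests with Bonferroni adjustment, and unpaired rank
#' tests (Mann-Whitney for two-level covariates, Kruskal-Wallis otherwise)
#' for the effect of tooth type, crowding and wear amount within each
#' technique. Raw p-values are reported; the alpha level is left to the
#' caller.
#'
#' @param diffs data.frame with caseId, techniqueId, diff, and optional
#'   covariate columns toothType, crowding, loss.
#' @return list with \code{friedman} (htest), \code{pairwise} (data.frame
#'   with raw and Bonferroni-adjusted p), and \code{covariates}.
#' @export
compareTechniques <- function(diffs) {
  wide <- tapply(diffs$diff, list(diffs$caseId, diffs$techniqueId), identity)
  wide <- matrix(unlist(wide), nrow = nrow(wide), dimnames = dimnames(wide))
  if (anyNA(wide)) stop("incomplete blocks: every case needs every technique")
  fr <- friedman.test(wide)
  if (is.nan(fr$statistic)) {
    # fully tied blocks (identical columns): no evidence of any difference
    fr$statistic[] <- 0
    fr$p.value <- 1
  }
  ids <- colnames(wide)
  pw <- list()
  if (length(ids) > 1) {
    cmb <- combn(ids, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      wt <- suppressWarnings(wilcox.test(wide[, a], wide[, b], paired = TRUE))
      pw[[k]] <- data.frame(techniqueA = a, techniqueB = b, p = wt$p.value)
    }
  }
  pw <- if (length(pw)) do.call(rbind, pw) else NULL
  if (!is.null(pw)) pw$pAdjusted <- p.adjust(pw$p, method = "bonferroni")
  covs <- list()
  for (cv in intersect(c("toothType", "crowding", "loss"), names(diffs))) {
    per <- lapply(split(diffs, diffs$techniqueId), function(g) {
      grp <- factor(g[[cv]])
      if (nlevels(grp) < 2) return(NA_real_)
      if (nlevels(grp) == 2)
        suppressWarnings(wilcox.test(g$diff ~ grp))$p.value
      else
        kruskal.test(g$diff ~ grp)$p.value
    })
    covs[[cv]] <- unlist(per)
  }
  list(friedman = fr, pairwise = pw, covariates = covs)
}

#' Repeated-scan (scanner plus superimposition) error
#'
#' For single teeth: two independent scan-noise realisations of the same
#' tooth, a random relative pose of the second scan, superimposition of the
#' complete crown at 20\% estimated overlap (the clinical technique of
#' choice) and the full wear measurement. With no morphological change the
#' absolute measured volume difference is the scanner-plus-superimposition
#' error.
#'
#' @param n number of teeth (default 10).
#' @param noise a \code{\link{scanNoiseSpec}}.
#' @param technique technique id (default "CC_C").
#' @param seed integer seed.
#' @param resolution triangle target per tooth.
#' @return list with the per-tooth absolute differences (mm^3), their median
#'   and range.
#' @export
repeatedScanError <- function(n = 10L, noise = scanNoiseSpec(),
                              technique = "CC_C", seed = 1L,
                              resolution = 8000L) {
  if (n < 2) stop("need at least 2 teeth")
  diffs <- numeric(n)
  for (k in seq_len(n)) {
    tt <- if (k %% 2 == 0) "canine" else "incisor"
    tooth <- generateTooth(toothSpec(tt, resolution = resolution))
    s <- (as.numeric(seed) %% 100000) * 100 + k
    scan1 <- applyScanNoise(tooth, noise, seed = s)
    scan2 <- applyScanNoise(tooth, noise, seed = s + 50)
    rng <- localSeed(s, 13L)
    pose <- randomRigidDisplacement(rng)
    scan2 <- applyTransform(scan2, pose)
    h <- max(tooth@vertices[, 3])
    landmarks <- rbind(c(0, 0, h), c(0, -3, 0), c(-3, 0, h * 0.4), c(3, 0, h * 0.4))
    crown <- RegionMask("crown", which(scan1@vertices[, 3] > 0), scan1)
    labels <- list(crown = crown)
    m <- measureWear(scan1, scan2, labels, labels, technique,
                     list(t0 = landmarks, t1 = applyTransform(landmarks, pose)),
                     seed = s)
    diffs[k] <- abs(wearVolume(m))
  }
  list(differences = diffs, median = median(diffs), range = range(diffs),
       max = max(diffs))
}

#' Reproducibility of the wear measurement
#'
#' Re-measures each case with an independently perturbed initial
#' approximation (jittered coarse-alignment landmarks), the in-silico analog
#' of an operator repeating the measurement after an interval, and reports
#' the per-case differences and their Bland-Altman summary per technique.
#'
#' @param cases list of \linkS4class{WearCase}.
#' @param techniques technique ids (default GS and CC_C, the two assessed for
#'   intra-operator error).
#' @param landmarkJitterSd sd of the landmark jitter, mm.
#' @param seed integer seed.
#' @param ... passed to \code{\link{measureWear}}.
#' @return data.frame with caseId, techniqueId, measurement1, measurement2,
#'   difference; the per-technique \code{\link{blandAltman}} summaries are
#'   attached as attribute \code{"blandAltman"}.
#' @export
measureReproducibility <- function(cases, techniques = c("GS", "CC_C"),
                                   landmarkJitterSd = 0.3, seed = 1L, ...) {
  rows <- list()
  for (case in cases) {
    for (tech in techniques) {
      m1 <- measureCaseWear(case, tech, seed = seed, ...)
      m2 <- measureCaseWear(case, tech, seed = seed + 9999L,
                            landmarkJitterSd = landmarkJitterSd, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        caseId = case@id, techniqueId = tech,
        measurement1 = wearVolume(m1), measurement2 = wearVolume(m2),
        difference = wearVolume(m1) - wearVolume(m2))
    }
  }
  out <- do.call(rbind, rows)
  ba <- lapply(split(out, out$techniqueId), function(g)
    blandAltman(g[, c("measurement1", "measurement2")]))
  attr(out, "blandAltman") <- ba
  out
}
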