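## Synthetic pyrosequencing allele-frequency data: gDNA fractions centred
## on k/ploidy, cDNA fractions centred either on a composition-consistent
## expression profile or on per-assay target fractions, with beta-binomial
## replicate noise.

#' Expected genomic diagnostic-base frequency under the copy-number null
#'
#' An allele (or set of alleles sharing a diagnostic base) present in k of
#' the ploidy chromosome sets contributes fraction k/ploidy of molecules in
#' genomic DNA: 0.2, 0.4 and 0.6 for one, two and three copies in a
#' pentaploid. Under equal per-copy transcription the same fractions are
#' expected in cDNA pools, which is the null hypothesis the ASE tests use.
#'
#' @param k integer carrier copies, \eqn{1 \le k \le ploidy}.
#' @param ploidy integer genome copies (default 5).
#' @return numeric fraction \code{k/ploidy}.
#' @examples
#' expectedFrequency(2, 5)  # 0.4
#' @export
expectedFrequency <- function(k, ploidy = 5L) {
  if (any(k < 1L) || any(k > ploidy) || any(k != round(k)))
    stop("carrier copies k must be integers in [1, ploidy]")
  k / ploidy
}

#' Expected cDNA diagnostic-base frequency under an expression profile
#'
#' With per-copy transcription rates e_a, the expected cDNA fraction of the
#' diagnostic base shared by a carrier set C is
#' \eqn{\sum_{a \in C} k_a e_a / \sum_b k_b e_b}. Equal rates reduce this to
#' the genomic null k/ploidy; only rate ratios matter.
#'
#' @param copyNumbers named numeric/integer vector of copies per allele.
#' @param carriers character vector of carrier allele labels (subset of
#'   \code{names(copyNumbers)}).
#' @param rates optional named per-copy rates (> 0); default all equal.
#' @return expected cDNA fraction.
#' @examples
#' k <- c("LEAFY-1" = 1, "LEAFY-2" = 1, "LEAFY-3" = 2, "LEAFY-4" = 1)
#' cdnaExpectedFrequency(k, "LEAFY-3")                    # 0.4 under the null
#' cdnaExpectedFrequency(k, "LEAFY-3", rates = c("LEAFY-3" = 0.25,
#'   "LEAFY-1" = 1, "LEAFY-2" = 1, "LEAFY-4" = 1))        # depressed allele
#' @export
cdnaExpectedFrequency <- function(copyNumbers, carriers, rates = NULL) {
  alleles <- names(copyNumbers)
  if (is.null(rates)) rates <- setNames(rep(1, length(alleles)), alleles)
  if (!all(carriers %in% alleles)) stop("carriers must be among the alleles")
  if (!all(alleles %in% names(rates))) stop("rates must cover every allele")
  rates <- rates[alleles]
  if (any(rates <= 0)) stop("per-copy rates must be strictly positive")
  sum(copyNumbers[carriers] * rates[carriers]) / sum(copyNumbers * rates)
}

#' Technical noise model for one pyrosequencing assay
#'
#' Replicate diagnostic-base counts are modelled beta-binomial: depth N
#' reads, mean equal to the (optionally biased, clipped) true fraction and
#' intra-class correlation \code{rho}; \code{rho = 0} degenerates to
#' binomial sampling. \code{bias} is a multiplicative per-assay distortion
#' of the true fraction (default none).
#'
#' @param depth integer reads per replicate (nominal instrument depth);
#'   \code{Inf} gives noiseless measurements (every replicate reports the
#'   true fraction exactly).
#' @param rho beta-binomial intra-class correlation in [0, 1).
#' @param bias multiplicative assay bias > 0.
#' @return a list of class \code{"assayNoise"}.
#' @export
assayNoise <- function(depth = 500L, rho = 0.005, bias = 1) {
  if (depth < 1L) stop("depth must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (bias <= 0) stop("bias must be > 0")
  structure(list(depth = if (is.finite(depth)) as.integer(depth) else Inf,
                 rho = rho, bias = bias),
            class = "assayNoise")
}

## one beta-binomial draw per replicate; rho = 0 -> binomial
.rbetabinom <- function(n, size, mean, rho) {
  if (mean <= 0) return(integer(n))
  if (mean >= 1) return(rep(size, n))
  if (rho == 0) return(rbinom(n, size, mean))
  a <- mean * (1 - rho) / rho
  b <- (1 - mean) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate replicate fraction measurements for one assay
#'
#' @param trueFraction underlying diagnostic-base fraction in \eqn{[0, 1]}.
#' @param noise an [assayNoise()] model.
#' @param nReplicates number of replicate measurements.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{replicate}, \code{fraction},
#'   \code{depth}.
#' @examples
#' simulateAssay(0.4, assayNoise(depth = 500, rho = 0.005), nReplicates = 3,
#'               seed = 1)
#' @export
simulateAssay <- function(trueFraction, noise = assayNoise(), nReplicates = 1L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- min(max(trueFraction * noise$bias, 0), 1)
  if (is.infinite(noise$depth))
    return(data.frame(replicate = seq_len(nReplicates), fraction = m,
                      depth = NA_integer_))
  counts <- .rbetabinom(nReplicates, noise$depth, m, noise$rho)
  data.frame(replicate = seq_len(nReplicates),
             fraction = counts / noise$depth, depth = noise$depth)
}

#' Simulate a full pyrosequencing experiment (gDNA + cDNA pools)
#'
#' Emulates the study design: per individual, \code{nGdnaReplicates} PCR
#' products from genomic DNA (bud stage NA) and \code{nCdnaReplicates} PCR
#' products from cDNA pools of each bud stage. gDNA fractions are centred
#' on the copy-number null k/ploidy; cDNA fractions are centred either on
#' [cdnaExpectedFrequency()] under \code{rates} (composition-consistent
#' mode) or on per-assay target fractions (\code{cdnaTargets}, independent
#' assays -- each real pyrosequencing assay carries its own bias, so
#' observed per-assay fractions need not be mutually consistent).
#'
#' @param copyNumbers named vector of copies per allele (summing to the
#'   ploidy), or a [CaninaGenotype-class] plus \code{locus}.
#' @param assays data.frame with columns \code{assay_id}, \code{locus},
#'   \code{position}, \code{diagnostic_base}, \code{carriers}
#'   (comma-separated allele labels).
#' @param noise an [assayNoise()] model.
#' @param rates optional named per-copy transcription rates (mode a).
#' @param cdnaTargets optional named numeric, per-assay target cDNA
#'   fraction (mode b; overrides \code{rates} for listed assays).
#' @param individuals character vector of individual ids.
#' @param budStages character vector of cDNA bud stages.
#' @param stageEffect optional named multiplier per bud stage on the cDNA
#'   fraction (default none, matching the absence of a bud-age effect).
#' @param nGdnaReplicates,nCdnaReplicates replicate PCR products per
#'   individual (gDNA) and per individual x stage (cDNA).
#' @param ploidy genome copies.
#' @param locus locus name when \code{copyNumbers} is a genotype.
#' @param seed optional integer seed.
#' @return a frequency-observation data.frame (columns \code{assay_id},
#'   \code{locus}, \code{template}, \code{individual}, \code{bud_stage},
#'   \code{replicate}, \code{fraction}, \code{depth}).
#' @export
simulateExperiment <- function(copyNumbers, assays, noise = assayNoise(),
                               rates = NULL, cdnaTargets = NULL,
                               individuals = c("H13", "H19", "H20"),
                               budStages = c("small", "large"),
                               stageEffect = NULL,
                               nGdnaReplicates = 2L, nCdnaReplicates = 3L,
                               ploidy = 5L, locus = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is(copyNumbers, "CaninaGenotype")) {
    if (is.null(locus)) stop("locus required when passing a genotype")
    copyNumbers <- alleleCopyNumbers(copyNumbers, locus)
  }
  if (abs(sum(copyNumbers) - ploidy) > 1e-9)
    stop("copy numbers must sum to the ploidy")
  rows <- list()
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    carriers <- strsplit(a$carriers, ",", fixed = TRUE)[[1]]
    carriers <- trimws(carriers)
    if (!all(carriers %in% names(copyNumbers)))
      stop("assay ", a$assay_id, " references unknown allele(s): ",
           paste(setdiff(carriers, names(copyNumbers)), collapse = ", "))
    gFrac <- sum(copyNumbers[carriers]) / ploidy
    cFrac <- if (!is.null(cdnaTargets) && a$assay_id %in% names(cdnaTargets))
      cdnaTargets[[a$assay_id]]
    else cdnaExpectedFrequency(copyNumbers, carriers, rates)
    for (ind in individuals) {
      g <- simulateAssay(gFrac, noise, nGdnaReplicates)
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = a$assay_id, locus = a$locus, template = "gDNA",
        individual = ind, bud_stage = NA_character_,
        replicate = g$replicate, fraction = g$fraction, depth = g$depth)
      for (stage in budStages) {
        mult <- if (!is.null(stageEffect) && stage %in% names(stageEffect))
          stageEffect[[stage]] else 1
        cc <- simulateAssay(min(cFrac * mult, 1), noise, nCdnaReplicates)
        rows[[length(rows) + 1L]] <- data.frame(
          assay_id = a$assay_id, locus = a$locus, template = "cDNA",
          individual = ind, bud_stage = stage,
          replicate = cc$replicate, fraction = cc$fraction, depth = cc$depth)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
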