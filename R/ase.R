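## Allele-specific transcription: fold deviations of cDNA fractions from
## the copy-number null, a mixed-model ANOVA comparing templates with
## individual as random factor, and one-way nuisance-factor ANOVAs.

#' Fold deviation of cDNA fractions from the copy-number null
#'
#' \code{fold = mean(cDNA fraction) / expected}, with a seeded percentile
#' bootstrap confidence interval over replicates. Values below 1 are
#' reported as "(1/fold)-fold lower" so that, e.g., a two-copy allele
#' measured at 0.174 against an expected 0.4 reads as 2.3-fold lower.
#'
#' @param fractions numeric vector of cDNA replicate fractions.
#' @param expected expected fraction under the null (in (0, 1]).
#' @param nBoot bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional integer seed for the bootstrap.
#' @return list: \code{fold} (observed/expected), \code{foldReported}
#'   (\code{max(fold, 1/fold)}), \code{direction} ("up", "down" or
#'   "null"), \code{label} (e.g. "2.3-fold lower"), \code{ci} (percentile
#'   CI on \code{fold}), \code{n}.
#' @examples
#' foldDeviation(c(0.17, 0.18, 0.175), expected = 0.4, seed = 1)
#' @export
foldDeviation <- function(fractions, expected, nBoot = 1000L, conf = 0.95,
                          seed = NULL) {
  if (expected <= 0 || expected > 1) stop("expected must lie in (0, 1]")
  fractions <- fractions[!is.na(fractions)]
  if (length(fractions) < 1L) stop("need at least one cDNA observation")
  fold <- mean(fractions) / expected
  ci <- c(NA_real_, NA_real_)
  if (length(fractions) > 1L && nBoot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boots <- vapply(seq_len(nBoot), function(i)
      mean(sample(fractions, replace = TRUE)) / expected, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  direction <- if (fold > 1) "up" else if (fold < 1) "down" else "null"
  reported <- if (fold >= 1) fold else 1 / fold
  label <- if (fold == 1) "1-fold (null)"
  else sprintf("%.1f-fold %s", reported, if (fold > 1) "higher" else "lower")
  list(fold = fold, foldReported = reported, direction = direction,
       label = label, ci = ci, n = length(fractions))
}

#' Mixed-model ANOVA comparing gDNA and cDNA fractions
#'
#' Tests whether the diagnostic-base fraction measured in cDNA differs
#' from genomic DNA for one assay, treating template as a fixed factor and
#' individual as random. Implemented as the classical expected-mean-squares
#' ANOVA: \eqn{F = MS(template) / MS(template \times individual)} with 1
#' and \eqn{(n_{ind} - 1)} denominator degrees of freedom -- the exact
#' mixed-model test for this layout and free of fitting-failure modes at
#' the tiny sample sizes typical of pyrosequencing designs. With a single
#' individual the test falls back to a one-way ANOVA on template with a
#' warning.
#'
#' @param observations frequency-observation rows of one assay (both
#'   templates present).
#' @return list: \code{p}, \code{F}, \code{df} (numerator, denominator),
#'   \code{effect} (difference of template marginal means, cDNA - gDNA),
#'   \code{method}.
#' @export
glmTemplateTest <- function(observations) {
  d <- observations[!is.na(observations$fraction), , drop = FALSE]
  if (length(unique(d$template)) < 2L)
    stop("both templates (gDNA and cDNA) required")
  d$template <- factor(d$template)
  d$individual <- factor(d$individual)
  effect <- mean(tapply(d$fraction[d$template == "cDNA"],
                        droplevels(d$individual[d$template == "cDNA"]), mean)) -
            mean(tapply(d$fraction[d$template == "gDNA"],
                        droplevels(d$individual[d$template == "gDNA"]), mean))
  if (var(d$fraction) == 0)
    return(list(p = 1, F = 0, df = c(NA, NA), effect = 0,
                method = "degenerate (constant response)"))
  if (nlevels(d$individual) < 2L) {
    warning("single individual: falling back to one-way ANOVA on template")
    fit <- anova(aov(fraction ~ template, data = d))
    return(list(p = fit[["Pr(>F)"]][1], F = fit[["F value"]][1],
                df = c(fit$Df[1], fit$Df[2]), effect = effect,
                method = "one-way ANOVA (single individual)"))
  }
  tab <- anova(aov(fraction ~ template * individual, data = d))
  msT <- tab["template", "Mean Sq"]
  msTI <- tab["template:individual", "Mean Sq"]
  dfT <- tab["template", "Df"]
  dfTI <- tab["template:individual", "Df"]
  if (!is.finite(msTI) || msTI <= 0) {
    Fstat <- if (msT <= 0) 0 else Inf
  } else Fstat <- msT / msTI
  p <- if (Fstat == 0) 1 else pf(Fstat, dfT, dfTI, lower.tail = FALSE)
  list(p = p, F = Fstat, df = c(dfT, dfTI), effect = effect,
       method = "EMS mixed-model ANOVA (template fixed, individual random)")
}

#' One-way ANOVA for nuisance factors on cDNA fractions
#'
#' Tests the influence of bud age or of the individual on the transcript
#' fraction of an assay (cDNA rows only).
#'
#' @param observations frequency-observation rows of one assay.
#' @param factor \code{"bud_stage"} or \code{"individual"}.
#' @return list: \code{p}, \code{F}, \code{df}, \code{degenerate} (TRUE
#'   with \code{p = NA} when the response is constant).
#' @export
anovaNuisanceTest <- function(observations, factor = c("bud_stage", "individual")) {
  factor <- match.arg(factor)
  d <- observations[observations$template == "cDNA" &
                    !is.na(observations$fraction), , drop = FALSE]
  f <- base::factor(d[[factor]])
  if (nlevels(f) < 2L) stop("factor '", factor, "' needs at least 2 levels")
  if (var(d$fraction) == 0) {
    warning("constant response: no test performed")
    return(list(p = NA_real_, F = NA_real_, df = c(NA, NA), degenerate = TRUE))
  }
  tab <- anova(aov(d$fraction ~ f))
  list(p = tab[["Pr(>F)"]][1], F = tab[["F value"]][1],
       df = c(tab$Df[1], tab$Df[2]), degenerate = FALSE)
}

#' Allele-specific expression report
#'
#' One row per assay per group of individuals sharing the same genomic
#' composition at that assay (individuals with a different composition,
#' and hence a different null, are reported separately). Each row carries
#' the expected fraction under the copy-number null, the mean observed
#' cDNA fraction, the fold deviation with its reported direction, the
#' mixed-model template p-value, and (optionally) Benjamini-Hochberg
#' adjusted p-values across the assays of the locus.
#'
#' @param calls list of [CopyNumberCall-class] keyed by individual.
#' @param observations frequency-observation data.frame.
#' @param assays assay table.
#' @param ploidy genome copies.
#' @param adjust add BH-adjusted p-values (default TRUE; raw p-values are
#'   always reported).
#' @param nBoot,seed bootstrap settings passed to [foldDeviation()].
#' @return data.frame: \code{assay_id}, \code{locus}, \code{individuals},
#'   \code{expected}, \code{meanCdna}, \code{fold}, \code{foldReported},
#'   \code{direction}, \code{p}, \code{pAdj}, \code{nGdna}, \code{nCdna}.
#' @export
aseReport <- function(calls, observations, assays, ploidy = 5L,
                      adjust = TRUE, nBoot = 1000L, seed = NULL) {
  rows <- list()
  for (i in seq_len(nrow(assays))) {
    a <- assays[i, ]
    carriers <- .parseCarriers(a$carriers)
    obsA <- observations[observations$assay_id == a$assay_id, , drop = FALSE]
    if (nrow(obsA) == 0L) next
    inds <- unique(obsA$individual)
    noCall <- setdiff(inds, names(calls))
    if (length(noCall))
      stop("no copy-number call for individual(s): ",
           paste(noCall, collapse = ", "))
    kCarrier <- vapply(inds, function(ind)
      sum(calls[[ind]]@copyNumbers[carriers]), numeric(1))
    for (k in unique(kCarrier)) {
      group <- inds[kCarrier == k]
      obsG <- obsA[obsA$individual %in% group, , drop = FALSE]
      cdna <- obsG$fraction[obsG$template == "cDNA"]
      gdna <- obsG$fraction[obsG$template == "gDNA"]
      if (length(cdna) == 0L || length(gdna) == 0L) {
        warning("assay ", a$assay_id, ": template missing for group ",
                paste(group, collapse = "+"), "; skipped")
        next
      }
      expected <- k / ploidy
      fd <- foldDeviation(cdna, expected, nBoot = nBoot, seed = seed)
      tst <- glmTemplateTest(obsG)
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = a$assay_id, locus = a$locus,
        individuals = paste(sort(group), collapse = "+"),
        expected = expected, meanCdna = mean(cdna), fold = fd$fold,
        foldReported = fd$foldReported, direction = fd$direction,
        p = tst$p, nGdna = length(gdna), nCdna = length(cdna))
    }
  }
  if (!length(rows))
    return(data.frame(assay_id = character(), locus = character(),
                      individuals = character(), expected = numeric(),
                      meanCdna = numeric(), fold = numeric(),
                      foldReported = numeric(), direction = character(),
                      p = numeric(), pAdj = numeric(),
                      nGdna = integer(), nCdna = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pAdj <- if (adjust) {
    unsplit(lapply(split(out$p, out$locus), p.adjust, method = "BH"),
            out$locus)
  } else NA_real_
  out
}
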