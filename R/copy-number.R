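## Integer per-allele copy numbers from gDNA diagnostic-base fractions
## under the canina copy-number model: expected fraction = carrier copies
## / ploidy, maximized over all positive integer compositions of the
## ploidy.

#' Enumerate positive integer compositions of the ploidy
#'
#' All vectors of positive integers of length \code{nAlleles} summing to
#' \code{ploidy}, in lexicographic order. These are the candidate
#' copy-number assignments for the detected alleles of a locus.
#'
#' @param nAlleles number of alleles (each gets at least one copy).
#' @param ploidy total copies to distribute.
#' @return matrix with one composition per row.
#' @examples
#' enumerateCompositions(4, 5)   # the four permutations of (2,1,1,1)
#' @export
enumerateCompositions <- function(nAlleles, ploidy) {
  if (nAlleles < 1L || nAlleles > ploidy)
    stop("need 1 <= nAlleles <= ploidy")
  rec <- function(n, total) {
    if (n == 1L) return(matrix(total, 1L, 1L))
    out <- list()
    for (k in seq_len(total - n + 1L)) {
      rest <- rec(n - 1L, total - k)
      out[[k]] <- cbind(k, rest)
    }
    do.call(rbind, out)
  }
  m <- rec(as.integer(nAlleles), as.integer(ploidy))
  dimnames(m) <- NULL
  m
}

## beta-binomial log density on counts (rho > 0), binomial at rho = 0
.dbetabinomLog <- function(x, size, mean, rho) {
  if (rho == 0) return(dbinom(x, size, mean, log = TRUE))
  a <- mean * (1 - rho) / rho
  b <- (1 - mean) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

.parseCarriers <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1]])

#' Infer per-allele genomic copy numbers
#'
#' Maximizes, over all positive compositions of the ploidy among the
#' alleles, the likelihood of the observed gDNA diagnostic-base fractions,
#' whose expected value for an assay is (carrier copies)/ploidy. With read
#' depths present the likelihood is beta-binomial on
#' \code{round(fraction * depth)} counts with intra-class correlation
#' \code{rho}; without depths it is Gaussian on fractions with a pooled
#' replicate variance. Alleles covered by no assay absorb the residual
#' copies; among likelihood-tied compositions the residual is split as
#' evenly as possible, remaining ties broken by allele label order (the
#' call is then flagged as tied). Calls are made independently per
#' individual, since compositions can differ between plants.
#'
#' @param observations frequency-observation data.frame (see
#'   [simulateExperiment()] / [readFrequencyTable()]); only gDNA rows are
#'   used.
#' @param assays assay table (\code{assay_id}, \code{carriers}, ...).
#' @param alleles character vector of all allele labels at the locus
#'   (assayed or not).
#' @param ploidy genome copies.
#' @param rho beta-binomial intra-class correlation of the noise model.
#' @param locus locus name recorded in the calls (default from assays).
#' @return named list of [CopyNumberCall-class], one per individual.
#' @export
inferCopyNumbers <- function(observations, assays, alleles, ploidy = 5L,
                             rho = 0.005, locus = NULL) {
  g <- observations[observations$template == "gDNA", , drop = FALSE]
  if (nrow(g) == 0L) stop("no gDNA observations")
  assays <- assays[assays$assay_id %in% g$assay_id, , drop = FALSE]
  if (nrow(assays) == 0L) stop("no assays with gDNA observations")
  carrierSets <- lapply(assays$carriers, .parseCarriers)
  names(carrierSets) <- assays$assay_id
  bad <- setdiff(unlist(carrierSets), alleles)
  if (length(bad)) stop("assay carriers not among alleles: ",
                        paste(bad, collapse = ", "))
  if (is.null(locus)) locus <- as.character(assays$locus[1])
  comps <- enumerateCompositions(length(alleles), ploidy)
  colnames(comps) <- alleles
  assayed <- sort(unique(unlist(carrierSets)))
  unassayed <- setdiff(alleles, assayed)
  haveDepth <- "depth" %in% names(g) && all(!is.na(g$depth))

  calls <- list()
  for (ind in unique(g$individual)) {
    gi <- g[g$individual == ind, , drop = FALSE]
    pooledVar <- NULL
    if (!haveDepth) {
      v <- tapply(gi$fraction, gi$assay_id, var)
      pooledVar <- max(mean(v, na.rm = TRUE), 1e-6)
      if (!is.finite(pooledVar)) pooledVar <- 1e-4
    }
    ll <- apply(comps, 1, function(k) {
      tot <- 0
      for (aid in names(carrierSets)) {
        rowsA <- gi[gi$assay_id == aid, , drop = FALSE]
        if (nrow(rowsA) == 0L) next
        mu <- sum(k[carrierSets[[aid]]]) / ploidy
        mu <- min(max(mu, 1e-6), 1 - 1e-6)   # keep the likelihood finite
        tot <- tot + if (haveDepth) {
          sum(.dbetabinomLog(round(rowsA$fraction * rowsA$depth),
                             rowsA$depth, mu, rho))
        } else {
          sum(dnorm(rowsA$fraction, mu, sqrt(pooledVar), log = TRUE))
        }
      }
      tot
    })
    ord <- order(-ll)
    ranked <- data.frame(comps[ord, , drop = FALSE], logLik = ll[ord],
                         check.names = FALSE)
    topIdx <- which(ll >= max(ll) - 1e-9)
    tied <- length(topIdx) > 1L
    if (tied && length(unassayed) > 1L) {
      ## prefer the most even residual split over the unassayed alleles
      spread <- apply(comps[topIdx, unassayed, drop = FALSE], 1,
                      function(x) max(x) - min(x))
      topIdx <- topIdx[spread == min(spread)]
    }
    if (length(topIdx) > 1L) {
      ## lexicographic tie-break over the full composition
      keyOrd <- do.call(order, as.data.frame(comps[topIdx, , drop = FALSE]))
      topIdx <- topIdx[keyOrd[1]]
      warning("likelihood-tied compositions for individual ", ind,
              "; primary call chosen by tie-break")
    } else topIdx <- topIdx[1]
    best <- comps[topIdx, ]
    fitted <- vapply(names(carrierSets), function(aid)
      sum(best[carrierSets[[aid]]]) / ploidy, numeric(1))
    calls[[ind]] <- new("CopyNumberCall", locus = locus, individual = ind,
                        copyNumbers = setNames(as.integer(best), alleles),
                        logLik = unname(ll[topIdx]), fittedMeans = fitted,
                        alternatives = ranked, tied = tied)
  }
  calls
}

#' Tidy table of copy-number calls
#' @param calls list of [CopyNumberCall-class] (from [inferCopyNumbers()]).
#' @return data.frame with one row per individual x allele.
#' @export
copyNumberTable <- function(calls) {
  do.call(rbind, lapply(calls, function(cc)
    data.frame(locus = cc@locus, individual = cc@individual,
               allele = names(cc@copyNumbers),
               copies = unname(cc@copyNumbers),
               logLik = cc@logLik, tied = cc@tied, row.names = NULL)))
}

#' Flag assays deviating from their fitted copy-number mean
#'
#' Flags assays whose mean observed gDNA fraction deviates from the fitted
#' k/ploidy mean by more than \code{zThreshold} standard deviations of the
#' replicate mean under the beta-binomial noise model -- the signature of
#' a per-assay bias or a mis-specified carrier set (as seen when an
#' observed fraction of 0.778 stands against an expected 0.6).
#'
#' @param call a [CopyNumberCall-class].
#' @param observations frequency-observation data.frame (gDNA rows of the
#'   call's individual are used).
#' @param zThreshold flag threshold in noise standard deviations.
#' @param rho beta-binomial intra-class correlation.
#' @param depth fallback read depth when the table carries none.
#' @return character vector of flagged assay ids (possibly empty).
#' @export
flagAnomalousAssays <- function(call, observations, zThreshold = 3,
                                rho = 0.005, depth = 500L) {
  g <- observations[observations$template == "gDNA" &
                    observations$individual == call@individual, , drop = FALSE]
  flagged <- character(0)
  for (aid in names(call@fittedMeans)) {
    rowsA <- g[g$assay_id == aid, , drop = FALSE]
    if (nrow(rowsA) == 0L) next
    mu <- call@fittedMeans[[aid]]
    N <- if ("depth" %in% names(rowsA) && all(!is.na(rowsA$depth)))
      mean(rowsA$depth) else depth
    sd1 <- sqrt(mu * (1 - mu) * (1 + (N - 1) * rho) / N)
    sdMean <- sd1 / sqrt(nrow(rowsA))
    if (abs(mean(rowsA$fraction) - mu) > zThreshold * sdMean)
      flagged <- c(flagged, aid)
  }
  flagged
}

setMethod("show", "CopyNumberCall", function(object) {
  k <- object@copyNumbers
  cat(sprintf("CopyNumberCall %s / %s: %s (logLik %.2f%s)\n",
              object@locus, object@individual,
              paste(sprintf("%s=%d", names(k), k), collapse = ", "),
              object@logLik, if (object@tied) ", tied" else ""))
  gap <- if (nrow(object@alternatives) > 1L)
    object@alternatives$logLik[1] - object@alternatives$logLik[2] else NA
  if (!is.na(gap)) cat(sprintf("  log-likelihood gap to runner-up: %.2f\n", gap))
})
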