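## Molecular evolution of homeologous alleles: minimum-change substitution
## counting, Nei-Gojobori (1986) dN/dS, Goldman-Yang codon ML (one- and
## two-ratio), Tajima's relative rate test, and a codon simulator used as
## the closure oracle for the fitter.

#' Construct a codon alignment
#'
#' @param sequences named [Biostrings::DNAStringSet] or character vector of
#'   equal-length in-frame coding sequences (length divisible by 3).
#' @param locus locus name.
#' @param tree optional [ape::phylo] tree whose tip labels match the
#'   sequence names (an outgroup may be included).
#' @return a [CodonAlignment-class].
#' @export
codonAlignment <- function(sequences, locus = "locus", tree = NULL) {
  if (!is(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
    names(sequences) <- nm
  }
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  new("CodonAlignment", locus = locus, sequences = sequences,
      tree = list(tree))
}

## ---------------------------------------------------------------------------
## substitution counting
## ---------------------------------------------------------------------------

## all minimal nucleotide paths between two codons; returns average
## (syn, nonsyn) step counts over paths avoiding stop codons (all paths
## if none avoids a stop)
.pathwayAverage <- function(c1, c2) {
  tb <- .codonTables()
  gc <- Biostrings::GENETIC_CODE
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  diff <- which(s1 != s2)
  if (length(diff) == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(diff) == 1L) list(diff)
  else if (length(diff) == 2L) list(diff, rev(diff))
  else {
    idx <- list()
    for (p in asplit(.permutations3(), 1)) idx[[length(idx) + 1L]] <- diff[p]
    idx
  }
  paths <- list()
  for (ord in perms) {
    cur <- s1
    steps <- c(syn = 0, nonsyn = 0)
    valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- s2[pos]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (gc[[to]] == "*" || gc[[from]] == "*") { valid <- FALSE }
      else if (gc[[from]] == gc[[to]]) steps["syn"] <- steps["syn"] + 1
      else steps["nonsyn"] <- steps["nonsyn"] + 1
      cur <- nxt
    }
    paths[[length(paths) + 1L]] <- list(steps = steps, valid = valid)
  }
  ok <- Filter(function(p) p$valid, paths)
  if (length(ok) == 0L) ok <- paths     # every path crosses a stop: keep all
  colMeans(do.call(rbind, lapply(ok, function(p) p$steps)))
}

.permutations3 <- function() {
  rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}

## deterministic Prim MST over observed codons (nt hamming distances,
## lexicographic tie-breaks); returns matrix of edges (i, j)
.codonMst <- function(codons) {
  n <- length(codons)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  spl <- strsplit(codons, "")
  d <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(spl[[i]] != spl[[j]])
  inTree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  for (e in seq_len(n - 1)) {
    best <- NULL
    for (i in which(inTree)) for (j in which(!inTree)) {
      if (is.null(best) || d[i, j] < d[best[1], best[2]] ||
          (d[i, j] == d[best[1], best[2]] &&
           (i < best[1] || (i == best[1] && j < best[2]))))
        best <- c(i, j)
    }
    edges[e, ] <- best
    inTree[best[2]] <- TRUE
  }
  edges
}

#' Count synonymous and non-synonymous substitutions
#'
#' Column-wise minimum-change counting over the codon alignment: for each
#' polymorphic codon column, the distinct observed codons are connected by
#' a minimum spanning tree in the codon graph (single-nucleotide steps)
#' and each edge is classified by pathway-averaged parsimony (all minimal
#' nucleotide paths, stop-crossing paths excluded, ties averaged). Codons
#' containing a gap or ambiguity in any sequence are excluded
#' (complete deletion). Indel events are maximal runs of alignment columns
#' gapped in the same non-empty subset of sequences.
#'
#' @param aln a [CodonAlignment-class].
#' @return list: \code{nSynonymous}, \code{nNonsynonymous} (pathway
#'   averaging can make these fractional), \code{nIndelEvents},
#'   \code{nCodonsUsed}, \code{nCodonsDropped}, and \code{perColumn}
#'   (data.frame of per-codon-column classifications).
#' @export
countSubstitutions <- function(aln) {
  if (length(aln@sequences) < 2L) stop("need at least 2 sequences")
  st <- .codonStates(aln)
  tb <- .codonTables()
  nSyn <- 0; nNon <- 0
  rows <- list()
  for (i in seq_len(nrow(st$codons))) {
    obs <- unique(st$codons[i, ])
    if (length(obs) < 2L) next
    mst <- .codonMst(obs)
    syn <- 0; non <- 0
    for (e in seq_len(nrow(mst))) {
      pa <- .pathwayAverage(obs[mst[e, 1]], obs[mst[e, 2]])
      syn <- syn + pa["syn"]; non <- non + pa["nonsyn"]
    }
    nSyn <- nSyn + syn; nNon <- nNon + non
    rows[[length(rows) + 1L]] <- data.frame(
      codonColumn = st$used[i], nCodons = length(obs),
      synonymous = unname(syn), nonSynonymous = unname(non))
  }
  ## indel events: maximal column runs sharing the same gap pattern
  m <- .alnMatrix(aln@sequences)
  gapPat <- apply(m == .GAP, 2, function(col) paste(which(col), collapse = ","))
  hasGap <- nzchar(gapPat)
  events <- 0L
  if (any(hasGap)) {
    newRun <- hasGap & (c("", gapPat[-length(gapPat)]) != gapPat)
    events <- sum(newRun)
  }
  list(nSynonymous = unname(nSyn), nNonsynonymous = unname(nNon),
       nIndelEvents = events, nCodonsUsed = nrow(st$codons),
       nCodonsDropped = st$nDropped,
       perColumn = if (length(rows)) do.call(rbind, rows)
       else data.frame(codonColumn = integer(), nCodons = integer(),
                       synonymous = numeric(), nonSynonymous = numeric()))
}

## ---------------------------------------------------------------------------
## NG86
## ---------------------------------------------------------------------------

## synonymous site count of one codon (fraction of the 9 possible
## single-nucleotide changes that are synonymous; changes to stops count
## as non-synonymous, per the usual convention)
.ng86Sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  s <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), s[pos])) {
    alt <- s
    alt[pos] <- b
    altc <- paste(alt, collapse = "")
    if (gc[[altc]] != "*" && gc[[altc]] == gc[[codon]]) syn <- syn + 1
  }
  syn / 3
}

#' Nei-Gojobori (1986) dN/dS for a pair of coding sequences
#'
#' Counting method: synonymous site counts by codon degeneracy, observed
#' differences classified by pathway averaging over minimal mutation
#' paths, and Jukes-Cantor multiple-hit correction of the proportions.
#' Codons with a gap or ambiguity in either sequence are excluded.
#'
#' @param a,b equal-length in-frame coding sequences (character or
#'   [Biostrings::DNAString]).
#' @return list: \code{dN}, \code{dS}, \code{omega} (NA when dS = 0),
#'   \code{S}, \code{N} (site counts), \code{Sd}, \code{Nd} (difference
#'   counts), \code{nCodons}.
#' @export
ng86 <- function(a, b) {
  tb <- .codonTables()
  A <- toupper(as.character(a)); B <- toupper(as.character(b))
  if (nchar(A) != nchar(B)) stop("sequences must have equal aligned length")
  if (nchar(A) %% 3L != 0L) stop("length must be divisible by 3")
  L <- nchar(A) / 3L
  ca <- substring(A, 3L * (seq_len(L) - 1L) + 1L, 3L * seq_len(L))
  cb <- substring(B, 3L * (seq_len(L) - 1L) + 1L, 3L * seq_len(L))
  keep <- ca %in% tb$sense & cb %in% tb$sense
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no comparable codons")
  S <- sum((vapply(ca, .ng86Sites, numeric(1)) +
            vapply(cb, .ng86Sites, numeric(1))) / 2)
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    pa <- .pathwayAverage(ca[i], cb[i])
    Sd <- Sd + pa["syn"]; Nd <- Nd + pa["nonsyn"]
  }
  jc <- function(p) {
    if (p >= 0.75) stop("sequences too diverged for the Jukes-Cantor ",
                        "correction (p >= 3/4)")
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- if (S > 0) jc(Sd / S) else 0
  dN <- if (N > 0) jc(Nd / N) else 0
  omega <- if (dS > 0) dN / dS else NA_real_
  list(dN = unname(dN), dS = unname(dS), omega = unname(omega),
       S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       nCodons = length(ca))
}

## ---------------------------------------------------------------------------
## Goldman-Yang ML
## ---------------------------------------------------------------------------

.prepareTree <- function(aln, tree) {
  if (is.null(tree)) tree <- if (length(aln@tree)) aln@tree[[1]] else NULL
  nm <- names(aln@sequences)
  if (is.null(tree)) {
    chars <- strsplit(toupper(as.character(aln@sequences)), "")
    n <- length(chars)
    d <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ok <- chars[[i]] %in% .BASES & chars[[j]] %in% .BASES
      d[i, j] <- d[j, i] <- if (any(ok))
        sum(chars[[i]][ok] != chars[[j]][ok]) / sum(ok) else 0
    }
    tree <- ape::nj(as.dist(d))
  }
  if (!setequal(tree$tip.label, nm))
    stop("tree tip labels must match the sequence names")
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length <- pmin(pmax(tree$edge.length * 3, 1e-4), 5)  # per codon
  stats::reorder(tree, "postorder")
}

.fitCodonModel <- function(patterns, pi, tree, edgeClass, kappaStart,
                           omegaStarts, nOmega, seqNames, control = list()) {
  tb <- .codonTables()
  tipStates <- patterns$tipStates[match(tree$tip.label, seqNames), ,
                                  drop = FALSE]
  storage.mode(tipStates) <- "integer"
  edge <- tree$edge
  storage.mode(edge) <- "integer"
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  E <- nrow(edge)
  negLnL <- function(par) {
    kappa <- exp(par[1])
    omegas <- exp(par[2:(1 + nOmega)])
    blen <- exp(par[-(1:(1 + nOmega))])
    -.codonLnLCpp(edge, blen, as.integer(edgeClass), nTip, nNode, tipStates,
                  patterns$weights, pi, tb$type, kappa, omegas)
  }
  lower <- c(log(1e-3), rep(log(1e-4), nOmega), rep(log(1e-6), E))
  upper <- c(log(99), rep(log(49), nOmega), rep(log(19), E))
  best <- NULL
  for (om in omegaStarts) {
    par0 <- c(log(kappaStart), rep(log(om), nOmega), log(tree$edge.length))
    fit <- tryCatch(
      optim(par0, negLnL, method = "L-BFGS-B", lower = lower, upper = upper,
            control = modifyList(list(maxit = 500, factr = 1e7), control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("codon model optimization failed from every starting point")
  list(kappa = exp(best$par[1]),
       omegas = exp(best$par[2:(1 + nOmega)]),
       blen = exp(best$par[-(1:(1 + nOmega))]),
       lnL = -best$value, convergence = best$convergence)
}

#' One-ratio (M0) Goldman-Yang codon model fit
#'
#' Maximizes the likelihood of a codon alignment under the GY94-style
#' model with a single dN/dS ratio for all branches, one
#' transition/transversion ratio and F3x4 codon frequencies estimated
#' from the data, with free branch lengths, by bounded quasi-Newton
#' optimization from several omega starting points. \code{dS} and
#' \code{dN} are per-site tree distances computed from the fitted rate
#' matrix (so \code{dN/dS} equals the fitted omega), mirroring the usual
#' codeml reporting convention.
#'
#' @param aln a [CodonAlignment-class] (at least 3 sequences).
#' @param tree optional [ape::phylo]; defaults to the alignment's tree or,
#'   failing that, a neighbour-joining topology.
#' @param kappaStart starting transition/transversion ratio.
#' @param omegaStarts starting omega values (multiple documented starts).
#' @param control passed to [stats::optim()].
#' @return a [CodonModelFit-class].
#' @export
m0Fit <- function(aln, tree = NULL, kappaStart = 2, omegaStarts = c(0.1, 0.5, 1.5),
                  control = list()) {
  if (length(aln@sequences) < 3L) stop("need at least 3 sequences")
  st <- .codonStates(aln)
  if (nrow(st$codons) == 0L) stop("no clean codon columns")
  flags <- character(0)
  if (all(apply(st$states, 2, function(x) length(unique(x)) == 1L)))
    flags <- c(flags, "no variation: omega unidentifiable")
  pi <- .f3x4(as.vector(st$codons))
  patterns <- .sitePatterns(st$states)
  tr <- .prepareTree(aln, tree)
  fit <- .fitCodonModel(patterns, pi, tr, rep(1L, nrow(tr$edge)),
                        kappaStart, omegaStarts, 1L, names(aln@sequences),
                        control)
  if (fit$omegas[1] <= 2e-4)
    flags <- c(flags, "omega at lower boundary")
  tr$edge.length <- fit$blen
  Q <- .codonQ(fit$kappa, fit$omegas[1], pi)
  Q1 <- .codonQ(fit$kappa, 1, pi)
  fl <- .fluxProportions(Q, pi)
  fl1 <- .fluxProportions(Q1, pi)
  treeLen <- sum(fit$blen)
  dS <- treeLen * fl["syn"] / (3 * fl1["syn"])
  dN <- treeLen * fl["nonsyn"] / (3 * fl1["nonsyn"])
  new("CodonModelFit", model = "one-ratio", omega = unname(fit$omegas),
      kappa = fit$kappa, dN = unname(dN), dS = unname(dS), logLik = fit$lnL,
      tree = list(tr), branchClass = rep(1L, nrow(tr$edge)), flags = flags)
}

#' Two-ratio codon model and likelihood ratio test
#'
#' Fits the one-ratio model and a two-ratio alternative in which the
#' branches leading to the \code{foreground} tips (e.g. the allele with
#' two or more genomic copies) have their own dN/dS, then compares them
#' with a likelihood ratio test on one degree of freedom. The alternative
#' fit is started at the null solution, so its likelihood can never fall
#' below the null's.
#'
#' @param aln a [CodonAlignment-class].
#' @param tree optional [ape::phylo].
#' @param foreground character vector of tip labels whose pendant
#'   branches form the second omega class.
#' @param kappaStart,omegaStarts,control as in [m0Fit()].
#' @return list: \code{fit0}, \code{fit1} ([CodonModelFit-class]),
#'   \code{statistic} (2 x lnL difference, clamped at 0), \code{df},
#'   \code{p}.
#' @export
twoRatioLrt <- function(aln, tree = NULL, foreground,
                        kappaStart = 2, omegaStarts = c(0.1, 0.5, 1.5),
                        control = list()) {
  fit0 <- m0Fit(aln, tree, kappaStart, omegaStarts, control)
  tr <- fit0@tree[[1]]
  if (!all(foreground %in% tr$tip.label))
    stop("foreground labels must be tree tips")
  fgTips <- match(foreground, tr$tip.label)
  edgeClass <- ifelse(tr$edge[, 2] %in% fgTips, 2L, 1L)
  if (all(edgeClass == 1L) || all(edgeClass == 2L))
    stop("partition must place branches in both classes")
  st <- .codonStates(aln)
  pi <- .f3x4(as.vector(st$codons))
  patterns <- .sitePatterns(st$states)
  fit1 <- .fitCodonModel(patterns, pi, tr, edgeClass, fit0@kappa,
                         fit0@omega[1], 2L, names(aln@sequences), control)
  tr1 <- tr
  tr1$edge.length <- fit1$blen
  lnL1 <- max(fit1$lnL, fit0@logLik)
  alt <- new("CodonModelFit", model = "two-ratio", omega = unname(fit1$omegas),
             kappa = fit1$kappa, dN = fit0@dN, dS = fit0@dS, logLik = lnL1,
             tree = list(tr1), branchClass = edgeClass, flags = character(0))
  stat <- max(0, 2 * (lnL1 - fit0@logLik))
  list(fit0 = fit0, fit1 = alt, statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE))
}

## ---------------------------------------------------------------------------
## Tajima relative rate test
## ---------------------------------------------------------------------------

#' Tajima's (1993) relative rate test
#'
#' Counts alignment sites at which only the first (m1) or only the second
#' (m2) ingroup sequence differs from the outgroup; under equal rates m1
#' and m2 have equal expectation and
#' \eqn{\chi^2 = (m_1 - m_2)^2 / (m_1 + m_2)} has 1 degree of freedom.
#'
#' @param seq1,seq2 aligned ingroup sequences.
#' @param outgroup aligned outgroup sequence.
#' @return list: \code{m1}, \code{m2}, \code{statistic}, \code{p}
#'   (p = 1 with a \code{noTest} flag when m1 + m2 = 0), \code{nSites}.
#' @export
tajimaRrt <- function(seq1, seq2, outgroup) {
  x <- strsplit(toupper(as.character(seq1)), "")[[1]]
  y <- strsplit(toupper(as.character(seq2)), "")[[1]]
  o <- strsplit(toupper(as.character(outgroup)), "")[[1]]
  if (length(unique(c(length(x), length(y), length(o)))) != 1L)
    stop("three aligned sequences of equal length required")
  ok <- x %in% .BASES & y %in% .BASES & o %in% .BASES
  m1 <- sum(ok & x != o & y == o)
  m2 <- sum(ok & y != o & x == o)
  if (m1 + m2 == 0)
    return(list(m1 = m1, m2 = m2, statistic = 0, p = 1, noTest = TRUE,
                nSites = sum(ok)))
  stat <- (m1 - m2)^2 / (m1 + m2)
  list(m1 = m1, m2 = m2, statistic = stat,
       p = pchisq(stat, df = 1, lower.tail = FALSE), noTest = FALSE,
       nSites = sum(ok))
}

#' Relative rate tests over all ingroup pairs with FDR control
#'
#' Runs [tajimaRrt()] for every pair of ingroup sequences against a common
#' outgroup and adjusts the p-values with the Benjamini-Hochberg formula.
#'
#' @param aln a [CodonAlignment-class] (or named DNAStringSet).
#' @param outgroup name of the outgroup sequence.
#' @param alpha significance level for the verdicts.
#' @return data.frame: \code{seq1}, \code{seq2}, \code{m1}, \code{m2},
#'   \code{statistic}, \code{p}, \code{pAdj}, \code{verdict}.
#' @export
tajimaRrtBatch <- function(aln, outgroup, alpha = 0.05) {
  seqs <- if (is(aln, "CodonAlignment")) aln@sequences else aln
  if (!outgroup %in% names(seqs)) stop("outgroup not found among sequences")
  ingroup <- setdiff(names(seqs), outgroup)
  if (length(ingroup) < 2L) stop("need at least two ingroup sequences")
  pairs <- combn(ingroup, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    r <- tajimaRrt(seqs[[pairs[1, i]]], seqs[[pairs[2, i]]], seqs[[outgroup]])
    data.frame(seq1 = pairs[1, i], seq2 = pairs[2, i], m1 = r$m1, m2 = r$m2,
               statistic = r$statistic, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- p.adjust(out$p, method = "BH")
  out$verdict <- ifelse(out$pAdj < alpha, "unequal rates", "equal rates")
  out
}

## ---------------------------------------------------------------------------
## codon simulator (closure oracle for the fitter)
## ---------------------------------------------------------------------------

#' Simulate a codon alignment under the GY94 process
#'
#' Evolves codons along a tree under the same model [m0Fit()] assumes
#' (stop codons are not part of the state space), so simulator and fitter
#' close over each other for parameter-recovery checks.
#'
#' @param tree [ape::phylo] with branch lengths in expected substitutions
#'   per codon.
#' @param omega dN/dS ratio; either a single value for all branches or, with
#'   \code{foreground} set, \code{c(background, foreground)}.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param nCodons alignment length in codons.
#' @param pi optional sense-codon frequencies (default uniform).
#' @param foreground optional tip labels whose pendant branches evolve
#'   under the second omega (two-ratio simulation).
#' @param seed optional integer seed.
#' @return a [CodonAlignment-class] with one sequence per tip.
#' @export
simulateCodons <- function(tree, omega, kappa, nCodons, pi = NULL,
                           foreground = NULL, seed = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (any(omega < 0) || kappa <= 0) stop("omega must be >= 0 and kappa > 0")
  if (is.null(foreground) && length(omega) != 1L)
    stop("a single omega is required without a foreground class")
  if (!is.null(foreground) && length(omega) != 2L)
    stop("two-ratio simulation needs omega = c(background, foreground)")
  if (!is.null(seed)) set.seed(seed)
  tb <- .codonTables()
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  Qs <- lapply(pmax(omega, 1e-12), .codonQ, kappa = kappa, pi = pi)
  tr <- stats::reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  edgeClass <- rep(1L, nrow(tr$edge))
  if (!is.null(foreground)) {
    if (!all(foreground %in% tr$tip.label))
      stop("foreground labels must be tree tips")
    edgeClass[tr$edge[, 2] %in% match(foreground, tr$tip.label)] <- 2L
  }
  root <- tr$edge[nrow(tr$edge), 1]
  states <- matrix(NA_integer_, nTip + tr$Nnode, nCodons)
  states[root, ] <- sample.int(61, nCodons, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(tr$edge)))) {      # preorder
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- .codonPmat(Qs[[edgeClass[e]]], pi, tr$edge.length[e])
    ps <- states[parent, ]
    cs <- integer(nCodons)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      cs[idx] <- sample.int(61, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[child, ] <- cs
  }
  seqs <- vapply(seq_len(nTip), function(i)
    paste(tb$sense[states[i, ]], collapse = ""), character(1))
  names(seqs) <- tr$tip.label
  codonAlignment(seqs, locus = "simulated", tree = tree)
}

setMethod("show", "CodonModelFit", function(object) {
  cat(sprintf("CodonModelFit (%s): omega = %s, kappa = %.3f\n",
              object@model,
              paste(sprintf("%.4f", object@omega), collapse = " / "),
              object@kappa))
  cat(sprintf("  dN = %.4f, dS = %.4f, lnL = %.2f\n",
              object@dN, object@dS, object@logLik))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment of", object@locus, "-", length(object@sequences),
      "sequences x", Biostrings::width(object@sequences)[1] / 3, "codons\n")
})
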