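## Shared machinery for the Goldman-Yang codon model: sense-codon tables,
## the one-nucleotide-step type matrix, F3x4 frequencies, the scaled rate
## matrix and its transition probabilities. Used by the ML fitter, the
## codon simulator and the counting methods.

.codonTables <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    sense <- codons[gc != "*"]
    aa <- gc[sense]
    n <- length(sense)                      # 61
    spl <- do.call(rbind, strsplit(sense, ""))
    type <- matrix(0L, n, n, dimnames = list(sense, sense))
    isTransition <- function(x, y)
      (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diff <- which(spl[i, ] != spl[j, ])
      if (length(diff) != 1L) next
      ts <- isTransition(spl[i, diff], spl[j, diff])
      syn <- aa[i] == aa[j]
      t <- if (syn && !ts) 1L else if (syn && ts) 2L
      else if (!syn && !ts) 3L else 4L
      type[i, j] <- type[j, i] <- t
    }
    cache <<- list(sense = sense, aa = aa, split = spl, type = type,
                   index = setNames(seq_len(n), sense),
                   stops = codons[gc == "*"])
    cache
  }
})

## F3x4 sense-codon frequencies from a character vector of clean codons
.f3x4 <- function(codons) {
  tb <- .codonTables()
  m <- do.call(rbind, strsplit(codons, ""))
  pos <- lapply(1:3, function(p) {
    f <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
    f <- as.numeric(f)
    if (sum(f) == 0) rep(0.25, 4) else f / sum(f)
  })
  s <- tb$split
  nt <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  pi <- pos[[1]][nt[s[, 1]]] * pos[[2]][nt[s[, 2]]] * pos[[3]][nt[s[, 3]]]
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

## scaled GY94 rate matrix (mean rate 1 per codon)
.codonQ <- function(kappa, omega, pi) {
  tb <- .codonTables()
  mult <- c(1, kappa, omega, kappa * omega)   # type 1..4
  Q <- matrix(0, 61, 61)
  nz <- tb$type > 0L
  Q[nz] <- mult[tb$type[nz]]
  Q <- Q * rep(pi, each = 61)                 # Q[i, j] ~ pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

## transition probabilities via the reversible symmetrization
.codonPmat <- function(Q, pi, t) {
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * Q
  B <- (B + t(B)) / 2                         # guard symmetry numerically
  e <- eigen(B, symmetric = TRUE)
  P <- ((1 / d) %o% d) * (e$vectors %*% (exp(e$values * t) * t(e$vectors)))
  P[P < 0] <- 0
  P / rowSums(P)
}

## synonymous/non-synonymous flux proportions under Q (scaled)
.fluxProportions <- function(Q, pi) {
  tb <- .codonTables()
  flow <- Q * rep(pi, times = 61)             # pi_i Q_ij: rows scaled by pi_i
  syn <- tb$type == 1L | tb$type == 2L
  nonsyn <- tb$type == 3L | tb$type == 4L
  c(syn = sum(flow[syn]), nonsyn = sum(flow[nonsyn]))
}

## codon state matrix from a CodonAlignment under complete deletion:
## list(states = ntaxa x nUsed integer matrix (1..61), used = kept codon
## columns, nDropped)
.codonStates <- function(aln) {
  tb <- .codonTables()
  seqs <- toupper(as.character(aln@sequences))
  n <- length(seqs)
  L <- nchar(seqs[1]) / 3L
  codons <- vapply(seqs, function(s)
    substring(s, 3L * (seq_len(L) - 1L) + 1L, 3L * seq_len(L)), character(L))
  codons <- matrix(codons, nrow = L)          # L x n
  isStop <- matrix(codons %in% tb$stops, nrow = L)
  if (any(isStop)) {
    w <- which(isStop, arr.ind = TRUE)[1, ]
    stop("internal stop codon in sequence '", names(aln@sequences)[w[2]],
         "' at codon ", w[1])
  }
  gappy <- apply(codons, 1, function(x)
    any(!x %in% tb$sense))
  used <- which(!gappy)
  states <- matrix(tb$index[codons[used, , drop = FALSE]],
                   nrow = length(used), ncol = n)
  list(states = t(states), used = used, nDropped = L - length(used),
       codons = codons[used, , drop = FALSE])
}

## compress site patterns: list(tipStates = ntaxa x P, weights)
.sitePatterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ".")
  uk <- unique(key)
  idx <- match(uk, key)
  list(tipStates = states[, idx, drop = FALSE],
       weights = as.numeric(table(key)[uk]))
}
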