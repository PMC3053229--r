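# Independent oracles for the codon analyses, written against the raw
# genetic code and deliberately sharing no code with the package:
# - oracleCountPair(): exhaustive enumeration of all orderings of the
#   differing positions between two codons, averaging synonymous /
#   non-synonymous step counts over stop-free orderings;
# - oraclePairAlignment(): column-wise pair counting built on it;
# - oracleCodonLnL(): a direct (slow) pruning likelihood for the codon
#   model using matrix exponentials from first principles.

oracleGeneticCode <- Biostrings::GENETIC_CODE

oracleCountPair <- function(c1, c2) {
  s1 <- strsplit(c1, "")[[1]]
  s2 <- strsplit(c2, "")[[1]]
  d <- which(s1 != s2)
  if (!length(d)) return(c(0, 0))
  orderings <- if (length(d) == 1) matrix(d, 1)
  else do.call(rbind, lapply(
    asplit(as.matrix(expand.grid(rep(list(seq_along(d)), length(d)))), 1),
    function(p) if (length(unique(p)) == length(d)) d[p] else NULL))
  results <- list()
  for (r in seq_len(nrow(orderings))) {
    cur <- s1; syn <- 0; non <- 0; valid <- TRUE
    for (pos in orderings[r, ]) {
      nxt <- cur; nxt[pos] <- s2[pos]
      aaFrom <- oracleGeneticCode[[paste(cur, collapse = "")]]
      aaTo <- oracleGeneticCode[[paste(nxt, collapse = "")]]
      if (aaTo == "*" || aaFrom == "*") valid <- FALSE
      else if (aaFrom == aaTo) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    results[[r]] <- list(syn = syn, non = non, valid = valid)
  }
  ok <- Filter(function(x) x$valid, results)
  if (!length(ok)) ok <- results
  c(mean(vapply(ok, `[[`, numeric(1), "syn")),
    mean(vapply(ok, `[[`, numeric(1), "non")))
}

oraclePairAlignment <- function(seq1, seq2) {
  L <- nchar(seq1) / 3
  syn <- 0; non <- 0
  for (i in seq_len(L)) {
    c1 <- substr(seq1, 3 * i - 2, 3 * i)
    c2 <- substr(seq2, 3 * i - 2, 3 * i)
    cnt <- oracleCountPair(c1, c2)
    syn <- syn + cnt[1]; non <- non + cnt[2]
  }
  c(syn = syn, non = non)
}

# slow reference likelihood: explicit rate matrix, series-free matrix
# exponential via eigen() on the plain (non-symmetrized) generator
oracleCodonLnL <- function(tree, seqs, kappa, omega, pi) {
  gc <- oracleGeneticCode
  sense <- names(gc)[gc != "*"]
  n <- length(sense)
  spl <- do.call(rbind, strsplit(sense, ""))
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(spl[i, ] != spl[j, ])
    if (length(d) != 1) next
    ts <- paste(sort(c(spl[i, d], spl[j, d])), collapse = "") %in% c("AG", "CT")
    syn <- gc[[sense[i]]] == gc[[sense[j]]]
    Q[i, j] <- pi[j] * (if (ts) kappa else 1) * (if (syn) 1 else omega)
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))
  Pm <- function(t) {
    e <- eigen(Q)
    Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  tr <- stats::reorder(tree, "postorder")
  nTip <- length(tr$tip.label)
  codonIdx <- function(s) {
    L <- nchar(s) / 3
    match(substring(s, 3 * (1:L) - 2, 3 * (1:L)), sense)
  }
  states <- lapply(tr$tip.label, function(l) codonIdx(seqs[[l]]))
  nSites <- length(states[[1]])
  Lmat <- vector("list", nTip + tr$Nnode)
  for (i in seq_len(nTip)) {
    m <- matrix(0, n, nSites)
    m[cbind(states[[i]], seq_len(nSites))] <- 1
    Lmat[[i]] <- m
  }
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- Pm(tr$edge.length[e])
    contrib <- P %*% Lmat[[child]]
    Lmat[[parent]] <- if (is.null(Lmat[[parent]])) contrib
    else Lmat[[parent]] * contrib
  }
  root <- tr$edge[nrow(tr$edge), 1]
  sum(log(colSums(pi * Lmat[[root]])))
}
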