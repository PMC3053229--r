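## Collapse cloned sequences into allele consensi, screen PCR chimeras,
## compute pairwise divergence and discover pyrosequencing-suitable
## diagnostic SNPs. All user-facing coordinates are 0-based half-open
## alignment columns.

.alnMatrix <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- names(seqs)
  m
}

.GAP <- "-"
.BASES <- c("A", "C", "G", "T")

## substitutions among mutually ungapped columns + one event per
## contiguous indel run (a run of columns gapped in exactly one of the two)
.cloneDistance <- function(x, y) {
  gx <- x == .GAP
  gy <- y == .GAP
  both <- !gx & !gy
  subs <- sum(x[both] != y[both])
  indel <- gx != gy
  events <- sum(indel & !c(FALSE, indel[-length(indel)]))
  subs + events
}

.distMatrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- .cloneDistance(m[i, ], m[j, ])
  }
  d
}

.IUPAC_REV <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  setNames(names(map), vapply(strsplit(map, ""), function(x)
    paste(sort(x), collapse = ""), character(1)))
})

## column-majority consensus; base ties -> IUPAC ambiguity code
.columnConsensus <- function(col) {
  tab <- table(col)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  bases <- sort(intersect(top, .BASES))
  if (length(bases) == 0L) return(top[1])
  code <- .IUPAC_REV[paste(bases, collapse = "")]
  if (is.na(code)) "N" else unname(code)
}

#' Construct a clone alignment
#'
#' @param sequences a [Biostrings::DNAStringSet] (or named character
#'   vector) of equal-length aligned clone sequences.
#' @param locus locus name.
#' @param individual character vector of source individuals (recycled).
#' @param clone clone identifiers (default: sequence names).
#' @param codingMask coding region as a 2-column matrix/data.frame of
#'   0-based half-open \code{[start, end)} alignment-column intervals, or
#'   an [IRanges::IRanges] (taken as 1-based closed, as returned by
#'   [readCodingMask()]).
#' @return a [CloneAlignment-class].
#' @export
cloneAlignment <- function(sequences, locus = "locus", individual = NA_character_,
                           clone = NULL, codingMask = NULL) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  else sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  if (length(sequences) == 0L) stop("empty alignment")
  if (is.null(clone)) clone <- names(sequences)
  if (is.null(clone)) clone <- paste0("clone", seq_along(sequences))
  names(sequences) <- clone
  mask <- if (is.null(codingMask)) IRanges::IRanges()
  else if (is(codingMask, "IRanges")) codingMask
  else IRanges::IRanges(start = as.integer(codingMask[, 1]) + 1L,
                        end = as.integer(codingMask[, 2]))
  new("CloneAlignment", locus = locus, sequences = sequences,
      individual = rep_len(individual, length(sequences)),
      clone = clone, codingMask = mask)
}

#' Collapse cloned sequences into alleles
#'
#' Single-linkage clustering of clones at a substitution-distance
#' threshold (contiguous indels count as one event each), mirroring the
#' pragmatic lumping of near-identical sub-clades into one allele.
#' Clusters supported by fewer than \code{minClones} clones are treated as
#' putative PCR-error singletons: excluded from the allele set but
#' reported. Consensi are column-majority with IUPAC codes at ties.
#'
#' @param aln a [CloneAlignment-class].
#' @param maxIntraAlleleDiff single-linkage threshold (substitutions +
#'   indel events) below or at which clones join one allele.
#' @param minClones minimum supporting clones per allele.
#' @param labelPrefix prefix for allele labels (default the locus name).
#' @return an [AlleleSet-class]; allele labels are
#'   \code{<prefix>-1, -2, ...} ordered by decreasing support.
#' @export
collapseClones <- function(aln, maxIntraAlleleDiff = 4L, minClones = 2L,
                           labelPrefix = aln@locus) {
  m <- .alnMatrix(aln@sequences)
  n <- nrow(m)
  if (n == 1L) {
    cl <- 1L
  } else {
    d <- .distMatrix(m)
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    cl <- stats::cutree(hc, h = maxIntraAlleleDiff)
  }
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= minClones])
  ## order alleles by support (desc), then by first occurrence for ties
  first <- vapply(keep, function(k) min(which(cl == k)), integer(1))
  keep <- keep[order(-as.integer(sizes[as.character(keep)]), first)]
  cons <- character(0); supp <- integer(0); inds <- list()
  for (i in seq_along(keep)) {
    members <- which(cl == keep[i])
    sub <- m[members, , drop = FALSE]
    cons[i] <- paste(apply(sub, 2, .columnConsensus), collapse = "")
    supp[i] <- length(members)
    inds[[i]] <- sort(unique(aln@individual[members]))
  }
  labels <- sprintf("%s-%d", labelPrefix, seq_along(keep))
  consensus <- if (length(cons)) Biostrings::DNAStringSet(setNames(cons, labels))
  else Biostrings::DNAStringSet()
  excludedIdx <- which(!cl %in% keep)
  excluded <- aln@sequences[excludedIdx]
  if (length(excludedIdx))
    warning(length(excludedIdx), " clone(s) in clusters below minClones = ",
            minClones, " excluded as putative PCR-error singletons")
  new("AlleleSet", locus = aln@locus, consensus = consensus,
      support = setNames(supp, labels), individuals = setNames(inds, labels),
      excluded = excluded, codingMask = aln@codingMask)
}

#' Screen clones for PCR chimeras
#'
#' For every clone, searches all ordered allele parent pairs and single
#' breakpoints for the mosaic (parent 1 left of the breakpoint, parent 2
#' right of it) minimizing mismatches. A clone is called chimeric when the
#' best mosaic improves on the best single parent by at least
#' \code{minImprovement} mismatches and each flank matches its parent at
#' \code{minFlankSites} or more diagnostic sites (columns where the two
#' parents differ).
#'
#' @param aln a [CloneAlignment-class].
#' @param alleles an [AlleleSet-class] with at least two alleles.
#' @param minImprovement minimum mismatch reduction of the mosaic over the
#'   best single parent.
#' @param minFlankSites minimum parent-supporting diagnostic sites per flank.
#' @return data.frame: \code{clone}, \code{verdict} (clean/chimeric),
#'   \code{parent1}, \code{parent2}, \code{breakpointStart},
#'   \code{breakpointEnd} (0-based half-open interval of candidate
#'   breakpoint columns, bounded by the flanking diagnostic sites),
#'   \code{singleMismatches}, \code{mosaicMismatches}, \code{score}.
#' @export
detectChimeras <- function(aln, alleles, minImprovement = 3L, minFlankSites = 1L) {
  if (length(alleles@consensus) < 2L) stop("need at least two alleles")
  cm <- .alnMatrix(aln@sequences)
  am <- .alnMatrix(alleles@consensus)
  out <- vector("list", nrow(cm))
  for (ci in seq_len(nrow(cm))) {
    clone <- cm[ci, ]
    singles <- vapply(seq_len(nrow(am)), function(ai) {
      p <- am[ai, ]
      ok <- clone != .GAP & p != .GAP & !(p %in% setdiff(unique(p), c(.BASES, .GAP)))
      sum(clone[ok] != p[ok])
    }, numeric(1))
    bestSingle <- min(singles)
    best <- list(mosaic = Inf)
    for (a1 in seq_len(nrow(am))) for (a2 in seq_len(nrow(am))) {
      if (a1 == a2) next
      p1 <- am[a1, ]; p2 <- am[a2, ]
      ok <- clone != .GAP & p1 != .GAP & p2 != .GAP &
        p1 %in% .BASES & p2 %in% .BASES
      cols <- which(ok)
      if (length(cols) < 2L) next
      m1 <- clone[cols] != p1[cols]
      m2 <- clone[cols] != p2[cols]
      diag <- p1[cols] != p2[cols]
      ## mosaic(b): first b columns scored vs p1, rest vs p2
      pre1 <- c(0, cumsum(m1))
      suf2 <- rev(c(0, cumsum(rev(m2))))
      mosaic <- pre1 + suf2               # length(cols) + 1 breakpoints
      for (b in seq_along(mosaic)) {
        if (mosaic[b] >= best$mosaic) next
        nb <- b - 1L                      # columns left of breakpoint
        leftSupport <- sum(diag[seq_len(nb)] & !m1[seq_len(nb)])
        rightIdx <- if (nb < length(cols)) (nb + 1L):length(cols) else integer(0)
        rightSupport <- sum(diag[rightIdx] & !m2[rightIdx])
        if (leftSupport < minFlankSites || rightSupport < minFlankSites) next
        leftDiag <- which(diag[seq_len(nb)] & !m1[seq_len(nb)])
        rightDiag <- rightIdx[diag[rightIdx] & !m2[rightIdx]]
        best <- list(
          mosaic = mosaic[b], a1 = a1, a2 = a2,
          bpStart = cols[max(leftDiag)],          # 0-based: col after last left site
          bpEnd = cols[min(rightDiag)] - 1L       # 0-based index of first right site
        )
      }
    }
    chim <- is.finite(best$mosaic) &&
      best$mosaic <= bestSingle - minImprovement
    out[[ci]] <- data.frame(
      clone = aln@clone[ci],
      verdict = if (chim) "chimeric" else "clean",
      parent1 = if (chim) rownames(am)[best$a1] else NA_character_,
      parent2 = if (chim) rownames(am)[best$a2] else NA_character_,
      breakpointStart = if (chim) best$bpStart else NA_integer_,
      breakpointEnd = if (chim) best$bpEnd + 1L else NA_integer_,
      singleMismatches = bestSingle,
      mosaicMismatches = if (is.finite(best$mosaic)) best$mosaic else NA_real_,
      score = if (is.finite(best$mosaic)) bestSingle - best$mosaic else 0
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Percent divergence between two aligned sequences
#'
#' 100 x mismatches / compared columns; columns gapped in either sequence
#' are excluded from both numerator and denominator.
#'
#' @param a,b aligned sequences (character or [Biostrings::DNAString]).
#' @param region \code{"whole"} or \code{"coding"}.
#' @param codingMask required for \code{region = "coding"}: an
#'   [IRanges::IRanges] (1-based) or 2-column 0-based half-open matrix.
#' @return percent divergence (numeric).
#' @export
pairwiseDivergence <- function(a, b, region = c("whole", "coding"),
                               codingMask = NULL) {
  region <- match.arg(region)
  x <- strsplit(toupper(as.character(a)), "")[[1]]
  y <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(x) != length(y)) stop("aligned sequences must have equal length")
  if (region == "coding") {
    if (is.null(codingMask)) stop("codingMask required for region = 'coding'")
    cols <- .maskColumns(codingMask)
    x <- x[cols]; y <- y[cols]
  }
  ok <- x != .GAP & y != .GAP
  if (!any(ok)) return(NA_real_)
  100 * sum(x[ok] != y[ok]) / sum(ok)
}

## mask -> sorted 1-based alignment columns
.maskColumns <- function(mask) {
  if (is(mask, "IRanges"))
    sort(unlist(Map(seq, IRanges::start(mask), IRanges::end(mask))))
  else sort(unlist(Map(seq, as.integer(mask[, 1]) + 1L, as.integer(mask[, 2]))))
}

#' Discover pyrosequencing-suitable diagnostic SNPs
#'
#' Emits coding-region alignment columns where one base partitions the
#' alleles into a carrier set of size at most \code{carrierMax} versus the
#' rest, with no gaps or ambiguity codes at the column and monomorphic,
#' gap-free flanks of \code{flank} columns on both sides (a proxy for
#' pyrosequencing assay suitability). Carrier sets of size two or more are
#' allowed: some assays cannot separate closely related alleles and then
#' measure their combined frequency.
#'
#' @param alleles an [AlleleSet-class].
#' @param codingMask optional override of the allele set's coding mask.
#' @param carrierMax maximum carrier-set size.
#' @param flank monomorphic flank width in columns.
#' @return data.frame of assays: \code{assay_id}, \code{locus},
#'   \code{position} (0-based alignment column), \code{diagnostic_base},
#'   \code{carriers} (comma-separated allele labels); zero rows when no
#'   column qualifies.
#' @export
findDiagnosticSnps <- function(alleles, codingMask = NULL, carrierMax = 2L,
                               flank = 3L) {
  if (length(alleles@consensus) < 2L) stop("need at least two alleles")
  mask <- if (is.null(codingMask)) alleles@codingMask else codingMask
  if (length(mask) == 0L) stop("no coding mask available")
  m <- .alnMatrix(alleles@consensus)
  width <- ncol(m)
  codingCols <- .maskColumns(mask)
  cleanCol <- apply(m, 2, function(col) all(col %in% .BASES))
  monoCol <- cleanCol & apply(m, 2, function(col) length(unique(col)) == 1L)
  rows <- list()
  for (j in codingCols) {
    if (!cleanCol[j]) next
    col <- m[, j]
    if (length(unique(col)) < 2L) next
    lo <- j - flank; hi <- j + flank
    if (lo < 1L || hi > width) next
    if (!all(monoCol[c(lo:(j - 1L), (j + 1L):hi)])) next
    for (base in unique(col)) {
      carriers <- rownames(m)[col == base]
      if (length(carriers) <= carrierMax && length(carriers) < nrow(m))
        rows[[length(rows) + 1L]] <- data.frame(
          locus = alleles@locus, position = j - 1L, diagnostic_base = base,
          carriers = paste(sort(carriers), collapse = ","))
    }
  }
  if (!length(rows))
    return(data.frame(assay_id = character(), locus = character(),
                      position = integer(), diagnostic_base = character(),
                      carriers = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  out <- cbind(assay_id = sprintf("%s_SNP%d", out$locus, seq_len(nrow(out))),
               out)
  rownames(out) <- NULL
  out
}

setMethod("show", "CloneAlignment", function(object) {
  cat("CloneAlignment of", object@locus, "-", length(object@sequences),
      "clones x", Biostrings::width(object@sequences)[1], "columns;",
      sum(IRanges::width(object@codingMask)), "coding columns\n")
})

setMethod("show", "AlleleSet", function(object) {
  cat("AlleleSet of", object@locus, "-", length(object@consensus), "alleles",
      sprintf("(%d clone(s) excluded)\n", length(object@excluded)))
  for (a in names(object@consensus))
    cat(sprintf("  %s: %d clones from %s\n", a, object@support[[a]],
                paste(object@individuals[[a]], collapse = ", ")))
})
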