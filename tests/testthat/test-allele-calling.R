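test_that("identical clones collapse to a single fully supported allele", {
  seqs <- setNames(rep("ACGTACGTACGT", 20), sprintf("c%02d", 1:20))
  aln <- cloneAlignment(seqs, locus = "L", codingMask = cbind(0L, 12L))
  al <- collapseClones(aln)
  expect_length(al@consensus, 1L)
  expect_equal(unname(al@support), 20L)
  expect_equal(as.character(al@consensus[[1]]), "ACGTACGTACGT")
})

test_that("well-separated clone groups become distinct alleles", {
  set.seed(14)
  base <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  other <- strsplit(base, "")[[1]]
  flip <- sample(120, 30)
  other[flip] <- vapply(other[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  seqs <- c(setNames(rep(base, 10), paste0("a", 1:10)),
            setNames(rep(paste(other, collapse = ""), 10), paste0("b", 1:10)))
  al <- collapseClones(cloneAlignment(seqs, locus = "L"),
                       maxIntraAlleleDiff = 4)
  expect_length(al@consensus, 2L)
  expect_equal(sort(unname(al@support)), c(10L, 10L))
})

test_that("planted allele structure is recovered and singletons are flagged", {
  sim <- simulateCloneAlignment(locus = "LX", nAlleles = 3, nCodons = 200,
                                diffsPerAllele = 10, clonesPerAllele = 8,
                                errorRate = 0, seed = 51)
  aln <- sim$alignment
  # add one singleton with a single private substitution
  s <- strsplit(sim$truth$alleles[1], "")[[1]]
  j <- 50L
  s[j] <- setdiff(c("A", "C", "G", "T"), s[j])[1]
  seqs <- c(as.character(aln@sequences), singleton = paste(s, collapse = ""))
  aln2 <- cloneAlignment(seqs, locus = "LX", codingMask = cbind(0L, 600L))
  # the singleton sits within 1 substitution of allele 1, so it is lumped;
  # with a tight threshold it is split off and then dropped by minClones
  expect_warning(al <- collapseClones(aln2, maxIntraAlleleDiff = 0,
                                      minClones = 2),
                 "singleton")
  expect_length(al@consensus, 3L)
  expect_equal(length(al@excluded), 1L)
  # consensi match the planted alleles
  expect_setequal(as.character(al@consensus), unname(sim$truth$alleles))
})

test_that("clone collapsing is invariant under input order", {
  sim <- simulateCloneAlignment(nAlleles = 3, nCodons = 150, seed = 52,
                                clonesPerAllele = 6, errorRate = 0.002)
  aln <- sim$alignment
  set.seed(1)
  perm <- sample(length(aln@sequences))
  alnP <- cloneAlignment(as.character(aln@sequences)[perm], locus = aln@locus,
                         individual = aln@individual[perm],
                         codingMask = aln@codingMask)
  a1 <- collapseClones(aln)
  a2 <- collapseClones(alnP)
  expect_setequal(unname(as.character(a1@consensus)),
                  unname(as.character(a2@consensus)))
  expect_equal(sort(unname(a1@support)), sort(unname(a2@support)))
})

test_that("pairwise divergence matches a naive column scan and its axioms", {
  expect_equal(pairwiseDivergence("ACGT", "ACGT"), 0)
  two <- paste(c("A", rep("C", 999)), collapse = "")
  ref <- paste(c("G", rep("C", 998), "T"), collapse = "")
  expect_equal(pairwiseDivergence(two, ref), 0.2)   # 2 diffs / 1000 columns
  # gapped columns are excluded from numerator and denominator
  expect_equal(pairwiseDivergence("AC-T", "ACGT"), 0)
  expect_equal(pairwiseDivergence("AC-A", "ACGT"), 100 / 3)
  expect_error(pairwiseDivergence("ACG", "ACGT"), "equal length")
  set.seed(15)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                                  prob = c(rep(0.23, 4), 0.08)),
                           collapse = "")
    a <- mk(); b <- mk()
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    ok <- x != "-" & y != "-"
    naive <- if (any(ok)) 100 * sum(x[ok] != y[ok]) / sum(ok) else NA_real_
    expect_equal(pairwiseDivergence(a, b), naive)
    expect_equal(pairwiseDivergence(a, b), pairwiseDivergence(b, a))
  }
})

test_that("chimera detection recovers planted breakpoints and spares clean clones", {
  sim <- simulateCloneAlignment(locus = "LC", nAlleles = 3, nCodons = 250,
                                diffsPerAllele = 12, clonesPerAllele = 6,
                                errorRate = 0, nChimeras = 3, seed = 61)
  # the unique chimeric clones are expected to fall below minClones
  al <- suppressWarnings(collapseClones(sim$alignment))
  rep <- detectChimeras(sim$alignment, al)
  truth <- sim$truth$chimeras
  for (i in seq_len(nrow(truth))) {
    row <- rep[rep$clone == truth$clone[i], ]
    expect_equal(row$verdict, "chimeric")
    # 0-based half-open breakpoint interval contains the planted cut
    expect_lte(row$breakpointStart, truth$breakpoint[i])
    expect_gt(row$breakpointEnd, truth$breakpoint[i])
  }
  # exact allele consensi are never flagged
  consAln <- cloneAlignment(as.character(al@consensus), locus = "LC")
  expect_true(all(detectChimeras(consAln, al)$verdict == "clean"))
})

test_that("chimera false-positive rate on clean noisy clones stays below 5 percent", {
  sim <- simulateCloneAlignment(locus = "LF", nAlleles = 4, nCodons = 250,
                                diffsPerAllele = 10, clonesPerAllele = 50,
                                errorRate = 0.001, nChimeras = 0, seed = 62)
  al <- suppressWarnings(collapseClones(sim$alignment))
  rep <- detectChimeras(sim$alignment, al)
  expect_lt(mean(rep$verdict == "chimeric"), 0.05)
})

test_that("diagnostic SNP discovery honors carrier sets, flanks and masks", {
  cons <- c(
    "AAATTTGGGCCCAAATTTGGG",
    "AAATTTGGACCCAAATTTGGG",   # private base at column 8 (0-based)
    "AAATTTGGGCCCAAATTTGGG",
    "AAATTTGGGCCCAAATTTGGG")
  al <- new("AlleleSet", locus = "L",
            consensus = Biostrings::DNAStringSet(
              setNames(cons, paste0("L-", 1:4))),
            support = setNames(rep(5L, 4), paste0("L-", 1:4)),
            individuals = setNames(as.list(rep("H", 4)), paste0("L-", 1:4)),
            excluded = Biostrings::DNAStringSet(),
            codingMask = IRanges::IRanges(1, 21))
  snps <- findDiagnosticSnps(al, carrierMax = 1)
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$position, 8L)
  expect_equal(snps$diagnostic_base, "A")
  expect_equal(snps$carriers, "L-2")
  # shared diagnostic base -> carrier set of size two (allowed at carrierMax 2)
  cons2 <- cons
  cons2[3] <- cons2[2]
  al2 <- al
  al2@consensus <- Biostrings::DNAStringSet(setNames(cons2, paste0("L-", 1:4)))
  snps2 <- findDiagnosticSnps(al2, carrierMax = 2)
  # both base partitions of the column qualify at carrierMax 2
  expect_equal(snps2$carriers[snps2$position == 8 &
                              snps2$diagnostic_base == "A"], "L-2,L-3")
  expect_equal(snps2$carriers[snps2$position == 8 &
                              snps2$diagnostic_base == "G"], "L-1,L-4")
  expect_equal(nrow(findDiagnosticSnps(al2, carrierMax = 1)), 0L)
  # monomorphic alignment -> empty result
  al3 <- al
  al3@consensus <- Biostrings::DNAStringSet(setNames(rep(cons[1], 4),
                                                     paste0("L-", 1:4)))
  expect_equal(nrow(findDiagnosticSnps(al3)), 0L)
})

test_that("emitted SNPs always sit in the coding mask on gap-free columns", {
  sim <- simulateCloneAlignment(locus = "LS", nAlleles = 4, nCodons = 200,
                                diffsPerAllele = 15, clonesPerAllele = 5,
                                errorRate = 0, seed = 63)
  al <- collapseClones(sim$alignment)
  snps <- findDiagnosticSnps(al)
  expect_gt(nrow(snps), 0L)
  m <- do.call(rbind, strsplit(as.character(al@consensus), ""))
  maskCols <- seq(IRanges::start(al@codingMask), IRanges::end(al@codingMask))
  for (i in seq_len(nrow(snps))) {
    col <- snps$position[i] + 1L
    expect_true(col %in% maskCols)
    expect_true(all(m[, col] %in% c("A", "C", "G", "T")))
    carriers <- strsplit(snps$carriers[i], ",")[[1]]
    expect_true(all(m[match(carriers, names(al@consensus)), col] ==
                    snps$diagnostic_base[i]))
  }
})
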