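test_that("single-difference codon pairs classify by the genetic code", {
  a <- codonAlignment(c(s1 = "AAATTTGGG", s2 = "AAGTTTGGG"))  # Lys/Lys
  ca <- countSubstitutions(a)
  expect_equal(ca$nSynonymous, 1)
  expect_equal(ca$nNonsynonymous, 0)
  b <- codonAlignment(c(s1 = "TTTAAA", s2 = "ATTAAA"))        # Phe/Ile
  cb <- countSubstitutions(b)
  expect_equal(cb$nSynonymous, 0)
  expect_equal(cb$nNonsynonymous, 1)
  expect_error(countSubstitutions(codonAlignment(c(s1 = "TAAAAA",
                                                   s2 = "TAAAAA"))),
               "stop codon")
})

test_that("pairwise counting equals the exhaustive pathway-enumeration oracle", {
  set.seed(81)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (rep in 1:60) {
    L <- sample(20:60, 1)
    s1 <- sample(sense, L, replace = TRUE)
    s2 <- s1
    nmut <- sample(1:8, 1)
    cols <- sample(L, min(nmut, L))
    s2[cols] <- sample(sense, length(cols), replace = TRUE)
    a <- paste(s1, collapse = ""); b <- paste(s2, collapse = "")
    got <- countSubstitutions(codonAlignment(c(x = a, y = b)))
    want <- oraclePairAlignment(a, b)
    expect_equal(got$nSynonymous, unname(want["syn"]), tolerance = 1e-9)
    expect_equal(got$nNonsynonymous, unname(want["non"]), tolerance = 1e-9)
  }
})

test_that("multi-sequence columns are counted over the codon spanning tree", {
  # AAA (Lys), AAG (Lys), AAT (Asn): two single-step edges from AAA
  a <- codonAlignment(c(s1 = "AAA", s2 = "AAG", s3 = "AAT"))
  ca <- countSubstitutions(a)
  expect_equal(ca$nSynonymous, 1)
  expect_equal(ca$nNonsynonymous, 1)
  # gap codons are dropped under complete deletion; gap runs count as events
  g <- codonAlignment(c(s1 = "AAATTTGGG", s2 = "AAA---GGG", s3 = "AAATTTGGG"))
  cg <- countSubstitutions(g)
  expect_equal(cg$nCodonsUsed, 2L)
  expect_equal(cg$nIndelEvents, 1L)
})

test_that("NG86 is symmetric, zero on identical input, and sane on known pairs", {
  s <- "ATGGCCAAATTTGGGCCCTAT"
  r <- ng86(s, s)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$omega))
  # one synonymous difference: dS > 0, dN = 0
  r2 <- ng86("ATGGCCAAATTTGGGCCCTAT", "ATGGCCAAGTTTGGGCCCTAT")
  expect_gt(r2$dS, 0)
  expect_equal(r2$dN, 0)
  set.seed(82)
  tr2 <- ape::read.tree(text = "(a:0.4,b:0.4);")
  for (i in 1:20) {
    sim <- simulateCodons(tr2, omega = 0.5, kappa = 2, nCodons = 150)
    x <- as.character(sim@sequences[["a"]])
    y <- as.character(sim@sequences[["b"]])
    f <- ng86(x, y); g <- ng86(y, x)
    expect_equal(f$dN, g$dN)
    expect_equal(f$dS, g$dS)
  }
})

test_that("NG86 recovers the simulation omega on average", {
  tr2 <- ape::read.tree(text = "(a:0.35,b:0.35);")
  set.seed(83)
  om <- vapply(1:100, function(i) {
    sim <- simulateCodons(tr2, omega = 0.3, kappa = 1, nCodons = 300)
    ng86(as.character(sim@sequences[["a"]]),
         as.character(sim@sequences[["b"]]))$omega
  }, numeric(1))
  expect_gt(mean(om, na.rm = TRUE), 0.2)
  expect_lt(mean(om, na.rm = TRUE), 0.4)
})

test_that("the pruning likelihood matches an independent dense-matrix oracle", {
  set.seed(84)
  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.25,d:0.15);")
  sim <- simulateCodons(tr, omega = 0.4, kappa = 2, nCodons = 40, seed = 85)
  seqs <- as.list(as.character(sim@sequences))
  for (pars in list(c(2, 0.4), c(1.5, 0.15), c(3, 1.2))) {
    pi <- rep(1 / 61, 61)
    want <- oracleCodonLnL(tr, seqs, pars[1], pars[2], pi)
    st <- caninaASE:::.codonStates(sim)
    pat <- caninaASE:::.sitePatterns(st$states)
    trp <- stats::reorder(tr, "postorder")
    tips <- pat$tipStates[match(trp$tip.label, names(sim@sequences)), ,
                          drop = FALSE]
    storage.mode(tips) <- "integer"
    edge <- trp$edge
    storage.mode(edge) <- "integer"
    got <- caninaASE:::.codonLnLCpp(edge, trp$edge.length,
                                    rep(1L, nrow(edge)),
                                    length(trp$tip.label),
                                    length(trp$tip.label) + trp$Nnode,
                                    tips, pat$weights, pi,
                                    caninaASE:::.codonTables()$type,
                                    pars[1], pars[2])
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("the one-ratio fit is reproducible across restarts and flags boundaries", {
  tr <- ape::read.tree(text = "((a:0.3,b:0.3):0.15,c:0.4,d:0.4);")
  sim <- simulateCodons(tr, omega = 0.2, kappa = 2, nCodons = 200, seed = 86)
  f1 <- m0Fit(sim, omegaStarts = 0.1)
  f2 <- m0Fit(sim, omegaStarts = 1.5)
  expect_lt(abs(f1@logLik - f2@logLik), 1e-4)
  expect_lt(abs(f1@omega - f2@omega), 0.01)
  expect_equal(f1@dN / f1@dS, f1@omega, tolerance = 1e-6)
  # purely synonymous variation drives omega to the boundary
  syn <- codonAlignment(c(a = "AAATTTGGGCCC", b = "AAGTTTGGGCCC",
                          c = "AAATTCGGGCCC", d = "AAATTTGGACCC"))
  fs <- m0Fit(syn)
  expect_lt(fs@omega, 1e-3)
  expect_true(any(grepl("boundary", fs@flags)))
  expect_error(m0Fit(codonAlignment(c(a = "AAA", b = "AAA"))), "3 sequences")
})

test_that("the two-ratio model nests the one-ratio model and detects rate contrasts", {
  tr <- ape::read.tree(text = "((a:0.3,b:0.3):0.15,c:0.4,d:0.4);")
  set.seed(87)
  # null data: statistic is non-negative and alternative never fits worse
  sim0 <- simulateCodons(tr, omega = 0.3, kappa = 2, nCodons = 200)
  lrt0 <- twoRatioLrt(sim0, foreground = "a")
  expect_gte(lrt0$fit1@logLik, lrt0$fit0@logLik)
  expect_gte(lrt0$statistic, 0)
  # strong contrast: foreground omega 0.9 vs background 0.1
  hits <- vapply(1:10, function(i) {
    sim <- simulateCodons(tr, omega = c(0.1, 0.9), kappa = 2, nCodons = 400,
                          foreground = "a")
    lrt <- twoRatioLrt(sim, foreground = "a", omegaStarts = c(0.1, 1))
    lrt$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("codon simulation honors its process definition", {
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.2,c:0.5,d:0.5);")
  # omega 0: no non-synonymous change can occur, so every tip encodes the
  # same protein (parsimony counting may still average over nonsyn-crossing
  # orderings for multi-hit codons, so the process property is checked on
  # the translations)
  sim0 <- simulateCodons(tr, omega = 0, kappa = 2, nCodons = 150, seed = 88)
  aa <- as.character(Biostrings::translate(sim0@sequences))
  expect_equal(length(unique(aa)), 1L)
  # zero branch lengths: all sequences identical
  trz <- tr
  trz$edge.length[] <- 0
  simz <- simulateCodons(trz, omega = 0.5, kappa = 2, nCodons = 50, seed = 89)
  expect_equal(length(unique(as.character(simz@sequences))), 1L)
  # seed reproducibility
  s1 <- simulateCodons(tr, 0.5, 2, 50, seed = 90)
  s2 <- simulateCodons(tr, 0.5, 2, 50, seed = 90)
  expect_identical(as.character(s1@sequences), as.character(s2@sequences))
})

test_that("simulator and counters agree on the synonymous/non-synonymous balance at omega 1", {
  # at omega = 1 the expected dN/dS from counting should be near 1
  tr2 <- ape::read.tree(text = "(a:0.4,b:0.4);")
  set.seed(91)
  om <- vapply(1:40, function(i) {
    sim <- simulateCodons(tr2, omega = 1, kappa = 1, nCodons = 300)
    ng86(as.character(sim@sequences[["a"]]),
         as.character(sim@sequences[["b"]]))$omega
  }, numeric(1))
  expect_gt(mean(om), 0.85)
  expect_lt(mean(om), 1.2)
})

test_that("Tajima's relative rate test matches its closed form", {
  # equal unique differences: no signal
  o <- paste(rep("AAA", 40), collapse = "")
  base <- strsplit(o, "")[[1]]
  mk <- function(cols, to) {
    s <- base; s[cols] <- to; paste(s, collapse = "")
  }
  s1 <- mk(1:4 * 3, "C")          # 4 unique sites in s1
  s2 <- mk(1:4 * 3 + 60, "G")     # 4 unique sites in s2
  r <- tajimaRrt(s1, s2, o)
  expect_equal(r$m1, 4); expect_equal(r$m2, 4)
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  # m1 = 10, m2 = 2: chi-square 64/12, hand-computable p
  s1b <- mk(seq(1, 28, 3), "C")   # 10 sites
  s2b <- mk(c(61, 64), "G")       # 2 sites
  rb <- tajimaRrt(s1b, s2b, o)
  expect_equal(rb$m1, 10); expect_equal(rb$m2, 2)
  expect_equal(rb$statistic, 64 / 12)
  expect_equal(rb$p, pchisq(64 / 12, 1, lower.tail = FALSE))
  expect_equal(round(rb$p, 3), 0.021)
  # no informative sites: flagged no-test
  rn <- tajimaRrt(o, o, o)
  expect_true(rn$noTest)
  expect_equal(rn$p, 1)
})

test_that("batch relative rate tests keep the false-positive rate controlled under equal rates", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.2,c:0.2):0.2,o:0.4);")
  set.seed(92)
  anySig <- vapply(1:150, function(i) {
    sim <- simulateCodons(tr, omega = 0.5, kappa = 2, nCodons = 200)
    out <- tajimaRrtBatch(sim, outgroup = "o")
    any(out$pAdj < 0.05)
  }, logical(1))
  expect_lte(mean(anySig), 0.06)
  # adjusted p never drops below raw p
  sim <- simulateCodons(tr, omega = 0.5, kappa = 2, nCodons = 200, seed = 93)
  out <- tajimaRrtBatch(sim, outgroup = "o")
  expect_true(all(out$pAdj >= out$p))
})
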