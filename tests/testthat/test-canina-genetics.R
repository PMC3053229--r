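test_that("founder genotypes carry the duplicated bivalent allele", {
  g <- leafyFounder()
  expect_equal(alleleCopyNumbers(g, "LEAFY"),
               c("LEAFY-1" = 1L, "LEAFY-2" = 1L, "LEAFY-3" = 2L,
                 "LEAFY-4" = 1L))
  # all-identical founder collapses to a single fixed allele
  g1 <- makeFounder("A", c("A", "A", "A"), "L")
  expect_equal(alleleCopyNumbers(g1, "L"), c(A = 5L))
  # fully heterozygous univalents give the four-allele maximum
  g4 <- makeFounder("a", c("b", "c", "d"), "L")
  expect_length(alleleCopyNumbers(g4, "L"), 4L)
  expect_error(makeFounder("a", c("b", "c"), "L"), "univalent")
  expect_error(makeFounder("a", c("b", "c", "d"), character(0)), "locus")
})

test_that("chromosome accounting holds for every gamete and zygote", {
  p <- meiosisParam()
  g <- leafyFounder()
  set.seed(11)
  for (i in 1:25) {
    po <- pollenGamete(g, p)
    eg <- eggGamete(g, p)
    zy <- fertilize(po, eg)
    expect_identical(nChromosomes(po), 7L)
    expect_identical(nChromosomes(eg), 28L)
    expect_identical(nChromosomes(zy), 35L)
  }
  # tetraploid mode: haploid pollen, triploid eggs, tetraploid zygotes
  p4 <- meiosisParam(ploidy = 4L)
  g4 <- makeFounder("a", c("b", "c"), "L", p4)
  expect_identical(nChromosomes(pollenGamete(g4, p4)), 7L)
  expect_identical(nChromosomes(eggGamete(g4, p4)), 21L)
  expect_identical(nChromosomes(fertilize(pollenGamete(g4, p4),
                                          eggGamete(g4, p4))), 28L)
})

test_that("pollen is a bivalent mosaic; no crossover keeps chromosomes intact", {
  # two loci on the same chromosome; differing alleles on B1 and B2
  map <- data.frame(locus = c("L1", "L2"), chromosome = c(1L, 1L),
                    position = c(0.2, 0.8))
  p0 <- meiosisParam(recombinationRate = 0, lociMap = map)
  g <- new("CaninaGenotype", individualId = "het", sets = list(
    new("ChromosomeSet", label = "B1", role = "bivalent",
        alleles = c(L1 = "x1", L2 = "x2"), nChromosomes = 7L),
    new("ChromosomeSet", label = "B2", role = "bivalent",
        alleles = c(L1 = "y1", L2 = "y2"), nChromosomes = 7L),
    new("ChromosomeSet", label = "U1", role = "univalent",
        alleles = c(L1 = "u", L2 = "u"), nChromosomes = 7L),
    new("ChromosomeSet", label = "U2", role = "univalent",
        alleles = c(L1 = "u", L2 = "u"), nChromosomes = 7L),
    new("ChromosomeSet", label = "U3", role = "univalent",
        alleles = c(L1 = "u", L2 = "u"), nChromosomes = 7L)))
  set.seed(21)
  for (i in 1:50) {
    a <- pollenGamete(g, p0)@sets[[1]]@alleles
    expect_true(identical(unname(a), c("x1", "x2")) ||
                identical(unname(a), c("y1", "y2")))
  }
  # with recombination, both parental phases and recombinants appear,
  # but alleles always come from B1/B2, never a univalent
  p1 <- meiosisParam(recombinationRate = 2, lociMap = map)
  seen <- replicate(200, paste(pollenGamete(g, p1)@sets[[1]]@alleles,
                               collapse = "/"))
  expect_true(all(!grepl("u", seen)))
  expect_gt(length(unique(seen)), 2L)
  # identical bivalents make recombination invisible
  gid <- leafyFounder()
  expect_identical(
    pollenGamete(gid, meiosisParam(recombinationRate = 2))@sets[[1]]@alleles[["LEAFY"]],
    "LEAFY-3")
})

test_that("univalent alleles pass through eggs unchanged when mutation is off", {
  p <- meiosisParam(mutationRate = 0)
  g <- leafyFounder()
  set.seed(31)
  eggs <- replicate(500, eggGamete(g, p), simplify = FALSE)
  uAlleles <- vapply(eggs, function(e) {
    u <- Filter(function(s) s@role == "univalent", e@sets)
    paste(sort(vapply(u, function(s) s@alleles[["LEAFY"]], character(1))),
          collapse = ",")
  }, character(1))
  expect_true(all(uAlleles == "LEAFY-1,LEAFY-2,LEAFY-4"))
})

test_that("selfing a founder reproduces its copy numbers and respects the four-allele ceiling", {
  p <- meiosisParam(mutationRate = 0)
  g <- leafyFounder()
  set.seed(41)
  for (i in 1:20) {
    off <- fertilize(pollenGamete(g, p), eggGamete(g, p))
    expect_equal(alleleCopyNumbers(off, "LEAFY"),
                 alleleCopyNumbers(g, "LEAFY"))
  }
  expect_error(fertilize(pollenGamete(g, p), pollenGamete(g, p)), "pollen")
})

test_that("evolvePopulation reproduces the founder census at zero generations and conserves labels", {
  founders <- list(leafyFounder(),
                   makeFounder("LEAFY-3", c("LEAFY-1", "LEAFY-1", "LEAFY-2"),
                               "LEAFY", individualId = "f2"))
  res0 <- evolvePopulation(founders, 0L, seed = 5)
  expect_equal(res0$summary$generation, 0L)
  expect_equal(res0$summary$maxDistinctAlleles, 4)
  expect_identical(res0$population, founders)
  res <- evolvePopulation(founders, 5L, nOffspring = 40L,
                          param = meiosisParam(mutationRate = 0), seed = 6)
  labels <- unlist(lapply(res$population, function(g)
    names(alleleCopyNumbers(g, "LEAFY"))))
  expect_true(all(labels %in% paste0("LEAFY-", 1:4)))
  # copy-number conservation in every individual
  expect_true(all(vapply(res$population, function(g)
    sum(alleleCopyNumbers(g, "LEAFY")) == 5L, logical(1))))
  expect_error(evolvePopulation(list(), 1L), "empty")
})

test_that("mutation increases allele diversity relative to the mutation-free run", {
  founders <- replicate(20, leafyFounder(), simplify = FALSE)
  resMut <- evolvePopulation(founders, 15L, nOffspring = 80L,
                             param = meiosisParam(mutationRate = 1e-2),
                             seed = 77)
  resNull <- evolvePopulation(founders, 15L, nOffspring = 80L,
                              param = meiosisParam(mutationRate = 0),
                              seed = 77)
  lastMut <- tail(resMut$summary$meanDistinctAlleles, 1)
  lastNull <- tail(resNull$summary$meanDistinctAlleles, 1)
  expect_gt(lastMut, lastNull)
})

test_that("reruns with the same seed reproduce the simulation exactly", {
  founders <- list(leafyFounder())
  a <- evolvePopulation(founders, 3L, nOffspring = 15L, seed = 99)
  b <- evolvePopulation(founders, 3L, nOffspring = 15L, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(lapply(a$population, alleleCopyNumbers, locus = "LEAFY"),
                   lapply(b$population, alleleCopyNumbers, locus = "LEAFY"))
})
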