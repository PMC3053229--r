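## Forward simulator of canina meiosis: haploid pollen from the two
## recombining bivalent sets, (ploidy-1)x eggs carrying one recombined
## bivalent-derived set plus every univalent set unchanged.

#' Construct canina meiosis parameters
#'
#' @param baseNumber chromosomes per set (x); 7 in \emph{Rosa}.
#' @param ploidy somatic sets; 5 for pentaploid dogroses, 4 for the
#'   tetraploid mode (haploid pollen, triploid eggs).
#' @param recombinationRate expected crossovers per chromosome per bivalent
#'   meiosis (Poisson-distributed count, uniform breakpoints on a unit map).
#' @param mutationRate per-locus per-transmission probability of creating a
#'   fresh, never-seen allele label (infinite-alleles model).
#' @param lociMap optional data.frame (\code{locus}, \code{chromosome},
#'   \code{position}) assigning loci to map positions; by default loci are
#'   distributed round-robin over chromosomes at position 0.5 when a founder
#'   is built.
#' @return a [MeiosisParam-class] object.
#' @examples
#' meiosisParam()                # pentaploid defaults: 2 bivalents, 3 univalents
#' meiosisParam(ploidy = 4L)     # tetraploid dogrose mode
#' @export
meiosisParam <- function(baseNumber = 7L, ploidy = 5L, recombinationRate = 1,
                         mutationRate = 0, lociMap = NULL) {
  if (is.null(lociMap))
    lociMap <- data.frame(locus = character(), chromosome = integer(),
                          position = numeric())
  new("MeiosisParam", baseNumber = as.integer(baseNumber),
      ploidy = as.integer(ploidy),
      recombinationRate = as.numeric(recombinationRate),
      mutationRate = as.numeric(mutationRate), lociMap = lociMap)
}

#' Number of univalent chromosome sets implied by the ploidy
#' @param param a [MeiosisParam-class].
#' @return integer, \code{ploidy - 2}.
#' @export
nUnivalentSets <- function(param) param@ploidy - 2L

.makeSet <- function(label, role, alleles, nChromosomes) {
  new("ChromosomeSet", label = label, role = role,
      alleles = alleles, nChromosomes = as.integer(nChromosomes))
}

.defaultLociMap <- function(loci, baseNumber) {
  data.frame(locus = loci,
             chromosome = ((seq_along(loci) - 1L) %% baseNumber) + 1L,
             position = 0.5)
}

#' Build a founder genotype with a duplicated bivalent allele
#'
#' The founder carries the same allele on both bivalent-forming sets at
#' every locus (the duplicated-copy configuration expected when the two
#' recombining sets descend from a common diploid progenitor) and the given
#' labels on the univalent sets, so per-locus copy numbers are 2 for the
#' bivalent allele and 1 for each distinct univalent allele.
#'
#' @param bivalentAllele allele label carried by both bivalent sets.
#' @param univalentAlleles character vector of length \code{ploidy - 2}
#'   (duplicates allowed): alleles on the univalent sets.
#' @param loci character vector of locus names. If allele labels should
#'   differ per locus, pass named lists instead: \code{bivalentAllele} and
#'   each univalent entry may be a vector with one element per locus.
#' @param param a [MeiosisParam-class].
#' @param individualId identifier for the founder.
#' @return a [CaninaGenotype-class].
#' @examples
#' g <- makeFounder("LEAFY-3", c("LEAFY-1", "LEAFY-2", "LEAFY-4"), "LEAFY")
#' alleleCopyNumbers(g, "LEAFY")   # LEAFY-3 has two copies
#' @export
makeFounder <- function(bivalentAllele, univalentAlleles, loci,
                        param = meiosisParam(), individualId = "founder") {
  nU <- nUnivalentSets(param)
  if (length(univalentAlleles) != nU)
    stop("expected ", nU, " univalent allele labels for ploidy ", param@ploidy,
         ", got ", length(univalentAlleles))
  if (length(loci) < 1L) stop("at least one locus required")
  expand <- function(x) {
    x <- rep_len(unlist(x), length(loci))
    names(x) <- loci
    x
  }
  biv <- expand(bivalentAllele)
  sets <- list(
    .makeSet("B1", "bivalent", biv, param@baseNumber),
    .makeSet("B2", "bivalent", biv, param@baseNumber)
  )
  for (i in seq_len(nU))
    sets[[2L + i]] <- .makeSet(paste0("U", i), "univalent",
                               expand(univalentAlleles[i]), param@baseNumber)
  new("CaninaGenotype", sets = sets, individualId = individualId)
}

#' Per-allele copy numbers of a genotype at a locus
#'
#' @param genotype a [CaninaGenotype-class].
#' @param locus locus name.
#' @return named integer vector of copies per allele, summing to the ploidy.
#' @export
alleleCopyNumbers <- function(genotype, locus) {
  a <- vapply(genotype@sets, function(s) s@alleles[[locus]], character(1))
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

#' Loci carried by a genotype
#' @param genotype a [CaninaGenotype-class].
#' @return character vector of locus names.
#' @export
lociOf <- function(genotype) names(genotype@sets[[1]]@alleles)

#' Chromosome count of a gamete or genotype
#'
#' @param x a [Gamete-class] or [CaninaGenotype-class].
#' @return integer: total chromosomes carried (e.g. 7 for pollen, 28 for a
#'   pentaploid egg, 35 for a pentaploid zygote at base number 7).
#' @export
nChromosomes <- function(x) {
  sets <- if (is(x, "Gamete") || is(x, "CaninaGenotype")) x@sets
          else stop("need a Gamete or CaninaGenotype")
  sum(vapply(sets, function(s) s@nChromosomes, integer(1)))
}

## A recombined bivalent-derived set: per chromosome, Poisson crossover
## count with uniform breakpoints; the emitted product is one of the two
## post-meiotic mosaics, chosen uniformly.
.recombineBivalents <- function(b1, b2, param) {
  map <- param@lociMap
  if (nrow(map) == 0L)
    map <- .defaultLociMap(names(b1@alleles), param@baseNumber)
  out <- b1@alleles
  for (chrom in unique(map$chromosome)) {
    onChrom <- map[map$chromosome == chrom, , drop = FALSE]
    start <- sample.int(2L, 1L)                    # which homolog leads
    k <- rpois(1L, param@recombinationRate)
    breaks <- sort(runif(k))
    for (i in seq_len(nrow(onChrom))) {
      segment <- sum(breaks <= onChrom$position[i])
      parent <- if ((start + segment) %% 2L == 1L) b1 else b2
      out[[onChrom$locus[i]]] <- parent@alleles[[onChrom$locus[i]]]
    }
  }
  out
}

.mutateAlleles <- function(alleles, rate) {
  if (rate <= 0) return(alleles)
  hit <- runif(length(alleles)) < rate
  if (any(hit))
    alleles[hit] <- sprintf("%s.m%09d", alleles[hit],
                            sample.int(.Machine$integer.max - 1L, sum(hit)))
  alleles
}

.bivalentSets <- function(genotype) {
  Filter(function(s) s@role == "bivalent", genotype@sets)
}
.univalentSets <- function(genotype) {
  Filter(function(s) s@role == "univalent", genotype@sets)
}

#' Simulate a pollen gamete
#'
#' Pollen carries a single haploid set (n = x) that is a recombination
#' mosaic of the two bivalent-forming sets; univalents are never
#' transmitted through pollen.
#'
#' @param genotype a [CaninaGenotype-class].
#' @param param a [MeiosisParam-class].
#' @return a [Gamete-class] of kind \code{"pollen"}.
#' @export
pollenGamete <- function(genotype, param = meiosisParam()) {
  b <- .bivalentSets(genotype)
  alleles <- .mutateAlleles(.recombineBivalents(b[[1]], b[[2]], param),
                            param@mutationRate)
  new("Gamete", kind = "pollen",
      sets = list(.makeSet("B", "bivalent", alleles, param@baseNumber)))
}

#' Simulate an egg gamete
#'
#' The egg carries one recombined bivalent-derived set plus every
#' univalent set unchanged (apart from mutation), i.e. n = (ploidy - 1) x:
#' tetraploid eggs in pentaploids, triploid eggs in tetraploids. Univalent
#' alleles are thereby transmitted exclusively maternally.
#'
#' @inheritParams pollenGamete
#' @return a [Gamete-class] of kind \code{"egg"}.
#' @export
eggGamete <- function(genotype, param = meiosisParam()) {
  b <- .bivalentSets(genotype)
  alleles <- .mutateAlleles(.recombineBivalents(b[[1]], b[[2]], param),
                            param@mutationRate)
  sets <- c(list(.makeSet("B", "bivalent", alleles, param@baseNumber)),
            lapply(.univalentSets(genotype), function(u)
              .makeSet(u@label, "univalent",
                       .mutateAlleles(u@alleles, param@mutationRate),
                       param@baseNumber)))
  new("Gamete", kind = "egg", sets = sets)
}

#' Fuse a pollen and an egg gamete into a zygote
#'
#' @param pollen a pollen [Gamete-class].
#' @param egg an egg [Gamete-class].
#' @param individualId identifier for the offspring.
#' @return a [CaninaGenotype-class] with the somatic chromosome number
#'   restored (2n = ploidy x, e.g. 35 in pentaploids).
#' @export
fertilize <- function(pollen, egg, individualId = "offspring") {
  if (pollen@kind != "pollen" || egg@kind != "egg")
    stop("fertilize() needs one pollen and one egg gamete")
  eggB <- Filter(function(s) s@role == "bivalent", egg@sets)[[1]]
  eggU <- Filter(function(s) s@role == "univalent", egg@sets)
  sets <- c(
    list(.makeSet("B1", "bivalent", pollen@sets[[1]]@alleles,
                  pollen@sets[[1]]@nChromosomes),
         .makeSet("B2", "bivalent", eggB@alleles, eggB@nChromosomes)),
    lapply(seq_along(eggU), function(i)
      .makeSet(paste0("U", i), "univalent", eggU[[i]]@alleles,
               eggU[[i]]@nChromosomes))
  )
  new("CaninaGenotype", sets = sets, individualId = individualId)
}

#' Evolve a population under canina meiosis
#'
#' Non-overlapping generations of constant size: each offspring draws a
#' uniform random mother (egg) and father (pollen) from the previous
#' generation. Returns the final population and a per-generation,
#' per-locus census of allele diversity.
#'
#' @param founders list of [CaninaGenotype-class] founders.
#' @param generations integer \eqn{\ge 0}.
#' @param nOffspring population size per generation (default: number of
#'   founders).
#' @param param a [MeiosisParam-class].
#' @param seed optional integer seed; identical seeds reproduce runs.
#' @return list with \code{population} (list of genotypes),
#'   \code{summary} (data.frame: generation, locus, meanDistinctAlleles,
#'   maxDistinctAlleles, nIndividuals) and \code{generations} (list of all
#'   generations, founders first).
#' @export
evolvePopulation <- function(founders, generations, nOffspring = length(founders),
                             param = meiosisParam(), seed = NULL) {
  if (length(founders) == 0L) stop("empty founder population")
  if (generations < 0L) stop("generations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  loci <- lociOf(founders[[1]])
  census <- function(pop, gen) {
    do.call(rbind, lapply(loci, function(l) {
      d <- vapply(pop, function(g) length(alleleCopyNumbers(g, l)), integer(1))
      data.frame(generation = gen, locus = l,
                 meanDistinctAlleles = mean(d), maxDistinctAlleles = max(d),
                 nIndividuals = length(pop))
    }))
  }
  pop <- founders
  gens <- list(pop)
  summaries <- list(census(pop, 0L))
  for (gen in seq_len(generations)) {
    pop <- lapply(seq_len(nOffspring), function(i) {
      mother <- pop[[sample.int(length(pop), 1L)]]
      father <- pop[[sample.int(length(pop), 1L)]]
      fertilize(pollenGamete(father, param), eggGamete(mother, param),
                individualId = sprintf("g%d.i%d", gen, i))
    })
    gens[[gen + 1L]] <- pop
    summaries[[gen + 1L]] <- census(pop, gen)
  }
  list(population = pop, summary = do.call(rbind, summaries),
       generations = gens)
}

#' Tidy genotype table for a population
#'
#' @param population a [CaninaGenotype-class] or list of them.
#' @return data.frame with one row per individual x chromosome set x
#'   locus: \code{individual}, \code{set}, \code{role}, \code{locus},
#'   \code{allele}.
#' @export
genotypeTable <- function(population) {
  if (is(population, "CaninaGenotype")) population <- list(population)
  do.call(rbind, lapply(population, function(g)
    do.call(rbind, lapply(g@sets, function(s)
      data.frame(individual = g@individualId, set = s@label, role = s@role,
                 locus = names(s@alleles), allele = unname(s@alleles),
                 row.names = NULL)))))
}

#' @describeIn makeFounder display method
#' @param object a [CaninaGenotype-class]
#' @export
setMethod("show", "CaninaGenotype", function(object) {
  cat("CaninaGenotype", object@individualId, "-",
      length(object@sets), "chromosome sets,",
      nChromosomes(object), "chromosomes\n")
  for (l in lociOf(object)) {
    k <- alleleCopyNumbers(object, l)
    cat(sprintf("  %s: %s\n", l,
                paste(sprintf("%s x%d", names(k), k), collapse = ", ")))
  }
})

setMethod("show", "Gamete", function(object) {
  cat("Gamete (", object@kind, "): ", length(object@sets), " sets, ",
      nChromosomes(object), " chromosomes\n", sep = "")
})
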