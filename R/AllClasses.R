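#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom IRanges IRanges
#' @importFrom stats aov anova optim median pchisq pf quantile rbeta
#'   rbinom rpois runif sd setNames var p.adjust dbinom dnorm as.dist hclust
#'   cutree reorder
#' @importFrom utils combn head read.delim write.table packageVersion
#'   modifyList
#' @useDynLib caninaASE, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## canina meiosis containers
## ---------------------------------------------------------------------------

#' Parameters of a canina meiosis simulation
#'
#' Holds the cytological and mutational parameters of the forward simulator:
#' the base chromosome number x (7 in \emph{Rosa}), the somatic ploidy
#' (5 for pentaploid dogroses, 4 for the tetraploid mode), the expected
#' number of crossovers per chromosome per bivalent meiosis, and the
#' per-locus per-transmission probability of creating a new allele label
#' (infinite-alleles mutation). Exactly two chromosome sets form bivalents;
#' the remaining \code{ploidy - 2} sets are univalents transmitted only
#' maternally.
#'
#' @slot baseNumber integer, chromosomes per set (x).
#' @slot ploidy integer, chromosome sets per somatic genome.
#' @slot recombinationRate numeric \eqn{\ge 0}, expected crossovers per
#'   chromosome per bivalent meiosis (Poisson).
#' @slot mutationRate numeric in \eqn{[0, 1]}, per-locus per-transmission
#'   probability of a fresh allele label.
#' @slot lociMap data.frame with columns \code{locus}, \code{chromosome}
#'   (1-based index within a set) and \code{position} (map position in
#'   \eqn{[0, 1]}); filled in by [makeFounder()] if empty.
#' @seealso [meiosisParam()]
#' @exportClass MeiosisParam
setClass("MeiosisParam",
  representation(
    baseNumber = "integer",
    ploidy = "integer",
    recombinationRate = "numeric",
    mutationRate = "numeric",
    lociMap = "data.frame"
  )
)

setValidity("MeiosisParam", function(object) {
  msg <- character()
  if (object@baseNumber < 1L) msg <- c(msg, "baseNumber must be >= 1")
  if (object@ploidy < 3L) msg <- c(msg, "ploidy must be >= 3 (2 bivalent sets + >=1 univalent)")
  if (object@recombinationRate < 0) msg <- c(msg, "recombinationRate must be >= 0")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0, 1]")
  if (nrow(object@lociMap) > 0) {
    if (!all(c("locus", "chromosome", "position") %in% names(object@lociMap)))
      msg <- c(msg, "lociMap needs columns locus, chromosome, position")
    else {
      if (any(object@lociMap$chromosome < 1 | object@lociMap$chromosome > object@baseNumber))
        msg <- c(msg, "lociMap chromosome indices must lie in [1, baseNumber]")
      if (any(object@lociMap$position < 0 | object@lociMap$position > 1))
        msg <- c(msg, "lociMap positions must lie in [0, 1]")
      if (anyDuplicated(object@lociMap$locus))
        msg <- c(msg, "duplicated locus in lociMap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' A chromosome set of a dogrose genotype or gamete
#'
#' One of the \code{ploidy} homologous chromosome sets. Only the two sets
#' labelled \code{B1}/\code{B2} pair as bivalents and recombine; univalent
#' sets (\code{U1}, \code{U2}, ...) are transmitted unchanged through the
#' egg. Loci are single copy: one allele label per locus per set.
#'
#' @slot label set label, e.g. \code{"B1"} or \code{"U2"}.
#' @slot role \code{"bivalent"} or \code{"univalent"}.
#' @slot alleles named character vector, locus -> allele label.
#' @slot nChromosomes integer, chromosomes in this set (the base number x).
#' @exportClass ChromosomeSet
setClass("ChromosomeSet",
  representation(
    label = "character",
    role = "character",
    alleles = "character",
    nChromosomes = "integer"
  )
)

setValidity("ChromosomeSet", function(object) {
  msg <- character()
  if (!object@role %in% c("bivalent", "univalent"))
    msg <- c(msg, "role must be 'bivalent' or 'univalent'")
  if (grepl("^B", object@label) && object@role != "bivalent")
    msg <- c(msg, "B-labelled set must have bivalent role")
  if (grepl("^U", object@label) && object@role != "univalent")
    msg <- c(msg, "U-labelled set must have univalent role")
  if (is.null(names(object@alleles)) || any(!nzchar(names(object@alleles))))
    msg <- c(msg, "alleles must be named by locus")
  if (anyDuplicated(names(object@alleles)))
    msg <- c(msg, "one allele per locus per set")
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A somatic dogrose genotype
#'
#' A pentaploid (or, in tetraploid mode, tetraploid) genotype: exactly two
#' bivalent-forming chromosome sets plus \code{ploidy - 2} univalent sets,
#' each carrying one allele label per locus.
#'
#' @slot sets list of [ChromosomeSet-class] objects (bivalents first).
#' @slot individualId character identifier.
#' @seealso [makeFounder()], [fertilize()], [alleleCopyNumbers()]
#' @exportClass CaninaGenotype
setClass("CaninaGenotype",
  representation(sets = "list", individualId = "character")
)

setValidity("CaninaGenotype", function(object) {
  msg <- character()
  roles <- vapply(object@sets, function(s) s@role, character(1))
  if (sum(roles == "bivalent") != 2L)
    msg <- c(msg, "a canina genotype carries exactly 2 bivalent-forming sets")
  if (sum(roles == "univalent") < 1L)
    msg <- c(msg, "at least one univalent set required")
  loci <- lapply(object@sets, function(s) names(s@alleles))
  if (length(unique(loci)) != 1L)
    msg <- c(msg, "all sets must carry the same loci in the same order")
  if (length(msg)) msg else TRUE
})

#' A gamete produced by canina meiosis
#'
#' Pollen carries a single (possibly recombined) bivalent-derived set;
#' eggs carry one bivalent-derived set plus every univalent set, so that
#' fertilization restores the somatic ploidy.
#'
#' @slot kind \code{"pollen"} or \code{"egg"}.
#' @slot sets list of [ChromosomeSet-class] objects.
#' @exportClass Gamete
setClass("Gamete", representation(kind = "character", sets = "list"))

setValidity("Gamete", function(object) {
  msg <- character()
  if (!object@kind %in% c("pollen", "egg"))
    msg <- c(msg, "kind must be 'pollen' or 'egg'")
  roles <- vapply(object@sets, function(s) s@role, character(1))
  if (object@kind == "pollen" &&
      !(length(object@sets) == 1L && roles[1] == "bivalent"))
    msg <- c(msg, "pollen carries exactly one bivalent-derived set")
  if (object@kind == "egg" &&
      !(sum(roles == "bivalent") == 1L && sum(roles == "univalent") >= 1L))
    msg <- c(msg, "egg carries one bivalent-derived set plus the univalents")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## sequence containers
## ---------------------------------------------------------------------------

#' Aligned cloned sequences for one locus
#'
#' Equal-length aligned clone sequences (IUPAC DNA plus \code{-} gaps) with
#' per-clone metadata and a coding-region mask given as alignment-column
#' intervals. All coordinates are 0-based half-open alignment columns.
#'
#' @slot locus locus name.
#' @slot sequences [Biostrings::DNAStringSet] of equal widths.
#' @slot individual character vector, source individual per clone.
#' @slot clone character vector of clone identifiers.
#' @slot codingMask [IRanges::IRanges] of coding alignment columns
#'   (stored 1-based internally, constructed from 0-based half-open input).
#' @seealso [cloneAlignment()], [collapseClones()], [readFastaAlignment()]
#' @exportClass CloneAlignment
setClass("CloneAlignment",
  representation(
    locus = "character",
    sequences = "DNAStringSet",
    individual = "character",
    clone = "character",
    codingMask = "IRanges"
  )
)

setValidity("CloneAlignment", function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(w) == 0L) msg <- c(msg, "empty alignment")
  if (length(unique(w)) > 1L) msg <- c(msg, "sequences must be aligned (equal widths)")
  n <- length(object@sequences)
  if (length(object@individual) != n || length(object@clone) != n)
    msg <- c(msg, "individual/clone metadata must match the number of sequences")
  if (length(object@codingMask) > 0 && length(w)) {
    if (sum(IRanges::width(object@codingMask)) %% 3L != 0L)
      msg <- c(msg, "coding mask length must be divisible by 3")
    if (max(IRanges::end(object@codingMask)) > w[1] || min(IRanges::start(object@codingMask)) < 1L)
      msg <- c(msg, "coding mask outside alignment")
  }
  if (length(msg)) msg else TRUE
})

#' Allele consensi for one locus
#'
#' The result of collapsing cloned sequences into alleles: one consensus
#' sequence per allele with its supporting clone count and source
#' individuals, plus any clusters too small to call (putative PCR-error
#' singletons), which are reported but excluded.
#'
#' @slot locus locus name.
#' @slot consensus named [Biostrings::DNAStringSet] of allele consensi
#'   (full alignment length).
#' @slot support named integer vector, clones supporting each allele.
#' @slot individuals named list, source individuals per allele.
#' @slot excluded [Biostrings::DNAStringSet] of excluded low-support clones.
#' @slot codingMask [IRanges::IRanges], inherited from the clone alignment.
#' @seealso [collapseClones()], [findDiagnosticSnps()]
#' @exportClass AlleleSet
setClass("AlleleSet",
  representation(
    locus = "character",
    consensus = "DNAStringSet",
    support = "integer",
    individuals = "list",
    excluded = "DNAStringSet",
    codingMask = "IRanges"
  )
)

setValidity("AlleleSet", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@consensus))) msg <- c(msg, "allele labels must be unique")
  if (length(object@support) != length(object@consensus))
    msg <- c(msg, "one support count per allele")
  if (length(unique(Biostrings::width(object@consensus))) > 1L)
    msg <- c(msg, "consensi must share the alignment length")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## copy number / codon model results
## ---------------------------------------------------------------------------

#' An integer copy-number call for one individual at one locus
#'
#' Maximum-likelihood assignment of integer copies per allele under the
#' canina copy-number model (expected genomic diagnostic-base fraction
#' = carrier copies / ploidy), with the ranked alternative compositions.
#'
#' @slot locus locus name.
#' @slot individual individual identifier.
#' @slot copyNumbers named integer vector summing to the ploidy.
#' @slot logLik log-likelihood of the best composition.
#' @slot fittedMeans named numeric, fitted mean fraction per assay.
#' @slot alternatives data.frame of all enumerated compositions ranked by
#'   log-likelihood (columns: one per allele, plus \code{logLik}).
#' @slot tied logical, TRUE if the best likelihood was tied and the
#'   primary call was chosen by the documented tie-break.
#' @seealso [inferCopyNumbers()]
#' @exportClass CopyNumberCall
setClass("CopyNumberCall",
  representation(
    locus = "character",
    individual = "character",
    copyNumbers = "integer",
    logLik = "numeric",
    fittedMeans = "numeric",
    alternatives = "data.frame",
    tied = "logical"
  )
)

setValidity("CopyNumberCall", function(object) {
  msg <- character()
  if (any(object@copyNumbers < 0L)) msg <- c(msg, "copy numbers must be >= 0")
  if (is.null(names(object@copyNumbers))) msg <- c(msg, "copyNumbers must be named by allele")
  if (length(msg)) msg else TRUE
})

#' An in-frame codon alignment of allele consensi
#'
#' Equal-length coding sequences (length divisible by 3, no internal stop
#' codons) for molecular-evolution analyses, optionally with a fixed
#' unrooted tree over the alleles (plus outgroup).
#'
#' @slot locus locus name.
#' @slot sequences named [Biostrings::DNAStringSet], in frame.
#' @slot tree an [ape::phylo] tree or NULL (stored in a list slot).
#' @seealso [codonAlignment()], [m0Fit()], [countSubstitutions()]
#' @exportClass CodonAlignment
setClass("CodonAlignment",
  representation(locus = "character", sequences = "DNAStringSet", tree = "list")
)

setValidity("CodonAlignment", function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(unique(w)) > 1L) msg <- c(msg, "sequences must be aligned")
  if (length(w) && w[1] %% 3L != 0L) msg <- c(msg, "alignment length must be divisible by 3")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "sequences must carry unique names")
  if (length(object@tree) &&
      !is.null(object@tree[[1]]) && !inherits(object@tree[[1]], "phylo"))
    msg <- c(msg, "tree must be an ape phylo object")
  if (length(msg)) msg else TRUE
})

#' A fitted codon substitution model
#'
#' Maximum-likelihood fit of a Goldman-Yang-style codon model with F3x4
#' codon frequencies: either one dN/dS ratio for the whole tree
#' (\code{"one-ratio"}) or one ratio per branch class
#' (\code{"two-ratio"}). \code{dN} and \code{dS} are per-site distances
#' summed over the tree, computed from the fitted rate matrix so that
#' \code{dN/dS} equals the fitted omega.
#'
#' @slot model \code{"one-ratio"} or \code{"two-ratio"}.
#' @slot omega numeric, dN/dS per branch class (length 1 or 2).
#' @slot kappa transition/transversion rate ratio.
#' @slot dN,dS per-site non-synonymous / synonymous tree distances.
#' @slot logLik maximized log-likelihood.
#' @slot tree the [ape::phylo] tree with fitted branch lengths
#'   (expected substitutions per codon), in a list slot.
#' @slot branchClass integer class per tree edge.
#' @slot flags character vector of fit warnings (e.g. omega at boundary).
#' @seealso [m0Fit()], [twoRatioLrt()]
#' @exportClass CodonModelFit
setClass("CodonModelFit",
  representation(
    model = "character",
    omega = "numeric",
    kappa = "numeric",
    dN = "numeric",
    dS = "numeric",
    logLik = "numeric",
    tree = "list",
    branchClass = "integer",
    flags = "character"
  )
)

setValidity("CodonModelFit", function(object) {
  msg <- character()
  if (any(object@omega < 0) || object@kappa < 0 || object@dN < 0 || object@dS < 0)
    msg <- c(msg, "omega, kappa, dN, dS must be >= 0")
  if (!is.finite(object@logLik)) msg <- c(msg, "logLik must be finite")
  if (length(msg)) msg else TRUE
})
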