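## File formats and the end-to-end driver. All tables are TSV with '.'
## for missing values; coordinates in emitted files are 0-based half-open
## alignment columns.

#' Read an aligned multi-FASTA of cloned sequences
#'
#' Headers follow the \code{>cloneID|individual} dialect; a missing
#' \code{|individual} part leaves the individual NA. Sequences are
#' uppercased and must be equal length over the IUPAC DNA alphabet plus
#' gaps.
#'
#' @param path FASTA file.
#' @param locus locus name (default: file base name).
#' @param codingMask optional mask (see [cloneAlignment()]), e.g. from
#'   [readCodingMask()].
#' @return a [CloneAlignment-class].
#' @export
readFastaAlignment <- function(path, locus = NULL,
                               codingMask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  if (length(unique(Biostrings::width(seqs))) != 1L)
    stop("ragged alignment in ", path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  clone <- vapply(parts, `[`, character(1), 1)
  individual <- vapply(parts, function(p)
    if (length(p) > 1) p[2] else NA_character_, character(1))
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  cloneAlignment(seqs, locus = locus, individual = individual,
                 clone = clone, codingMask = codingMask)
}

#' Write an alignment or allele consensi to FASTA
#' @param x a [CloneAlignment-class], [AlleleSet-class] or DNAStringSet.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeFastaAlignment <- function(x, path) {
  seqs <- if (is(x, "CloneAlignment")) x@sequences
  else if (is(x, "AlleleSet")) x@consensus
  else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a BED-like coding mask
#'
#' Three tab-separated columns (locus, start, end), 0-based half-open
#' alignment-column intervals, no header.
#'
#' @param path mask file.
#' @param locus optional locus filter.
#' @return an [IRanges::IRanges] (1-based closed, internal convention).
#' @export
readCodingMask <- function(path, locus = NULL) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("locus", "start", "end"),
                  stringsAsFactors = FALSE)
  if (!is.null(locus)) d <- d[d$locus == locus, , drop = FALSE]
  if (nrow(d) == 0L) stop("no mask intervals", if (!is.null(locus))
    paste0(" for locus ", locus) else "")
  IRanges::IRanges(start = d$start + 1L, end = d$end)
}

.FREQ_COLS <- c("assay_id", "locus", "template", "individual", "bud_stage",
                "replicate", "fraction", "depth")

#' Read a pyrosequencing frequency table
#'
#' TSV with mandatory header (columns \code{assay_id, locus, template,
#' individual, bud_stage, replicate, fraction, depth}); \code{.} denotes
#' missing. Rows are validated: fractions must lie in \eqn{[0, 1]}, template in
#' \{gDNA, cDNA\}, the (assay, template, individual, stage, replicate)
#' key must be unique; gDNA rows get bud_stage NA.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readFrequencyTable <- function(path) {
  d <- read.delim(path, na.strings = ".", stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(.FREQ_COLS, "depth"), names(d))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (!"depth" %in% names(d)) d$depth <- NA_integer_
  validateFrequencyTable(d)
}

#' Validate a frequency-observation table
#' @param d data.frame in the frequency-table dialect.
#' @return the validated (and normalized) data.frame.
#' @export
validateFrequencyTable <- function(d) {
  bad <- which(!is.finite(d$fraction) | d$fraction < 0 | d$fraction > 1)
  if (length(bad)) stop("fraction outside [0, 1] at row(s): ",
                        paste(head(bad, 5), collapse = ", "))
  badT <- which(!d$template %in% c("gDNA", "cDNA"))
  if (length(badT)) stop("unknown template value at row(s): ",
                         paste(head(badT, 5), collapse = ", "))
  d$bud_stage[d$template == "gDNA"] <- NA_character_
  key <- paste(d$assay_id, d$template, d$individual, d$bud_stage, d$replicate)
  if (anyDuplicated(key))
    stop("duplicated (assay, template, individual, stage, replicate) key at row ",
         which(duplicated(key))[1])
  d[.FREQ_COLS]
}

#' Write a frequency table (TSV, '.' for missing)
#' @param d frequency-observation data.frame.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeFrequencyTable <- function(d, path) {
  write.table(d[.FREQ_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

#' Simulate a clone alignment with known allele truth
#'
#' Generates allele consensus sequences by planting random substitutions
#' on a random ancestral sequence, then emits sequencing clones per
#' allele with independent per-base error, optionally spiked with PCR
#' chimeras (two parents joined at a random breakpoint) and low-support
#' error singletons. The whole alignment is coding (gap-free, length a
#' multiple of 3, no stop codons planted), so it doubles as input for the
#' diagnostic-SNP finder and the codon analyses.
#'
#' @param locus locus name.
#' @param nAlleles number of alleles.
#' @param nCodons alignment length in codons.
#' @param diffsPerAllele substitutions distinguishing each allele from the
#'   ancestor (distinct columns per allele).
#' @param clonesPerAllele sequenced clones per allele.
#' @param errorRate per-base clone error probability.
#' @param nChimeras chimeric clones to append.
#' @param seed optional integer seed.
#' @return list: \code{alignment} ([CloneAlignment-class]), \code{truth}
#'   (list with \code{alleles} (named character), \code{assignment}
#'   (clone -> allele), \code{chimeras} (data.frame)).
#' @export
simulateCloneAlignment <- function(locus = "LOCUS", nAlleles = 4L,
                                   nCodons = 300L, diffsPerAllele = 8L,
                                   clonesPerAllele = 10L, errorRate = 0.001,
                                   nChimeras = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tb <- .codonTables()
  width <- 3L * nCodons
  ## ancestor from random non-stop codons
  anc <- strsplit(paste(sample(tb$sense, nCodons, replace = TRUE),
                        collapse = ""), "")[[1]]
  mutate <- function(seqchar, cols) {
    for (j in cols) {
      repeat {
        b <- sample(setdiff(.BASES, seqchar[j]), 1)
        cand <- seqchar
        cand[j] <- b
        cod <- ceiling(j / 3)
        codon <- paste(cand[(3 * cod - 2):(3 * cod)], collapse = "")
        if (codon %in% tb$sense) { seqchar <- cand; break }
      }
    }
    seqchar
  }
  alleles <- character(nAlleles)
  for (a in seq_len(nAlleles)) {
    cols <- sample.int(width, diffsPerAllele)
    alleles[a] <- paste(mutate(anc, cols), collapse = "")
  }
  names(alleles) <- sprintf("%s-%d", locus, seq_len(nAlleles))
  clones <- character(0); assignment <- character(0)
  for (a in seq_len(nAlleles)) for (cl in seq_len(clonesPerAllele)) {
    s <- strsplit(alleles[a], "")[[1]]
    err <- which(runif(width) < errorRate)
    if (length(err)) s <- mutate(s, err)
    clones <- c(clones, paste(s, collapse = ""))
    assignment <- c(assignment, names(alleles)[a])
  }
  names(clones) <- sprintf("clone%03d", seq_along(clones))
  chim <- data.frame(clone = character(), parent1 = character(),
                     parent2 = character(), breakpoint = integer())
  for (i in seq_len(nChimeras)) {
    ab <- sample.int(nAlleles, 2)
    bp <- sample(seq(width %/% 4, 3 * (width %/% 4)), 1)   # interior break
    s <- paste0(substr(alleles[ab[1]], 1, bp),
                substr(alleles[ab[2]], bp + 1, width))
    nm <- sprintf("chimera%02d", i)
    clones[nm] <- s
    assignment <- c(assignment, "chimera")
    chim <- rbind(chim, data.frame(clone = nm,
                                   parent1 = names(alleles)[ab[1]],
                                   parent2 = names(alleles)[ab[2]],
                                   breakpoint = bp))
  }
  aln <- cloneAlignment(clones, locus = locus,
                        individual = "sim",
                        codingMask = cbind(0L, width))
  list(alignment = aln,
       truth = list(alleles = alleles,
                    assignment = setNames(assignment, names(clones)),
                    chimeras = chim))
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Chains every stage with zero external files: simulate a clone
#' alignment with known alleles, collapse clones and screen chimeras,
#' discover diagnostic SNPs, simulate the pyrosequencing experiment for a
#' pentaploid genotype built from the called alleles, infer copy numbers,
#' produce the allele-specific expression report and the
#' molecular-evolution summaries, and write all stage outputs plus a
#' run manifest to \code{outDir}.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed governing every stochastic stage.
#' @param nAlleles,nCodons,diffsPerAllele,clonesPerAllele passed to
#'   [simulateCloneAlignment()].
#' @param ploidy genome copies.
#' @param noise an [assayNoise()] model.
#' @param rates optional per-copy transcription rates for the cDNA pools
#'   (default: equal transcription, the null).
#' @param locus locus name.
#' @return the manifest (list: seeds, stage row counts, file checksums,
#'   warnings), invisibly written as \code{manifest.txt}.
#' @export
runPipeline <- function(outDir, seed = 1L, nAlleles = 4L, nCodons = 300L,
                        diffsPerAllele = 8L, clonesPerAllele = 10L,
                        ploidy = 5L, noise = assayNoise(), rates = NULL,
                        locus = "LOCUS") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  wrap <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  files <- character(0)
  counts <- integer(0)
  emit <- function(stage, obj, writer, name) {
    p <- file.path(outDir, name)
    writer(obj, p)
    files[[stage]] <<- p
    counts[[stage]] <<- if (is.data.frame(obj)) nrow(obj) else length(obj)
  }
  ## stage 1: simulate clones
  set.seed(seed)
  sim <- simulateCloneAlignment(locus = locus, nAlleles = nAlleles,
                                nCodons = nCodons,
                                diffsPerAllele = diffsPerAllele,
                                clonesPerAllele = clonesPerAllele)
  emit("clones", sim$alignment, writeFastaAlignment, "clones.fasta")
  ## stage 2: allele calling
  alleles <- wrap(collapseClones(sim$alignment))
  emit("alleles", alleles, writeFastaAlignment, "alleles.fasta")
  chim <- detectChimeras(sim$alignment, alleles)
  emit("chimeras", chim, function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "chimeras.tsv")
  assays <- findDiagnosticSnps(alleles)
  if (nrow(assays) == 0L) stop("stage callalleles: no diagnostic SNP found")
  skipped <- setdiff(names(alleles@consensus),
                     unique(unlist(lapply(assays$carriers, .parseCarriers))))
  if (length(skipped)) {
    warnings <- c(warnings, paste0("no suitable SNP for allele(s): ",
                                   paste(skipped, collapse = ", ")))
  }
  emit("assays", assays, function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "assays.tsv")
  ## stage 3: simulate the pyrosequencing experiment
  alleleNames <- names(alleles@consensus)
  genotype <- makeFounder(alleleNames[1],
                          rep_len(alleleNames[-1], ploidy - 2L),
                          locus, meiosisParam(ploidy = ploidy))
  emit("genotypes", genotypeTable(genotype), function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "genotypes.tsv")
  obs <- simulateExperiment(genotype, assays, noise = noise, rates = rates,
                            ploidy = ploidy, locus = locus, seed = seed + 1L)
  emit("observations", obs, writeFrequencyTable, "frequencies.tsv")
  ## stage 4: copy number
  calls <- wrap(inferCopyNumbers(obs, assays, alleleNames, ploidy = ploidy,
                                 rho = noise$rho))
  emit("copy_numbers", copyNumberTable(calls), function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "copy_numbers.tsv")
  ## stage 5: allele-specific expression
  ase <- wrap(aseReport(calls, obs, assays, ploidy = ploidy,
                        seed = seed + 2L))
  emit("ase", ase, function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "ase.tsv")
  ## stage 6: molecular evolution
  caln <- codonAlignment(alleles@consensus, locus = locus)
  counts_sub <- countSubstitutions(caln)
  pairsDf <- do.call(rbind, lapply(asplit(combn(alleleNames, 2), 2),
    function(pr) {
      r <- ng86(alleles@consensus[[pr[1]]], alleles@consensus[[pr[2]]])
      data.frame(allele1 = pr[1], allele2 = pr[2], dN = r$dN, dS = r$dS,
                 omega = r$omega)
    }))
  dnds <- data.frame(locus = locus,
                     nSynonymous = counts_sub$nSynonymous,
                     nNonsynonymous = counts_sub$nNonsynonymous,
                     nIndelEvents = counts_sub$nIndelEvents)
  emit("dnds", cbind(dnds[rep(1, nrow(pairsDf)), ], pairsDf), function(o, p)
    write.table(o, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "."),
    "dnds.tsv")
  manifest <- list(
    tool = paste0("caninaASE ", as.character(packageVersion("caninaASE"))),
    seed = seed,
    stages = names(files),
    files = unlist(files),
    checksums = tools::md5sum(unlist(files)),
    rowCounts = counts,
    warnings = warnings
  )
  mpath <- file.path(outDir, "manifest.txt")
  writeLines(c(
    paste0("tool\t", manifest$tool),
    paste0("seed\t", seed),
    sprintf("stage\t%s\t%s\t%s\t%s", manifest$stages,
            basename(unlist(files)), counts, manifest$checksums),
    if (length(warnings)) paste0("warning\t", warnings) else character(0)
  ), mpath)
  manifest$manifest <- mpath
  invisible(manifest)
}
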