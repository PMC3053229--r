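# Shared fixtures: a LEAFY-like assay panel (three singleton-carrier SNPs
# over a (2,1,1)+1-unassayed pentaploid composition) and small builders.

leafyAssays <- function() {
  data.frame(
    assay_id = c("LEAFY_SNP1", "LEAFY_SNP3", "LEAFY_SNP4"),
    locus = "LEAFY",
    position = c(12L, 45L, 90L),
    diagnostic_base = c("A", "G", "T"),
    carriers = c("LEAFY-1", "LEAFY-3", "LEAFY-4"),
    stringsAsFactors = FALSE
  )
}

leafyCopyNumbers <- function() {
  c("LEAFY-1" = 1L, "LEAFY-2" = 1L, "LEAFY-3" = 2L, "LEAFY-4" = 1L)
}

leafyFounder <- function() {
  makeFounder("LEAFY-3", c("LEAFY-1", "LEAFY-2", "LEAFY-4"), "LEAFY")
}

# observation table with exact fractions, no noise, for identifiability tests
exactObservations <- function(assays, fractions, individuals = "H13",
                              nReplicates = 2L) {
  do.call(rbind, lapply(individuals, function(ind)
    do.call(rbind, lapply(seq_len(nrow(assays)), function(i)
      data.frame(assay_id = assays$assay_id[i], locus = assays$locus[i],
                 template = "gDNA", individual = ind,
                 bud_stage = NA_character_, replicate = seq_len(nReplicates),
                 fraction = fractions[i], depth = NA_integer_)))))
}
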