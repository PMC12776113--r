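# Builders for tiny hand-constructed events and evidence used by the
# cascade stage tests. Defaults are non-discriminating for every stage.

full12 <- paste(rep("1", 12), collapse = ",")
partial12 <- function(n_present) {
  paste(c(rep("1", n_present), rep("0", 12 - n_present)), collapse = ",")
}

mk_evidence <- function(gene_id, species = "mel", flag = "none",
                        presence = full12, introns = 2L, orthologs = 20L,
                        orthogroup = 5L) {
  data.frame(gene_id = gene_id, species = species, literature_flag = flag,
             presence12 = presence, intron_count = as.integer(introns),
             ortholog_species_count = as.integer(orthologs),
             orthogroup_size = as.integer(orthogroup),
             stringsAsFactors = FALSE)
}

mk_event <- function(event_id = "ev1", lineage = "pse",
                     class = "redundant", s = "S1", l = "L1", d = "D1") {
  data.frame(event_id = event_id, deletion_lineage = lineage,
             functional_class = class, s_gene = s, l_gene = l, d_gene = d,
             stringsAsFactors = FALSE)
}

# One-event cohort: evidence for S/L in the ancestral species, D in the
# deletion lineage, with per-gene overrides passed as lists of
# mk_evidence arguments.
mk_trio <- function(s_args = list(), l_args = list(), d_args = list(),
                    lineage = "pse", class = "redundant") {
  anc <- if (lineage == "mel") "pse" else "mel"
  ev <- rbind(
    do.call(mk_evidence, c(list(gene_id = "S1", species = anc), s_args)),
    do.call(mk_evidence, c(list(gene_id = "L1", species = anc), l_args)),
    do.call(mk_evidence, c(list(gene_id = "D1", species = lineage), d_args)))
  list(event = mk_event(lineage = lineage, class = class), evidence = ev)
}
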