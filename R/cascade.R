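# Six-stage sequential evidence cascade assigning parent (ancestral) and
# child (derived) labels to the S and L copies of each deletion event. Each
# stage either resolves the event or passes it on; the first resolving stage
# is authoritative and recorded, and later stages only ever see events the
# earlier stages could not resolve.

CASCADE_STAGES <- c("literature", "conservation12", "retrotransposition",
                    "orthodb37", "orthogroup", "derived_copy")

# Parse evidence into a fast lookup: one list entry per gene with the fields
# the stage rules consume. Accepts an already-built index unchanged.
evidence_index <- function(evidence) {
  if (inherits(evidence, "dupdel_evidence_index")) return(evidence)
  pres <- parse_presence12(evidence$presence12)
  idx <- lapply(seq_len(nrow(evidence)), function(i) {
    list(literature_flag = evidence$literature_flag[i],
         all12 = all(pres[i, ]),
         has_presence = !anyNA(pres[i, ]),
         intron_count = evidence$intron_count[i],
         ortholog_species_count = evidence$ortholog_species_count[i],
         orthogroup_size = evidence$orthogroup_size[i])
  })
  names(idx) <- evidence$gene_id
  class(idx) <- "dupdel_evidence_index"
  idx
}

stage_pass <- function(conflict = NULL) {
  list(resolved = FALSE, parent_gene = NA_character_,
       child_gene = NA_character_, conflict = conflict)
}

stage_resolve <- function(parent, child) {
  list(resolved = TRUE, parent_gene = parent, child_gene = child,
       conflict = NULL)
}

gene_ev <- function(idx, gene) {
  ev <- idx[[gene]]
  if (is.null(ev)) stop("no evidence for gene '", gene, "'", call. = FALSE)
  ev
}

#' Cascade stage: literature evidence
#'
#' Resolves an event when curated literature flags identify the parent
#' and/or child copy unambiguously: either exactly one copy is flagged
#' (`parent` or `child`, the other `none`) or the two flags are
#' complementary. Conflicting flags (both `parent`, or both `child`) pass
#' the event on with a logged conflict instead of failing.
#'
#' @param event One event (a one-row data frame or list with `s_gene`,
#'   `l_gene`, `d_gene`).
#' @param evidence Evidence table (see [read_evidence()]) or a prebuilt
#'   index.
#' @return A stage verdict: list with `resolved`, `parent_gene`,
#'   `child_gene`, `conflict`.
#' @export
stage_literature <- function(event, evidence) {
  idx <- evidence_index(evidence)
  fs <- gene_ev(idx, event$s_gene)$literature_flag
  fl <- gene_ev(idx, event$l_gene)$literature_flag
  if (fs == "none" && fl == "none") return(stage_pass())
  if (fs != "none" && fl != "none" && fs == fl) {
    return(stage_pass(conflict = sprintf(
      "event %s: both copies carry literature flag '%s'", event$event_id, fs)))
  }
  # at this point flags are informative: one flagged, or complementary
  parent_is_s <- (fs == "parent") || (fl == "child")
  if (parent_is_s) stage_resolve(event$s_gene, event$l_gene)
  else stage_resolve(event$l_gene, event$s_gene)
}

#' Cascade stage: conservation across 12 reference species
#'
#' The copy conserved (present) in all 12 reference species is designated
#' the parent, on the expectation that the ancestral copy is the conserved
#' one. Resolves only when exactly one of the two copies is fully conserved;
#' passes when both or neither are, or when a presence profile is missing.
#'
#' @inheritParams stage_literature
#' @return A stage verdict.
#' @export
stage_conservation12 <- function(event, evidence) {
  idx <- evidence_index(evidence)
  es <- gene_ev(idx, event$s_gene)
  el <- gene_ev(idx, event$l_gene)
  if (!es$has_presence || !el$has_presence) return(stage_pass())
  if (es$all12 == el$all12) return(stage_pass())
  if (es$all12) stage_resolve(event$s_gene, event$l_gene)
  else stage_resolve(event$l_gene, event$s_gene)
}

#' Cascade stage: retrotransposition signature
#'
#' Retrotransposed duplicates arise by reverse transcription of mRNA and are
#' typically intronless, unlike their multi-exon source gene. When exactly
#' one copy has zero introns and its paralog has at least one, the
#' intronless copy is designated the child. Passes when both or neither are
#' intronless, or when an intron count is missing.
#'
#' @inheritParams stage_literature
#' @return A stage verdict.
#' @export
stage_retrotransposition <- function(event, evidence) {
  idx <- evidence_index(evidence)
  is_ <- gene_ev(idx, event$s_gene)$intron_count
  il <- gene_ev(idx, event$l_gene)$intron_count
  if (is.na(is_) || is.na(il)) return(stage_pass())
  if ((is_ == 0L) == (il == 0L)) return(stage_pass())
  if (il == 0L) stage_resolve(event$s_gene, event$l_gene)
  else stage_resolve(event$l_gene, event$s_gene)
}

#' Cascade stage: ortholog counts across 37 species
#'
#' The copy with orthologs detected in strictly more of the 37 surveyed
#' species is designated the parent, consistent with greater evolutionary
#' age. Ties and missing counts pass.
#'
#' @inheritParams stage_literature
#' @return A stage verdict.
#' @export
stage_orthodb37 <- function(event, evidence) {
  idx <- evidence_index(evidence)
  cs <- gene_ev(idx, event$s_gene)$ortholog_species_count
  cl <- gene_ev(idx, event$l_gene)$ortholog_species_count
  if (is.na(cs) || is.na(cl) || cs == cl) return(stage_pass())
  if (cs > cl) stage_resolve(event$s_gene, event$l_gene)
  else stage_resolve(event$l_gene, event$s_gene)
}

#' Cascade stage: orthogroup size
#'
#' The copy belonging to the strictly larger orthogroup is designated the
#' parent. Ties and missing sizes pass.
#'
#' @inheritParams stage_literature
#' @return A stage verdict.
#' @export
stage_orthogroup <- function(event, evidence) {
  idx <- evidence_index(evidence)
  gs <- gene_ev(idx, event$s_gene)$orthogroup_size
  gl <- gene_ev(idx, event$l_gene)$orthogroup_size
  if (is.na(gs) || is.na(gl) || gs == gl) return(stage_pass())
  if (gs > gl) stage_resolve(event$s_gene, event$l_gene)
  else stage_resolve(event$l_gene, event$s_gene)
}

#' Cascade stage: derived-copy conservation
#'
#' For events still unresolved, the conservation criteria are re-applied
#' between the derived copy D (the single copy in the deletion lineage,
#' orthologous to S) and the lost copy L, in the order: full 12-species
#' conservation, then 37-species ortholog counts, then orthogroup size. If D
#' wins a comparison the conserved lineage is S's, so S is parent and L is
#' child; if L wins, L is parent and S is child. All three comparisons tied
#' (or D evidence missing) passes.
#'
#' @inheritParams stage_literature
#' @return A stage verdict.
#' @export
stage_derived_copy <- function(event, evidence) {
  idx <- evidence_index(evidence)
  if (is.null(idx[[event$d_gene]])) return(stage_pass())
  ed <- gene_ev(idx, event$d_gene)
  el <- gene_ev(idx, event$l_gene)

  decide <- function(d_wins) {
    if (d_wins) stage_resolve(event$s_gene, event$l_gene)
    else stage_resolve(event$l_gene, event$s_gene)
  }
  if (ed$has_presence && el$has_presence && ed$all12 != el$all12)
    return(decide(ed$all12))
  cd <- ed$ortholog_species_count
  cl <- el$ortholog_species_count
  if (!is.na(cd) && !is.na(cl) && cd != cl) return(decide(cd > cl))
  gd <- ed$orthogroup_size
  gl <- el$orthogroup_size
  if (!is.na(gd) && !is.na(gl) && gd != gl) return(decide(gd > gl))
  stage_pass()
}

stage_fun <- function(stage) {
  switch(stage,
         literature = stage_literature,
         conservation12 = stage_conservation12,
         retrotransposition = stage_retrotransposition,
         orthodb37 = stage_orthodb37,
         orthogroup = stage_orthogroup,
         derived_copy = stage_derived_copy,
         stop("unknown stage '", stage, "'", call. = FALSE))
}

#' Run the six-stage parent-child assignment cascade
#'
#' Applies the stages in fixed order (literature, 12-species conservation,
#' retrotransposition, 37-species ortholog counts, orthogroup size,
#' derived-copy conservation) to every event. Each event is labeled by the
#' first stage that resolves it and is never revisited; later stages see
#' only previously unresolved events. The deleted role follows from the
#' labels: the L copy is the one that was deleted in the derived lineage, so
#' `deleted_role` is `parent` when L is the parent and `child` when L is the
#' child.
#'
#' @param events Event table (see [read_events()]).
#' @param evidence Evidence table covering every S, L and D gene.
#' @param stage_order Stage names; default is the canonical order. Intended
#'   for sensitivity analysis only.
#'
#' @return List with:
#'   * `assignments`: data frame with `event_id`, `parent_gene`,
#'     `child_gene`, `stage`, `deleted_role`;
#'   * `stage_tally`: named integer vector over stages plus `unresolved`;
#'   * `conflicts`: character vector of logged within-stage conflicts.
#' @export
run_cascade <- function(events, evidence, stage_order = CASCADE_STAGES) {
  stopifnot(all(stage_order %in% CASCADE_STAGES),
            !anyDuplicated(stage_order))
  validate_events(events, evidence)
  idx <- evidence_index(evidence)

  n <- nrow(events)
  assignments <- data.frame(
    event_id = events$event_id,
    parent_gene = rep(NA_character_, n),
    child_gene = rep(NA_character_, n),
    stage = rep("unresolved", n),
    deleted_role = rep("unresolved", n),
    stringsAsFactors = FALSE)
  conflicts <- character(0)

  for (i in seq_len(n)) {
    event <- events[i, ]
    for (stage in stage_order) {
      verdict <- stage_fun(stage)(event, idx)
      if (!is.null(verdict$conflict))
        conflicts <- c(conflicts, paste0(stage, ": ", verdict$conflict))
      if (verdict$resolved) {
        assignments$parent_gene[i] <- verdict$parent_gene
        assignments$child_gene[i] <- verdict$child_gene
        assignments$stage[i] <- stage
        assignments$deleted_role[i] <-
          if (identical(verdict$parent_gene, event$l_gene)) "parent" else "child"
        break
      }
    }
  }

  tally <- table(factor(assignments$stage,
                        levels = c(CASCADE_STAGES, "unresolved")))
  list(assignments = assignments,
       stage_tally = stats::setNames(as.integer(tally), names(tally)),
       conflicts = conflicts)
}

#' Tally deleted-role bias by functional class
#'
#' Counts, within each functional class (redundant, unique), how many
#' resolved events lost the parent copy versus the child copy, and how many
#' remain unresolved. Counts partition each class:
#' `deleted_parent + deleted_child + unresolved = n_total`.
#'
#' @param assignments Assignment table from [run_cascade()].
#' @param events Matching event table.
#' @return Data frame with one row per functional class and columns
#'   `functional_class`, `n_total`, `n_resolved`, `deleted_parent`,
#'   `deleted_child`, `unresolved`.
#' @export
tally_bias <- function(assignments, events) {
  if (!all(assignments$event_id %in% events$event_id))
    stop("assignment references unknown event_id: ",
         paste(setdiff(assignments$event_id, events$event_id), collapse = ", "),
         call. = FALSE)
  if (!setequal(assignments$event_id, events$event_id))
    stop("assignments do not cover all events", call. = FALSE)
  m <- merge(assignments, events[, c("event_id", "functional_class")],
             by = "event_id")
  classes <- sort(unique(m$functional_class))
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- m[m$functional_class == cl, ]
    data.frame(functional_class = cl,
               n_total = nrow(sub),
               n_resolved = sum(sub$deleted_role != "unresolved"),
               deleted_parent = sum(sub$deleted_role == "parent"),
               deleted_child = sum(sub$deleted_role == "child"),
               unresolved = sum(sub$deleted_role == "unresolved"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
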