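test_that("literature stage resolves flagged copies and logs conflicts", {
  tr <- mk_trio(s_args = list(flag = "parent"))
  v <- stage_literature(tr$event, tr$evidence)
  expect_true(v$resolved)
  expect_identical(v$parent_gene, "S1")
  expect_identical(v$child_gene, "L1")

  tr <- mk_trio(l_args = list(flag = "child"))
  v <- stage_literature(tr$event, tr$evidence)
  expect_identical(v$parent_gene, "S1")

  tr <- mk_trio(s_args = list(flag = "child"), l_args = list(flag = "parent"))
  v <- stage_literature(tr$event, tr$evidence)
  expect_identical(v$parent_gene, "L1")

  tr <- mk_trio()
  expect_false(stage_literature(tr$event, tr$evidence)$resolved)

  tr <- mk_trio(s_args = list(flag = "parent"), l_args = list(flag = "parent"))
  v <- stage_literature(tr$event, tr$evidence)
  expect_false(v$resolved)
  expect_match(v$conflict, "both copies")
})

test_that("conservation stage requires exactly one fully conserved copy", {
  tr <- mk_trio(l_args = list(presence = partial12(9)))
  v <- stage_conservation12(tr$event, tr$evidence)
  expect_identical(v$parent_gene, "S1")

  tr <- mk_trio()   # both 12/12
  expect_false(stage_conservation12(tr$event, tr$evidence)$resolved)

  tr <- mk_trio(s_args = list(presence = partial12(11)),
                l_args = list(presence = partial12(10)))
  expect_false(stage_conservation12(tr$event, tr$evidence)$resolved)

  tr <- mk_trio(s_args = list(presence = NA_character_))
  expect_false(stage_conservation12(tr$event, tr$evidence)$resolved)
})

test_that("retrotransposition stage designates the intronless copy as child", {
  tr <- mk_trio(s_args = list(introns = 3), l_args = list(introns = 0))
  v <- stage_retrotransposition(tr$event, tr$evidence)
  expect_identical(v$child_gene, "L1")

  tr <- mk_trio(s_args = list(introns = 0), l_args = list(introns = 2))
  v <- stage_retrotransposition(tr$event, tr$evidence)
  expect_identical(v$child_gene, "S1")

  tr <- mk_trio(s_args = list(introns = 0), l_args = list(introns = 0))
  expect_false(stage_retrotransposition(tr$event, tr$evidence)$resolved)

  tr <- mk_trio()   # both >= 1
  expect_false(stage_retrotransposition(tr$event, tr$evidence)$resolved)

  tr <- mk_trio(l_args = list(introns = NA))
  expect_false(stage_retrotransposition(tr$event, tr$evidence)$resolved)
})

test_that("ortholog-count and orthogroup stages use strict comparisons", {
  tr <- mk_trio(s_args = list(orthologs = 37), l_args = list(orthologs = 12))
  expect_identical(stage_orthodb37(tr$event, tr$evidence)$parent_gene, "S1")

  tr <- mk_trio(s_args = list(orthologs = 4), l_args = list(orthologs = 5))
  expect_identical(stage_orthodb37(tr$event, tr$evidence)$parent_gene, "L1")

  tr <- mk_trio()   # tied at 20
  expect_false(stage_orthodb37(tr$event, tr$evidence)$resolved)

  tr <- mk_trio(s_args = list(orthogroup = 48), l_args = list(orthogroup = 3))
  expect_identical(stage_orthogroup(tr$event, tr$evidence)$parent_gene, "S1")

  tr <- mk_trio(s_args = list(orthogroup = 1), l_args = list(orthogroup = 2))
  expect_identical(stage_orthogroup(tr$event, tr$evidence)$parent_gene, "L1")

  tr <- mk_trio()   # tied orthogroup sizes
  expect_false(stage_orthogroup(tr$event, tr$evidence)$resolved)
})

test_that("derived-copy stage compares D against L with criterion fallthrough", {
  tr <- mk_trio(l_args = list(presence = partial12(7)))
  v <- stage_derived_copy(tr$event, tr$evidence)
  expect_identical(v$parent_gene, "S1")
  expect_identical(v$child_gene, "L1")

  tr <- mk_trio(d_args = list(orthologs = 30), l_args = list(orthologs = 10))
  expect_identical(stage_derived_copy(tr$event, tr$evidence)$parent_gene, "S1")

  tr <- mk_trio(d_args = list(orthologs = 10), l_args = list(orthologs = 30))
  expect_identical(stage_derived_copy(tr$event, tr$evidence)$parent_gene, "L1")

  tr <- mk_trio(d_args = list(orthogroup = 9), l_args = list(orthogroup = 2))
  expect_identical(stage_derived_copy(tr$event, tr$evidence)$parent_gene, "S1")

  tr <- mk_trio()   # all three comparisons tied
  expect_false(stage_derived_copy(tr$event, tr$evidence)$resolved)
})

test_that("cascade on an empty event list yields empty assignments", {
  fx <- generate_reference_fixture()
  res <- run_cascade(fx$events[0, ], fx$evidence)
  expect_equal(nrow(res$assignments), 0)
  expect_true(all(res$stage_tally == 0))
})

test_that("each event is resolved at most once and tallies conserve counts", {
  for (seed in c(5, 17)) {
    co <- generate_cohort(cohort_config(seed = seed))
    res <- run_cascade(co$events, co$evidence)
    expect_equal(sum(res$stage_tally), nrow(co$events))
    expect_equal(nrow(res$assignments), nrow(co$events))
    resolved <- res$assignments$stage != "unresolved"
    expect_true(all(res$assignments$deleted_role[resolved] %in%
                      c("parent", "child")))
    expect_true(all(res$assignments$deleted_role[!resolved] == "unresolved"))
  }
})

test_that("cascade recovers the generator's planted truth exactly", {
  for (seed in c(3, 99)) {
    co <- generate_cohort(cohort_config(seed = seed))
    res <- run_cascade(co$events, co$evidence)
    m <- merge(res$assignments, co$truth$events, by = "event_id",
               suffixes = c("", ".truth"))
    expect_identical(m$stage, m$stage.truth)
    resolved <- m$stage != "unresolved"
    expect_identical(m$parent_gene[resolved], m$true_parent[resolved])
    expect_identical(m$child_gene[resolved], m$true_child[resolved])
    # the truth table keeps the hidden role even for events the generator
    # left unresolvable; the cascade must match it wherever it resolves
    expect_identical(m$deleted_role[resolved], m$deleted_role.truth[resolved])
    expect_true(all(m$deleted_role[!resolved] == "unresolved"))
  }
})

test_that("assignments are invariant to stage order on single-signal cohorts", {
  co <- generate_cohort(cohort_config(seed = 8))
  base <- run_cascade(co$events, co$evidence)$assignments
  set.seed(80)
  for (i in 1:5) {
    perm <- sample(c("literature", "conservation12", "retrotransposition",
                     "orthodb37", "orthogroup", "derived_copy"))
    alt <- run_cascade(co$events, co$evidence, stage_order = perm)$assignments
    expect_identical(alt$parent_gene, base$parent_gene)
    expect_identical(alt$child_gene, base$child_gene)
    expect_identical(alt$deleted_role, base$deleted_role)
  }
})

test_that("cascade output is deterministic for identical inputs", {
  co <- generate_cohort(cohort_config(seed = 14))
  expect_identical(run_cascade(co$events, co$evidence),
                   run_cascade(co$events, co$evidence))
})

test_that("bias tally matches a brute-force recount and partitions classes", {
  co <- generate_cohort(cohort_config(seed = 55))
  res <- run_cascade(co$events, co$evidence)
  tally <- tally_bias(res$assignments, co$events)
  truth <- merge(co$truth$events, co$events[, c("event_id", "functional_class")],
                 by = "event_id")
  for (cl in c("redundant", "unique")) {
    sub <- truth[truth$functional_class == cl, ]
    row <- tally[tally$functional_class == cl, ]
    expect_equal(row$deleted_parent,
                 sum(sub$deleted_role == "parent" & sub$stage != "unresolved"))
    expect_equal(row$deleted_child,
                 sum(sub$deleted_role == "child" & sub$stage != "unresolved"))
    expect_equal(row$n_total, row$deleted_parent + row$deleted_child +
                   row$unresolved)
  }
})

test_that("bias tally on unresolvable input returns all-unresolved counts", {
  cfg <- cohort_config(seed = 2, stage_resolution_probs = c(
    literature = 0, conservation12 = 0, retrotransposition = 0,
    orthodb37 = 0, orthogroup = 0, derived_copy = 0, unresolved = 1))
  co <- generate_cohort(cfg)
  res <- run_cascade(co$events, co$evidence)
  tally <- tally_bias(res$assignments, co$events)
  expect_true(all(tally$deleted_parent == 0 & tally$deleted_child == 0))
  expect_equal(tally$unresolved, tally$n_total)
})

test_that("bias tally rejects assignments referencing unknown events", {
  co <- generate_cohort(cohort_config(seed = 4))
  res <- run_cascade(co$events, co$evidence)
  bad <- res$assignments
  bad$event_id[1] <- "bogus"
  expect_error(tally_bias(bad, co$events), "bogus")
})
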