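# End-to-end orchestration: cascade + deletion-bias binomial tests, and the
# grouped feature comparisons, with figure-ready tables and a plain-text
# run report.

#' Analysis run configuration
#'
#' @param deleted_role_gene Which copy's features represent a deleted event
#'   in the group comparisons: `"L"` (default; the copy that was actually
#'   deleted in the derived lineage, observable in the ancestral-state
#'   species), `"S"` or `"D"`. Exposed because the choice is a genuine
#'   modeling decision, not a data fact.
#' @param tissue_aggregate How the six per-tissue expression values collapse
#'   to one per gene: `"mean"` (default) or `"max"` of the six
#'   `log10(FPKM + 1)` values.
#' @param mw_mode Mann-Whitney mode passed to [mann_whitney()].
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust the comparison
#'   p-values within the comparison table (off by default; raw p-values
#'   match the conventional star thresholds).
#' @return A config list of class `dupdel_run_config`.
#' @export
run_config <- function(deleted_role_gene = c("L", "S", "D"),
                       tissue_aggregate = c("mean", "max"),
                       mw_mode = c("auto", "exact", "approx"),
                       adjust = FALSE) {
  cfg <- list(deleted_role_gene = match.arg(deleted_role_gene),
              tissue_aggregate = match.arg(tissue_aggregate),
              mw_mode = match.arg(mw_mode),
              adjust = isTRUE(adjust))
  class(cfg) <- "dupdel_run_config"
  cfg
}

#' Run the cascade and the deletion-bias binomial tests
#'
#' Runs the six-stage cascade, tallies deleted roles by functional class,
#' then computes the three exact binomial tests: (1) resolution-rate
#' comparison — successes = resolved redundant events, trials = all
#' redundant events, null probability = the fraction of unique events
#' resolved; (2) redundant-class bias — successes = deleted children among
#' resolved redundant events, trials = resolved redundant events, null 0.5;
#' (3) unique-class bias, analogous. A test whose class has zero resolved
#' events is skipped with a logged reason rather than failing.
#'
#' @param events,evidence Validated tables (see [read_tables()]).
#' @return List with `assignments`, `stage_tally`, `conflicts`, `tally`
#'   (from [tally_bias()]), `tests` (data frame: test, x, n, p0, p_value,
#'   star) and `skipped` (character log).
#' @export
run_bias_analysis <- function(events, evidence) {
  res <- run_cascade(events, evidence)
  tally <- tally_bias(res$assignments, events)
  red <- tally[tally$functional_class == "redundant", ]
  unq <- tally[tally$functional_class == "unique", ]
  skipped <- character(0)
  tests <- list()

  add_test <- function(name, x, n, p0) {
    p <- binom_test_exact(x, n, p0)
    data.frame(test = name, x = x, n = n, p0 = p0, p_value = p,
               star = star_label(p), stringsAsFactors = FALSE)
  }

  if (nrow(red) == 1 && nrow(unq) == 1 && unq$n_total > 0) {
    tests$resolution <- add_test("resolution_redundant_vs_unique",
                                 red$n_resolved, red$n_total,
                                 unq$n_resolved / unq$n_total)
  } else {
    skipped <- c(skipped, "resolution test skipped: missing class")
  }
  for (cl in c("redundant", "unique")) {
    row <- tally[tally$functional_class == cl, ]
    if (nrow(row) == 1 && row$n_resolved > 0) {
      tests[[cl]] <- add_test(paste0("deletion_bias_", cl),
                              row$deleted_child, row$n_resolved, 0.5)
    } else {
      skipped <- c(skipped,
                   paste0("deletion-bias test skipped for class '", cl,
                          "': zero resolved events"))
    }
  }

  list(assignments = res$assignments,
       stage_tally = res$stage_tally,
       conflicts = res$conflicts,
       tally = tally,
       tests = do.call(rbind, c(tests, list(make.row.names = FALSE))),
       skipped = skipped)
}

# Per-gene comparison value for one feature, with its transform label.
feature_values <- function(features, feature, config) {
  if (feature == "expression") {
    mat <- log10(as.matrix(features[, FPKM_COLUMNS]) + 1)
    agg <- if (config$tissue_aggregate == "mean") rowMeans(mat)
           else apply(mat, 1, max)
    list(values = agg, transform = "log10_plus1")
  } else {
    transform <- switch(feature,
                        ka_ks = "log10_ratio",
                        ppi_count = "log10_plus1",
                        tm_score = "log10_raw",
                        plddt = "log10_raw",
                        stop("unknown feature '", feature, "'", call. = FALSE))
    tr <- apply_transform(features[[feature]], transform)
    vals <- rep(NA_real_, nrow(features))
    keep <- if (transform == "log10_plus1") !is.na(features[[feature]])
            else !is.na(features[[feature]]) & features[[feature]] > 0
    vals[keep] <- tr$values
    list(values = vals, transform = transform)
  }
}

COMPARISON_FEATURES <- c("ka_ks", "expression", "ppi_count", "tm_score",
                         "plddt")
GROUP_PAIRS <- list(c("single_copy", "deleted_redundant"),
                    c("single_copy", "deleted_unique"),
                    c("deleted_redundant", "deleted_unique"))

#' Pairwise group comparisons of the five features
#'
#' For each feature (Ka/Ks, expression, interaction degree, TM-score,
#' pLDDT), applies its log10 transform (expression is first collapsed
#' across the six tissues, see [run_config()]) and runs two-sided
#' Mann-Whitney U tests for all three group pairs among single-copy,
#' deleted-redundant and deleted-unique genes. Values excluded by a
#' transform (missing, or nonpositive for ratio/raw log transforms) are
#' dropped per feature, never per gene. A pair with an empty group for a
#' feature is skipped with a log entry.
#'
#' @param features Validated feature table (with `ppi_count`).
#' @param config A [run_config()].
#' @return List with `comparisons` (one row per feature x pair:
#'   `feature`, `transform`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `median_a`, `median_b`, `u_statistic`, `p_value`, `star`), `long`
#'   (boxplot-ready long table: `feature`, `group`, `gene_id`, `value`) and
#'   `skipped` (character log).
#' @export
run_feature_comparisons <- function(features, config = run_config()) {
  validate_features(features)
  rows <- list()
  long <- list()
  skipped <- character(0)

  for (feature in COMPARISON_FEATURES) {
    fv <- feature_values(features, feature, config)
    by_group <- split(fv$values, features$group)
    for (g in names(by_group)) {
      v <- by_group[[g]]
      keep <- !is.na(v)
      long[[paste(feature, g)]] <- data.frame(
        feature = feature, group = g,
        gene_id = split(features$gene_id, features$group)[[g]][keep],
        value = v[keep], stringsAsFactors = FALSE)
    }
    for (pair in GROUP_PAIRS) {
      a <- by_group[[pair[1]]]; a <- a[!is.na(a)]
      b <- by_group[[pair[2]]]; b <- b[!is.na(b)]
      if (!length(a) || !length(b)) {
        skipped <- c(skipped, sprintf(
          "comparison skipped for %s (%s vs %s): empty group",
          feature, pair[1], pair[2]))
        next
      }
      mw <- mann_whitney(a, b, mode = config$mw_mode)
      rows[[paste(feature, pair[1], pair[2])]] <- data.frame(
        feature = feature, transform = fv$transform,
        group_a = pair[1], group_b = pair[2],
        n_a = mw$n_a, n_b = mw$n_b,
        median_a = stats::median(a), median_b = stats::median(b),
        u_statistic = mw$u_statistic, p_value = mw$p_value,
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(comparisons)) {
    if (config$adjust)
      comparisons$p_value <- stats::p.adjust(comparisons$p_value, "BH")
    comparisons$star <- star_label(comparisons$p_value)
  }
  list(comparisons = comparisons,
       long = do.call(rbind, c(long, list(make.row.names = FALSE))),
       skipped = skipped)
}

#' Write analysis outputs to a directory
#'
#' Writes machine-readable TSVs (`assignments.tsv`, `bias_tally.tsv`,
#' `bias_tests.tsv`, `comparisons.tsv`, `comparison_long.tsv`) and a
#' human-readable `report.txt` echoing the configuration, package version,
#' per-stage tallies and every test result. Output is deterministic given
#' the inputs.
#'
#' @param bias Result of [run_bias_analysis()].
#' @param comparisons Result of [run_feature_comparisons()], or `NULL`.
#' @param config A [run_config()] echoed into the report.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(bias, comparisons = NULL, config = run_config(),
                         dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir,
                             call. = FALSE)
  write_tsv_file(bias$assignments, file.path(dir, "assignments.tsv"))
  write_tsv_file(bias$tally, file.path(dir, "bias_tally.tsv"))
  if (!is.null(bias$tests))
    write_tsv_file(bias$tests, file.path(dir, "bias_tests.tsv"))
  if (!is.null(comparisons$comparisons)) {
    write_tsv_file(comparisons$comparisons, file.path(dir, "comparisons.tsv"))
    write_tsv_file(comparisons$long, file.path(dir, "comparison_long.tsv"))
  }

  fmt_tally <- paste(sprintf("%s=%d", names(bias$stage_tally),
                             bias$stage_tally), collapse = " ")
  lines <- c(
    "dupdel run report",
    sprintf("package version: %s",
            as.character(utils::packageVersion("dupdel"))),
    sprintf("config: deleted_role_gene=%s tissue_aggregate=%s mw_mode=%s adjust=%s",
            config$deleted_role_gene, config$tissue_aggregate,
            config$mw_mode, config$adjust),
    "",
    sprintf("stage tally: %s", fmt_tally),
    sprintf("events total: %d", sum(bias$stage_tally)),
    "",
    "deleted-role tally by class:",
    utils::capture.output(print(bias$tally, row.names = FALSE)),
    "",
    "binomial tests:",
    if (!is.null(bias$tests))
      utils::capture.output(print(bias$tests, row.names = FALSE, digits = 4))
    else "  (none)",
    if (length(bias$skipped)) paste("  skipped:", bias$skipped) else character(0),
    if (length(bias$conflicts)) c("", "conflicts:", paste(" ", bias$conflicts))
      else character(0))
  if (!is.null(comparisons$comparisons)) {
    lines <- c(lines, "", "feature comparisons:",
               utils::capture.output(print(comparisons$comparisons,
                                           row.names = FALSE, digits = 4)),
               if (length(comparisons$skipped))
                 paste("  skipped:", comparisons$skipped) else character(0))
  }
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}
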