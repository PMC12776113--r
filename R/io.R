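# Readers, writers and validators for the tabular and sequence formats the
# pipeline touches. All tables are plain TSV with headers; missing values
# are the literal token "NA". Collections are plain data frames whose
# invariants are enforced by the validate_* functions at read time.

SPECIES_LEVELS <- c("mel", "pse")
LITERATURE_FLAGS <- c("parent", "child", "none")
FEATURE_GROUPS <- c("single_copy", "deleted_redundant", "deleted_unique")
FPKM_TISSUES <- c("carcass", "male_head", "female_head", "testis",
                  "accessory_gland", "ovary")
FPKM_COLUMNS <- paste0("fpkm_", FPKM_TISSUES)

# presence12 TSV encoding: 12 comma-separated 0/1 entries, or NA.
parse_presence12 <- function(x) {
  out <- matrix(NA, nrow = length(x), ncol = 12L)
  filled <- !is.na(x)
  if (any(filled)) {
    parts <- strsplit(x[filled], ",", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) != 12L || !all(p %in% c("0", "1")),
                  logical(1))
    if (any(bad))
      stop("presence12 must be 12 comma-separated 0/1 values; bad rows: ",
           paste(which(filled)[bad], collapse = ", "), call. = FALSE)
    out[filled, ] <- t(vapply(parts, function(p) p == "1", logical(12L)))
  }
  out
}

format_presence12 <- function(mat) {
  apply(mat, 1, function(r) if (anyNA(r)) NA_character_
        else paste(as.integer(r), collapse = ","))
}

stop_rows <- function(cond, msg) {
  if (any(cond, na.rm = TRUE))
    stop(msg, "; offending rows: ",
         paste(utils::head(which(cond), 20), collapse = ", "), call. = FALSE)
}

#' Validate an evidence table
#'
#' Checks the per-gene evidence bundle: unique gene identifiers, valid
#' species and literature flags, well-formed 12-entry presence profiles,
#' nonnegative intron counts, ortholog counts within 0..37 and positive
#' orthogroup sizes. Missing values are allowed for presence profiles,
#' intron counts, ortholog counts and orthogroup sizes.
#'
#' @param evidence Data frame in the `evidence.tsv` layout.
#' @return The validated evidence table, invisibly.
#' @export
validate_evidence <- function(evidence) {
  req <- c("gene_id", "species", "literature_flag", "presence12",
           "intron_count", "ortholog_species_count", "orthogroup_size")
  missing_cols <- setdiff(req, names(evidence))
  if (length(missing_cols))
    stop("evidence table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(evidence$gene_id))
    stop("duplicate gene_id in evidence table", call. = FALSE)
  stop_rows(!evidence$species %in% SPECIES_LEVELS, "invalid species")
  stop_rows(!evidence$literature_flag %in% LITERATURE_FLAGS,
            "invalid literature_flag")
  parse_presence12(evidence$presence12)  # errors on malformed entries
  stop_rows(evidence$intron_count < 0, "negative intron_count")
  stop_rows(evidence$ortholog_species_count < 0 |
              evidence$ortholog_species_count > 37,
            "ortholog_species_count outside [0, 37]")
  stop_rows(evidence$orthogroup_size < 1, "orthogroup_size below 1")
  invisible(evidence)
}

#' Validate an event table
#'
#' Checks the deletion-event table: unique event identifiers, valid deletion
#' lineage and functional class, distinct S and L genes. When an evidence
#' table is supplied, additionally enforces referential integrity (every
#' referenced S, L, D gene has an evidence row) and species consistency: S
#' and L belong to the ancestral-state species (the one in which the
#' deletion did not occur) and D to the deletion lineage.
#'
#' @param events Data frame in the `events.tsv` layout.
#' @param evidence Optional evidence table for cross-checks.
#' @return The validated event table, invisibly.
#' @export
validate_events <- function(events, evidence = NULL) {
  req <- c("event_id", "deletion_lineage", "functional_class",
           "s_gene", "l_gene", "d_gene")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(events$event_id))
    stop("duplicate event_id in event table", call. = FALSE)
  stop_rows(!events$deletion_lineage %in% SPECIES_LEVELS,
            "invalid deletion_lineage")
  stop_rows(!events$functional_class %in% c("redundant", "unique"),
            "invalid functional_class")
  stop_rows(events$s_gene == events$l_gene, "s_gene equals l_gene")
  if (!is.null(evidence) && !inherits(evidence, "dupdel_evidence_index")) {
    refs <- c(events$s_gene, events$l_gene, events$d_gene)
    unknown <- !refs %in% evidence$gene_id
    if (any(unknown)) {
      bad_events <- unique(events$event_id[((which(unknown) - 1) %% nrow(events)) + 1])
      stop("events reference genes absent from the evidence table: ",
           paste(utils::head(bad_events, 10), collapse = ", "), call. = FALSE)
    }
    sp <- stats::setNames(evidence$species, evidence$gene_id)
    ancestral <- ifelse(events$deletion_lineage == "mel", "pse", "mel")
    stop_rows(sp[events$s_gene] != ancestral |
                sp[events$l_gene] != ancestral,
              "S/L genes not in the ancestral-state species")
    stop_rows(sp[events$d_gene] != events$deletion_lineage,
              "D gene not in the deletion lineage")
  }
  invisible(events)
}

#' Validate a feature table
#'
#' Checks per-gene quantitative features: unique gene identifiers, valid
#' group labels, positive Ka/Ks where present, nonnegative FPKM values,
#' nonnegative integer interaction degree, TM-scores within `[0, 1]` and
#' pLDDT within `[0, 100]`.
#'
#' @param features Data frame in the `features.tsv` layout (with
#'   `ppi_count`).
#' @return The validated feature table, invisibly.
#' @export
validate_features <- function(features) {
  req <- c("gene_id", "group", "ka_ks", FPKM_COLUMNS, "ppi_count",
           "tm_score", "plddt")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(features$gene_id))
    stop("duplicate gene_id in feature table", call. = FALSE)
  stop_rows(!features$group %in% FEATURE_GROUPS, "invalid group label")
  stop_rows(features$ka_ks <= 0, "nonpositive ka_ks")
  for (col in FPKM_COLUMNS)
    stop_rows(features[[col]] < 0, paste("negative", col))
  stop_rows(features$ppi_count < 0 |
              features$ppi_count != round(features$ppi_count),
            "ppi_count not a nonnegative integer")
  stop_rows(features$tm_score < 0 | features$tm_score > 1,
            "tm_score outside [0, 1]")
  stop_rows(features$plddt < 0 | features$plddt > 100,
            "plddt outside [0, 100]")
  invisible(features)
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = TRUE)
}

write_tsv_file <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      # %.17g round-trips IEEE doubles exactly
      v <- sprintf("%.17g", out[[col]])
      v[is.na(out[[col]])] <- NA_character_
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
}

#' Read a deletion-event table
#' @param path Path to `events.tsv`.
#' @param evidence Optional evidence table for referential-integrity checks.
#' @return Validated event data frame.
#' @export
read_events <- function(path, evidence = NULL) {
  ev <- read_tsv_file(path)
  ev$event_id <- as.character(ev$event_id)
  for (col in c("s_gene", "l_gene", "d_gene")) ev[[col]] <- as.character(ev[[col]])
  validate_events(ev, evidence)
  ev
}

#' Read a per-gene evidence table
#' @param path Path to `evidence.tsv`.
#' @return Validated evidence data frame.
#' @export
read_evidence <- function(path) {
  ev <- read_tsv_file(path)
  ev$gene_id <- as.character(ev$gene_id)
  ev$presence12 <- as.character(ev$presence12)
  ev$intron_count <- as.integer(ev$intron_count)
  ev$ortholog_species_count <- as.integer(ev$ortholog_species_count)
  ev$orthogroup_size <- as.integer(ev$orthogroup_size)
  validate_evidence(ev)
  ev
}

#' Compute interaction degree from physical-link and alias tables
#'
#' Counts, for each gene, the number of distinct partner proteins with which
#' its protein product has a recorded physical link (either link direction;
#' duplicate records and self-links ignored). Link scores are retained only
#' through the optional `min_score` filter, which defaults to 0 (no
#' filtering). Genes without an aliased protein, or whose protein has no
#' links, get degree 0.
#'
#' @param ppi Data frame with columns `protein_a`, `protein_b`, `score`.
#' @param alias Data frame with columns `protein_id`, `gene_id`.
#' @param gene_ids Genes to report (default: all aliased genes).
#' @param min_score Minimum link score to retain.
#' @return Named integer vector of degrees over `gene_ids`.
#' @export
ppi_degree <- function(ppi, alias, gene_ids = unique(alias$gene_id),
                       min_score = 0) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(ppi)),
            all(c("protein_id", "gene_id") %in% names(alias)))
  if (!is.null(ppi$score)) ppi <- ppi[ppi$score >= min_score, , drop = FALSE]
  ppi <- ppi[ppi$protein_a != ppi$protein_b, , drop = FALSE]
  pairs <- unique(rbind(
    data.frame(p = ppi$protein_a, q = ppi$protein_b, stringsAsFactors = FALSE),
    data.frame(p = ppi$protein_b, q = ppi$protein_a, stringsAsFactors = FALSE)))
  deg <- table(factor(pairs$p, levels = unique(pairs$p)))
  gene_of <- stats::setNames(alias$gene_id, alias$protein_id)
  out <- stats::setNames(integer(length(gene_ids)), gene_ids)
  hit <- names(deg)[names(deg) %in% names(gene_of)]
  for (p in hit) {
    g <- gene_of[[p]]
    if (g %in% gene_ids) out[[g]] <- out[[g]] + as.integer(deg[[p]])
  }
  out
}

#' Read the full set of analysis tables
#'
#' Reads and cross-validates the four inputs of a run: the event table, the
#' per-gene evidence table, the per-gene feature table and the physical
#' protein-link tables. The interaction degree of each gene in the feature
#' table is computed from the link table (distinct physical partners of the
#' gene's protein product) and attached as `ppi_count`.
#'
#' @param event_tsv,evidence_tsv,feature_tsv Paths to the TSV tables.
#' @param ppi_tsv Path to the physical-link table
#'   (`protein_a`, `protein_b`, `score`).
#' @param alias_tsv Path to the protein-to-gene alias table.
#' @param min_score Minimum link score retained when computing degree.
#' @return List with validated `events`, `evidence` and `features` (the
#'   latter including `ppi_count`).
#' @export
read_tables <- function(event_tsv, evidence_tsv, feature_tsv, ppi_tsv,
                        alias_tsv, min_score = 0) {
  evidence <- read_evidence(evidence_tsv)
  events <- read_events(event_tsv, evidence)
  features <- read_tsv_file(feature_tsv)
  features$gene_id <- as.character(features$gene_id)
  ppi <- read_tsv_file(ppi_tsv)
  alias <- read_tsv_file(alias_tsv)
  deg <- ppi_degree(ppi, alias, gene_ids = features$gene_id,
                    min_score = min_score)
  features$ppi_count <- as.integer(deg[features$gene_id])
  features <- features[, c("gene_id", "group", "ka_ks", FPKM_COLUMNS,
                           "ppi_count", "tm_score", "plddt")]
  validate_features(features)
  list(events = events, evidence = evidence, features = features)
}

#' Derive intron counts from gene models
#'
#' Reads a GFF3 file and returns, for each gene, the intron count of its
#' longest transcript: the transcript with the greatest summed exon length
#' (ties broken by lexicographically smallest transcript identifier), whose
#' intron count is its exon count minus one. Genes with no transcript are
#' absent from the result. Strand is ignored; the count is strand-invariant.
#'
#' @param gff_source Path to a GFF3 file with gene, mRNA/transcript and exon
#'   features linked by `ID`/`Parent` attributes.
#' @return Named integer vector: `gene_id -> intron_count`.
#' @export
read_gene_models <- function(gff_source) {
  lines <- readLines(gff_source)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfields <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length,
                    integer(1))
  if (any(nfields != 9L))
    stop("malformed GFF3 at line ",
         which(body)[which(nfields != 9L)[1]], ": expected 9 tab-separated fields",
         call. = FALSE)

  gr <- rtracklayer::import(gff_source, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  tx <- which(type %in% c("mRNA", "transcript"))
  if (!length(tx)) return(stats::setNames(integer(0), character(0)))
  tx_id <- ids[tx]
  tx_gene <- parents[tx]

  ex <- which(type == "exon")
  ex_parent <- parents[ex]
  ex_width <- BiocGenerics::width(gr)[ex]
  n_exon <- table(factor(ex_parent, levels = tx_id))
  if (any(n_exon == 0L))
    stop("transcript(s) with zero exons: ",
         paste(utils::head(tx_id[n_exon == 0L], 10), collapse = ", "),
         call. = FALSE)
  sum_len <- tapply(ex_width, factor(ex_parent, levels = tx_id), sum)

  out <- integer(0)
  for (g in unique(tx_gene)) {
    sel <- which(tx_gene == g)
    # longest transcript = greatest summed exon length, then smallest ID
    ord <- sel[order(-sum_len[sel], tx_id[sel])]
    out[[g]] <- as.integer(n_exon[ord[1]]) - 1L
  }
  out
}

#' Read coding sequences, retaining the longest transcript per gene
#'
#' Reads a nucleotide FASTA with one record per transcript. Headers carry
#' the transcript identifier first, then a `gene=<gene_id>` field. For each
#' gene the longest sequence is retained (ties broken by lexicographically
#' smallest transcript identifier).
#'
#' @param fasta_source Path to the FASTA file.
#' @return Named character vector: `gene_id -> coding sequence`.
#' @export
read_sequences <- function(fasta_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) == 0L) return(stats::setNames(character(0), character(0)))
  headers <- names(seqs)
  tx_id <- sub("\\s.*$", "", headers)
  if (anyDuplicated(tx_id))
    stop("duplicate transcript identifier(s): ",
         paste(unique(tx_id[duplicated(tx_id)]), collapse = ", "),
         call. = FALSE)
  gene <- sub("^.*gene=([^\\s;]+).*$", "\\1", headers, perl = TRUE)
  if (any(gene == headers))
    stop("FASTA header(s) lack a gene=<id> field", call. = FALSE)
  w <- BiocGenerics::width(seqs)
  if (any(w == 0L))
    stop("empty record(s): ",
         paste(tx_id[w == 0L], collapse = ", "), call. = FALSE)
  out <- character(0)
  for (g in unique(gene)) {
    sel <- which(gene == g)
    ord <- sel[order(-w[sel], tx_id[sel])]
    out[[g]] <- as.character(seqs[[ord[1]]])
  }
  out
}
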