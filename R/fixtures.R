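# Packaged census tables: the regulator census (HTCS and SusR-like
# regulators with ortholog counts and predicted substrates), the
# monosaccharide-utilization regulon table, the gene-category counts of
# the polysaccharide-utilization (PSU) metabolic/regulatory network,
# and the global regulator's palindromic binding consensus. Rows are
# transcribed verbatim, including regulon names that label two paralogs
# (e.g. HTCS_Rgu-1 on two rows); counting is therefore by row, not by
# distinct name. Loaders validate against the packaged schema.

#' @noRd
fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "regufoot")
  if (p == "") stopf("packaged fixture '%s' is missing", name)
  p
}

#' @noRd
census_schema <- function() {
  jsonlite::read_json(fixture_path("census_schema.json"))
}

#' Load the regulator census table
#'
#' One row per membrane-anchored regulator (HTCS or SusR-like) of the
#' reference genome, with its ortholog count across the related genomes
#' and predicted substrate. An empty `regulon_name` means no regulon
#' was reconstructed for that regulator.
#'
#' @return data.frame with columns `locus_tag`, `regulon_name`,
#'   `class`, `n_orthologs`, `substrate`.
#' @export
load_table1 <- function() {
  tab <- read.delim(fixture_path("regulator_census.tsv"),
                    stringsAsFactors = FALSE, na.strings = NULL)
  schema <- census_schema()$regulator_census
  if (!identical(names(tab), unlist(schema$columns))) {
    stopf("regulator census schema mismatch")
  }
  names(tab)[names(tab) == "regulator_name"] <- "regulon_name"
  tab$regulon_name[is.na(tab$regulon_name)] <- ""
  tab$substrate[is.na(tab$substrate)] <- ""
  if (!all(tab$class %in% unlist(schema$classes))) {
    stopf("unexpected regulator class in census")
  }
  if (any(tab$n_orthologs < 0)) stopf("negative ortholog count")
  tab
}

#' Load the monosaccharide-utilization regulon table
#'
#' One row per reconstructed transcription-factor regulon controlling a
#' cytoplasmic monosaccharide utilization pathway.
#'
#' @return data.frame with columns `regulator_name`, `locus_tag`,
#'   `n_orthologs`, `pathway`, `family`.
#' @export
load_table2 <- function() {
  tab <- read.delim(fixture_path("monosaccharide_regulons.tsv"),
                    stringsAsFactors = FALSE, na.strings = NULL)
  schema <- census_schema()$monosaccharide_regulons
  if (!identical(names(tab), unlist(schema$columns))) {
    stopf("monosaccharide regulon schema mismatch")
  }
  if (any(!nzchar(tab$family))) stopf("regulator family must be non-empty")
  tab
}

#' Load the PSU network category counts
#'
#' Category counts for the reconstructed polysaccharide-utilization
#' metabolic/regulatory network: the functional breakdown of the full
#' network, of its novel genes, and of its overlaps with an
#' automatically generated and a manually curated metabolic model.
#'
#' @return nested list of non-negative integer counts with blocks
#'   `network`, `novel`, `overlap_model_seed`, `overlap_curated_model`,
#'   `overlap_all_three`.
#' @export
load_network_counts <- function() {
  counts <- jsonlite::read_json(fixture_path("network_counts.json"))
  schema <- census_schema()$network_counts
  missing <- setdiff(unlist(schema$blocks), names(counts))
  if (length(missing) > 0L) {
    stopf("network counts lack block(s): %s", paste(missing, collapse = ", "))
  }
  vals <- unlist(counts)
  if (any(vals < 0) || any(vals != round(vals))) {
    stopf("network counts must be non-negative integers")
  }
  counts
}

#' The global regulator's palindromic binding consensus
#'
#' Returns the packaged 22-bp IUPAC consensus verbatim (lowercase
#' letters mark degenerate positions: `w` = A/T, `n` = any base).
#'
#' @return a `consensus_string`.
#' @export
crp_consensus <- function() {
  s <- readLines(fixture_path("crp_consensus.txt"), n = 1L)
  structure(s, class = "consensus_string")
}
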