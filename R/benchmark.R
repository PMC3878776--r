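# Reproducible benchmark drivers. These run the full pipeline on the
# synthetic study design and score the result against the generator's
# ground truth; the test suite and the acceptance script call them with
# swept seeds.

#' Run the direct-repeat recovery benchmark for one seed
#'
#' Generates the standard benchmark collection (5 genomes, one planted
#' direct-repeat regulator with two 16-bp boxes around a 5-bp spacer,
#' 6 target operons, divergence 0.2), runs Workflow 1 seeded at the
#' regulator gene, and scores the recovered geometry and membership
#' against the truth manifest.
#'
#' @param seed RNG seed for both the generator and the workflow.
#' @param synth_overrides named list of [synth_config()] arguments to
#'   override.
#' @param outdir artifact directory (a temporary directory by default).
#' @return list with `geometry` (recovered), `geometry_ok` (exact
#'   recovery of the planted box/spacer), `f1` (membership F1 over
#'   (genome, gene) pairs), `result` (the [run_workflow1()] output) and
#'   `manifest`.
#' @export
benchmark_direct_repeat <- function(seed, synth_overrides = list(),
                                    outdir = tempfile("benchmark_")) {
  args <- utils::modifyList(list(seed = seed), synth_overrides)
  cfg <- do.call(synth_config, args)
  col <- generate_collection(cfg)
  man <- col$manifest
  truth <- man$regulators[[1]]
  ref <- man$genome_ids[1]
  reg_tag <- man$families[[ref]][truth$regulator_family]
  pcfg <- pipeline_config(col$genomes, "footprint_repeat",
                          regulator = list(genome_id = ref,
                                           locus_tag = reg_tag),
                          outdir = outdir, seed = seed)
  res <- run_workflow1(pcfg)
  g <- res$model$geometry
  planted <- truth$geometry
  list(geometry = g,
       geometry_ok = g$kind == "direct_repeat" &&
         g$box_len == planted$box_len && g$spacer == planted$spacer,
       f1 = membership_f1(res$regulon, truth$sites),
       result = res, manifest = man)
}

#' Membership F1 of a regulon against planted truth
#'
#' @param regulon a `regulon`.
#' @param truth_sites the manifest's site table for the regulator.
#' @return F1 over (genome, gene) membership pairs.
#' @export
membership_f1 <- function(regulon, truth_sites) {
  truth <- unique(paste(truth_sites$genome_id, truth_sites$locus_tag))
  pred <- unique(paste(regulon$member_genes$genome_id,
                       regulon$member_genes$gene_id))
  tp <- length(intersect(pred, truth))
  if (length(pred) + length(truth) == 0L) return(1)
  2 * tp / (length(pred) + length(truth))
}

#' Run the palindrome recovery benchmark for one seed
#'
#' Generates a collection carrying the packaged 22-bp palindromic
#' consensus upstream of four target operons, runs the
#' symmetry-constrained EM on the targets' upstream regions, and
#' compares the recovered consensus with the planted one.
#'
#' @param seed RNG seed.
#' @param n_restarts EM restarts (default 20).
#' @return list with `model`, `consensus`, `symmetry_error` (max
#'   absolute deviation of the frequency matrix from its reverse
#'   complement; exactly 0 by construction), `fixed_match` (fraction of
#'   non-degenerate planted positions recovered) and `manifest`.
#' @export
benchmark_palindrome <- function(seed, n_restarts = 20L) {
  planted <- as.character(crp_consensus())
  cfg <- synth_config(seed = seed, global_palindrome = planted)
  col <- generate_collection(cfg)
  man <- col$manifest
  seqs <- vapply(seq_len(nrow(man$palindrome$sites)), function(k) {
    row <- man$palindrome$sites[k, ]
    extract_upstream(col$genomes[[row$genome_id]], row$locus_tag)$sequence
  }, character(1))
  model <- discover_palindrome_em(seqs, motif_len = nchar(planted),
                                  n_restarts = n_restarts, seed = seed)
  cons <- toupper(as.character(consensus(model)))
  planted_up <- toupper(planted)
  fixed <- strsplit(planted_up, "")[[1]] %in% DNA_BASES4
  match_vec <- strsplit(planted_up, "")[[1]][fixed] ==
    strsplit(cons, "")[[1]][fixed]
  list(model = model, consensus = consensus(model),
       symmetry_error = max(abs(model$freq - revcomp_freq(model$freq))),
       fixed_match = mean(match_vec), manifest = man)
}

#' False-positive control: scan genomes that lack the regulon
#'
#' Generates a collection whose regulator plants no sites
#' (`site_rate = 0`), scans every operon-leader upstream region with a
#' foreign planted-motif PWM at its training threshold, and counts the
#' members accepted by the consistency check at `min_support`.
#'
#' @param seed RNG seed for the null collection.
#' @param model a trained `motif_model` from a different collection.
#' @param threshold scan threshold (the model's training minimum).
#' @param min_support consistency support (default 2).
#' @return number of accepted members (0 expected for almost all
#'   seeds).
#' @export
benchmark_null_members <- function(seed, model, threshold,
                                   min_support = 2L) {
  cfg <- synth_config(n_genomes = 3L, genes_per_genome = 16L,
                      seed = seed,
                      regulators = list(regulator_spec(site_rate = 0)))
  col <- generate_collection(cfg)
  man <- col$manifest
  genomes <- col$genomes
  operons <- unlist(lapply(genomes, predict_operons), recursive = FALSE)
  regions <- lapply(operons, function(op) {
    r <- extract_upstream(genomes[[op$genome_id]], op$leader_gene)
    r$operon_id <- op$operon_id
    r
  })
  hits <- scan_regions(model, regions, threshold)
  # orthology is positional by construction in the generator; use the
  # family map directly as the ortholog map so the null result is not
  # an artifact of BBH failures
  fam <- man$families
  groups_df <- do.call(rbind, lapply(man$genome_ids, function(g) {
    data.frame(genome_id = g, locus_tag = fam[[g]],
               group_id = sprintf("OG%04d", fam$family),
               stringsAsFactors = FALSE)
  }))
  reg_fam <- man$regulators[[1]]$regulator_family
  reg_group <- list(group_id = sprintf("OG%04d", reg_fam),
                    members = data.frame(
                      genome_id = man$genome_ids,
                      locus_tag = vapply(man$genome_ids, function(g) {
                        fam[[g]][reg_fam]
                      }, character(1)),
                      stringsAsFactors = FALSE))
  accepted <- consistency_filter(hits, groups_df, reg_group,
                                 min_support = min_support,
                                 operons = operons)
  nrow(accepted)
}
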