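# The two end-to-end regulon-reconstruction workflows.
#
# Workflow 1 (footprint_repeat) targets membrane-anchored regulators
# whose motifs are spaced direct repeats: orthology -> candidate
# operons from the regulator's chromosomal neighborhood -> upstream
# extraction -> phylogenetic footprinting -> direct-repeat discovery ->
# PWM -> genome scan -> consistency check -> iterative refinement.
#
# Workflow 2 (palindrome_em) targets cytoplasmic regulators of
# monosaccharide pathways: upstream regions of user-supplied candidate
# co-regulated gene sets -> palindrome-constrained EM -> PWM -> scan
# with the training-set minimum threshold -> consistency filter ->
# final regulon.

#' Pipeline configuration
#'
#' @param genomes named list of [genome_record()]s, or a character
#'   vector of FASTA paths (each `X.fasta` must have an
#'   `X.features.tsv` feature table next to it).
#' @param workflow `"footprint_repeat"` (Workflow 1) or
#'   `"palindrome_em"` (Workflow 2).
#' @param regulator `list(genome_id=, locus_tag=)` of the regulator
#'   seed gene.
#' @param candidate_sets for Workflow 2: list of candidate co-regulated
#'   gene sets, each a list of `list(genome_id=, locus_tag=)`.
#' @param outdir artifact directory.
#' @param window upstream window relative to the translation start
#'   (default `c(-400, 50)`).
#' @param max_gap operon-prediction gap (default 100 bp).
#' @param island_window,island_identity footprinting parameters
#'   (defaults 10 columns, 0.8).
#' @param box_len_range,spacer_range,susr_mode,n_seeds direct-repeat
#'   discovery grid (defaults 10:18, 3:12, off, 8).
#' @param motif_len,n_restarts palindrome EM parameters (defaults 22,
#'   20).
#' @param min_identity orthology identity threshold (default 0.30).
#' @param min_support consistency-check support (default 2 genomes).
#' @param pseudocount PWM pseudocount (default 0.5).
#' @param seed RNG seed; identical config + seed give byte-identical
#'   outputs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genomes,
                            workflow = c("footprint_repeat",
                                         "palindrome_em"),
                            regulator = NULL, candidate_sets = NULL,
                            outdir = tempfile("regufoot_run_"),
                            window = c(-400L, 50L), max_gap = 100L,
                            island_window = 10L, island_identity = 0.8,
                            box_len_range = 10:18, spacer_range = 3:12,
                            susr_mode = FALSE, n_seeds = 8L,
                            motif_len = 22L, n_restarts = 20L,
                            min_identity = 0.30, min_support = 2L,
                            pseudocount = 0.5, seed = 1L) {
  workflow <- match.arg(workflow)
  if (is.character(genomes)) {
    genomes <- lapply(genomes, function(p) {
      read_genome(p, annotations = sub("\\.(fa|fasta|fna)$",
                                       ".features.tsv", p))
    })
  }
  names(genomes) <- vapply(genomes, function(g) g$genome_id, character(1))
  structure(
    list(genomes = genomes, workflow = workflow, regulator = regulator,
         candidate_sets = candidate_sets, outdir = outdir,
         window = window, max_gap = max_gap,
         island_window = island_window,
         island_identity = island_identity,
         box_len_range = box_len_range, spacer_range = spacer_range,
         susr_mode = susr_mode, n_seeds = n_seeds,
         motif_len = motif_len, n_restarts = n_restarts,
         min_identity = min_identity, min_support = min_support,
         pseudocount = pseudocount, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

# Shared plumbing: operons, leader upstream regions, and the ortholog
# map of all operon leaders seeded from a reference genome.
#' @noRd
workflow_context <- function(config, ref_genome) {
  genomes <- config$genomes
  operons <- unlist(lapply(genomes, predict_operons,
                           max_gap = config$max_gap), recursive = FALSE)
  leader_regions <- lapply(operons, function(op) {
    r <- extract_upstream(genomes[[op$genome_id]], op$leader_gene,
                          window = config$window)
    r$operon_id <- op$operon_id
    r
  })
  ref_leaders <- Filter(function(op) op$genome_id == ref_genome, operons)
  seeds <- lapply(ref_leaders, function(op) {
    list(genome_id = ref_genome, locus_tag = op$leader_gene)
  })
  edges <- bbh_edges(genomes, min_identity = config$min_identity)
  groups <- build_ortholog_groups(genomes, seeds,
                                  min_identity = config$min_identity,
                                  edges = edges)
  groups_df <- do.call(rbind, lapply(groups, function(g) {
    cbind(g$members[, c("genome_id", "locus_tag")],
          group_id = g$group_id, stringsAsFactors = FALSE)
  }))
  list(operons = operons, leader_regions = leader_regions,
       groups = groups, groups_df = groups_df, edges = edges)
}

#' @noRd
operon_of_gene <- function(operons, genome_id, gene) {
  for (op in operons) {
    if (op$genome_id == genome_id && gene %in% op$gene_ids) return(op)
  }
  NULL
}

#' Run Workflow 1: footprinting and direct-repeat regulons
#'
#' @param config a [pipeline_config()] with `workflow =
#'   "footprint_repeat"` and a `regulator` seed gene.
#' @return list with `model`, `regulon`, `hits`, `threshold`,
#'   `regulator_group`, `groups`, `candidate_group_ids`, `outdir`.
#' @export
run_workflow1 <- function(config) {
  genomes <- config$genomes
  if (length(genomes) < 2L) {
    stopf("Workflow 1 needs at least 2 genomes (the consistency check is impossible otherwise)")
  }
  if (is.null(config$regulator)) stopf("regulator seed gene not specified")
  ref <- config$regulator$genome_id
  ctx <- stage("context", workflow_context(config, ref))

  reg_group <- stage("orthology", {
    build_ortholog_groups(genomes, list(config$regulator),
                          min_identity = config$min_identity,
                          edges = ctx$edges)[[1]]
  })

  # candidate operons: the regulator's operon plus one upstream and one
  # downstream operon, in every genome carrying a regulator ortholog
  candidate_leaders <- stage("candidates", {
    leaders <- character(0)
    reg_ops <- Filter(function(op) op$genome_id == ref, ctx$operons)
    ord <- order(vapply(reg_ops, function(op) {
      min(genomes[[ref]]$features$start[
        genomes[[ref]]$features$locus_tag %in% op$gene_ids])
    }, numeric(1)))
    reg_ops <- reg_ops[ord]
    k <- which(vapply(reg_ops, function(op) {
      config$regulator$locus_tag %in% op$gene_ids
    }, logical(1)))
    if (length(k) != 1L) stopf("regulator gene not found in any operon")
    for (i in intersect(c(k - 1L, k, k + 1L), seq_along(reg_ops))) {
      leaders <- c(leaders, reg_ops[[i]]$leader_gene)
    }
    leaders
  })

  candidate_group_ids <- vapply(
    Filter(function(g) g$seed$locus_tag %in% candidate_leaders,
           ctx$groups),
    `[[`, character(1), "group_id")

  # Footprint-selected training sequences: for every conservation
  # island of a candidate ortholog set, each row's region subsequence
  # extended by a flank wide enough to contain the partner box of a
  # spaced repeat whose boxes footprint as two separate islands.
  flank <- max(config$box_len_range) + max(config$spacer_range) + 5L
  training <- stage("footprinting", {
    seqs <- character(0)
    for (g in ctx$groups) {
      if (!g$group_id %in% candidate_group_ids) next
      if (nrow(g$members) < 2L) next
      regions <- lapply(seq_len(nrow(g$members)), function(i) {
        extract_upstream(genomes[[g$members$genome_id[i]]],
                         g$members$locus_tag[i], window = config$window)
      })
      aln <- align_upstreams(regions)
      islands <- find_islands(aln, config$island_window,
                              config$island_identity)
      region_seq <- setNames(vapply(regions, function(r) r$sequence,
                                    character(1)), aln$region_ids)
      spans <- list()   # per region id: merged [from, to) island spans
      for (isl in islands) {
        for (k in seq_len(nrow(isl$rows))) {
          id <- isl$rows$region_id[k]
          spans[[id]] <- rbind(spans[[id]],
                               c(isl$rows$from[k], isl$rows$to[k]))
        }
      }
      for (id in names(spans)) {
        sp <- spans[[id]]
        len <- nchar(region_seq[[id]])
        from <- max(0L, min(sp[, 1L]) - flank)
        to <- min(len, max(sp[, 2L]) + flank)
        if (to - from >= config$island_window) {
          seqs <- c(seqs, substr(region_seq[[id]], from + 1L, to))
        }
      }
    }
    if (length(seqs) < 3L) {
      stopf("footprinting found no conserved candidate regions")
    }
    unname(seqs)
  })

  model <- stage("motif discovery", {
    discover_direct_repeat(training,
                           box_len_range = config$box_len_range,
                           spacer_range = config$spacer_range,
                           n_seeds = config$n_seeds, seed = config$seed,
                           pseudocount = config$pseudocount,
                           susr_mode = config$susr_mode)
  })
  finish_workflow(config, ctx, reg_group, model,
                  extras = list(candidate_group_ids = candidate_group_ids))
}

#' Run Workflow 2: palindrome EM regulons
#'
#' @param config a [pipeline_config()] with `workflow = "palindrome_em"`,
#'   a `regulator` seed gene and non-empty `candidate_sets`.
#' @return list as in [run_workflow1()].
#' @export
run_workflow2 <- function(config) {
  genomes <- config$genomes
  if (length(genomes) < 2L) {
    stopf("Workflow 2 needs at least 2 genomes")
  }
  if (is.null(config$candidate_sets) ||
      length(config$candidate_sets) == 0L) {
    stopf("candidate co-regulated gene sets not specified")
  }
  if (is.null(config$regulator)) stopf("regulator seed gene not specified")
  ref <- config$regulator$genome_id
  ctx <- stage("context", workflow_context(config, ref))
  reg_group <- stage("orthology", {
    build_ortholog_groups(genomes, list(config$regulator),
                          min_identity = config$min_identity,
                          edges = ctx$edges)[[1]]
  })
  training <- stage("upstream extraction", {
    unlist(lapply(config$candidate_sets, function(set) {
      vapply(set, function(g) {
        extract_upstream(genomes[[g$genome_id]], g$locus_tag,
                         window = config$window)$sequence
      }, character(1))
    }), use.names = FALSE)
  })
  model <- stage("motif discovery", {
    discover_palindrome_em(training, motif_len = config$motif_len,
                           n_restarts = config$n_restarts,
                           seed = config$seed,
                           pseudocount = config$pseudocount)
  })
  finish_workflow(config, ctx, reg_group, model, extras = list())
}

# Scan, filter, refine, and write artifacts - shared by both workflows.
#' @noRd
finish_workflow <- function(config, ctx, reg_group, model, extras) {
  threshold <- stage("threshold", training_threshold(model, "loo_min"))
  hits <- stage("scan", {
    scan_regions(model, ctx$leader_regions, threshold)
  })
  accepted <- stage("consistency check", {
    consistency_filter(hits, ctx$groups_df, reg_group,
                       min_support = config$min_support,
                       operons = ctx$operons)
  })
  if (nrow(accepted) == 0L) {
    stopf("stage 'consistency check' accepted no members (regulator %s)",
          config$regulator$locus_tag)
  }
  regulon <- stage("refinement", {
    assemble_regulon(model, reg_group, accepted, hits,
                     ctx$leader_regions, ctx$groups_df, ctx$operons,
                     min_support = config$min_support)
  })
  out <- c(list(model = regulon$model, regulon = regulon, hits = hits,
                threshold = regulon$threshold,
                regulator_group = reg_group, groups = ctx$groups_df,
                outdir = config$outdir), extras)
  stage("artifacts", write_workflow_artifacts(config, out))
  out
}

#' @noRd
write_workflow_artifacts <- function(config, out) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)
  write_meme(out$model, p("motif.meme"),
             name = config$regulator$locus_tag)
  write_transfac(out$model, p("motif.transfac"),
                 name = config$regulator$locus_tag)
  write_hits_tsv(out$hits, p("hits.tsv"))
  write_bed6(out$hits, p("hits.bed"))
  write_regulon_json(out$regulon, p("regulon.json"))
  write.table(out$groups, p("ortholog_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # reproducibility manifest: all parameters and seeds, no timestamps,
  # so reruns of the same config are byte-identical
  scalar_fields <- c("workflow", "window", "max_gap", "island_window",
                     "island_identity", "box_len_range", "spacer_range",
                     "susr_mode", "n_seeds", "motif_len", "n_restarts",
                     "min_identity", "min_support", "pseudocount", "seed")
  lines <- c(sprintf("package_version: %s",
                     as.character(packageVersion("regufoot"))),
             sprintf("genomes: %s",
                     paste(names(config$genomes), collapse = ",")),
             sprintf("regulator: %s/%s", config$regulator$genome_id,
                     config$regulator$locus_tag),
             vapply(scalar_fields, function(f) {
               sprintf("%s: %s", f,
                       paste(format(config[[f]]), collapse = ","))
             }, character(1)),
             sprintf("threshold: %.6f", out$threshold),
             sprintf("converged: %s", out$regulon$converged))
  writeLines(lines, p("run_manifest.txt"))
  invisible(config$outdir)
}
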