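# Orthology by bidirectional best hits: Smith-Waterman local protein
# alignment (via Biostrings) with an identity threshold, applied
# genome-wide, plus neighbor-joining distance trees used to group
# regulator DNA-binding domains.

#' @noRd
substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Local protein alignment
#'
#' Optimal Smith-Waterman local alignment. Identity is the number of
#' identical aligned pairs divided by the number of aligned columns,
#' counting gap columns inside the local alignment span in the
#' denominator.
#'
#' @param a,b protein sequences (single strings).
#' @param substitution name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (default 11 and 1; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return list with `score`, `identity`, `aligned_length`, `query_id`,
#'   `subject_id`.
#' @export
local_align <- function(a, b, substitution = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  mat <- substitution_matrix(substitution)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  ncol_aln <- Biostrings::nchar(aln)
  list(score = Biostrings::score(aln),
       identity = if (ncol_aln > 0) Biostrings::nmatch(aln) / ncol_aln else 0,
       aligned_length = ncol_aln,
       query_id = NA_character_, subject_id = NA_character_)
}

# All-vs-all local alignment scores between two protein sets; identity
# is computed lazily (scores first, full alignments only where needed).
#' @noRd
score_matrix <- function(prots_a, prots_b, substitution, gap_open,
                         gap_extend) {
  mat <- substitution_matrix(substitution)
  set_a <- Biostrings::AAStringSet(prots_a)
  out <- matrix(NA_real_, length(prots_a), length(prots_b),
                dimnames = list(names(prots_a), names(prots_b)))
  for (j in seq_along(prots_b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      set_a, Biostrings::AAString(prots_b[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
  }
  out
}

#' @noRd
genome_proteins <- function(genome) {
  ft <- genome$features
  prots <- ft$translation
  keep <- !is.na(prots) & nzchar(prots)
  setNames(prots[keep], ft$locus_tag[keep])
}

#' @noRd
best_hits <- function(scores) {
  # per row: best column by score, ties broken by lexicographic name
  apply_order <- function(v) {
    ord <- order(-v, colnames(scores))
    colnames(scores)[ord[1]]
  }
  vapply(seq_len(nrow(scores)), function(i) apply_order(scores[i, ]),
         character(1))
}

#' Bidirectional best hits between two genomes
#'
#' A pair `(x, y)` is reported iff `y` is `x`'s top-scoring hit in
#' `genome_b`, `x` is `y`'s top-scoring hit in `genome_a`, and the local
#' alignment identity is at least `min_identity` (inclusive). Score ties
#' are broken by lexicographic locus tag.
#'
#' @param genome_a,genome_b [genome_record()]s with translations.
#' @param min_identity minimum identity fraction (default 0.30).
#' @param substitution,gap_open,gap_extend see [local_align()].
#' @return data.frame with columns `tag_a`, `tag_b`, `score`, `identity`.
#' @export
find_bbh <- function(genome_a, genome_b, min_identity = 0.30,
                     substitution = "BLOSUM62", gap_open = 11,
                     gap_extend = 1) {
  prots_a <- genome_proteins(genome_a)
  prots_b <- genome_proteins(genome_b)
  empty <- data.frame(tag_a = character(0), tag_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(prots_a) == 0L || length(prots_b) == 0L) return(empty)
  scores <- score_matrix(prots_a, prots_b, substitution, gap_open,
                         gap_extend)
  best_ab <- setNames(best_hits(scores), rownames(scores))
  best_ba <- setNames(best_hits(t(scores)), colnames(scores))
  pairs <- list()
  for (x in names(best_ab)) {
    y <- best_ab[[x]]
    if (best_ba[[y]] != x) next
    al <- local_align(prots_a[[x]], prots_b[[y]], substitution,
                      gap_open, gap_extend)
    if (al$identity >= min_identity) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        tag_a = x, tag_b = y, score = al$score, identity = al$identity,
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0L) return(empty)
  out <- do.call(rbind, pairs)
  out <- out[order(out$tag_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build ortholog groups around seed genes
#'
#' For each seed gene, collects its bidirectional-best-hit partners
#' transitively across all genome pairs. When two genes of one genome
#' are reachable, the one with the higher local-alignment score to the
#' seed is kept (ties by lexicographic locus tag). Membership is
#' invariant to the order in which genomes are supplied.
#'
#' All pairwise bidirectional-best-hit edges of a genome collection
#'
#' @param genomes list of [genome_record()]s.
#' @param min_identity,substitution,gap_open,gap_extend see [find_bbh()].
#' @return data.frame of BBH edges (`genome_a`, `tag_a`, `genome_b`,
#'   `tag_b`), reusable across [build_ortholog_groups()] calls.
#' @export
bbh_edges <- function(genomes, min_identity = 0.30,
                      substitution = "BLOSUM62", gap_open = 11,
                      gap_extend = 1) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  genomes <- genomes[order(ids)]
  ids <- sort(ids)
  edges <- list()
  if (length(genomes) >= 2L) {
    for (i in seq_len(length(genomes) - 1L)) {
      for (j in (i + 1L):length(genomes)) {
        bbh <- find_bbh(genomes[[i]], genomes[[j]], min_identity,
                        substitution, gap_open, gap_extend)
        if (nrow(bbh) > 0L) {
          edges[[length(edges) + 1L]] <- data.frame(
            genome_a = ids[i], tag_a = bbh$tag_a,
            genome_b = ids[j], tag_b = bbh$tag_b,
            stringsAsFactors = FALSE, row.names = NULL)
        }
      }
    }
  }
  if (length(edges) > 0L) do.call(rbind, edges) else NULL
}

#' @param genomes list of [genome_record()]s.
#' @param seed_genes list of seeds, each `list(genome_id=, locus_tag=)`.
#' @param min_identity,substitution,gap_open,gap_extend see [find_bbh()].
#' @param edges optional precomputed [bbh_edges()] table for these
#'   genomes (recomputed when `NULL`).
#' @return list of groups, each `list(group_id, seed, members)` where
#'   `members` is a data.frame `(genome_id, locus_tag, score, identity)`
#'   sorted by genome id (the seed has score/identity `NA`).
#' @export
build_ortholog_groups <- function(genomes, seed_genes,
                                  min_identity = 0.30,
                                  substitution = "BLOSUM62",
                                  gap_open = 11, gap_extend = 1,
                                  edges = NULL) {
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate genome ids")
  genomes <- genomes[order(ids)]
  ids <- sort(ids)
  names(genomes) <- ids
  if (is.null(edges)) {
    edges <- bbh_edges(genomes, min_identity, substitution, gap_open,
                       gap_extend)
  }
  node_id <- function(g, t) paste(g, t, sep = "/")
  adj <- list()
  if (!is.null(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- node_id(edges$genome_a[k], edges$tag_a[k])
      b <- node_id(edges$genome_b[k], edges$tag_b[k])
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  groups <- list()
  for (gidx in seq_along(seed_genes)) {
    seed <- seed_genes[[gidx]]
    if (!seed$genome_id %in% ids) stopf("seed genome '%s' not supplied",
                                        seed$genome_id)
    seed_prot <- genome_proteins(genomes[[seed$genome_id]])[[seed$locus_tag]]
    if (is.null(seed_prot)) stopf("seed gene %s/%s has no translation",
                                  seed$genome_id, seed$locus_tag)
    start <- node_id(seed$genome_id, seed$locus_tag)
    seen <- character(0)
    queue <- start
    while (length(queue) > 0L) {
      cur <- queue[1L]
      queue <- queue[-1L]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      queue <- c(queue, sort(setdiff(adj[[cur]] %||% character(0), seen)))
    }
    parts <- strsplit(seen, "/", fixed = TRUE)
    cand <- data.frame(genome_id = vapply(parts, `[`, character(1), 1L),
                       locus_tag = vapply(parts, `[`, character(1), 2L),
                       stringsAsFactors = FALSE)
    # score every candidate against the seed; resolve per-genome conflicts
    cand$score <- NA_real_
    cand$identity <- NA_real_
    for (k in seq_len(nrow(cand))) {
      if (cand$genome_id[k] == seed$genome_id &&
          cand$locus_tag[k] == seed$locus_tag) next
      prot <- genome_proteins(genomes[[cand$genome_id[k]]])[[cand$locus_tag[k]]]
      al <- local_align(seed_prot, prot, substitution, gap_open, gap_extend)
      cand$score[k] <- al$score
      cand$identity[k] <- al$identity
    }
    keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$genome_id),
                          function(rows) {
      if (length(rows) == 1L) return(rows)
      sub <- cand[rows, ]
      is_seed <- sub$genome_id == seed$genome_id &
        sub$locus_tag == seed$locus_tag
      if (any(is_seed)) return(rows[is_seed])
      rows[order(-sub$score, sub$locus_tag)][1L]
    }), use.names = FALSE)
    members <- cand[sort(keep), , drop = FALSE]
    members <- members[order(members$genome_id, members$locus_tag), ,
                       drop = FALSE]
    rownames(members) <- NULL
    groups[[gidx]] <- list(
      group_id = sprintf("OG%04d", gidx),
      seed = seed,
      members = members)
  }
  groups
}

#' Neighbor-joining tree from aligned domain sequences
#'
#' Pairwise distances are Poisson-corrected mismatch fractions
#' (`-log(1 - d)` with `d = 1 - identity` over aligned columns, columns
#' gapped in both members ignored). The tree is built by
#' neighbor-joining; negative branch lengths are clamped to zero. The
#' result is deterministic given the input order.
#'
#' @param members named character vector of aligned (equal-length)
#'   sequences, names are member ids.
#' @return an [ape::as.phylo] tree (class `phylo`), newick-serializable
#'   via [ape::write.tree].
#' @export
build_distance_tree <- function(members) {
  if (length(members) < 2L) stopf("need at least 2 members")
  if (length(unique(nchar(members))) != 1L) {
    stopf("members must be aligned to equal length")
  }
  if (is.null(names(members))) names(members) <- paste0("m", seq_along(members))
  n <- length(members)
  chars <- lapply(members, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  D <- matrix(0, n, n, dimnames = list(names(members), names(members)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      use <- !(a == "-" & b == "-")
      d <- if (any(use)) mean(a[use] != b[use]) else 0
      d <- min(d, 0.95)   # keep the Poisson correction finite
      D[i, j] <- D[j, i] <- -log(1 - d)
    }
  }
  if (n == 2L) {
    tree <- ape::read.tree(
      text = sprintf("(%s:%.10f,%s:%.10f);", names(members)[1], D[1, 2] / 2,
                     names(members)[2], D[1, 2] / 2))
    return(tree)
  }
  tree <- ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
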