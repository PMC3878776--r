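# Cross-genome consistency check. A candidate site upstream of a gene
# is credible when sites also occur upstream of the gene's orthologs in
# other genomes carrying the orthologous regulator; sites scattered at
# random do not repeat in orthologous positions. Membership can also be
# inherited by the other genes of an operon whose leader carries a
# conserved site, and - behind an explicit flag - granted to strong
# non-conserved sites upstream of genes functionally related to an
# accepted member.

#' Consistency-check filtering of scan hits
#'
#' A target operon is accepted when sites occur upstream of it and of
#' its orthologs in at least `min_support` genomes carrying the
#' orthologous regulator (the member's own genome counts toward the
#' support); the remaining genes of an accepted operon are accepted by
#' operon inheritance. With `functional_link = TRUE`, a non-conserved
#' hit scoring at least `threshold + 2` bits upstream of a gene sharing
#' a functional-category tag with an accepted member is also accepted.
#'
#' @param hits data.frame from [scan_regions()].
#' @param groups ortholog map covering the target genes: data.frame
#'   with columns `genome_id`, `locus_tag`, `group_id`.
#' @param regulator_group the regulator's ortholog group (from
#'   [build_ortholog_groups()]); hits in genomes outside it are ignored
#'   with a warning.
#' @param min_support minimum number of genomes with a conserved site
#'   (default 2).
#' @param operons optional list of operons (from [predict_operons()],
#'   possibly concatenated across genomes) enabling operon inheritance.
#' @param functional_link enable the functional-link rule (default
#'   `FALSE`).
#' @param annotations data.frame `genome_id`, `locus_tag`, `category`
#'   used by the functional-link rule.
#' @param threshold the scan threshold, required when
#'   `functional_link = TRUE`.
#' @return data.frame of accepted members: `genome_id`, `operon_id`,
#'   `gene_id`, `group_id`, `support`, `accepted_via`.
#' @export
consistency_filter <- function(hits, groups, regulator_group,
                               min_support = 2L, operons = NULL,
                               functional_link = FALSE,
                               annotations = NULL, threshold = NULL) {
  empty <- data.frame(genome_id = character(0), operon_id = character(0),
                      gene_id = character(0), group_id = character(0),
                      support = integer(0), accepted_via = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  reg_genomes <- unique(regulator_group$members$genome_id)
  outside <- !hits$genome_id %in% reg_genomes
  if (any(outside)) {
    warning(sprintf(
      "ignoring %d hit(s) in genome(s) without the orthologous regulator: %s",
      sum(outside), paste(unique(hits$genome_id[outside]), collapse = ", ")),
      call. = FALSE)
    hits <- hits[!outside, , drop = FALSE]
  }
  if (nrow(hits) == 0L) return(empty)
  key <- paste(hits$genome_id, hits$target_gene)
  gkey <- paste(groups$genome_id, groups$locus_tag)
  hits$group_id <- groups$group_id[match(key, gkey)]

  grouped <- hits[!is.na(hits$group_id), , drop = FALSE]
  support_by_group <- vapply(
    split(grouped$genome_id, grouped$group_id),
    function(g) length(unique(g)), integer(1))
  ok_groups <- names(support_by_group)[support_by_group >= min_support]

  accepted <- empty
  if (length(ok_groups) > 0L) {
    core <- grouped[grouped$group_id %in% ok_groups, , drop = FALSE]
    accepted <- data.frame(
      genome_id = core$genome_id,
      operon_id = core$target_operon,
      gene_id = core$target_gene,
      group_id = core$group_id,
      support = support_by_group[core$group_id],
      accepted_via = "conserved_site",
      stringsAsFactors = FALSE)
    accepted <- unique(accepted)
  }

  if (!is.null(operons) && nrow(accepted) > 0L) {
    op_index <- setNames(operons, vapply(operons, `[[`, character(1),
                                         "operon_id"))
    inherit <- list()
    for (k in seq_len(nrow(accepted))) {
      op <- op_index[[accepted$operon_id[k]]]
      if (is.null(op)) next
      others <- setdiff(op$gene_ids, accepted$gene_id[accepted$operon_id ==
                                                        op$operon_id])
      for (g in others) {
        inherit[[length(inherit) + 1L]] <- data.frame(
          genome_id = accepted$genome_id[k], operon_id = op$operon_id,
          gene_id = g, group_id = NA_character_,
          support = accepted$support[k],
          accepted_via = "operon_inheritance", stringsAsFactors = FALSE)
      }
    }
    if (length(inherit) > 0L) {
      accepted <- rbind(accepted, unique(do.call(rbind, inherit)))
    }
  }

  if (functional_link && nrow(accepted) > 0L) {
    if (is.null(threshold) || is.null(annotations)) {
      stopf("functional_link mode needs 'threshold' and 'annotations'")
    }
    akey <- paste(annotations$genome_id, annotations$locus_tag)
    member_cat <- unique(annotations$category[
      akey %in% paste(accepted$genome_id, accepted$gene_id)])
    member_cat <- member_cat[!is.na(member_cat) & nzchar(member_cat)]
    rest <- hits[!(paste(hits$genome_id, hits$target_gene) %in%
                     paste(accepted$genome_id, accepted$gene_id)), ,
                 drop = FALSE]
    strong <- rest[rest$score >= threshold + 2, , drop = FALSE]
    if (nrow(strong) > 0L && length(member_cat) > 0L) {
      cat_of <- annotations$category[match(
        paste(strong$genome_id, strong$target_gene), akey)]
      linked <- strong[!is.na(cat_of) & cat_of %in% member_cat, ,
                       drop = FALSE]
      if (nrow(linked) > 0L) {
        accepted <- rbind(accepted, unique(data.frame(
          genome_id = linked$genome_id, operon_id = linked$target_operon,
          gene_id = linked$target_gene,
          group_id = linked$group_id,
          support = 1L, accepted_via = "functional_link",
          stringsAsFactors = FALSE)))
      }
    }
  }
  accepted <- accepted[order(accepted$genome_id, accepted$operon_id,
                             accepted$gene_id), , drop = FALSE]
  rownames(accepted) <- NULL
  accepted
}

#' Assemble a regulon by iterative motif refinement
#'
#' Rebuilds the PWM from the sites of all accepted members, rescans
#' with the training-set minimum threshold, re-filters, and iterates
#' until the accepted set is a fixed point (capped at `max_rounds`;
#' `converged = FALSE` is reported if the cap is hit).
#'
#' @param model the seed `motif_model`.
#' @param regulator_group the regulator's ortholog group.
#' @param accepted initial accepted members from [consistency_filter()].
#' @param hits the hits that produced `accepted`.
#' @param regions scan regions (see [scan_regions()]).
#' @param groups ortholog map (see [consistency_filter()]).
#' @param operons optional operon list for inheritance.
#' @param min_support see [consistency_filter()].
#' @param max_rounds refinement cap (default 10).
#' @return object of class `regulon`: `regulator`, `members`
#'   (operon-level data.frame `operon_id`, `genome_id`, `support`,
#'   `accepted_via`, `genes`), `sites`, `model`, `threshold`,
#'   `converged`, `rounds`.
#' @export
assemble_regulon <- function(model, regulator_group, accepted, hits,
                             regions, groups, operons = NULL,
                             min_support = 2L, max_rounds = 10L) {
  if (nrow(accepted) == 0L) stopf("accepted member set is empty")
  state_key <- function(acc) {
    paste(acc$genome_id, acc$operon_id, acc$gene_id, acc$accepted_via,
          sep = "|", collapse = "\n")
  }
  converged <- FALSE
  rounds <- 0L
  cur_accepted <- accepted
  cur_hits <- hits
  cur_model <- model
  threshold <- NA_real_
  for (round in seq_len(max_rounds)) {
    rounds <- round
    member_key <- paste(cur_accepted$genome_id, cur_accepted$gene_id)
    member_hits <- cur_hits[paste(cur_hits$genome_id, cur_hits$target_gene)
                            %in% member_key, , drop = FALSE]
    if (nrow(member_hits) == 0L) break
    words <- vapply(member_hits$sequence, function(s) {
      hit_scoring_word(cur_model, s)
    }, character(1), USE.NAMES = FALSE)
    cur_model <- build_pwm(words, cur_model$background,
                           cur_model$pseudocount, cur_model$geometry)
    if (cur_model$geometry$kind == "palindrome") {
      cur_model <- symmetrize_model(cur_model)
    }
    threshold <- training_threshold(cur_model, "loo_min")
    new_hits <- scan_regions(cur_model, regions, threshold)
    new_accepted <- consistency_filter(new_hits, groups, regulator_group,
                                       min_support, operons)
    if (nrow(new_accepted) == 0L) break
    same <- identical(state_key(new_accepted), state_key(cur_accepted))
    cur_hits <- new_hits
    cur_accepted <- new_accepted
    if (same) {
      converged <- TRUE
      break
    }
  }
  member_key <- paste(cur_accepted$genome_id, cur_accepted$gene_id)
  site_rows <- cur_hits[paste(cur_hits$genome_id, cur_hits$target_gene) %in%
                          member_key, , drop = FALSE]
  ops <- split(cur_accepted, paste(cur_accepted$genome_id,
                                   cur_accepted$operon_id))
  members <- do.call(rbind, lapply(ops, function(m) {
    data.frame(operon_id = m$operon_id[1], genome_id = m$genome_id[1],
               support = max(m$support),
               accepted_via = if (any(m$accepted_via == "conserved_site")) {
                 "conserved_site"
               } else m$accepted_via[1],
               genes = paste(sort(m$gene_id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  members <- members[order(members$genome_id, members$operon_id), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(
    list(regulator = regulator_group, members = members,
         member_genes = cur_accepted, sites = site_rows,
         model = cur_model, threshold = threshold,
         converged = converged, rounds = rounds),
    class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> regulator %s: %d member operon(s) in %d genome(s), %d site(s)%s\n",
              x$regulator$group_id %||% "?", nrow(x$members),
              length(unique(x$members$genome_id)), nrow(x$sites),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Write a regulon as JSON
#'
#' Mirrors a RegPrecise-style record: regulator group, member operons
#' with support and acceptance route, and the supporting sites.
#'
#' @param regulon a `regulon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regulon_json <- function(regulon, path) {
  payload <- list(
    regulator = list(group_id = regulon$regulator$group_id,
                     members = regulon$regulator$members),
    threshold = regulon$threshold,
    converged = regulon$converged,
    members = regulon$members,
    sites = regulon$sites)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
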