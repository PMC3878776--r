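# PWM scanning of upstream regions. The scan threshold follows the
# training-set rule: the smallest score among the sites the PWM was
# built from, so every training site passes its own scan by
# construction.

#' Training-set minimum score threshold
#'
#' The scan threshold is the smallest score among the model's training
#' sites. With `method = "loo_min"` each training site is scored under
#' the PWM rebuilt from the *other* sites (leave-one-out), which
#' removes the self-counting inflation of small training sets; every
#' training site still passes the resulting threshold under the full
#' model, since leave-one-out scores are never higher than self
#' scores.
#'
#' @param model a `motif_model` with at least one training site.
#' @param method `"min"` (plain minimum, the default) or `"loo_min"`
#'   (leave-one-out minimum, used by the workflows to calibrate genome
#'   scans).
#' @return the threshold score in bits.
#' @export
training_threshold <- function(model, method = c("min", "loo_min")) {
  method <- match.arg(method)
  sites <- model$training_sites
  if (is.null(sites) || length(sites) == 0L) {
    stopf("model has no training sites")
  }
  if (method == "min" || length(sites) < 2L) {
    return(min(vapply(sites, function(s) score_word(model, s),
                      numeric(1))))
  }
  bg <- model$background
  pc <- model$pseudocount
  n <- model$n_sites
  L <- ncol(model$counts)
  min(vapply(sites, function(s) {
    codes <- dna_codes(s)
    if (anyNA(codes)) return(-Inf)
    idx <- cbind(codes, seq_len(L))
    counts_loo <- model$counts
    counts_loo[idx] <- counts_loo[idx] - 1L
    f <- (counts_loo[idx] + pc * bg[codes]) / (n - 1L + pc)
    sum(log2(f / bg[codes]))
  }, numeric(1)))
}

#' Scan upstream regions with a PWM
#'
#' Every start position is scored on both strands; per position the
#' better strand is reported (ties prefer the forward read of the
#' region). Positions scoring at least `threshold` become hits. For
#' direct-repeat models, overlapping hits closer than one center
#' distance are collapsed to the best-scoring one (ties to the smaller
#' position). Sites containing `N` score `-Inf` and never pass a finite
#' threshold.
#'
#' @param model a `motif_model`.
#' @param regions list of [extract_upstream()] regions. A region may
#'   carry an `operon_id` element, propagated to its hits.
#' @param threshold finite score cutoff in bits (inclusive), typically
#'   [training_threshold()].
#' @return data.frame of site hits sorted by (genome, contig,
#'   position): `genome_id`, `contig_id`, `position` (absolute 0-based
#'   start of the site on the contig), `strand` (contig strand),
#'   `score`, `sequence` (full site including any spacer, in scanned
#'   orientation), `target_gene`, `target_operon`, `region_offset`.
#' @export
scan_regions <- function(model, regions, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  g <- model$geometry
  tl <- g$total_len
  hits <- lapply(regions, function(r) {
    seq_fwd <- r$sequence
    n <- nchar(seq_fwd)
    if (n < tl) return(NULL)
    seq_rev <- revcomp(seq_fwd)
    sf <- score_positions(model, dna_codes(seq_fwd))
    sr <- score_positions(model, dna_codes(seq_rev))
    # map reverse-read starts into the forward frame of the region
    sr_fwd_frame <- rev(sr)
    use_rev <- sr_fwd_frame > sf
    sc <- ifelse(use_rev, sr_fwd_frame, sf)
    keep <- which(sc >= threshold)
    if (length(keep) == 0L) return(NULL)
    if (g$kind == "direct_repeat" && length(keep) > 1L) {
      # scores equal to within 1e-9 bits count as tied (guards the
      # smaller-position tie rule against summation-order jitter)
      ord <- keep[order(-round(sc[keep], 9), keep)]
      chosen <- integer(0)
      for (p in ord) {
        if (all(abs(p - chosen) >= g$center_distance)) chosen <- c(chosen, p)
      }
      keep <- sort(chosen)
    }
    offs <- keep - 1L                      # 0-based region offsets
    site_fwd <- substr(rep(seq_fwd, length(offs)), offs + 1L, offs + tl)
    site_seq <- ifelse(use_rev[keep], revcomp(site_fwd), site_fwd)
    # strand relative to the contig: region read direction XOR hit strand
    region_minus <- r$strand == "-"
    hit_minus <- xor(region_minus, use_rev[keep])
    data.frame(
      genome_id = r$genome_id,
      contig_id = r$contig_id,
      position = vapply(offs, function(o) {
        region_offset_to_absolute(r, o, tl)
      }, numeric(1)),
      strand = ifelse(hit_minus, "-", "+"),
      score = sc[keep],
      sequence = site_seq,
      target_gene = r$gene_id,
      target_operon = (r$operon_id %||% NA_character_),
      region_offset = offs,
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(genome_id = character(0), contig_id = character(0),
                       position = numeric(0), strand = character(0),
                       score = numeric(0), sequence = character(0),
                       target_gene = character(0),
                       target_operon = character(0),
                       region_offset = integer(0), stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$genome_id, hits$contig_id, hits$position), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# The scoring word of a hit: boxes only for direct repeats (spacer
# stripped), the full site otherwise.
#' @noRd
hit_scoring_word <- function(model, site_sequence) {
  g <- model$geometry
  if (g$kind == "direct_repeat") {
    paste0(substr(site_sequence, 1L, g$box_len),
           substr(site_sequence, g$box_len + g$spacer + 1L, g$total_len))
  } else {
    site_sequence
  }
}

#' Write site hits as TSV
#'
#' @param hits data.frame from [scan_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
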