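# Operon prediction by the standard prokaryotic distance heuristic:
# consecutive genes on the same strand and contig whose intergenic gap is
# at most max_gap are transcribed together.

#' Predict operons from gene coordinates
#'
#' Groups consecutive same-strand genes whose intergenic gap is at most
#' `max_gap` base pairs. Every gene belongs to exactly one operon;
#' isolated genes form singleton operons. The leader is the 5'-most gene
#' in transcription order (smallest start on `+`, largest end on `-`).
#'
#' @param genome a [genome_record()].
#' @param max_gap maximum intergenic distance in bp (default 100).
#' @return list of operons, each a list with `operon_id`, `genome_id`,
#'   `contig_id`, `strand`, `gene_ids` (transcription order) and
#'   `leader_gene`.
#' @export
predict_operons <- function(genome, max_gap = 100L) {
  ft <- genome$features
  operons <- list()
  if (nrow(ft) == 0L) return(operons)
  for (contig in unique(ft$contig_id)) {
    sub <- ft[ft$contig_id == contig, ]
    sub <- sub[order(sub$start, sub$locus_tag), ]
    run_id <- integer(nrow(sub))
    current <- 1L
    run_id[1] <- current
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        gap <- sub$start[i] - sub$end[i - 1L]
        if (sub$strand[i] != sub$strand[i - 1L] || gap > max_gap) {
          current <- current + 1L
        }
        run_id[i] <- current
      }
    }
    for (r in unique(run_id)) {
      genes <- sub[run_id == r, ]
      strand <- genes$strand[1]
      # transcription order: coordinate order on +, reverse on -
      ord <- order(genes$start)
      if (strand == "-") ord <- rev(ord)
      gene_ids <- genes$locus_tag[ord]
      operons[[length(operons) + 1L]] <- list(
        operon_id = sprintf("%s_op%04d", genome$genome_id,
                            length(operons) + 1L),
        genome_id = genome$genome_id,
        contig_id = contig,
        strand = strand,
        gene_ids = gene_ids,
        leader_gene = gene_ids[1])
    }
  }
  operons
}

#' Extract the upstream region of a gene
#'
#' Returns the window `(from, to)` relative to the translation start,
#' default -400..+50, read 5' to 3' toward the gene; for `-` strand
#' genes the genomic slice is reverse complemented. The window is
#' clamped at contig boundaries. By default the region may run into the
#' previous gene's coding sequence; `truncate_at_neighbor = TRUE` cuts it
#' at the nearest upstream feature boundary instead.
#'
#' @param genome a [genome_record()].
#' @param gene locus tag of the gene.
#' @param window integer pair `c(from, to)` relative to the translation
#'   start (default `c(-400, 50)`).
#' @param truncate_at_neighbor cut the window at the 3' boundary of the
#'   closest upstream gene (default `FALSE`, the literal window).
#' @return an object of class `upstream_region` with fields `genome_id`,
#'   `gene_id`, `window`, `sequence`, `contig_id`, `start`, `end`,
#'   `strand` (`start`/`end` are the absolute 0-based half-open span).
#' @export
extract_upstream <- function(genome, gene, window = c(-400L, 50L),
                             truncate_at_neighbor = FALSE) {
  f <- get_feature(genome, gene)
  contig <- genome$contigs[[f$contig_id]]
  clen <- nchar(contig)
  if (f$strand == "+") {
    s0 <- f$start + window[1]
    e0 <- f$start + window[2]
  } else {
    s0 <- f$end - window[2]
    e0 <- f$end - window[1]
  }
  s <- max(0L, s0)
  e <- min(clen, e0)
  if (truncate_at_neighbor) {
    ft <- genome$features[genome$features$contig_id == f$contig_id, ]
    ft <- ft[ft$locus_tag != gene, ]
    if (f$strand == "+") {
      prev_end <- ft$end[ft$end <= f$start]
      if (length(prev_end) > 0L) s <- max(s, max(prev_end))
    } else {
      nxt_start <- ft$start[ft$start >= f$end]
      if (length(nxt_start) > 0L) e <- min(e, min(nxt_start))
    }
  }
  if (e <= s) stopf("empty upstream window for gene %s", gene)
  seq <- substr(contig, s + 1L, e)
  if (f$strand == "-") seq <- revcomp(seq)
  structure(
    list(genome_id = genome$genome_id, gene_id = gene,
         window = as.integer(window), sequence = seq,
         contig_id = f$contig_id, start = s, end = e, strand = f$strand),
    class = "upstream_region")
}

#' @export
print.upstream_region <- function(x, ...) {
  cat(sprintf("<upstream_region> %s/%s %s:[%d,%d)%s, %d bp\n",
              x$genome_id, x$gene_id, x$contig_id, x$start, x$end,
              x$strand, nchar(x$sequence)))
  invisible(x)
}

# Map an offset within the region sequence (0-based, 5'->3' toward the
# gene) to the absolute 0-based position of that base on the contig.
#' @noRd
region_offset_to_absolute <- function(region, offset, site_len = 1L) {
  if (region$strand == "+") {
    region$start + offset
  } else {
    region$end - offset - site_len
  }
}

#' Write regions or hits as BED6
#'
#' Regions are written 0-based half-open with the locus tag as name and
#' score 0; site hits carry their PWM score scaled by 100.
#'
#' @param x list of `upstream_region` objects or a site-hit data.frame
#'   as returned by [scan_regions()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(x, path) {
  if (is.data.frame(x)) {
    bed <- data.frame(chrom = x$contig_id, start = x$position,
                      end = x$position + nchar(x$sequence),
                      name = x$target_gene,
                      score = round(x$score * 100),
                      strand = x$strand, stringsAsFactors = FALSE)
  } else {
    bed <- do.call(rbind, lapply(x, function(r) {
      data.frame(chrom = r$contig_id, start = r$start, end = r$end,
                 name = r$gene_id, score = 0, strand = r$strand,
                 stringsAsFactors = FALSE)
    }))
  }
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
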