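# Phylogenetic footprinting: conserved blocks ("islands") in global
# multiple alignments of orthologous upstream regions supply the
# candidate binding sites. Functional sites diverge more slowly than
# the surrounding intergenic sequence, so islands stand out against the
# background identity of diverged spacer DNA.

# Column identity: mean pairwise identity among the non-gap rows of the
# column; columns with more than 50% gaps score 0. The pairwise mean is
# used (rather than the majority-character frequency) because it stays
# near (1 - d)^2 for background diverged by d per branch, keeping the
# island threshold discriminative even for closely related genomes
# where the per-column majority is still high.
#' @noRd
column_identity <- function(aln) {
  chars <- do.call(rbind, strsplit(unlist(aln$rows), "", fixed = TRUE))
  n <- nrow(chars)
  vapply(seq_len(ncol(chars)), function(j) {
    col <- chars[, j]
    non_gap <- col[col != "-"]
    k <- length(non_gap)
    if (k <= n / 2 || k < 2L) return(0)
    counts <- tabulate(factor(non_gap, levels = c(DNA_BASES4, "N")))
    sum(counts * (counts - 1L)) / (k * (k - 1L))
  }, numeric(1))
}

#' Detect conservation islands in an upstream alignment
#'
#' Scans the alignment with a sliding window of `window_len` columns and
#' reports maximal runs of columns covered by at least one window whose
#' mean column identity reaches `min_identity`. Islands never overlap.
#'
#' @param aln an `upstream_alignment` from [align_upstreams()].
#' @param window_len sliding window width in columns (default 10).
#' @param min_identity window mean identity threshold (default 0.8);
#'   must comfortably exceed the ~0.25 background identity of diverged
#'   DNA.
#' @return list of `conservation_island` objects: `start`, `end`
#'   (1-based inclusive alignment columns), `mean_identity`, and `rows`,
#'   a data.frame with per-row ungapped `sequence` plus `from`/`to`
#'   (0-based half-open offsets into the original region) and absolute
#'   `contig_id`/`abs_start`/`abs_end` when the alignment carries
#'   regions.
#' @export
find_islands <- function(aln, window_len = 10L, min_identity = 0.8) {
  if (window_len > aln$ncol) stopf("window_len exceeds alignment length")
  ident <- column_identity(aln)
  nwin <- aln$ncol - window_len + 1L
  means <- vapply(seq_len(nwin), function(w) {
    mean(ident[w:(w + window_len - 1L)])
  }, numeric(1))
  covered <- logical(aln$ncol)
  for (w in which(means >= min_identity)) {
    covered[w:(w + window_len - 1L)] <- TRUE
  }
  if (!any(covered)) return(list())
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  islands <- list()
  for (k in which(runs$values)) {
    s <- starts[k]
    e <- ends[k]
    # trim edges until the boundary columns are themselves conserved,
    # so a window overrunning into diverged flanks does not stretch
    # the reported span
    while (s < e && ident[s] < min_identity) s <- s + 1L
    while (e > s && ident[e] < min_identity) e <- e - 1L
    if (e - s + 1L < 2L) next
    islands[[length(islands) + 1L]] <- make_island(aln, s, e, ident)
  }
  islands
}

#' @noRd
make_island <- function(aln, start, end, ident) {
  rows <- lapply(seq_along(aln$rows), function(i) {
    chars <- strsplit(aln$rows[[i]], "", fixed = TRUE)[[1]]
    non_gap_before <- cumsum(chars != "-")
    block <- chars[start:end]
    seq <- paste(block[block != "-"], collapse = "")
    from <- if (start > 1L) non_gap_before[start - 1L] else 0L
    to <- non_gap_before[end]
    out <- data.frame(region_id = aln$region_ids[i], sequence = seq,
                      from = from, to = to, stringsAsFactors = FALSE)
    if (!is.null(aln$regions)) {
      r <- aln$regions[[i]]
      if (r$strand == "+") {
        out$abs_start <- r$start + from
        out$abs_end <- r$start + to
      } else {
        out$abs_start <- r$end - to
        out$abs_end <- r$end - from
      }
      out$contig_id <- r$contig_id
    }
    out
  })
  structure(
    list(start = start, end = end,
         mean_identity = mean(ident[start:end]),
         rows = do.call(rbind, rows)),
    class = "conservation_island")
}

#' @export
print.conservation_island <- function(x, ...) {
  cat(sprintf("<conservation_island> columns %d-%d, mean identity %.2f, %d rows\n",
              x$start, x$end, x$mean_identity, nrow(x$rows)))
  invisible(x)
}

#' Candidate binding sites from conservation islands
#'
#' Without a geometry, emits every per-row ungapped island subsequence
#' verbatim as motif-discovery input. With a direct-repeat geometry,
#' island pairs whose center-to-center distance matches the geometry's
#' `box_len + spacer` (within `tol` columns) are combined: for each row,
#' two `box_len` windows centered on the per-row island centers are cut
#' from the original region sequence and concatenated into one two-box
#' site.
#'
#' @param islands list of islands from [find_islands()].
#' @param geometry optional [motif_geometry()] of kind `direct_repeat`.
#' @param region_seqs named character vector of the original region
#'   sequences (required for geometry pairing; names = region ids).
#' @param tol tolerance on the center distance in columns (default 2).
#' @return character vector of candidate site strings.
#' @export
candidate_sites_from_islands <- function(islands, geometry = NULL,
                                         region_seqs = NULL, tol = 2L) {
  if (length(islands) == 0L) stopf("islands must be non-empty")
  if (is.null(geometry)) {
    return(unlist(lapply(islands, function(isl) {
      s <- isl$rows$sequence
      s[nzchar(s)]
    }), use.names = FALSE))
  }
  stopifnot(geometry$kind == "direct_repeat")
  if (is.null(region_seqs)) {
    stopf("region_seqs required when pairing islands by geometry")
  }
  b <- geometry$box_len
  target <- geometry$center_distance
  sites <- character(0)
  if (length(islands) >= 2L) {
    for (i in seq_len(length(islands) - 1L)) {
      for (j in (i + 1L):length(islands)) {
        ri <- islands[[i]]$rows
        rj <- islands[[j]]$rows
        shared <- intersect(ri$region_id, rj$region_id)
        for (id in shared) {
          a <- ri[ri$region_id == id, ]
          z <- rj[rj$region_id == id, ]
          c1 <- (a$from + a$to - 1) / 2
          c2 <- (z$from + z$to - 1) / 2
          if (abs(abs(c2 - c1) - target) > tol) next
          seq <- region_seqs[[id]]
          cut_box <- function(center) {
            s <- round(center - (b - 1) / 2)
            if (s < 0 || s + b > nchar(seq)) return(NA_character_)
            substr(seq, s + 1L, s + b)
          }
          box1 <- cut_box(min(c1, c2))
          box2 <- cut_box(max(c1, c2))
          if (!is.na(box1) && !is.na(box2)) {
            sites <- c(sites, paste0(box1, box2))
          }
        }
      }
    }
  }
  sites
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an `upstream_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in aln$region_ids) {
    writeLines(c(paste0(">", id), aln$rows[[id]]), con)
  }
  invisible(path)
}

#' Write islands as TSV
#'
#' @param islands list of islands from [find_islands()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_islands_tsv <- function(islands, path) {
  rows <- do.call(rbind, lapply(islands, function(isl) {
    cbind(aln_start = isl$start, aln_end = isl$end,
          mean_identity = isl$mean_identity, isl$rows)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
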