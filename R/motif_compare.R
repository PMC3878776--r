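# Pairwise PWM similarity and clustering. Two frequency matrices are
# compared by the Pearson correlation of their aligned columns over all
# offsets (both orientations), and the all-pairs similarity matrix is
# clustered by average linkage on d = 1 - r, yielding the ordered
# matrix behind a motif-similarity heat map.

#' Compare two PWMs by Pearson correlation over offsets
#'
#' Slides `b` (in both orientations) along `a` over all offsets keeping
#' at least `min_overlap` aligned columns, computes the Pearson
#' correlation of the flattened aligned frequency submatrices, and
#' returns the best offset. Offset ties prefer the smaller absolute
#' offset, then the forward orientation. The p-value is from a
#' column-shuffle permutation null.
#'
#' @param a,b `motif_model` objects.
#' @param min_overlap minimum aligned columns (default 4).
#' @param n_perm permutation count for the p-value (default 1000).
#' @param seed RNG seed for the permutation null.
#' @return list with `motif_a`, `motif_b`, `best_offset`,
#'   `orientation` (`"forward"`/`"reverse"`), `correlation`, `p_value`.
#' @export
compare_pwms <- function(a, b, min_overlap = 4L, n_perm = 1000L,
                         seed = 1L) {
  fa <- a$freq
  fb <- b$freq
  if (min_overlap < 4L) min_overlap <- 4L
  if (min(ncol(fa), ncol(fb)) < min_overlap) {
    stopf("motifs too short for min_overlap = %d", min_overlap)
  }
  best <- best_offset_cor(fa, fb, min_overlap)
  pv <- 1
  if (n_perm > 0L) {
    obs <- best$correlation
    hits <- 0L
    withr::with_seed(seed, {
      for (k in seq_len(n_perm)) {
        perm <- fb[, sample.int(ncol(fb)), drop = FALSE]
        if (best_offset_cor(fa, perm, min_overlap)$correlation >=
            obs - 1e-12) {
          hits <- hits + 1L
        }
      }
    })
    pv <- (hits + 1L) / (n_perm + 1L)
  }
  list(motif_a = attr(a, "name") %||% NA_character_,
       motif_b = attr(b, "name") %||% NA_character_,
       best_offset = best$offset, orientation = best$orientation,
       correlation = best$correlation, p_value = pv)
}

#' @noRd
best_offset_cor <- function(fa, fb, min_overlap) {
  la <- ncol(fa)
  candidates <- list()
  for (orientation in c("forward", "reverse")) {
    fbo <- if (orientation == "forward") fb else revcomp_freq(fb)
    lb <- ncol(fbo)
    for (off in (-(lb - min_overlap)):(la - min_overlap)) {
      a_from <- max(1L, 1L + off)
      a_to <- min(la, lb + off)
      if (a_to - a_from + 1L < min_overlap) next
      b_from <- a_from - off
      b_to <- a_to - off
      va <- as.vector(fa[, a_from:a_to])
      vb <- as.vector(fbo[, b_from:b_to])
      r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) 0 else cor(va, vb)
      candidates[[length(candidates) + 1L]] <- list(
        offset = off, orientation = orientation, correlation = r)
    }
  }
  ord <- order(-vapply(candidates, `[[`, numeric(1), "correlation"),
               abs(vapply(candidates, `[[`, numeric(1), "offset")),
               vapply(candidates, `[[`, character(1), "orientation") !=
                 "forward")
  candidates[[ord[1]]]
}

#' All-pairs motif similarity
#'
#' @param models named list of `motif_model` objects.
#' @param min_overlap,n_perm,seed see [compare_pwms()].
#' @return data.frame with one row per unordered pair: `motif_a`,
#'   `motif_b`, `best_offset`, `orientation`, `correlation`, `p_value`.
#' @export
compare_all_pwms <- function(models, min_overlap = 4L, n_perm = 0L,
                             seed = 1L) {
  if (is.null(names(models))) names(models) <- paste0("motif", seq_along(models))
  ids <- names(models)
  rows <- list()
  for (i in seq_along(models)) {
    for (j in seq_len(i)) {
      cmp <- compare_pwms(models[[j]], models[[i]], min_overlap,
                          n_perm = if (i == j) 0L else n_perm, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_a = ids[j], motif_b = ids[i], best_offset = cmp$best_offset,
        orientation = cmp$orientation, correlation = cmp$correlation,
        p_value = cmp$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cluster motifs by similarity
#'
#' Average-linkage agglomerative clustering on distance `d = 1 - r`.
#'
#' @param similarities all-pairs table from [compare_all_pwms()]; every
#'   unordered pair must be present.
#' @return list of class `motif_dendrogram`: `hclust` (the merge
#'   history), `cophenetic` (distance matrix), `order` (leaf order for
#'   heat-map rendering), `distance` (the input distance matrix).
#' @export
cluster_motifs <- function(similarities) {
  ids <- sort(unique(c(similarities$motif_a, similarities$motif_b)))
  n <- length(ids)
  D <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (k in seq_len(nrow(similarities))) {
    i <- similarities$motif_a[k]
    j <- similarities$motif_b[k]
    D[i, j] <- D[j, i] <- 1 - similarities$correlation[k]
  }
  if (anyNA(D)) {
    miss <- which(is.na(D), arr.ind = TRUE)[1, ]
    stopf("missing similarity for pair (%s, %s)", ids[miss[1]], ids[miss[2]])
  }
  if (n == 1L) {
    return(structure(list(hclust = NULL, cophenetic = D, order = ids,
                          distance = D), class = "motif_dendrogram"))
  }
  hc <- hclust(as.dist(D), method = "average")
  structure(
    list(hclust = hc, cophenetic = as.matrix(cophenetic(hc)),
         order = ids[hc$order], distance = D),
    class = "motif_dendrogram")
}

#' @export
print.motif_dendrogram <- function(x, ...) {
  cat(sprintf("<motif_dendrogram> %d motifs; leaf order: %s\n",
              length(x$order), paste(x$order, collapse = ", ")))
  invisible(x)
}

#' Cut a motif dendrogram into families
#'
#' @param dendrogram a `motif_dendrogram`.
#' @param k number of families.
#' @return named integer vector of family labels.
#' @export
cut_motif_families <- function(dendrogram, k) {
  if (is.null(dendrogram$hclust)) {
    return(setNames(1L, dendrogram$order))
  }
  cutree(dendrogram$hclust, k = k)
}

#' Write a motif dendrogram as newick
#'
#' @param dendrogram a `motif_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  if (is.null(dendrogram$hclust)) {
    writeLines(sprintf("(%s);", dendrogram$order), path)
    return(invisible(path))
  }
  ape::write.tree(ape::as.phylo(dendrogram$hclust), path)
  invisible(path)
}

#' Write the clustered similarity matrix as TSV
#'
#' Rows and columns follow the dendrogram leaf order, ready for
#' heat-map rendering.
#'
#' @param dendrogram a `motif_dendrogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ordered_matrix_tsv <- function(dendrogram, path) {
  M <- 1 - dendrogram$distance[dendrogram$order, dendrogram$order,
                               drop = FALSE]
  out <- cbind(data.frame(motif = rownames(M), stringsAsFactors = FALSE),
               as.data.frame(M))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
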