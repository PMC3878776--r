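# Built-in progressive DNA aligner used for phylogenetic footprinting.
# Global (Needleman-Wunsch) profile-profile alignment with a linear gap
# penalty; the linear penalty lets each DP row be computed with a
# vectorised running-maximum, which keeps pure-R alignment of ~450-bp
# upstream regions fast. The aligner is pluggable: any engine whose
# output degaps back to the input rows satisfies the module contract.

#' @noRd
profile_from_rows <- function(rows) {
  n <- length(rows)
  L <- nchar(rows[1])
  mat <- matrix(0, 4L, L, dimnames = list(DNA_BASES4, NULL))
  for (r in rows) {
    codes <- dna_codes(r)
    ok <- which(!is.na(codes))
    if (length(ok) > 0L) {
      idx <- cbind(codes[ok], ok)
      mat[idx] <- mat[idx] + 1
    }
  }
  mat / n
}

# Global alignment of two profiles (4 x L frequency matrices).
# Returns per-output-column source indices (0 = gap) for both sides.
#' @noRd
nw_profile <- function(P, Q, match = 1, mismatch = -1, gap = -2) {
  nP <- ncol(P)
  nQ <- ncol(Q)
  subst <- matrix(mismatch, 4L, 4L)
  diag(subst) <- match
  S <- crossprod(P, subst %*% Q)          # nP x nQ expected column scores
  M <- matrix(0, nP + 1L, nQ + 1L)
  M[1L, ] <- gap * (0:nQ)
  M[, 1L] <- gap * (0:nP)
  gj <- gap * (0:nQ)
  for (i in seq_len(nP)) {
    A <- c(M[i + 1L, 1L],
           pmax(M[i, 1:nQ] + S[i, ], M[i, 2:(nQ + 1L)] + gap))
    M[i + 1L, ] <- cummax(A - gj) + gj
  }
  # traceback, deterministic preference: diagonal, then up, then left
  eps <- 1e-9
  i <- nP; j <- nQ
  src_p <- integer(0); src_q <- integer(0)
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        abs(here - (M[i, j] + S[i, j])) < eps) {
      src_p <- c(i, src_p); src_q <- c(j, src_q)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && abs(here - (M[i, j + 1L] + gap)) < eps) {
      src_p <- c(i, src_p); src_q <- c(0L, src_q)
      i <- i - 1L
    } else {
      src_p <- c(0L, src_p); src_q <- c(j, src_q)
      j <- j - 1L
    }
  }
  list(score = M[nP + 1L, nQ + 1L], src_p = src_p, src_q = src_q)
}

#' @noRd
expand_rows <- function(rows, src) {
  vapply(rows, function(r) {
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    out <- rep("-", length(src))
    out[src > 0L] <- chars[src[src > 0L]]
    paste(out, collapse = "")
  }, character(1))
}

#' Progressive global multiple alignment of upstream regions
#'
#' Builds a guide tree (average-linkage on pairwise alignment
#' distances) and merges profiles progressively with global
#' profile-profile alignment (match +1, mismatch -1, gap -2 by
#' default). Deterministic for a given input.
#'
#' @param regions list of [extract_upstream()] regions, or a named
#'   character vector of DNA sequences.
#' @param match,mismatch,gap scoring parameters.
#' @return object of class `upstream_alignment`: `region_ids`, `rows`
#'   (named character vector of equal-length gapped rows), `ncol`, and
#'   `regions` (the inputs, for coordinate mapping).
#' @export
align_upstreams <- function(regions, match = 1, mismatch = -1, gap = -2) {
  if (is.character(regions)) {
    seqs <- regions
    if (is.null(names(seqs))) names(seqs) <- paste0("r", seq_along(seqs))
    region_objs <- NULL
  } else {
    seqs <- vapply(regions, function(r) r$sequence, character(1))
    names(seqs) <- vapply(regions, function(r) {
      paste(r$genome_id, r$gene_id, sep = "/")
    }, character(1))
    region_objs <- regions
  }
  if (length(seqs) < 2L) stopf("need at least 2 regions to align")
  if (anyDuplicated(names(seqs))) stopf("duplicate region ids")
  n <- length(seqs)
  profiles <- lapply(seqs, function(s) {
    list(rows = setNames(s, NA), freq = profile_from_rows(s))
  })
  for (k in seq_len(n)) names(profiles[[k]]$rows) <- names(seqs)[k]

  if (n == 2L) {
    order_merge <- matrix(c(-1L, -2L), 1L)
  } else {
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- nw_profile(profiles[[i]]$freq, profiles[[j]]$freq,
                         match, mismatch, gap)
        a <- expand_rows(seqs[i], al$src_p)
        b <- expand_rows(seqs[j], al$src_q)
        ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
        D[i, j] <- D[j, i] <- 1 - mean(ca == cb)
      }
    }
    hc <- hclust(as.dist(D), method = "average")
    order_merge <- hc$merge
  }
  merged <- vector("list", nrow(order_merge))
  fetch <- function(id) if (id < 0L) profiles[[-id]] else merged[[id]]
  for (m in seq_len(nrow(order_merge))) {
    left <- fetch(order_merge[m, 1L])
    right <- fetch(order_merge[m, 2L])
    al <- nw_profile(left$freq, right$freq, match, mismatch, gap)
    rows <- c(expand_rows(left$rows, al$src_p),
              expand_rows(right$rows, al$src_q))
    merged[[m]] <- list(rows = rows, freq = profile_from_rows(rows))
  }
  final <- merged[[nrow(order_merge)]]
  rows <- final$rows[names(seqs)]            # restore input order
  structure(
    list(region_ids = names(seqs), rows = rows,
         ncol = nchar(rows[[1]]), regions = region_objs),
    class = "upstream_alignment")
}

#' @export
print.upstream_alignment <- function(x, ...) {
  cat(sprintf("<upstream_alignment> %d rows x %d columns\n",
              length(x$rows), x$ncol))
  invisible(x)
}

#' Remove gaps from an alignment row
#'
#' @param aln an `upstream_alignment`.
#' @param id region id of the row.
#' @return the original ungapped sequence.
#' @export
degap_row <- function(aln, id) {
  gsub("-", "", aln$rows[[id]], fixed = TRUE)
}
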