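# Palindrome-constrained motif discovery by expectation maximisation.
# A one-occurrence-per-sequence (OOPS) model: each sequence carries
# exactly one site of fixed length; the E-step distributes posterior
# weight over start positions, the M-step re-estimates the frequency
# matrix and then symmetrises it,
#   f[b, j] <- (f[b, j] + f[comp(b), L - 1 - j]) / 2,
# so the matrix is exactly reverse-complement symmetric after every
# iteration - the formal counterpart of searching for a palindrome with
# the highest information content. A zero-or-one (ZOOPS) variant is
# available by flag for inputs where some sequences may lack a site.

COMP_IDX <- c(4L, 3L, 2L, 1L)   # A<->T, C<->G in the ACGT row order

#' @noRd
revcomp_freq <- function(f) {
  out <- f[COMP_IDX, rev(seq_len(ncol(f))), drop = FALSE]
  rownames(out) <- rownames(f)
  out
}

#' Discover a palindromic motif by symmetry-constrained EM
#'
#' @param sequences DNA strings (>= 3).
#' @param motif_len site length in bp (even length recommended for a
#'   palindrome).
#' @param n_restarts random restarts (default 20); the best restart by
#'   information content is returned.
#' @param seed RNG seed; deterministic given it.
#' @param background base frequencies; default estimated from the
#'   input.
#' @param pseudocount smoothing added in the M-step (default 0.5).
#' @param zoops use the zero-or-one-occurrence model with prior
#'   `site_prior` (default `FALSE`, i.e. OOPS).
#' @param site_prior prior probability that a sequence has a site under
#'   ZOOPS (default 0.5).
#' @param tol convergence threshold on `max |delta f|` (default 1e-6).
#' @param max_iter EM iteration cap (default 200).
#' @return a `motif_model` of kind `palindrome` whose frequency matrix
#'   is exactly reverse-complement symmetric; attribute `occupancy`
#'   holds the maximum-posterior site per sequence and attribute
#'   `iterations` the iteration count of the winning restart.
#' @export
discover_palindrome_em <- function(sequences, motif_len, n_restarts = 20L,
                                   seed = 1L, background = NULL,
                                   pseudocount = 0.5, zoops = FALSE,
                                   site_prior = 0.5, tol = 1e-6,
                                   max_iter = 200L) {
  if (length(sequences) < 3L) stopf("need at least 3 sequences")
  motif_len <- as.integer(motif_len)
  if (motif_len > min(nchar(sequences))) {
    stopf("motif_len %d exceeds the shortest sequence", motif_len)
  }
  background <- check_background(background %||% base_frequencies(sequences))
  codes <- lapply(sequences, dna_codes)
  n <- length(sequences)
  L <- motif_len

  # per-sequence position matrices: np x L integer base codes
  pos_codes <- lapply(codes, function(cc) {
    np <- length(cc) - L + 1L
    idx <- outer(seq_len(np) - 1L, 0:(L - 1L), "+") + 1L
    matrix(cc[idx], np, L)
  })
  log_bg <- log(background)

  run_em <- function(f0) {
    f <- f0
    iterations <- 0L
    for (iter in seq_len(max_iter)) {
      iterations <- iter
      logf <- log(f)
      Cn <- matrix(0, 4L, L)
      total_w <- 0
      for (i in seq_len(n)) {
        pc <- pos_codes[[i]]
        lodds <- logf[cbind(as.vector(pc), rep(seq_len(L), each = nrow(pc)))] -
          log_bg[as.vector(pc)]
        lodds[is.na(lodds)] <- -Inf
        llr <- rowSums(matrix(lodds, nrow(pc), L))
        m <- max(llr)
        if (!is.finite(m)) next
        w <- exp(llr - m)
        if (zoops) {
          w0 <- (1 - site_prior) / site_prior * nrow(pc) * exp(-m)
          w <- w / (sum(w) + w0)
        } else {
          w <- w / sum(w)
        }
        for (j in seq_len(L)) {
          bj <- pc[, j]
          ok <- !is.na(bj)
          if (any(ok)) {
            Cn[, j] <- Cn[, j] +
              rowsum_weights(bj[ok], w[ok])
          }
        }
        total_w <- total_w + sum(w)
      }
      f_new <- (Cn + pseudocount * background) / (total_w + pseudocount)
      f_new <- (f_new + revcomp_freq(f_new)) / 2
      delta <- max(abs(f_new - f))
      f <- f_new
      if (delta < tol) break
    }
    list(f = f, ic = sum(f * log2(f / background)), iterations = iterations)
  }

  withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      i <- sample.int(n, 1L)
      np <- nrow(pos_codes[[i]])
      p <- sample.int(np, 1L)
      word <- pos_codes[[i]][p, ]
      f0 <- matrix(background, 4L, L)
      ok <- which(!is.na(word))
      f0[cbind(word[ok], ok)] <- f0[cbind(word[ok], ok)] + 1
      f0 <- sweep(f0, 2L, colSums(f0), "/")
      f0 <- (f0 + revcomp_freq(f0)) / 2
      fit <- run_em(f0)
      if (is.null(best) || fit$ic > best$ic + 1e-12) best <- fit
    }
    finalize_palindrome(best, sequences, codes, pos_codes, background,
                        pseudocount)
  })
}

# Re-impose exact reverse-complement symmetry on a model rebuilt from
# hard site counts (used when refining a palindromic regulon).
#' @noRd
symmetrize_model <- function(model) {
  f <- (model$freq + revcomp_freq(model$freq)) / 2
  model$freq <- f
  model$pwm <- log2(f / model$background)
  model$ic <- colSums(f * log2(f / model$background))
  model
}

#' @noRd
rowsum_weights <- function(bases, w) {
  out <- numeric(4L)
  agg <- rowsum(w, bases)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' @noRd
finalize_palindrome <- function(best, sequences, codes, pos_codes,
                                background, pseudocount) {
  f <- best$f
  L <- ncol(f)
  geometry <- motif_geometry("palindrome", total_len = L)
  pwm <- log2(f / background)
  # hard (maximum-posterior) occurrences for reporting and thresholds
  occ <- do.call(rbind, lapply(seq_along(codes), function(i) {
    pc <- pos_codes[[i]]
    sc <- vapply(seq_len(nrow(pc)), function(p) {
      v <- pwm[cbind(pc[p, ], seq_len(L))]
      if (anyNA(v)) -Inf else sum(v)
    }, numeric(1))
    p <- which.max(sc)
    data.frame(seq_index = i, position = p, strand = "+",
               site = codes_to_dna(pc[p, ]), stringsAsFactors = FALSE)
  }))
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES4, NULL))
  for (s in occ$site) {
    cc <- dna_codes(s)
    ok <- which(!is.na(cc))
    counts[cbind(cc[ok], ok)] <- counts[cbind(cc[ok], ok)] + 1L
  }
  dimnames(f) <- list(DNA_BASES4, NULL)
  model <- structure(
    list(geometry = geometry, counts = counts, freq = f, pwm = pwm,
         ic = colSums(f * log2(f / background)), background = background,
         pseudocount = pseudocount, n_sites = nrow(occ),
         training_sites = occ$site),
    class = "motif_model")
  attr(model, "occupancy") <- occ
  attr(model, "iterations") <- best$iterations
  model
}
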