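# Synthetic multi-genome benchmark with planted regulons. The emulated
# study design: a set of related genomes sharing one-to-one ortholog
# families (star phylogeny - each genome diverges independently from a
# common ancestor by i.i.d. per-base substitution), a regulator gene
# whose neighboring operons carry planted binding sites of a chosen
# geometry, optionally a global palindromic motif, and i.i.d.
# background at a configurable GC content. Sites are planted after
# divergence, i.e. they are conserved across genomes the way functional
# sites are under purifying selection, which is exactly the signal
# phylogenetic footprinting and the consistency check exploit.

#' Synthetic benchmark configuration
#'
#' @param n_genomes number of genomes (default 5).
#' @param genes_per_genome genes per genome (default 24).
#' @param gene_codons protein length in codons incl. start/stop
#'   (default 150, i.e. 450 bp genes).
#' @param intergenic_len intergenic spacer length in bp (default 500;
#'   must fit the -350..-30 planting window).
#' @param gc_content background GC fraction (default 0.43, a
#'   Bacteroides-like value).
#' @param divergence expected substitutions per site between each
#'   genome and the ancestor (default 0.2).
#' @param regulators list of regulator specs from [regulator_spec()].
#' @param global_palindrome optional IUPAC consensus of a global
#'   palindromic motif (e.g. a 22-bp Crp-like palindrome).
#' @param n_palindrome_targets target operons of the global motif
#'   (default 4).
#' @param seed RNG seed; output is byte-identical given the seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_genomes = 5L, genes_per_genome = 24L,
                         gene_codons = 150L, intergenic_len = 500L,
                         gc_content = 0.43, divergence = 0.2,
                         regulators = list(regulator_spec()),
                         global_palindrome = NULL,
                         n_palindrome_targets = 4L, seed = 1L) {
  if (gc_content <= 0 || gc_content >= 1) stopf("gc_content must be in (0,1)")
  if (divergence < 0 || divergence > 1) stopf("divergence must be in [0,1]")
  if (intergenic_len < 360L) {
    stopf("intergenic_len %d cannot hold the -350..-30 planting window",
          intergenic_len)
  }
  for (r in regulators) {
    if (r$geometry$total_len > 320L) {
      stopf("site length %d exceeds the planting window",
            r$geometry$total_len)
    }
    if (r$site_rate < 0 || r$site_rate > 1) stopf("site_rate must be in [0,1]")
  }
  structure(list(n_genomes = as.integer(n_genomes),
                 genes_per_genome = as.integer(genes_per_genome),
                 gene_codons = as.integer(gene_codons),
                 intergenic_len = as.integer(intergenic_len),
                 gc_content = gc_content, divergence = divergence,
                 regulators = regulators,
                 global_palindrome = global_palindrome,
                 n_palindrome_targets = as.integer(n_palindrome_targets),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Planted regulator specification
#'
#' @param geometry a [motif_geometry()] (default direct repeat of two
#'   16-bp boxes around a 5-bp spacer).
#' @param n_target_operons target operons carrying sites (default 6);
#'   the regulator's own operon and its two chromosomal neighbors are
#'   always among them, mirroring the polysaccharide-utilization-locus
#'   architecture in which the regulator sits inside the locus it
#'   controls.
#' @param site_rate probability that a given genome's copy of a target
#'   carries the site (default 1).
#' @param box_noise per-base substitution probability applied when each
#'   site instance's boxes are sampled from the box consensus
#'   (default 0.05, a realistic within-regulon site degeneracy that
#'   keeps the per-column pairwise identity of orthologous sites near
#'   0.9); spacers are drawn at random per site instance and are not
#'   conserved.
#' @param consensus optional box consensus (for direct repeats) or full
#'   site consensus; random when `NULL`.
#' @return a `regulator_spec` list.
#' @export
regulator_spec <- function(geometry = motif_geometry("direct_repeat",
                                                     box_len = 16L,
                                                     spacer = 5L),
                           n_target_operons = 6L, site_rate = 1,
                           box_noise = 0.05, consensus = NULL) {
  structure(list(geometry = geometry,
                 n_target_operons = as.integer(n_target_operons),
                 site_rate = site_rate, box_noise = box_noise,
                 consensus = consensus),
            class = "regulator_spec")
}

# Per-base substitution: each flipped base moves to one of the three
# other bases, uniformly.
#' @noRd
mutate_bases <- function(s, rate) {
  if (rate <= 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- match(chars, DNA_BASES4)
  flip <- which(runif(length(chars)) < rate & !is.na(codes))
  if (length(flip) > 0L) {
    codes[flip] <- (codes[flip] - 1L +
                      sample.int(3L, length(flip), replace = TRUE)) %% 4L + 1L
    chars[flip] <- DNA_BASES4[codes[flip]]
  }
  paste(chars, collapse = "")
}

SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0)),
                          c("A", "C", "G", "T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Generate a synthetic genome collection with planted sites
#'
#' @param config a [synth_config()].
#' @return list with `genomes` (list of [genome_record()]) and
#'   `manifest`, the ground truth: per-regulator planted sites with
#'   absolute coordinates and sequences, the ortholog family map, and
#'   all motif parameters.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_collection_impl(config))
}

#' @noRd
generate_collection_impl <- function(config) {
  ng <- config$n_genomes
  nf <- config$genes_per_genome
  glen <- config$gene_codons * 3L
  ilen <- config$intergenic_len
  gc <- config$gc_content

  # ancestral layout: inter | gene | inter | gene | ... | inter
  strands <- sample(c("+", "-"), nf, replace = TRUE)
  gene_starts <- ilen + (seq_len(nf) - 1L) * (glen + ilen)

  # choose regulator and target families up front so gene orientations
  # can be fixed before sequences are built
  mid <- max(2L, nf %/% 2L)
  plans <- list()
  used_targets <- integer(0)
  for (ri in seq_along(config$regulators)) {
    spec <- config$regulators[[ri]]
    reg_fam <- mid + (ri - 1L) * 4L
    if (reg_fam + 1L > nf) stopf("not enough genes for regulator %d", ri)
    core <- c(reg_fam, reg_fam - 1L, reg_fam + 1L)
    pool <- setdiff(seq_len(nf), c(core, used_targets))
    extra <- sort(sample(pool, max(0L, spec$n_target_operons - 3L)))
    targets <- sort(unique(c(core, extra)))[seq_len(min(spec$n_target_operons,
                                                        nf))]
    used_targets <- c(used_targets, targets)
    plans[[ri]] <- list(spec = spec, reg_fam = reg_fam, targets = targets)
  }
  ptargets <- integer(0)
  if (!is.null(config$global_palindrome)) {
    pool <- setdiff(seq_len(nf), used_targets)
    ptargets <- sort(sample(pool, min(config$n_palindrome_targets,
                                      length(pool))))
  }
  # a target's upstream window must not double as the upstream window
  # of a divergently oriented non-target neighbor, otherwise the
  # planted site has two equally valid owners; co-orient such neighbors
  all_targets <- c(used_targets, ptargets)
  for (fam in all_targets) {
    if (strands[fam] == "+") {
      nb <- fam - 1L
      if (nb >= 1L && !nb %in% all_targets && strands[nb] == "-") {
        strands[nb] <- "+"
      }
    } else {
      nb <- fam + 1L
      if (nb <= nf && !nb %in% all_targets && strands[nb] == "+") {
        strands[nb] <- "-"
      }
    }
  }

  anc_genes <- vapply(seq_len(nf), function(i) {
    body <- paste(sample(SENSE_CODONS, config$gene_codons - 2L,
                         replace = TRUE), collapse = "")
    g <- paste0("ATG", body, "TAA")
    if (strands[i] == "-") revcomp(g) else g
  }, character(1))
  anc_inter <- vapply(seq_len(nf + 1L), function(i) random_dna(ilen, gc),
                      character(1))
  anc <- paste0(paste0(anc_inter[seq_len(nf)], anc_genes, collapse = ""),
                anc_inter[nf + 1L])

  genome_ids <- sprintf("G%02d", seq_len(ng))
  contigs <- vapply(genome_ids, function(id) {
    mutate_bases(anc, config$divergence)
  }, character(1))

  # non-overlapping planting intervals (gene layout is shared across
  # genomes, so reserving absolute intervals once suffices)
  reserved <- matrix(numeric(0), 0L, 2L)
  draw_offset <- function(fam, site_len) {
    for (try in 1:100) {
      off <- sample(seq(-350L, -30L - site_len), 1L)
      abs_start <- if (strands[fam] == "+") {
        gene_starts[fam] + off
      } else {
        gene_starts[fam] + glen - off - site_len
      }
      iv <- c(abs_start, abs_start + site_len)
      clash <- nrow(reserved) > 0L &&
        any(iv[1] < reserved[, 2L] & reserved[, 1L] < iv[2])
      if (!clash) {
        reserved <<- rbind(reserved, iv)
        return(off)
      }
    }
    stopf("cannot place a site upstream of family %d without overlap", fam)
  }

  reg_truth <- list()
  for (ri in seq_along(plans)) {
    spec <- plans[[ri]]$spec
    g <- spec$geometry
    reg_fam <- plans[[ri]]$reg_fam
    targets <- plans[[ri]]$targets
    if (g$kind == "direct_repeat") {
      consensus_used <- spec$consensus %||% random_dna(g$box_len, 0.5)
      # every site instance is an independent draw from the motif
      # model: each box is the consensus with per-base noise, the
      # spacer is random (non-conserved even between orthologous sites)
      sample_site <- function() {
        paste0(mutate_bases(consensus_used, spec$box_noise),
               random_dna(g$spacer, gc),
               mutate_bases(consensus_used, spec$box_noise))
      }
    } else {
      consensus_used <- spec$consensus %||% random_dna(g$total_len, 0.5)
      sample_site <- function() {
        mutate_bases(resolve_iupac(consensus_used), spec$box_noise)
      }
    }
    offsets <- vapply(targets, function(f) {
      draw_offset(f, g$total_len)
    }, integer(1))
    planted <- list()
    for (k in seq_along(targets)) {
      fam <- targets[k]
      for (gi in seq_len(ng)) {
        if (runif(1) > spec$site_rate) next
        site <- sample_site()
        pl <- plant_site(contigs[gi], gene_starts[fam], glen,
                         strands[fam], offsets[k], site)
        contigs[gi] <- pl$contig
        planted[[length(planted) + 1L]] <- data.frame(
          genome_id = genome_ids[gi],
          locus_tag = sprintf("%s_g%03d", genome_ids[gi], fam),
          family = fam, contig_id = "chr", start = pl$start,
          strand = strands[fam], offset = offsets[k], sequence = site,
          stringsAsFactors = FALSE)
      }
    }
    reg_truth[[ri]] <- list(
      name = sprintf("R%d", ri),
      geometry = unclass(g)[c("kind", "box_len", "spacer", "total_len",
                              "center_distance")],
      consensus = consensus_used,
      regulator_family = reg_fam,
      target_families = targets,
      sites = do.call(rbind, planted))
  }

  pal_truth <- NULL
  if (!is.null(config$global_palindrome)) {
    cons <- config$global_palindrome
    plen <- nchar(cons)
    planted <- list()
    for (fam in ptargets) {
      off <- draw_offset(fam, plen)
      for (gi in seq_len(ng)) {
        site <- resolve_iupac(cons)
        pl <- plant_site(contigs[gi], gene_starts[fam], glen,
                         strands[fam], off, site)
        contigs[gi] <- pl$contig
        planted[[length(planted) + 1L]] <- data.frame(
          genome_id = genome_ids[gi],
          locus_tag = sprintf("%s_g%03d", genome_ids[gi], fam),
          family = fam, contig_id = "chr", start = pl$start,
          strand = strands[fam], offset = off, sequence = site,
          stringsAsFactors = FALSE)
      }
    }
    pal_truth <- list(consensus = cons, target_families = ptargets,
                      sites = do.call(rbind, planted))
  }

  target_fams <- unique(unlist(lapply(reg_truth, `[[`, "target_families")))
  genomes <- lapply(seq_len(ng), function(gi) {
    ft <- data.frame(
      locus_tag = sprintf("%s_g%03d", genome_ids[gi], seq_len(nf)),
      contig_id = "chr", start = gene_starts, end = gene_starts + glen,
      strand = strands, product = sprintf("protein family %03d",
                                          seq_len(nf)),
      translation = NA_character_,
      annotations = ifelse(seq_len(nf) %in% target_fams,
                           "category=sugar_utilization", ""),
      stringsAsFactors = FALSE)
    fill_translations(genome_record(genome_ids[gi],
                                    c(chr = unname(contigs[gi])), ft))
  })
  names(genomes) <- genome_ids

  families <- data.frame(family = seq_len(nf))
  for (gi in seq_len(ng)) {
    families[[genome_ids[gi]]] <- sprintf("%s_g%03d", genome_ids[gi],
                                          seq_len(nf))
  }
  manifest <- list(seed = config$seed,
                   gc_content = config$gc_content,
                   divergence = config$divergence,
                   genome_ids = genome_ids,
                   families = families,
                   regulators = reg_truth,
                   palindrome = pal_truth)
  list(genomes = genomes, manifest = manifest)
}

# Splice a site into the upstream window of a gene, on its coding
# strand. `offset` is the 0-based coding-strand coordinate of the site
# start relative to the translation start (negative = upstream).
#' @noRd
plant_site <- function(contig, gene_start, gene_len, strand, offset,
                       site) {
  len <- nchar(site)
  if (strand == "+") {
    abs_start <- gene_start + offset
    insert <- site
  } else {
    gene_end <- gene_start + gene_len
    abs_start <- gene_end - offset - len
    insert <- revcomp(site)
  }
  if (abs_start < 0L || abs_start + len > nchar(contig)) {
    stopf("planted site does not fit the contig")
  }
  substr(contig, abs_start + 1L, abs_start + len) <- insert
  list(contig = contig, start = abs_start)
}

#' @noRd
resolve_iupac <- function(cons) {
  choices <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(cons), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- choices[[ch]]
    if (is.null(opts)) stopf("invalid IUPAC symbol '%s'", ch)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Corrupt planted sites with noise and dropout
#'
#' Stress-test harness: mutates each planted site base with probability
#' `noise` and removes whole sites with probability `dropout`
#' (replacing them with fresh background sequence). The manifest is
#' updated to match.
#'
#' @param collection list `(genomes, manifest)` from
#'   [generate_collection()].
#' @param noise per-base substitution rate in `[0,1]`.
#' @param dropout per-site loss rate in `[0,1]`.
#' @param seed RNG seed.
#' @return an updated `(genomes, manifest)` list.
#' @export
corrupt_sites <- function(collection, noise = 0, dropout = 0, seed = 1L) {
  if (noise < 0 || noise > 1 || dropout < 0 || dropout > 1) {
    stopf("noise and dropout must be in [0,1]")
  }
  genomes <- collection$genomes
  manifest <- collection$manifest
  gc <- manifest$gc_content %||% 0.5
  withr::with_seed(seed, {
    edit_block <- function(block_name) {
      block <- manifest[[block_name]]
      if (is.null(block)) return()
      blocks <- if (block_name == "regulators") block else list(block)
      for (bi in seq_along(blocks)) {
        sites <- blocks[[bi]]$sites
        if (is.null(sites) || nrow(sites) == 0L) next
        keep <- logical(nrow(sites))
        for (k in seq_len(nrow(sites))) {
          row <- sites[k, ]
          gnm <- genomes[[row$genome_id]]
          contig <- gnm$contigs[[row$contig_id]]
          len <- nchar(row$sequence)
          if (runif(1) < dropout) {
            substr(contig, row$start + 1L, row$start + len) <-
              random_dna(len, gc)
            keep[k] <- FALSE
          } else {
            new_site <- mutate_bases(row$sequence, noise)
            ins <- if (row$strand == "-") revcomp(new_site) else new_site
            substr(contig, row$start + 1L, row$start + len) <- ins
            sites$sequence[k] <- new_site
            keep[k] <- TRUE
          }
          gnm$contigs[[row$contig_id]] <- contig
          genomes[[row$genome_id]] <<- gnm
        }
        blocks[[bi]]$sites <- sites[keep, , drop = FALSE]
      }
      manifest[[block_name]] <<- if (block_name == "regulators") {
        blocks
      } else blocks[[1]]
    }
    edit_block("regulators")
    edit_block("palindrome")
  })
  genomes <- lapply(genomes, fill_translations)
  list(genomes = genomes, manifest = manifest)
}

#' Write a synthetic collection to disk
#'
#' Emits per-genome FASTA plus tabular feature files consumable by
#' [read_genome()], and the truth manifest as JSON.
#'
#' @param collection list `(genomes, manifest)`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in collection$genomes) {
    write_genome_fasta(g, file.path(dir, paste0(g$genome_id, ".fasta")))
    write_feature_table(g, file.path(dir, paste0(g$genome_id,
                                                 ".features.tsv")))
  }
  jsonlite::write_json(collection$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
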