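# Genome data model. A genome_record holds one replicon set: named contig
# sequences plus a gene-feature table. All coordinates are 0-based
# half-open on the forward strand; GenBank's 1-based inclusive intervals
# are converted at the parser boundary.

FEATURE_COLUMNS <- c("locus_tag", "contig_id", "start", "end", "strand",
                     "product", "translation")

#' Construct a genome record
#'
#' @param genome_id single string identifying the genome.
#' @param contigs named character vector of contig DNA sequences
#'   (alphabet `A`, `C`, `G`, `T`, `N`).
#' @param features data.frame with columns `locus_tag`, `contig_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), `product`,
#'   `translation` and optionally `annotations` (a `key=value;key=value`
#'   tag string).
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, features) {
  if (!is.character(genome_id) || length(genome_id) != 1L) {
    stopf("genome_id must be a single string")
  }
  contigs <- vapply(contigs, toupper, character(1))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  nr <- nrow(features)
  if (!"annotations" %in% names(features)) {
    features$annotations <- character(nr)
  }
  if (is.null(features$translation)) {
    features$translation <- rep(NA_character_, nr)
  }
  if (is.null(features$product)) features$product <- character(nr)
  missing_cols <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing_cols) > 0L) {
    stopf("feature table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  rec <- structure(
    list(genome_id = genome_id, contigs = contigs,
         features = features[, c(FEATURE_COLUMNS, "annotations")]),
    class = "genome_record")
  validate_genome_record(rec)
}

#' @noRd
validate_genome_record <- function(rec) {
  contigs <- rec$contigs
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stopf("contig ids must be present and unique")
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stopf("contig %s contains characters outside {A,C,G,T,N}",
          names(contigs)[bad][1])
  }
  ft <- rec$features
  if (nrow(ft) > 0L) {
    if (anyDuplicated(ft$locus_tag)) {
      stopf("duplicated locus_tag: %s", ft$locus_tag[duplicated(ft$locus_tag)][1])
    }
    bad_strand <- !ft$strand %in% c("+", "-")
    if (any(bad_strand)) {
      stopf("feature %s has invalid strand '%s'",
            ft$locus_tag[bad_strand][1], ft$strand[bad_strand][1])
    }
    bad_coord <- is.na(ft$start) | is.na(ft$end) | ft$start >= ft$end |
      ft$start < 0L
    if (any(bad_coord)) {
      stopf("feature %s has malformed coordinates (need 0 <= start < end)",
            ft$locus_tag[bad_coord][1])
    }
    unknown <- !ft$contig_id %in% names(contigs)
    if (any(unknown)) {
      stopf("feature %s refers to unknown contig '%s'",
            ft$locus_tag[unknown][1], ft$contig_id[unknown][1])
    }
    lens <- nchar(contigs)[ft$contig_id]
    beyond <- ft$end > lens
    if (any(beyond)) {
      stopf("feature %s extends beyond its contig", ft$locus_tag[beyond][1])
    }
  }
  rec
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d feature(s), %s bp\n",
              x$genome_id, length(x$contigs), nrow(x$features),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Read an annotated genome
#'
#' Reads either a GenBank flat file (sequence and CDS features in one
#' file) or a FASTA file accompanied by a tabular feature file. Tabular
#' features use 0-based half-open coordinates; GenBank locations
#' (1-based inclusive) are converted on input. Missing translations are
#' derived from the CDS coordinates under the bacterial genetic code
#' (translation table 11), with the trailing stop trimmed.
#'
#' @param path path to a FASTA or GenBank file.
#' @param annotations path to a tab-separated feature table (required for
#'   FASTA input; ignored for GenBank). Columns: `locus_tag`, `contig`,
#'   `start`, `end`, `strand`, `product`, `translation`, optional
#'   `annotations`.
#' @param genome_id genome identifier; defaults to the file base name.
#' @return a validated [genome_record()].
#' @export
read_genome <- function(path, annotations = NULL, genome_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  genome_id <- genome_id %||%
    sub("\\.(fa|fasta|fna|gb|gbk|gbff)$", "", basename(path))
  first <- readLines(path, n = 1L)
  if (grepl("^LOCUS", first)) {
    rec <- read_genbank(path, genome_id)
  } else {
    if (is.null(annotations)) {
      stopf("FASTA input requires a tabular feature file ('annotations')")
    }
    seqs <- Biostrings::readDNAStringSet(path)
    contigs <- setNames(as.character(seqs),
                        sub("\\s.*$", "", names(seqs)))
    ft <- read.delim(annotations, stringsAsFactors = FALSE,
                     colClasses = "character")
    if ("contig" %in% names(ft) && !"contig_id" %in% names(ft)) {
      names(ft)[names(ft) == "contig"] <- "contig_id"
    }
    ft$start <- suppressWarnings(as.integer(ft$start))
    ft$end <- suppressWarnings(as.integer(ft$end))
    if (anyNA(ft$start) || anyNA(ft$end)) {
      bad <- which(is.na(ft$start) | is.na(ft$end))[1]
      stopf("malformed coordinates for feature %s", ft$locus_tag[bad])
    }
    if (!is.null(ft$translation)) ft$translation[ft$translation == ""] <- NA
    rec <- genome_record(genome_id, contigs, ft)
  }
  fill_translations(rec)
}

#' @noRd
read_genbank <- function(path, genome_id) {
  lines <- readLines(path)
  locus_idx <- grep("^LOCUS", lines)
  bounds <- c(locus_idx, length(lines) + 1L)
  contigs <- character(0)
  feats <- list()
  for (k in seq_along(locus_idx)) {
    chunk <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    contig_id <- strsplit(trimws(chunk[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", chunk)
    if (length(ori) != 1L) stopf("GenBank record %s lacks ORIGIN", contig_id)
    seq_lines <- chunk[(ori + 1L):length(chunk)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    contigs[contig_id] <- seq
    fstart <- grep("^FEATURES", chunk)
    if (length(fstart) == 1L) {
      feats[[k]] <- parse_genbank_features(chunk[(fstart + 1L):(ori - 1L)],
                                           contig_id)
    }
  }
  ft <- do.call(rbind, feats)
  if (is.null(ft)) {
    ft <- data.frame(locus_tag = character(0), contig_id = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0), product = character(0),
                     translation = character(0), stringsAsFactors = FALSE)
  }
  genome_record(genome_id, contigs, ft)
}

# Minimal CDS-only GenBank feature parser: handles `a..b` and
# `complement(a..b)` locations plus /locus_tag /product /translation
# qualifiers, which covers the tabular information this package models.
#' @noRd
parse_genbank_features <- function(lines, contig_id) {
  is_key <- grepl("^\\s{5}\\S", lines)
  key_idx <- which(is_key)
  rows <- list()
  for (i in seq_along(key_idx)) {
    from <- key_idx[i]
    to <- if (i < length(key_idx)) key_idx[i + 1L] - 1L else length(lines)
    parts <- strsplit(trimws(lines[from]), "\\s+")[[1]]
    if (parts[1] != "CDS") next
    loc <- parts[2]
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
    if (length(nums) < 2L) {
      stopf("cannot parse GenBank location '%s' on %s", loc, contig_id)
    }
    start1 <- as.integer(nums[1])
    end1 <- as.integer(nums[length(nums)])
    qual_text <- paste(trimws(lines[seq(from + 1L, length.out = to - from)]),
                       collapse = " ")
    get_qual <- function(name) {
      m <- regmatches(qual_text,
                      regexpr(sprintf('/%s="[^"]*"', name), qual_text))
      if (length(m) == 0L) return(NA_character_)
      sub(sprintf('/%s="', name), "", sub('"$', "", m))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_tag = get_qual("locus_tag"),
      contig_id = contig_id,
      start = start1 - 1L,   # to 0-based half-open
      end = end1,
      strand = strand,
      product = get_qual("product") %|NA|% "",
      translation = gsub(" ", "", get_qual("translation")),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @noRd
`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

.regufoot_cache <- new.env(parent = emptyenv())

#' @noRd
bacterial_code <- function() {
  if (is.null(.regufoot_cache$gc11)) {
    .regufoot_cache$gc11 <- Biostrings::getGeneticCode("11")
  }
  .regufoot_cache$gc11
}

#' @noRd
fill_translations <- function(rec) {
  ft <- rec$features
  need <- which(is.na(ft$translation) | ft$translation == "")
  if (length(need) == 0L) return(rec)
  cds <- vapply(need, function(i) {
    dna <- substr(rec$contigs[[ft$contig_id[i]]], ft$start[i] + 1L,
                  ft$end[i])
    if (ft$strand[i] == "-") dna <- revcomp(dna)
    substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
  }, character(1))
  ok <- nzchar(cds)
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(cds[ok]),
      genetic.code = bacterial_code(), if.fuzzy.codon = "X"))
    ft$translation[need[ok]] <- sub("\\*$", "", aa)
  }
  ft$translation[need[!ok]] <- ""
  rec$features <- ft
  rec
}

#' Write the tabular feature dialect
#'
#' Writes a tab-separated feature table that [read_genome()] reads back
#' bit-exactly (0-based half-open coordinates).
#'
#' @param genome a [genome_record()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  ft <- genome$features
  out <- data.frame(locus_tag = ft$locus_tag, contig = ft$contig_id,
                    start = ft$start, end = ft$end, strand = ft$strand,
                    product = ft$product, translation = ft$translation,
                    annotations = ft$annotations,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genome contigs as FASTA
#'
#' @param genome a [genome_record()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' @noRd
get_feature <- function(genome, locus_tag) {
  i <- match(locus_tag, genome$features$locus_tag)
  if (is.na(i)) {
    stopf("locus_tag '%s' not found in genome %s", locus_tag,
          genome$genome_id)
  }
  genome$features[i, ]
}

#' @noRd
parse_annotations <- function(tagstring) {
  if (is.na(tagstring) || tagstring == "") return(list())
  kv <- strsplit(strsplit(tagstring, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
           vapply(kv, `[`, character(1), 1L))
}
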