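# Alphabet shared by the whole package: genomes are plain uppercase strings
# over {A,C,G,T,N}. All internal coordinates are 0-based, half-open; the only
# 1-based arithmetic happens at the SGA parse/format boundary.

IUPAC_AMBIGUOUS <- "RYSWKMBDHVU"

#' Construct a genome sequence
#'
#' A minimal container for a named chromosome-like sequence over the alphabet
#' `{A,C,G,T,N}`. Bases are uppercased; any IUPAC ambiguity code other than
#' `N` is degraded to `N` so real genomes always parse.
#'
#' @param name Chromosome identifier (non-empty string).
#' @param bases Character scalar of bases.
#' @return An object of class `genome_seq` with fields `name`, `bases`,
#'   `length`.
#' @export
genome_seq <- function(name, bases) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- normalize_bases(bases)
  structure(list(name = name, bases = bases, length = nchar(bases)),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bases\n", x$name, x$length))
  invisible(x)
}

# uppercase and degrade ambiguity codes to N; reject anything non-nucleotide
normalize_bases <- function(bases) {
  bases <- toupper(bases)
  bases <- chartr(IUPAC_AMBIGUOUS, strrep("N", nchar(IUPAC_AMBIGUOUS)), bases)
  bad <- gsub("[ACGTN]", "", bases)
  if (nzchar(bad)) {
    stop("sequence contains non-nucleotide character(s): ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  bases
}

assert_dna <- function(seq, allow_n = TRUE) {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, seq)
  if (any(bad)) {
    stop("sequence contains characters outside the ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}",
         " alphabet (first offender: record ", which(bad)[1L], ")")
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Records are parsed with [Biostrings::readBStringSet()]; bases are
#' uppercased and IUPAC ambiguity codes are mapped to `N` on read. Soft-masked
#' (lowercase) bases are retained as ordinary bases, not masked out.
#'
#' @param path Path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return List of [genome_seq] objects, one per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA parse error at line 1: file is empty")
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("FASTA parse error at line ", first,
         ": expected header line starting with '>'")
  }
  set <- Biostrings::readBStringSet(path)
  if (any(!nzchar(names(set)))) {
    stop("FASTA parse error: record ", which(!nzchar(names(set)))[1L],
         " has an empty header")
  }
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_seq(ids[i], as.character(set[[i]]))
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `genome_seq`, a list of them, or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "genome_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    nm <- names(seqs)
    if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
    seqs <- Map(genome_seq, nm, unname(seqs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$name), con)
    starts <- seq(1L, s$length, by = width)
    writeLines(substring(s$bases, starts, pmin(starts + width - 1L, s$length)),
               con)
  }
  invisible(path)
}

#' Construct TSS annotations
#'
#' A strand-aware transcription start site: the anchor from which promoter
#' regions are extrapolated. `pos0` is the 0-based index of the TSS base on
#' the forward strand.
#'
#' @param chrom,pos0,strand,label Vectors of equal length (recycled where
#'   length 1).
#' @return A data frame of class `tss_annotation`.
#' @export
tss_annotation <- function(chrom, pos0, strand, label = NA_character_) {
  stopifnot(all(pos0 >= 0), all(strand %in% c("+", "-")))
  out <- data.frame(chrom = chrom, pos0 = as.integer(pos0), strand = strand,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("tss_annotation", "data.frame")
  out
}

#' Parse TSS annotations from SGA or BED files
#'
#' SGA (the MGA/EPDnew dialect) is tab-separated with columns
#' `seq-id, feature, position (1-based), strand, count[, name]`; `pos0` is
#' `position - 1`. In BED the TSS base is the first base of the feature on the
#' `+` strand and the last base (`end - 1`) on the `-` strand.
#'
#' @param path Annotation file path.
#' @param dialect `"sga"` or `"bed"`.
#' @param strict If `TRUE` (default) a malformed record is a parse error with
#'   its line number; if `FALSE` malformed records are dropped with a warning
#'   reporting how many lines were skipped.
#' @return A [tss_annotation] data frame.
#' @export
parse_tss_annotations <- function(path, dialect = c("sga", "bed"),
                                  strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  recs <- vector("list", length(idx))
  bad <- integer(0)
  for (j in seq_along(idx)) {
    ln <- idx[j]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    rec <- tryCatch(
      parse_annotation_fields(f, dialect, ln),
      error = function(e) if (strict) stop(e) else NULL
    )
    if (is.null(rec)) bad <- c(bad, ln) else recs[[j]] <- rec
  }
  if (length(bad)) {
    warning(length(bad), " annotation line(s) failed validation and were ",
            "dropped (lines ", paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "", ")")
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(tss_annotation(character(0), integer(0), character(0),
                          character(0)))
  }
  do.call(rbind_tss, recs)
}

rbind_tss <- function(...) {
  out <- do.call(rbind.data.frame, c(list(...), stringsAsFactors = FALSE))
  class(out) <- c("tss_annotation", "data.frame")
  rownames(out) <- NULL
  out
}

parse_annotation_fields <- function(f, dialect, ln) {
  if (dialect == "sga") {
    if (length(f) < 5L) {
      stop("SGA parse error at line ", ln, ": expected >= 5 tab-separated ",
           "columns, found ", length(f))
    }
    pos <- suppressWarnings(as.integer(f[3L]))
    if (is.na(pos)) {
      stop("SGA parse error at line ", ln, ": non-integer position '",
           f[3L], "'")
    }
    if (!f[4L] %in% c("+", "-")) {
      stop("SGA parse error at line ", ln, ": unknown strand symbol '",
           f[4L], "'")
    }
    label <- if (length(f) >= 6L) f[6L] else f[2L]
    tss_annotation(f[1L], pos - 1L, f[4L], label)
  } else {
    if (length(f) < 6L) {
      stop("BED parse error at line ", ln, ": need BED6 (6 columns), found ",
           length(f))
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("BED parse error at line ", ln, ": non-integer coordinates")
    }
    if (!f[6L] %in% c("+", "-")) {
      stop("BED parse error at line ", ln, ": unknown strand symbol '",
           f[6L], "'")
    }
    pos0 <- if (f[6L] == "+") start else end - 1L
    tss_annotation(f[1L], pos0, f[6L], f[4L])
  }
}

#' Write TSS annotations in SGA or BED dialects
#'
#' Mirrors [parse_tss_annotations()]: SGA positions are written 1-based;
#' in BED the TSS becomes a single-base feature.
#'
#' @param tss A [tss_annotation] data frame.
#' @param path Output path.
#' @param dialect `"sga"` or `"bed"`.
#' @param feature Feature name for the SGA second column.
#' @return The path, invisibly.
#' @export
write_tss_annotations <- function(tss, path, dialect = c("sga", "bed"),
                                  feature = "TSS") {
  dialect <- match.arg(dialect)
  label <- ifelse(is.na(tss$label), "tss", tss$label)
  lines <- if (dialect == "sga") {
    paste(tss$chrom, feature, tss$pos0 + 1L, tss$strand, 1L, label, sep = "\t")
  } else {
    paste(tss$chrom, tss$pos0, tss$pos0 + 1L, label, 0L, tss$strand,
          sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct genomic intervals
#'
#' 0-based, half-open intervals `[start, end)` used for promoter regions and
#' benchmark windows.
#'
#' @param chrom,start,end,strand Vectors (recycled where length 1).
#' @return A data frame of class `genomic_interval`.
#' @export
interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    stop("interval must be non-empty with start < end (offender: [",
         start[which(start >= end)[1L]], ",", end[which(start >= end)[1L]],
         "))")
  }
  stopifnot(all(strand %in% c("+", "-")))
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Reverse complement of a DNA string
#'
#' `N` is a fixed point; any character outside `{A,C,G,T,N}` is an error.
#' Vectorized over its input.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract a window of a genome
#'
#' Returns the substring `[start, end)` of the genome; for `-` strand
#' intervals the reverse complement is returned. Out-of-bounds intervals are
#' an error — there is no silent clipping.
#'
#' @param genome A [genome_seq].
#' @param iv A single-row [interval()].
#' @return A base string of length `end - start`.
#' @export
extract_window <- function(genome, iv) {
  stopifnot(inherits(genome, "genome_seq"), nrow(iv) == 1L)
  if (iv$start < 0 || iv$end > genome$length || iv$start >= iv$end) {
    stop("interval [", iv$start, ",", iv$end, ") out of range for ",
         genome$name, " (length ", genome$length, ")")
  }
  s <- substr(genome$bases, iv$start + 1L, iv$end)
  if (iv$strand == "-") reverse_complement(s) else s
}
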