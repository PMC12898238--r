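#' Genomic sequence slice with an absolute origin
#'
#' A `GenomeSequence` is an uppercase DNA string over `{A,C,G,T,N}` together
#' with the 1-based genomic coordinate of its first base, so that a small
#' slice of a chromosome (for example 1 kb around a variant of interest)
#' behaves exactly like the whole chromosome in every coordinate-aware
#' operation.
#'
#' @param contig Contig/chromosome name (e.g. `"chr17"`).
#' @param seq DNA string; lowercase input is uppercased.
#' @param origin 1-based genomic coordinate of `seq`'s first base.
#'
#' @return An object of class `GenomeSequence`: a list with elements
#'   `contig`, `seq` and `origin`.
#' @examples
#' gs <- genome_sequence("chr17", "ACGTACGT", origin = 100)
#' genomic_base(gs, 103)
#' @export
genome_sequence <- function(contig, seq, origin = 1L) {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  seq <- toupper(seq)
  assert_dna(seq)
  if (nchar(seq) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  origin <- assert_scalar_int(origin, "origin", min = 1L)
  structure(list(contig = contig, seq = seq, origin = origin),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence %s:%d-%d (%d bp)\n", x$contig, x$origin,
              genome_end(x), nchar(x$seq)))
  head <- substr(x$seq, 1L, 60L)
  cat(" ", head, if (nchar(x$seq) > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname genome_sequence
#' @param x A `GenomeSequence`.
#' @export
genome_end <- function(x) x$origin + nchar(x$seq) - 1L

#' Extract bases by genomic coordinates
#'
#' @param x A `GenomeSequence`.
#' @param start,end 1-based inclusive genomic coordinates; must fall inside
#'   the slice.
#' @return Character string of bases on the plus strand.
#' @export
subseq_genomic <- function(x, start, end) {
  stopifnot(inherits(x, "GenomeSequence"))
  if (start < x$origin || end > genome_end(x) || start > end) {
    stop(sprintf("coordinates %d-%d outside slice %s:%d-%d",
                 start, end, x$contig, x$origin, genome_end(x)), call. = FALSE)
  }
  substr(x$seq, start - x$origin + 1L, end - x$origin + 1L)
}

#' @rdname subseq_genomic
#' @param pos Single genomic position.
#' @export
genomic_base <- function(x, pos) subseq_genomic(x, pos, pos)

#' Apply a single-nucleotide variant to a sequence slice
#'
#' Returns a copy of the slice carrying the alternate allele. The reference
#' allele is checked against the slice before substitution.
#'
#' @param x A `GenomeSequence`.
#' @param variant A [variant()] on the same contig.
#' @return A `GenomeSequence` with the alternate base at the variant position.
#' @export
apply_variant <- function(x, variant) {
  stopifnot(inherits(x, "GenomeSequence"), inherits(variant, "Variant"))
  if (!identical(x$contig, variant$contig)) {
    stop("variant contig ", variant$contig, " does not match slice contig ",
         x$contig, call. = FALSE)
  }
  have <- genomic_base(x, variant$pos)
  if (!identical(have, variant$ref)) {
    stop(sprintf("reference mismatch at %s:%d: slice has %s, variant ref is %s",
                 x$contig, variant$pos, have, variant$ref), call. = FALSE)
  }
  idx <- variant$pos - x$origin + 1L
  substr(x$seq, idx, idx) <- variant$alt
  x
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement, same alphabet.
#' @examples
#' revcomp("TTTA")
#' @export
revcomp <- function(seq) {
  assert_dna(toupper(seq))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Read a (multi-record) FASTA file
#'
#' @param path Path to an existing FASTA file.
#' @return A list of [genome_sequence()] objects in file order, named by the
#'   first whitespace-delimited token of each header. An `origin=<int>` token
#'   in the header (as written by [write_fasta()]) is honoured; otherwise the
#'   origin is 1.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- !startsWith(lines, ">")
  bad <- which(body & grepl("[^ACGTNacgtn[:space:]]", lines))
  if (length(bad)) {
    stop(sprintf("FASTA format error in %s, line %d: non-{A,C,G,T,N} characters",
                 path, bad[1]), call. = FALSE)
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- names(set)[i]
    tokens <- strsplit(header, "\\s+")[[1]]
    origin <- 1L
    om <- grep("^origin=\\d+$", tokens, value = TRUE)
    if (length(om) == 1L) origin <- as.integer(sub("^origin=", "", om))
    out[[i]] <- genome_sequence(tokens[1], as.character(set[[i]]), origin)
  }
  names(out) <- vapply(out, `[[`, "", "contig")
  out
}

#' Write GenomeSequence records as FASTA
#'
#' The absolute origin of each slice is preserved in the header as an
#' `origin=<int>` token so [read_fasta()] round-trips exactly.
#'
#' @param records A `GenomeSequence` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "GenomeSequence")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(seqs) <- vapply(records, function(r) {
    if (r$origin == 1L) r$contig else sprintf("%s origin=%d", r$contig, r$origin)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
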