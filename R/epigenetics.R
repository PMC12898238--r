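# CpG creation/destruction by an allele, per-read methylation aggregation,
# and homopolymer (poly-T) context detection.

#' CpG dinucleotides created or destroyed by an SNV
#'
#' An SNV can only alter the two dinucleotides overlapping the variant
#' base, so exactly those are compared before and after substitution on
#' the plus strand (CpG is strand-symmetric, so plus-strand detection
#' suffices). Positions reported are the genomic positions of the C of
#' each affected plus-strand CpG.
#'
#' @param genome A [genome_sequence()] with at least one base of flank on
#'   each side of the variant.
#' @param v A [variant()] whose `ref` matches the slice.
#' @return An object of class `CpGDelta`: lists `created` and `destroyed`
#'   of genomic C positions, plus the `variant`.
#' @examples
#' gs <- genome_sequence("chr17", "TCAGT", origin = 31155979)
#' cpg_delta(gs, variant("chr17", 31155981, "A", "G"))
#' @export
cpg_delta <- function(genome, v) {
  stopifnot(inherits(genome, "GenomeSequence"), inherits(v, "Variant"))
  if (v$pos - 1L < genome$origin || v$pos + 1L > genome_end(genome)) {
    stop("variant needs >= 1 base of flank inside the slice", call. = FALSE)
  }
  before <- subseq_genomic(genome, v$pos - 1L, v$pos + 1L)
  if (substr(before, 2L, 2L) != v$ref) {
    stop(sprintf("ref %s does not match slice base %s at %s:%d", v$ref,
                 substr(before, 2L, 2L), v$contig, v$pos), call. = FALSE)
  }
  after <- before
  substr(after, 2L, 2L) <- v$alt
  created <- integer(0); destroyed <- integer(0)
  # dinucleotide starting at pos-1 (C would sit at pos-1) and at pos (C at pos)
  for (k in 0:1) {
    din_before <- substr(before, k + 1L, k + 2L)
    din_after <- substr(after, k + 1L, k + 2L)
    cpos <- v$pos - 1L + k
    if (din_after == "CG" && din_before != "CG") created <- c(created, cpos)
    if (din_before == "CG" && din_after != "CG") destroyed <- c(destroyed, cpos)
  }
  structure(list(created = created, destroyed = destroyed, variant = v),
            class = "CpGDelta")
}

#' @export
print.CpGDelta <- function(x, ...) {
  cat(sprintf("CpGDelta for %s:%d %s>%s\n", x$variant$contig, x$variant$pos,
              x$variant$ref, x$variant$alt))
  cat("  created C at: ",
      if (length(x$created)) paste(x$created, collapse = ", ") else "none", "\n")
  cat("  destroyed C at: ",
      if (length(x$destroyed)) paste(x$destroyed, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Aggregate per-read methylation calls at one site
#'
#' @param calls Data frame with columns `read_id`, `pos` and `methylated`
#'   (0/1); an optional `contig` column is honoured when `contig` is given.
#' @param site_pos Genomic position of the cytosine.
#' @param contig Optional contig filter.
#' @return A list of class `MethylationSummary`: `site_pos`, `n_reads`,
#'   `n_methylated`, `fraction`.
#' @examples
#' calls <- data.frame(read_id = paste0("r", 1:12), pos = 100,
#'                     methylated = c(rep(1, 10), 0, 0))
#' methylation_fraction(calls, 100)$fraction
#' @export
methylation_fraction <- function(calls, site_pos, contig = NULL) {
  need <- c("read_id", "pos", "methylated")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hit <- calls[calls$pos == site_pos, , drop = FALSE]
  if (!is.null(contig) && "contig" %in% names(hit)) {
    hit <- hit[hit$contig == contig, , drop = FALSE]
  }
  if (nrow(hit) == 0L) stop("no calls at site ", site_pos, call. = FALSE)
  if (anyDuplicated(hit$read_id)) {
    stop("duplicate (read, site) calls at ", site_pos, call. = FALSE)
  }
  if (!all(hit$methylated %in% c(0L, 1L))) {
    stop("methylated must be 0/1", call. = FALSE)
  }
  n <- nrow(hit)
  nm <- sum(hit$methylated == 1L)
  structure(list(site_pos = site_pos, n_reads = n, n_methylated = nm,
                 fraction = nm / n), class = "MethylationSummary")
}

#' Read a per-read methylation call table
#'
#' Tab-separated columns: `read_id`, `contig`, `pos`, `methylated` (0/1).
#'
#' @param path Path to the TSV.
#' @return Data frame of calls.
#' @export
read_methylation_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "contig", "pos", "methylated")
  if (!all(need %in% names(df))) {
    stop("calls TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Maximal homopolymer runs of a sequence slice
#'
#' Finds every maximal single-base run of at least `min_length` bases
#' (e.g. the 20-bp intronic poly-T tract flanking an acceptor).
#'
#' @param genome A [genome_sequence()].
#' @param min_length Minimum run length (>= 2).
#' @return Data frame with `base`, `start_pos` (genomic), `length`;
#'   zero rows when there is no qualifying run.
#' @export
homopolymer_runs <- function(genome, min_length = 2L) {
  stopifnot(inherits(genome, "GenomeSequence"))
  min_length <- assert_scalar_int(min_length, "min_length", 2L)
  r <- rle(strsplit(genome$seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_length & r$values %in% c("A", "C", "G", "T")
  data.frame(base = r$values[keep],
             start_pos = genome$origin + starts[keep] - 1L,
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Intersect created CpG positions with transcription-factor sites
#'
#' Optional helper for user-supplied BED intervals of TF binding sites
#' (0-based half-open, as in BED): reports which created-CpG cytosines
#' fall inside a site. No motif scanning is performed.
#'
#' @param delta A `CpGDelta`.
#' @param bed_path Path to a BED file (chrom, start, end, optional name).
#' @return Data frame of overlapping (position, site name) pairs.
#' @export
cpg_tf_overlap <- function(delta, bed_path) {
  if (!file.exists(bed_path)) stop("no such file: ", bed_path, call. = FALSE)
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4L) names(bed)[4] <- "name" else bed$name <- NA_character_
  hits <- list()
  for (p in delta$created) {
    sel <- bed$chrom == delta$variant$contig & p > bed$start & p <= bed$end
    if (any(sel)) {
      hits[[length(hits) + 1L]] <- data.frame(pos = p, name = bed$name[sel],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(pos = integer(0), name = character(0)))
  }
  do.call(rbind, hits)
}
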