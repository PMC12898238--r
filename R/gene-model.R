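#' Strand-aware exon/CDS gene model
#'
#' Ordered exon intervals for one transcript plus the genomic positions of
#' the first and last coding base. Exons are stored in transcript order:
#' ascending genomic start on the plus strand, descending on the minus
#' strand. All coordinates are 1-based inclusive.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (or list of length-2 vectors) of 1-based
#'   closed genomic intervals, in transcript order.
#' @param cds_start Genomic position of the first coding base (start codon's
#'   first base in transcript orientation).
#' @param cds_end Genomic position of the last coding base.
#'
#' @return An object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, transcript_id, contig, strand, exons,
                       cds_start, cds_end) {
  if (is.list(exons)) exons <- do.call(rbind, lapply(exons, as.integer))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(exons[, 1] > exons[, 2])) {
    stop("exon start > end", call. = FALSE)
  }
  # transcript order: + ascending, - descending by genomic start
  ord <- order(exons[, 1], decreasing = (strand == "-"))
  if (!identical(ord, seq_len(nrow(exons)))) {
    stop("exons not in transcript order (", strand, " strand)", call. = FALSE)
  }
  by_start <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(by_start) > 1L &&
      any(by_start[-1L, 1] <= by_start[-nrow(by_start), 2])) {
    stop("exons overlap", call. = FALSE)
  }
  if (nrow(by_start) > 1L) {
    gaps <- by_start[-1L, 1] - by_start[-nrow(by_start), 2] - 1L
    if (any(gaps < 4L)) stop("intron shorter than 4 bases", call. = FALSE)
  }
  cds_start <- assert_scalar_int(cds_start, "cds_start", 1L)
  cds_end <- assert_scalar_int(cds_end, "cds_end", 1L)
  in_exon <- function(p) any(p >= exons[, 1] & p <= exons[, 2])
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("cds_start/cds_end must fall inside exons", call. = FALSE)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 contig = contig, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) on %s%s: %d exons, CDS %d..%d\n",
              x$gene_id, x$transcript_id, x$contig, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

#' @rdname gene_model
#' @param model A `GeneModel`.
#' @return For `n_exons()`, the exon count; for `introns()`, a matrix of
#'   intron genomic intervals `[start, end]` (plus-strand coordinates) in
#'   transcript order, one row per intron.
#' @export
n_exons <- function(model) nrow(model$exons)

#' @rdname gene_model
#' @export
introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  if (model$strand == "+") {
    cbind(start = ex[-n, 2] + 1L, end = ex[-1L, 1] - 1L)
  } else {
    cbind(start = ex[-1L, 2] + 1L, end = ex[-n, 1] - 1L)
  }
}

# Genomic positions of all CDS bases in transcript order (5' -> 3' of the
# coding sequence). Vectorized interval arithmetic, not per-base walking;
# the brute-force per-base walker lives in the test suite as its oracle.
#' @keywords internal
#' @noRd
cds_genomic_positions <- function(model) {
  ex <- model$exons
  pos <- integer(0)
  if (model$strand == "+") {
    for (i in seq_len(nrow(ex))) {
      s <- max(ex[i, 1], model$cds_start)
      e <- min(ex[i, 2], model$cds_end)
      if (s <= e) pos <- c(pos, s:e)
    }
  } else {
    for (i in seq_len(nrow(ex))) {
      s <- min(ex[i, 2], model$cds_start)  # first coding base has the larger coord
      e <- max(ex[i, 1], model$cds_end)
      if (s >= e) pos <- c(pos, s:e)
    }
  }
  pos
}

#' @rdname gene_model
#' @export
cds_length <- function(model) length(cds_genomic_positions(model))

#' Read a gene model from GFF3 or JSON
#'
#' Accepts either a GFF3 file restricted to gene/mRNA/exon/CDS features or
#' a JSON file with keys `gene_id, transcript_id, contig, strand, exons,
#' cds_start, cds_end` (exons as a list of `[start, end]` pairs in
#' transcript order).
#'
#' @param path Input path; format chosen by extension (`.json` vs
#'   `.gff`/`.gff3`) unless `format` is given.
#' @param format `"json"`, `"gff3"` or `NULL` (guess from extension).
#' @param transcript_id When a GFF3 file holds several mRNAs, the ID of the
#'   transcript to load (mandatory in that case).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, format = NULL, transcript_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "gff3"
  }
  if (format == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("gene_id", "transcript_id", "contig", "strand", "exons",
              "cds_start", "cds_end")
    missing <- setdiff(need, names(j))
    if (length(missing)) {
      stop("gene-model JSON missing fields: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    gene_model(j$gene_id, j$transcript_id, j$contig, j$strand,
               matrix(as.integer(as.matrix(j$exons)), ncol = 2L),
               j$cds_start, j$cds_end)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df$Parent1 <- vapply(df$Parent,
                         function(p) if (length(p)) as.character(p[1]) else NA_character_,
                         character(1))
    mrna <- df[df$type == "mRNA", , drop = FALSE]
    if (nrow(mrna) == 0L) stop("GFF3 has no mRNA feature", call. = FALSE)
    if (is.null(transcript_id)) {
      if (nrow(mrna) > 1L) {
        stop("GFF3 holds several mRNAs; supply transcript_id", call. = FALSE)
      }
      transcript_id <- mrna$ID[1]
    }
    mrna <- mrna[mrna$ID == transcript_id, , drop = FALSE]
    if (nrow(mrna) == 0L) {
      stop("transcript ", transcript_id, " not found", call. = FALSE)
    }
    strand <- as.character(mrna$strand[1])
    exons <- df[df$type == "exon" & df$Parent1 == transcript_id, , drop = FALSE]
    cds <- df[df$type == "CDS" & df$Parent1 == transcript_id, , drop = FALSE]
    if (nrow(exons) == 0L) stop("no exons for ", transcript_id, call. = FALSE)
    if (nrow(cds) == 0L) stop("no CDS for ", transcript_id, call. = FALSE)
    ex <- cbind(start = exons$start, end = exons$end)
    ex <- ex[order(ex[, 1], decreasing = (strand == "-")), , drop = FALSE]
    cs <- if (strand == "+") min(cds$start) else max(cds$end)
    ce <- if (strand == "+") max(cds$end) else min(cds$start)
    gene <- df[df$type == "gene", , drop = FALSE]
    gid <- if (nrow(gene)) gene$ID[1] else NA_character_
    gene_model(gid, transcript_id, as.character(mrna$seqnames[1]),
               strand, ex, cs, ce)
  }
}

#' Write a gene model as JSON
#'
#' @param model A [gene_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model_json <- function(model, path) {
  j <- list(gene_id = model$gene_id, transcript_id = model$transcript_id,
            contig = model$contig, strand = model$strand,
            exons = unname(lapply(seq_len(nrow(model$exons)),
                                  function(i) as.integer(model$exons[i, ]))),
            cds_start = model$cds_start, cds_end = model$cds_end)
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
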