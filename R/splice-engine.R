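# Splice-site disruption, cryptic-acceptor choice and reading-frame
# consequences. All exon/intron handling is in transcript orientation;
# genomic coordinates are plus-strand throughout.

#' Locate canonical splice sites of a gene model
#'
#' One donor (GT) and one acceptor (AG) per intron, read on the transcript
#' strand. Introns whose terminal dinucleotide deviates from GT-AG are
#' reported with `canonical = FALSE` rather than failing.
#'
#' @param model A [gene_model()].
#' @param genome A [genome_sequence()] covering all introns.
#' @return A data.frame with one row per site: `intron_index`, `kind`
#'   (donor/acceptor), `pos1`, `pos2` (genomic positions of the
#'   dinucleotide, 5' to 3' in transcript orientation), `dinucleotide`
#'   (transcript strand), `canonical`, `first_exonic_pos` (genomic position
#'   of the adjacent exon base).
#' @export
locate_splice_sites <- function(model, genome) {
  intr <- introns(model)
  ex <- model$exons
  if (nrow(intr) && any(intr[, 2] - intr[, 1] + 1L < 4L)) {
    stop("intron shorter than 4 bases", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(intr))) {
    a <- intr[i, 1]; b <- intr[i, 2]
    if (model$strand == "+") {
      don <- c(a, a + 1L); acc <- c(b - 1L, b)
      don_din <- subseq_genomic(genome, a, a + 1L)
      acc_din <- subseq_genomic(genome, b - 1L, b)
      don_exon <- ex[i, 2]; acc_exon <- ex[i + 1L, 1]
    } else {
      don <- c(b, b - 1L); acc <- c(a + 1L, a)
      don_din <- revcomp(subseq_genomic(genome, b - 1L, b))
      acc_din <- revcomp(subseq_genomic(genome, a, a + 1L))
      don_exon <- ex[i, 1]; acc_exon <- ex[i + 1L, 2]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      intron_index = i, kind = "donor", pos1 = don[1], pos2 = don[2],
      dinucleotide = don_din, canonical = identical(don_din, "GT"),
      first_exonic_pos = don_exon, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      intron_index = i, kind = "acceptor", pos1 = acc[1], pos2 = acc[2],
      dinucleotide = acc_din, canonical = identical(acc_din, "AG"),
      first_exonic_pos = acc_exon, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify a variant's position relative to splice sites
#'
#' @param v A [variant()] on the gene's contig.
#' @param model A [gene_model()].
#' @return List with `class` (one of `acceptor-2`, `acceptor-1`, `donor+1`,
#'   `donor+2`, `exonic`, `deep_intronic`) and `intron_index` (NA for
#'   exonic) plus `exon_index` for exonic variants.
#' @export
classify_splice_variant <- function(v, model) {
  if (!identical(v$contig, model$contig)) {
    stop("variant contig does not match gene model", call. = FALSE)
  }
  ex <- model$exons
  span <- range(ex)
  if (v$pos < span[1] || v$pos > span[2]) {
    stop(sprintf("variant %s:%d outside gene span %d-%d (deep intergenic)",
                 v$contig, v$pos, span[1], span[2]), call. = FALSE)
  }
  exon_hit <- which(v$pos >= ex[, 1] & v$pos <= ex[, 2])
  if (length(exon_hit)) {
    return(list(class = "exonic", intron_index = NA_integer_,
                exon_index = exon_hit[1]))
  }
  intr <- introns(model)
  for (i in seq_len(nrow(intr))) {
    a <- intr[i, 1]; b <- intr[i, 2]
    if (v$pos < a || v$pos > b) next
    if (model$strand == "+") {
      cls <- if (v$pos == a) "donor+1" else if (v$pos == a + 1L) "donor+2"
             else if (v$pos == b) "acceptor-1" else if (v$pos == b - 1L) "acceptor-2"
             else "deep_intronic"
    } else {
      cls <- if (v$pos == b) "donor+1" else if (v$pos == b - 1L) "donor+2"
             else if (v$pos == a) "acceptor-1" else if (v$pos == a + 1L) "acceptor-2"
             else "deep_intronic"
    }
    return(list(class = cls, intron_index = i, exon_index = NA_integer_))
  }
  stop("variant position could not be classified", call. = FALSE)
}

# Genomic position of exonic offset t (1-based, transcript orientation)
# within exon j.
#' @keywords internal
#' @noRd
exonic_to_genomic <- function(model, exon_index, t) {
  unname(if (model$strand == "+") model$exons[exon_index, 1] + t - 1L
         else model$exons[exon_index, 2] - t + 1L)
}

#' Scan for the cryptic acceptor activated by an acceptor-site mutation
#'
#' When the canonical AG of an intron is disrupted, the spliceosome's
#' fallback modeled here is the nearest downstream exonic AG: the new exon
#' begins immediately after the chosen AG, deleting the exonic bases up to
#' and including it. The scan runs on the alternate-allele sequence in
#' transcript orientation over the downstream exon only (the disrupted
#' canonical AG is intronic and therefore never a candidate).
#'
#' @param genome_with_alt A [genome_sequence()] carrying the alternate
#'   allele (see [apply_variant()]).
#' @param model A [gene_model()].
#' @param intron_index Index of the intron whose acceptor is disrupted.
#' @param variant Optional [variant()]; enables `distance_from_variant`,
#'   the inclusive base count from the variant position to the second base
#'   of the chosen AG.
#' @param max_scan_nt Scan limit in exonic bases (default 100); absence of
#'   an AG within it is a valid result (`found = FALSE`).
#' @param include_upstream Also report the nearest upstream intronic AG
#'   (a partial intron-retention acceptor), clearly labeled; the canonical
#'   acceptor's own positions are excluded.
#' @return An object of class `CrypticAcceptorCall`: `found`,
#'   `offset_exonic` (1-based exonic position of the AG's second base; the
#'   new exon begins at `offset_exonic + 1`), `deletion_length`
#'   (`= offset_exonic`), `distance_from_variant`, genomic positions of the
#'   AG, and optionally `upstream_intronic_ag`.
#' @export
scan_cryptic_acceptor <- function(genome_with_alt, model, intron_index,
                                  variant = NULL, max_scan_nt = 100L,
                                  include_upstream = FALSE) {
  j <- intron_index + 1L
  if (j > n_exons(model)) stop("no exon downstream of intron ", intron_index,
                               call. = FALSE)
  exon_len <- abs(model$exons[j, 2] - model$exons[j, 1]) + 1L
  exon_seq <- exon_sequence(genome_with_alt, model, j)
  limit <- min(max_scan_nt, exon_len)
  call <- list(found = FALSE, offset_exonic = NA_integer_,
               deletion_length = NA_integer_,
               distance_from_variant = NA_integer_,
               ag_pos_genomic = c(NA_integer_, NA_integer_),
               intron_index = intron_index)
  for (i in seq_len(limit - 1L)) {
    if (substr(exon_seq, i, i + 1L) == "AG") {
      off <- i + 1L
      g1 <- exonic_to_genomic(model, j, i)
      g2 <- exonic_to_genomic(model, j, off)
      call$found <- TRUE
      call$offset_exonic <- off
      call$deletion_length <- off
      call$ag_pos_genomic <- c(g1, g2)
      if (!is.null(variant)) {
        call$distance_from_variant <- abs(g2 - variant$pos) + 1L
      }
      break
    }
  }
  if (include_upstream) {
    intr_seq <- intron_sequence(genome_with_alt, model, intron_index)
    L <- nchar(intr_seq)
    up <- list(found = FALSE)
    # positions -2,-1 (the canonical acceptor) are excluded by construction
    for (d in 3:(L - 1L)) {  # second AG base at intron position -(d-?) ...
      i1 <- L - d           # first base index (1-based from intron 5')
      if (i1 < 1L) break
      if (substr(intr_seq, i1, i1 + 1L) == "AG") {
        up <- list(found = TRUE, second_base_intron_offset = -(L - (i1 + 1L) + 1L),
                   retained_intron_nt = L - (i1 + 1L))
        break
      }
    }
    call$upstream_intronic_ag <- up
  }
  structure(call, class = "CrypticAcceptorCall")
}

#' @export
print.CrypticAcceptorCall <- function(x, ...) {
  if (!x$found) {
    cat("CrypticAcceptorCall: no exonic AG found within scan window\n")
  } else {
    cat(sprintf(paste0("CrypticAcceptorCall: AG at exonic positions %d-%d ",
                       "(deletion %d nt%s)\n"),
                x$offset_exonic - 1L, x$offset_exonic, x$deletion_length,
                if (!is.na(x$distance_from_variant))
                  sprintf(", %d nt from variant", x$distance_from_variant)
                else ""))
  }
  invisible(x)
}

# Transcript-strand sequence of exon/intron j.
#' @keywords internal
#' @noRd
exon_sequence <- function(genome, model, j) {
  s <- subseq_genomic(genome, model$exons[j, 1], model$exons[j, 2])
  if (model$strand == "-") revcomp(s) else s
}

#' @keywords internal
#' @noRd
intron_sequence <- function(genome, model, i) {
  intr <- introns(model)[i, ]
  s <- subseq_genomic(genome, intr["start"], intr["end"])
  if (model$strand == "-") revcomp(s) else s
}

# mRNA coordinate (wild-type structure) of a genomic position.
#' @keywords internal
#' @noRd
genomic_to_mrna <- function(model, gpos) {
  ex <- model$exons
  lens <- abs(ex[, 2] - ex[, 1]) + 1L
  before <- 0L
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex[i, 1] && gpos <= ex[i, 2]) {
      off <- if (model$strand == "+") gpos - ex[i, 1] + 1L else ex[i, 2] - gpos + 1L
      return(unname(before + off))
    }
    before <- before + lens[i]
  }
  stop("position ", gpos, " is not exonic", call. = FALSE)
}

#' Reconstruct the spliced transcript, wild-type or cryptically spliced
#'
#' Exons are concatenated in transcript orientation (reverse-complemented
#' for minus-strand models). With a cryptic acceptor call, the affected
#' exon (the exon downstream of the call's intron) is trimmed by
#' `deletion_length` at its 5' end.
#'
#' @param model A [gene_model()].
#' @param genome A [genome_sequence()] covering the gene. For a mutant
#'   reconstruction pass the alternate-allele sequence.
#' @param cryptic_call Optional `CrypticAcceptorCall` from
#'   [scan_cryptic_acceptor()]; `NULL` reconstructs the wild type.
#' @return A list: `mrna`; `cds` (wild type: first to last coding base;
#'   cryptic: from the start codon to the transcript 3' end, since a
#'   frameshift forfeits the annotated stop); `cds_offset` (mRNA position
#'   of the start codon); `exon_lengths`; `junctions` (mRNA positions of
#'   the last base of each exon except the final one); `affected_exon`;
#'   `deletion_length`.
#' @export
reconstruct_transcript <- function(model, genome, cryptic_call = NULL) {
  n <- n_exons(model)
  seqs <- lapply(seq_len(n), function(j) exon_sequence(genome, model, j))
  deletion <- 0L
  affected <- NA_integer_
  if (!is.null(cryptic_call)) {
    if (!isTRUE(cryptic_call$found)) stop("cryptic call has found = FALSE",
                                          call. = FALSE)
    affected <- cryptic_call$intron_index + 1L
    deletion <- cryptic_call$deletion_length
    if (deletion >= nchar(seqs[[affected]])) {
      stop("deletion consumes the whole affected exon", call. = FALSE)
    }
    seqs[[affected]] <- substr(seqs[[affected]], deletion + 1L,
                               nchar(seqs[[affected]]))
  }
  lens <- vapply(seqs, nchar, 0L)
  mrna <- paste(unlist(seqs), collapse = "")
  w <- genomic_to_mrna(model, model$cds_start)
  if (!is.na(affected)) {
    del_start <- sum(abs(model$exons[seq_len(affected - 1L), 2] -
                           model$exons[seq_len(affected - 1L), 1]) + 1L) + 1L
    if (w >= del_start + deletion) {
      w <- w - deletion
    } else if (w >= del_start) {
      stop("deletion removes the start codon", call. = FALSE)
    }
  }
  cds <- if (is.null(cryptic_call)) {
    we <- genomic_to_mrna(model, model$cds_end)
    substr(mrna, w, we)
  } else {
    substr(mrna, w, nchar(mrna))
  }
  list(mrna = mrna, cds = cds, cds_offset = w, exon_lengths = lens,
       junctions = if (n > 1L) cumsum(lens)[seq_len(n - 1L)] else integer(0),
       affected_exon = affected, deletion_length = deletion)
}

#' CDS coordinates spanned by one exon's coding part
#'
#' @param model A [gene_model()].
#' @param exon_index Exon index in transcript order.
#' @return `c(first, last)` 1-based CDS coordinates, or `NULL` for a fully
#'   non-coding exon.
#' @export
exon_cds_span <- function(model, exon_index) {
  pos <- cds_genomic_positions(model)
  ex <- model$exons[exon_index, ]
  idx <- which(pos >= ex[1] & pos <= ex[2])
  if (!length(idx)) return(NULL)
  c(min(idx), max(idx))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @keywords internal
#' @noRd
codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate up to (not including) the first stop codon.
#' @keywords internal
#' @noRd
translate_to_stop <- function(seq) {
  cods <- codons_of(seq)
  gc <- Biostrings::GENETIC_CODE
  aas <- character(0)
  stop_found <- FALSE
  for (cd in cods) {
    if (cd %in% STOP_CODONS) { stop_found <- TRUE; break }
    if (grepl("N", cd)) stop("codon with N cannot be translated", call. = FALSE)
    aas <- c(aas, unname(gc[cd]))
  }
  list(peptide = paste(aas, collapse = ""), stop_found = stop_found,
       stop_codon_index = if (stop_found) length(aas) + 1L else NA_integer_)
}

#' Per-frame stop-codon map
#'
#' Positions (1-based, first codon base) of every stop codon of `seq` in
#' each of the three reading frames.
#'
#' @param seq DNA string.
#' @return List of three integer vectors named `frame1`..`frame3`.
#' @export
stop_map <- function(seq) {
  assert_dna(toupper(seq))
  seq <- toupper(seq)
  out <- lapply(1:3, function(f) {
    if (nchar(seq) - 2L < f) return(integer(0))
    starts <- seq.int(f, nchar(seq) - 2L, by = 3L)
    starts[substring(seq, starts, starts + 2L) %in% STOP_CODONS]
  })
  names(out) <- paste0("frame", 1:3)
  out
}

#' Reading-frame analysis of a cryptically spliced CDS
#'
#' Compares the mutant coding sequence against the wild type: both must
#' begin at the canonical start codon. Computes the frame offset, the
#' number of novel amino acids encoded in the shifted frame before the
#' first stop (residues after the last wild-type-identical residue), the
#' premature termination codon position, the count of whole wild-type
#' amino-acid codons of the affected exon lying entirely downstream of the
#' PTC's wild-coordinate footprint, the truncated peptide and its average
#' mass, and a per-frame stop map of the mutant CDS.
#'
#' @param wild_cds Wild-type CDS (start codon through stop codon).
#' @param mutant_cds Mutant CDS from the start codon to the transcript 3'
#'   end (see [reconstruct_transcript()]).
#' @param affected_exon_cds_span Wild-type CDS span of the affected exon,
#'   as from [exon_cds_span()]; may be `NULL` to skip the truncation count.
#' @param deletion_length Exonic bases removed by the cryptic splice.
#' @return An object of class `SpliceConsequence`.
#' @export
analyze_frame <- function(wild_cds, mutant_cds, affected_exon_cds_span = NULL,
                          deletion_length) {
  wild_cds <- toupper(wild_cds); mutant_cds <- toupper(mutant_cds)
  if (substr(wild_cds, 1L, 3L) != "ATG" || substr(mutant_cds, 1L, 3L) != "ATG") {
    stop("CDS must begin with the ATG start codon", call. = FALSE)
  }
  deletion_length <- assert_scalar_int(deletion_length, "deletion_length", 0L)
  frame_offset <- deletion_length %% 3L
  is_frameshift <- frame_offset != 0L

  wt <- translate_to_stop(wild_cds)
  mt <- translate_to_stop(mutant_cds)
  wild_pep <- wt$peptide
  mut_pep <- mt$peptide

  # residue-wise common prefix
  maxm <- min(nchar(wild_pep), nchar(mut_pep))
  m <- 0L
  while (m < maxm &&
         substr(wild_pep, m + 1L, m + 1L) == substr(mut_pep, m + 1L, m + 1L)) {
    m <- m + 1L
  }

  ptc_cds_pos <- if (mt$stop_found) 3L * nchar(mut_pep) + 1L else NA_integer_
  wild_stop_pos <- if (wt$stop_found) 3L * nchar(wild_pep) + 1L else NA_integer_
  premature <- !is.na(ptc_cds_pos) && !is.na(wild_stop_pos) &&
    (ptc_cds_pos + deletion_length) < wild_stop_pos
  if (!is.na(ptc_cds_pos) && is.na(wild_stop_pos)) premature <- TRUE

  novel_aa_count <- if (is_frameshift) nchar(mut_pep) - m else 0L

  lost <- NA_integer_
  if (premature && !is.null(affected_exon_cds_span)) {
    span <- affected_exon_cds_span
    footprint_end <- ptc_cds_pos + 2L + deletion_length
    starts <- seq.int(1L, nchar(wild_cds) - 2L, by = 3L)
    starts <- starts[starts >= span[1] & (starts + 2L) <= span[2] &
                       starts > footprint_end]
    if (length(starts)) {
      cods <- substring(wild_cds, starts, starts + 2L)
      lost <- sum(!cods %in% STOP_CODONS)
    } else lost <- 0L
  }

  rule <- if (!mt$stop_found) {
    "no stop codon in mutant CDS; peptide reported to CDS end"
  } else if (!premature) {
    "mutant stop is the wild-type stop equivalent (no PTC)"
  } else if (is_frameshift) {
    sprintf("frameshift (deletion %d nt, offset %d): %d novel aa before PTC",
            deletion_length, frame_offset, novel_aa_count)
  } else {
    "in-frame deletion with premature stop"
  }

  structure(list(
    deletion_length_nt = deletion_length,
    frame_offset = frame_offset,
    is_frameshift = is_frameshift,
    novel_aa_count = novel_aa_count,
    ptc_cds_pos = if (premature) ptc_cds_pos else NA_integer_,
    mutant_stop_cds_pos = ptc_cds_pos,
    wildtype_exon_aa_lost_after_ptc = lost,
    in_frame_aa_deleted = if (!is_frameshift) deletion_length %/% 3L else 0L,
    nmd_predicted = NA,
    rule_detail = rule,
    peptide = mut_pep,
    peptide_mass_kda = peptide_mass(mut_pep),
    no_stop = !mt$stop_found,
    stop_map_per_frame = stop_map(mutant_cds)),
    class = "SpliceConsequence")
}

#' @export
print.SpliceConsequence <- function(x, ...) {
  cat("SpliceConsequence\n")
  cat(sprintf("  deletion: %d nt (frame offset %d, %s)\n", x$deletion_length_nt,
              x$frame_offset, if (x$is_frameshift) "frameshift" else "in-frame"))
  if (!is.na(x$ptc_cds_pos)) {
    cat(sprintf("  PTC at mutant CDS position %d after %d novel aa\n",
                x$ptc_cds_pos, x$novel_aa_count))
  }
  if (!is.na(x$wildtype_exon_aa_lost_after_ptc)) {
    cat(sprintf("  wild-type exon aa lost beyond PTC: %d\n",
                x$wildtype_exon_aa_lost_after_ptc))
  }
  cat(sprintf("  peptide: %d aa, %.2f kDa\n", nchar(x$peptide),
              x$peptide_mass_kda))
  if (!is.na(x$nmd_predicted) && is.logical(x$nmd_predicted)) {
    cat(sprintf("  NMD predicted: %s\n", x$nmd_predicted))
  }
  invisible(x)
}

#' Nonsense-mediated decay prediction (55-nt rule)
#'
#' Classic exon-junction rule: a premature termination codon triggers NMD
#' when it lies at least `threshold` nucleotides upstream of the last
#' exon-exon junction of the (mutant) transcript; PTCs in the last exon,
#' or transcripts with a single exon, are NMD-negative.
#'
#' @param consequence A `SpliceConsequence` from [analyze_frame()].
#' @param model A [gene_model()].
#' @param genome A [genome_sequence()] (alternate allele applied).
#' @param cryptic_call The `CrypticAcceptorCall` that produced the mutant
#'   transcript (for junction positions in mutant coordinates).
#' @param threshold Distance rule in nucleotides (default 55).
#' @return The `SpliceConsequence` with `nmd_predicted` and an extended
#'   `rule_detail`; also attaches `nmd_distance_nt`.
#' @export
predict_nmd <- function(consequence, model, genome, cryptic_call = NULL,
                        threshold = 55L) {
  tr <- reconstruct_transcript(model, genome, cryptic_call)
  if (length(tr$junctions) == 0L) {
    consequence$nmd_predicted <- FALSE
    consequence$nmd_rule <- "no junction (single-exon transcript)"
    return(consequence)
  }
  if (is.na(consequence$mutant_stop_cds_pos) || is.na(consequence$ptc_cds_pos)) {
    consequence$nmd_predicted <- FALSE
    consequence$nmd_rule <- "no premature termination codon"
    return(consequence)
  }
  ptc_mrna <- tr$cds_offset + consequence$ptc_cds_pos - 1L
  last_junction <- tr$junctions[length(tr$junctions)]
  dist <- unname(last_junction - ptc_mrna)
  consequence$nmd_distance_nt <- dist
  if (dist < 0L) {
    consequence$nmd_predicted <- FALSE
    consequence$nmd_rule <- "PTC in last exon"
  } else {
    consequence$nmd_predicted <- dist >= threshold
    consequence$nmd_rule <- sprintf(
      "PTC %d nt upstream of last exon-exon junction (threshold %d): %s",
      dist, threshold, if (dist >= threshold) "NMD-positive" else "NMD-negative")
  }
  consequence
}

# Average residue masses (Da), standard 20-letter alphabet.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Average molecular mass of a peptide, in kDa
#'
#' Sum of average residue masses plus one water; the empty peptide returns
#' the mass of water alone.
#'
#' @param peptide Amino-acid string over the standard 20-letter alphabet.
#' @return Mass in kDa (unrounded).
#' @examples
#' round(peptide_mass("G"), 5)  # 0.07507
#' @export
peptide_mass <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (nchar(peptide) == 0L) return(WATER_MASS / 1000)
  aa <- strsplit(toupper(peptide), "")[[1]]
  unknown <- setdiff(aa, names(AA_AVG_MASS))
  if (length(unknown)) {
    stop("unknown amino-acid letter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  (sum(AA_AVG_MASS[aa]) + WATER_MASS) / 1000
}

#' End-to-end splice consequence for one acceptor variant
#'
#' Convenience wrapper running classification, cryptic-acceptor scan,
#' transcript reconstruction, frame analysis and NMD prediction.
#'
#' @param genome Reference [genome_sequence()] (reference allele).
#' @param model A [gene_model()].
#' @param v A [variant()] at an acceptor -1/-2 position.
#' @param max_scan_nt Cryptic scan limit.
#' @param nmd_threshold NMD junction rule distance.
#' @return List with `classification`, `cryptic` (the
#'   `CrypticAcceptorCall`), `consequence` (the `SpliceConsequence`),
#'   `wild` and `mutant` transcript reconstructions.
#' @export
splice_consequence <- function(genome, model, v, max_scan_nt = 100L,
                               nmd_threshold = 55L) {
  cls <- classify_splice_variant(v, model)
  if (!cls$class %in% c("acceptor-1", "acceptor-2")) {
    stop("variant is not at an acceptor -1/-2 position (classified ",
         cls$class, ")", call. = FALSE)
  }
  genome_alt <- apply_variant(genome, v)
  cry <- scan_cryptic_acceptor(genome_alt, model, cls$intron_index,
                               variant = v, max_scan_nt = max_scan_nt)
  if (!cry$found) {
    return(list(classification = cls, cryptic = cry, consequence = NULL,
                wild = reconstruct_transcript(model, genome), mutant = NULL))
  }
  wild <- reconstruct_transcript(model, genome)
  mut <- reconstruct_transcript(model, genome_alt, cry)
  span <- exon_cds_span(model, cls$intron_index + 1L)
  # exon span relative to the CDS string (which starts at CDS coordinate 1)
  cons <- analyze_frame(wild$cds, mut$cds, span,
                        deletion_length = cry$deletion_length)
  cons <- predict_nmd(cons, model, genome_alt, cry, threshold = nmd_threshold)
  list(classification = cls, cryptic = cry, consequence = cons,
       wild = wild, mutant = mut)
}
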