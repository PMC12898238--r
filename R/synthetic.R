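# Seeded generators producing every input the pipeline consumes, with
# planted ground truth. Sequence backgrounds are drawn from restricted
# alphabets and deterministically patched so that planted features (the
# cryptic AG, the PAM, bystander-editable bases) are unique within the
# windows the engines scan.

# Codons free of T can never spell a stop (all stops start with T) in any
# frame; used for regions that must stay stop-free under frameshifts.
NO_T_CODONS <- c("GCA", "GCC", "GCG", "GAA", "GAG", "AAC", "AAA", "AAG",
                 "CAA", "CAG", "GGA", "GGC", "ACA", "ACC", "AGC", "CGA")
# General sense codons for the fixed-frame exon 1 filler.
SENSE_CODONS <- c("GCT", "GAA", "AAG", "CTG", "GAT", "TTC", "AGC", "GTG",
                  "CCT", "ACC", "ATC", "CAG", "GGT", "TCC")

#' @keywords internal
#' @noRd
random_codons <- function(n, pool) {
  if (n <= 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

#' Generate a planted splice-acceptor case
#'
#' Builds a multi-exon gene with canonical GT-AG introns, a polypyrimidine
#' tract and a 20-bp poly-T run upstream of the first acceptor, and an
#' acceptor-2 A>G variant whose cryptic consequence is fully engineered:
#' the first exonic AG of the affected exon (exon 2) sits at exonic
#' positions `(cryptic_offset - 1, cryptic_offset)`, the shifted reading
#' frame meets its first stop after exactly `novel_aa` codons, and
#' `truncation_aa` whole wild-type codons of the exon remain downstream of
#' the premature stop's wild-type footprint. Filler regions use a
#' stop-free codon alphabet so stop placement is exact.
#'
#' @param cryptic_offset Exonic position of the cryptic AG's second base
#'   (>= 2; equals the planted deletion length). Offsets that are a
#'   multiple of 3 give an in-frame case, for which `novel_aa` and
#'   `truncation_aa` must be 0.
#' @param novel_aa Planted count of novel amino acids before the premature
#'   stop (frameshift cases).
#' @param truncation_aa Planted count of wild-type exon codons wholly
#'   downstream of the stop's footprint.
#' @param n_exons Total exon count (>= 2; exons beyond the second are
#'   non-coding).
#' @param seed Integer seed; the same seed reproduces the case exactly.
#' @param contig,origin Coordinates of the emitted slice.
#' @return An object of class `PlantedSpliceCase`: `genome`, `gene`
#'   (a [gene_model()]), `variant`, and `truth` (`cryptic_offset`,
#'   `deletion_nt`, `novel_aa`, `truncation_aa`, `nmd`).
#' @examples
#' pc <- make_splice_case(cryptic_offset = 16, novel_aa = 17,
#'                        truncation_aa = 26, n_exons = 5, seed = 7)
#' pc$truth$deletion_nt
#' @export
make_splice_case <- function(cryptic_offset = 16L, novel_aa = 17L,
                             truncation_aa = 26L, n_exons = 5L, seed = 1L,
                             contig = "chrS", origin = 10001L) {
  k <- assert_scalar_int(cryptic_offset, "cryptic_offset", 2L)
  a <- assert_scalar_int(novel_aa, "novel_aa", 0L)
  t <- assert_scalar_int(truncation_aa, "truncation_aa", 0L)
  n_exons <- assert_scalar_int(n_exons, "n_exons", 2L)
  f <- k %% 3L
  if (f == 0L && (a != 0L || t != 0L)) {
    stop("in-frame cryptic offset (multiple of 3) forces novel_aa = 0 and ",
         "truncation_aa = 0", call. = FALSE)
  }
  if (f != 0L && a < 1L) {
    stop("frameshift case needs novel_aa >= 1", call. = FALSE)
  }
  with_seed(derive_seed(seed, "splice"), {
    utr <- "GCCGCCACC"
    exon1_coding <- paste0("ATG", paste(random_codons(19L, SENSE_CODONS),
                                        collapse = ""))
    exon1 <- paste0(utr, exon1_coding)

    # exon 2: AG-free pyrimidine prefix, the planted AG, then the
    # engineered downstream region
    prefix <- if (k > 2L) sample(c("C", "T"), k - 2L, replace = TRUE)
              else character(0)
    if (f == 0L && k > 2L) prefix[k - 2L] <- "C"  # keep wild frame stop-free
    if (f == 0L) {
      body <- paste(c(random_codons(8L, NO_T_CODONS), "TAA"), collapse = "")
    } else {
      novel <- c("GCA", random_codons(a - 1L, NO_T_CODONS))
      gap <- if (f == 1L) "GC" else "C"
      body <- paste(c(novel, "TAA", gap,
                      random_codons(t, NO_T_CODONS), "TAA"), collapse = "")
    }
    exon2 <- paste0(paste(prefix, collapse = ""), "AG", body)

    pyr <- function(n) paste(sample(c("C", "T"), n, replace = TRUE),
                             collapse = "")
    intron1 <- paste0("GT", substr(paste0(pyr(19L), "C"), 1L, 19L),
                      strrep("T", 20L), "CAG")
    other_intron <- function() paste0("GT", pyr(35L), "CAG")
    other_exon <- function() paste(sample(c("A", "C", "G", "T"), 80L,
                                          replace = TRUE), collapse = "")
    pieces <- list(exon1, intron1, exon2)
    if (n_exons > 2L) {
      for (i in seq_len(n_exons - 2L)) {
        pieces <- c(pieces, list(other_intron(), other_exon()))
      }
    }
    flank5 <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                    collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), 30L, replace = TRUE),
                    collapse = "")
    seq <- paste0(flank5, paste(unlist(pieces), collapse = ""), flank3)

    lens <- nchar(unlist(pieces))
    starts <- origin + 30L + c(0L, cumsum(lens)[-length(lens)])
    ends <- starts + lens - 1L
    exon_idx <- seq(1L, length(pieces), by = 2L)
    exons <- cbind(starts[exon_idx], ends[exon_idx])
    cds_start <- exons[1, 1] + 9L               # after the 9-nt UTR
    cds_end <- exons[2, 2]                      # wild stop ends exon 2
    gm <- gene_model("GENE_S", "TX_S", contig, "+", exons, cds_start, cds_end)
    gs <- genome_sequence(contig, seq, origin)

    acc2 <- introns(gm)[1, "end"] - 1L          # acceptor -2 position
    v <- variant(contig, acc2, "A", "G", genome = gs)

    exon2_len <- nchar(exon2)
    ptc_mrna <- 9L + 60L + 3L * a + 1L
    junctions <- cumsum(c(nchar(exon1), exon2_len - k,
                          rep(80L, max(0L, n_exons - 2L))))
    junctions <- junctions[seq_len(n_exons - 1L)]
    nmd <- f != 0L && length(junctions) > 0L &&
      (junctions[length(junctions)] - ptc_mrna) >= 55L

    structure(list(genome = gs, gene = gm, variant = v,
                   truth = list(cryptic_offset = k, deletion_nt = k,
                                novel_aa = if (f == 0L) 0L else a,
                                truncation_aa = if (f == 0L) NA_integer_ else t,
                                frame_offset = f, nmd = nmd)),
              class = "PlantedSpliceCase")
  })
}

#' Generate a planted base-editing feasibility case
#'
#' Builds a sequence slice around a target G (a pathogenic A>G allele to
#' be corrected G>A) carrying exactly one Cas12a TAM on the minus strand
#' (reading 5'-BAAA-3' on the displayed plus strand) whose editing window
#' covers the target, with `n_bystanders` additional editable guanines
#' planted inside the window. The A/T background forbids AAA runs so no
#' accidental TAM arises; a deterministic patch pass removes any residual
#' collision.
#'
#' @param pam_offset Distance from the target to the nearest TAM base
#'   (also the target's editing-window position; must lie inside the
#'   shipped Cas12a window, 8-14).
#' @param n_bystanders Number of planted bystander guanines (0-5).
#' @param hazardous When TRUE the first bystander is entered in the
#'   returned pathogenic table.
#' @param seed Integer seed.
#' @param contig,origin Slice coordinates.
#' @return An object of class `PlantedEditingCase`: `genome` (alternate
#'   allele applied), `target` (the [variant()]), `pathogenic_table`, and
#'   `truth` (`n_cas12a_candidates`, `bystander_positions`, `hazardous`).
#' @export
make_editing_case <- function(pam_offset = 9L, n_bystanders = 1L,
                              hazardous = TRUE, seed = 1L,
                              contig = "chrE", origin = 50001L) {
  pam_offset <- assert_scalar_int(pam_offset, "pam_offset", 1L)
  n_bystanders <- assert_scalar_int(n_bystanders, "n_bystanders", 0L)
  window <- c(8L, 14L)
  if (pam_offset < window[1] || pam_offset > window[2]) {
    stop("pam_offset must lie inside the Cas12a editing window [",
         window[1], ",", window[2], "]", call. = FALSE)
  }
  if (n_bystanders > length(window[1]:window[2]) - 1L) {
    stop("too many bystanders for the editing window", call. = FALSE)
  }
  with_seed(derive_seed(seed, "edit"), {
    len <- 101L
    centre <- 51L
    # A/T background with no AAA run
    bases <- character(len)
    for (i in seq_len(len)) {
      b <- sample(c("A", "T"), 1L)
      if (i >= 3L && b == "A" && bases[i - 1L] == "A" && bases[i - 2L] == "A") {
        b <- "T"
      }
      bases[i] <- b
    }
    v_pos <- origin + centre - 1L
    p <- centre + pam_offset               # slice index of the TAM's near base
    bases[centre] <- "G"                   # the pathogenic alt allele
    bases[p:(p + 3L)] <- c("T", "A", "A", "A")  # BAAA on plus = TTTV on minus
    bases[p - 1L] <- "A"                   # an A here cannot extend into BAAA
    # clear the rest of the editing window to non-editable background
    win_idx <- p - (window[1]:window[2])
    for (i in setdiff(win_idx, centre)) bases[i] <- "T"
    # plant bystander guanines, nearest window positions first
    byst_pos_window <- setdiff(window[1]:window[2], pam_offset)
    byst_pos_window <- byst_pos_window[order(abs(byst_pos_window - pam_offset))]
    byst_idx <- p - byst_pos_window[seq_len(n_bystanders)]
    for (i in byst_idx) bases[i] <- "G"
    # deterministic patch pass: destroy accidental BAAA (plus strand) and
    # TTTV-on-plus placements overlapping the scan region
    for (pass in 1:20) {
      s <- paste(bases, collapse = "")
      bad <- gregexpr("(?=[CGT]AAA)", s, perl = TRUE)[[1]]
      bad <- bad[bad != p & bad > 0L]
      if (!length(bad) || all(bad == -1L)) break
      i <- bad[1] + 1L                      # flip the first A of the run
      if (i %in% c(centre, byst_idx) || (i >= p && i <= p + 3L)) i <- bad[1] + 2L
      bases[i] <- "T"
    }
    gs <- genome_sequence(contig, paste(bases, collapse = ""), origin)
    target <- variant(contig, v_pos, "A", "G", id = "target_snv")

    byst_genomic <- sort(origin + byst_idx - 1L)
    tab <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      id = character(0), significance = character(0),
                      stringsAsFactors = FALSE)
    if (hazardous && n_bystanders > 0L) {
      tab <- data.frame(contig = contig, pos = byst_genomic[1], ref = "G",
                        alt = "A", id = "rsSYN0001",
                        significance = "Pathogenic", stringsAsFactors = FALSE)
    }
    structure(list(genome = gs, target = target, pathogenic_table = tab,
                   truth = list(n_cas12a_candidates = 1L,
                                bystander_positions = byst_genomic,
                                hazardous = hazardous && n_bystanders > 0L)),
              class = "PlantedEditingCase")
  })
}

#' Generate a control expression cohort with one patient value
#'
#' @param n Number of controls (>= 2).
#' @param mean,sd Gaussian cohort parameters (TPM).
#' @param patient_value Planted patient TPM.
#' @param seed Integer seed.
#' @param gene Gene id for the emitted matrix row.
#' @return List: `tpm` (1 x (n+1) matrix, last column `patient`),
#'   `controls`, `patient_value`, `truth` (requested parameters).
#' @export
make_expression_cohort <- function(n = 609L, mean = 4.43, sd = 1.97,
                                   patient_value = 2.94, seed = 1L,
                                   gene = "GENE1") {
  n <- assert_scalar_int(n, "n", 2L)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  with_seed(derive_seed(seed, "cohort"), {
    controls <- stats::rnorm(n, mean, sd)
    controls <- pmax(controls, 0.01)  # TPM is non-negative
    m <- matrix(c(controls, patient_value), nrow = 1L,
                dimnames = list(gene, c(sprintf("ctrl_%03d", seq_len(n)),
                                        "patient")))
    list(tpm = m, controls = controls, patient_value = patient_value,
         truth = list(n = n, mean = mean, sd = sd))
  })
}

#' Generate a qPCR Ct table with a planted fold change
#'
#' Target and reference Ct values for a calibrator and a test sample in
#' `replicates` technical replicates with Gaussian noise; the planted
#' relative expression of the test sample is `fold_change`
#' (`ddCt = -log2(fold_change)`).
#'
#' @param fold_change Planted 2^-ddCt of the test sample (> 0).
#' @param sigma Replicate Ct noise standard deviation.
#' @param replicates Technical replicates per (sample, gene).
#' @param seed Integer seed.
#' @param target_gene,reference_gene,calibrator_sample,test_sample Labels.
#' @return List: `ct_table` (long format), `truth` (`fold_change`,
#'   `percent_change`).
#' @export
make_ct_table <- function(fold_change = 0.2865, sigma = 0.1, replicates = 3L,
                          seed = 1L, target_gene = "NF1",
                          reference_gene = "GAPDH",
                          calibrator_sample = "father",
                          test_sample = "patient") {
  if (fold_change <= 0) stop("fold_change must be > 0", call. = FALSE)
  replicates <- assert_scalar_int(replicates, "replicates", 1L)
  with_seed(derive_seed(seed, "ct"), {
    ddct_true <- -log2(fold_change)
    base_ct <- c(ref = 20, target = 24)
    rows <- list()
    emit <- function(sample, gene, centre) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sample = sample, gene = gene, replicate = r,
          ct = centre + stats::rnorm(1L, 0, sigma), stringsAsFactors = FALSE)
      }
    }
    emit(calibrator_sample, reference_gene, base_ct["ref"])
    emit(calibrator_sample, target_gene, base_ct["target"])
    emit(test_sample, reference_gene, base_ct["ref"])
    emit(test_sample, target_gene, base_ct["target"] + ddct_true)
    list(ct_table = do.call(rbind, rows),
         truth = list(fold_change = fold_change,
                      percent_change = (fold_change - 1) * 100))
  })
}

#' Generate per-read binary methylation calls for one site
#'
#' @param n_reads Total reads covering the site.
#' @param n_methylated Methylated reads (0 <= n_methylated <= n_reads).
#' @param seed Integer seed (shuffles which reads carry the call).
#' @param contig,pos Site coordinates.
#' @return Data frame with columns `read_id, contig, pos, methylated`.
#' @export
make_methylation_calls <- function(n_reads = 12L, n_methylated = 10L,
                                   seed = 1L, contig = "chr17",
                                   pos = 31155980L) {
  n_reads <- assert_scalar_int(n_reads, "n_reads", 1L)
  n_methylated <- assert_scalar_int(n_methylated, "n_methylated", 0L)
  if (n_methylated > n_reads) {
    stop("n_methylated cannot exceed n_reads", call. = FALSE)
  }
  with_seed(derive_seed(seed, "meth"), {
    flags <- sample(c(rep(1L, n_methylated), rep(0L, n_reads - n_methylated)))
    data.frame(read_id = sprintf("read_%03d", seq_len(n_reads)),
               contig = contig, pos = pos, methylated = flags,
               stringsAsFactors = FALSE)
  })
}
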