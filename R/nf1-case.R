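#' Synthetic reconstruction of the NF1 c.61-2A>G locus geometry
#'
#' A fully synthetic ~700-bp sequence slice and 5-exon gene model built to
#' the published local geometry of the NF1 splice-acceptor case, at the
#' real GRCh38 coordinates: the acceptor-2 adenine at chr17:31,155,981
#' with exon 2 beginning at chr17:31,155,983 (coding position c.61), a
#' 20-bp intronic poly-T tract separated from the variant by a single
#' cytosine (chr17:31,155,980, the base that becomes a CpG cytosine under
#' the A>G allele), the first exonic AG at exonic positions 15-16 (a
#' 16-nt cryptic deletion), downstream codons engineered so the shifted
#' frame encodes 17 novel amino acids before its stop with 26 whole
#' wild-type exon codons beyond the stop's footprint, and a single
#' Cas12a TAM (5'-BAAA-3' on the plus strand) nine bases downstream of
#' the target with the neighbouring wild-type guanine at chr17:31,155,982
#' as the only bystander-editable base. Everything outside these planted
#' features is synthetic filler; this is a stand-in for the reference
#' locus, not GRCh38 sequence.
#'
#' @return A list of class `PlantedSpliceCase`: `genome`, `gene`,
#'   `variant` (chr17:31,155,981 A>G), `hgvs` (`"c.61-2A>G"`),
#'   `pathogenic_table` (the known pathogenic acceptor-1 G>A bystander at
#'   chr17:31,155,982), and `truth`.
#' @examples
#' case <- nf1_case()
#' case$variant
#' @export
nf1_case <- function() {
  origin <- 31155801L
  contig <- "chr17"

  utr <- "GCCGCCACC"
  exon1_codons <- c("ATG", "GAA", "AAG", "CTG", "GAT", "TTC", "AGC", "GTG",
                    "CCT", "ACC", "ATC", "CAG", "GGT", "GCT", "GAA", "AAG",
                    "CTG", "GAT", "AGC", "GTG")
  exon1 <- paste0(utr, paste(exon1_codons, collapse = ""))  # 69 nt

  intron1 <- paste0("GT", "CTCTTCTCTTCCTCTCTTC", strrep("T", 20L), "CAG")

  novel_codons <- c("GCA", "ACA", "GAA", "CAG", "GCA", "GGA", "AGC", "GAG",
                    "CAA", "GCG", "AAC", "AGG", "GCA", "GAA", "CAA", "GCG",
                    "CAG")
  tail_codons <- rep(c("GCA", "GAA", "CAG", "GGA", "ACA", "AGC"),
                     length.out = 26L)
  exon2 <- paste0("CTCTCTC", "TAAA", "CTC", "AG",
                  paste(novel_codons, collapse = ""), "TAA", "GC",
                  paste(tail_codons, collapse = ""), "TAA")  # 153 nt

  with_seed(20260926L, {
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
    pyr <- function(n) paste(sample(c("C", "T"), n, replace = TRUE),
                             collapse = "")
    pad <- rand(69L)
    intron_f <- function() paste0("GT", pyr(35L), "CAG")
    exon_f <- function() rand(80L)
    pieces <- list(exon1, intron1, exon2, intron_f(), exon_f(), intron_f(),
                   exon_f(), intron_f(), exon_f())
    seq <- paste0(pad, paste(unlist(pieces), collapse = ""), rand(40L))

    lens <- nchar(unlist(pieces))
    starts <- origin + 69L + c(0L, cumsum(lens)[-length(lens)])
    ends <- starts + lens - 1L
    exon_rows <- c(1L, 3L, 5L, 7L, 9L)
    exons <- cbind(starts[exon_rows], ends[exon_rows])
    gm <- gene_model("NF1_SYN", "NF1_SYN_TX", contig, "+", exons,
                     cds_start = exons[1, 1] + 9L, cds_end = exons[2, 2])
    gs <- genome_sequence(contig, seq, origin)
    v <- variant(contig, 31155981L, "A", "G", id = "rs1131691100",
                 genome = gs)
    tab <- data.frame(contig = contig, pos = 31155982L, ref = "G", alt = "A",
                      id = "rs1263745475", significance = "Pathogenic",
                      stringsAsFactors = FALSE)
    structure(list(genome = gs, gene = gm, variant = v, hgvs = "c.61-2A>G",
                   pathogenic_table = tab,
                   truth = list(cryptic_offset = 16L, deletion_nt = 16L,
                                novel_aa = 17L, truncation_aa = 26L,
                                frame_offset = 1L, nmd = TRUE,
                                created_cpg_c = 31155980L,
                                pam_distance = 9L,
                                bystander_pos = 31155982L)),
              class = "PlantedSpliceCase")
  })
}
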