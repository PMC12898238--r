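test_that("locate_splice_sites finds GT-AG pairs and flags deviants", {
  #           exon1      intron (GT....AG)  exon2
  seq <- paste0("ATGAAA", "GTCCTTTCAG", "CCCGGG")
  gs <- genome_sequence("c", seq, origin = 1)
  gm <- gene_model("G", "T", "c", "+", rbind(c(1, 6), c(17, 22)), 1, 22)
  sites <- locate_splice_sites(gm, gs)
  expect_equal(nrow(sites), 2L)
  expect_true(all(sites$canonical))
  expect_equal(sites$kind, c("donor", "acceptor"))
  expect_equal(sites$pos1[sites$kind == "acceptor"], 15)

  # GC donor: acceptor still reported, donor flagged non-canonical
  seq2 <- paste0("ATGAAA", "GCCCTTTCAG", "CCCGGG")
  gs2 <- genome_sequence("c", seq2, origin = 1)
  sites2 <- locate_splice_sites(gm, gs2)
  expect_false(sites2$canonical[sites2$kind == "donor"])
  expect_true(sites2$canonical[sites2$kind == "acceptor"])
})

test_that("splice-site counts equal exons minus one per kind", {
  for (seed in c(3, 14, 27)) {
    n <- sample(3:7, 1)
    pc <- make_splice_case(10, 2, 3, n_exons = n, seed = seed)
    sites <- locate_splice_sites(pc$gene, pc$genome)
    expect_equal(sum(sites$kind == "donor"), n - 1L)
    expect_equal(sum(sites$kind == "acceptor"), n - 1L)
    expect_true(all(sites$canonical))
  }
})

test_that("variant positions classify against splice-site registers", {
  pc <- make_splice_case(16, 17, 26, n_exons = 5, seed = 7)
  gm <- pc$gene
  expect_equal(classify_splice_variant(pc$variant, gm)$class, "acceptor-2")
  expect_equal(classify_splice_variant(pc$variant, gm)$intron_index, 1L)

  intr <- introns(gm)
  don1 <- variant("chrS", unname(intr[1, "start"]),
                  genomic_base(pc$genome, intr[1, "start"]), "C")
  expect_equal(classify_splice_variant(don1, gm)$class, "donor+1")

  ex2pos <- gm$exons[2, 1] + 50L
  exv <- variant("chrS", unname(ex2pos), genomic_base(pc$genome, ex2pos),
                 setdiff(c("A", "C", "G", "T"),
                         genomic_base(pc$genome, ex2pos))[1])
  cls <- classify_splice_variant(exv, gm)
  expect_equal(cls$class, "exonic")
  expect_equal(cls$exon_index, 2L)

  mid <- variant("chrS", unname(intr[2, "start"]) + 10L,
                 genomic_base(pc$genome, intr[2, "start"] + 10L), "A")
  expect_true(classify_splice_variant(mid, gm)$class %in%
                c("deep_intronic", "donor+1", "donor+2"))
  far <- variant("chrS", gm$exons[1, 1] - 500L, "A", "C")
  expect_error(classify_splice_variant(far, gm), "intergenic")
})

test_that("cryptic scan takes the nearest exonic AG and honours the limit", {
  # exon 2 beginning with AG: nearest-AG rule gives deletion 2
  seq <- paste0("ATGAAAGCA", "GTCCTTTCAG", "AGCCCGGGAAATTTCCCGGG")
  gs <- genome_sequence("c", seq, origin = 1)
  gm <- gene_model("G", "T", "c", "+", rbind(c(1, 9), c(20, 39)), 1, 39)
  cry <- scan_cryptic_acceptor(gs, gm, 1L)
  expect_true(cry$found)
  expect_equal(cry$deletion_length, 2L)
  expect_equal(cry$offset_exonic, 2L)

  # no AG in the scanned window: absence is a valid result
  seq2 <- paste0("ATGAAAGCA", "GTCCTTTCAG", strrep("CT", 10))
  gs2 <- genome_sequence("c", seq2, origin = 1)
  cry2 <- scan_cryptic_acceptor(gs2, gm, 1L)
  expect_false(cry2$found)
  expect_true(is.na(cry2$deletion_length))

  # max_scan_nt cuts the search short
  pc <- make_splice_case(40, 3, 2, seed = 2)
  galt <- apply_variant(pc$genome, pc$variant)
  expect_false(scan_cryptic_acceptor(galt, pc$gene, 1L,
                                     max_scan_nt = 20L)$found)
  expect_true(scan_cryptic_acceptor(galt, pc$gene, 1L,
                                    max_scan_nt = 100L)$found)
})

test_that("deletion length and variant distance use the stated conventions", {
  case <- nf1_case()
  galt <- apply_variant(case$genome, case$variant)
  cry <- scan_cryptic_acceptor(galt, case$gene, 1L, variant = case$variant)
  # removed exonic bases vs inclusive span from the acceptor-2 variant to
  # the AG's second base: 16 and 18 simultaneously
  expect_equal(cry$deletion_length, 16L)
  expect_equal(cry$distance_from_variant, 18L)
  expect_equal(cry$ag_pos_genomic, c(31155997L, 31155998L))
})

test_that("upstream intronic AG reporting is optional and labeled", {
  case <- nf1_case()
  galt <- apply_variant(case$genome, case$variant)
  cry <- scan_cryptic_acceptor(galt, case$gene, 1L, include_upstream = TRUE)
  expect_true(is.list(cry$upstream_intronic_ag))
  expect_false(isTRUE(cry$upstream_intronic_ag$found))  # poly-T tract has no AG
})

test_that("reconstruction is the identity without a cryptic call and
           conserves length with one", {
  pc <- make_splice_case(16, 17, 26, seed = 5)
  wild <- reconstruct_transcript(pc$gene, pc$genome)
  expect_equal(nchar(wild$cds), cds_length(pc$gene))
  expect_equal(substr(wild$cds, 1, 3), "ATG")

  galt <- apply_variant(pc$genome, pc$variant)
  cry <- scan_cryptic_acceptor(galt, pc$gene, 1L)
  mut <- reconstruct_transcript(pc$gene, galt, cry)
  expect_equal(nchar(mut$mrna), nchar(wild$mrna) - cry$deletion_length)
  expect_equal(mut$exon_lengths[2], wild$exon_lengths[2] - 16L)
  expect_equal(mut$junctions[1], wild$junctions[1])

  # deletion consuming the whole exon is rejected
  cry_bad <- cry
  cry_bad$deletion_length <- wild$exon_lengths[2]
  expect_error(reconstruct_transcript(pc$gene, galt, cry_bad), "consumes")
})

test_that("a minus-strand model reconstructs the reverse complement", {
  pc <- make_splice_case(7, 5, 4, n_exons = 3, seed = 11)
  gs <- pc$genome; gm <- pc$gene
  L <- nchar(gs$seq)
  mirror <- function(p) gs$origin + L - 1L - (p - gs$origin)
  gs2 <- genome_sequence("chrS", revcomp(gs$seq), origin = gs$origin)
  ex2 <- cbind(mirror(gm$exons[, 2]), mirror(gm$exons[, 1]))
  gm2 <- gene_model("G", "T", "chrS", "-", ex2, mirror(gm$cds_start),
                    mirror(gm$cds_end))
  w1 <- reconstruct_transcript(gm, gs)
  w2 <- reconstruct_transcript(gm2, gs2)
  expect_identical(w1$mrna, w2$mrna)
  expect_identical(w1$cds, w2$cds)

  v2 <- variant("chrS", mirror(pc$variant$pos), "T", "C", genome = gs2)
  sc2 <- splice_consequence(gs2, gm2, v2)
  expect_equal(sc2$cryptic$deletion_length, 7L)
  expect_equal(sc2$consequence$novel_aa_count, 5L)
  expect_equal(sc2$consequence$wildtype_exon_aa_lost_after_ptc, 4L)
})

test_that("frame analysis separates in-frame deletions from frameshifts", {
  pc15 <- make_splice_case(15, 0, 0, seed = 3)
  sc15 <- splice_consequence(pc15$genome, pc15$gene, pc15$variant)
  cons <- sc15$consequence
  expect_false(cons$is_frameshift)
  expect_equal(cons$frame_offset, 0L)
  expect_equal(cons$novel_aa_count, 0L)
  expect_equal(cons$in_frame_aa_deleted, 5L)

  pc16 <- make_splice_case(16, 17, 26, seed = 3)
  sc16 <- splice_consequence(pc16$genome, pc16$gene, pc16$variant)
  expect_true(sc16$consequence$is_frameshift)
  expect_equal(sc16$consequence$frame_offset, 1L)
  expect_equal(sc16$consequence$novel_aa_count, 17L)
  expect_equal(sc16$consequence$wildtype_exon_aa_lost_after_ptc, 26L)
})

test_that("frame_offset always equals deletion mod 3 and CDS length is
           conserved", {
  set.seed(23)
  for (i in 1:15) {
    k <- sample(2:45, 1); f <- k %% 3
    pc <- make_splice_case(k, if (f == 0) 0 else sample(1:20, 1),
                           if (f == 0) 0 else sample(0:20, 1), seed = i + 200)
    sc <- splice_consequence(pc$genome, pc$gene, pc$variant)
    expect_equal(sc$consequence$frame_offset, f)
    expect_identical(sc$consequence$is_frameshift, f != 0L)
    expect_equal(nchar(sc$mutant$mrna), nchar(sc$wild$mrna) - k)
  }
})

test_that("the per-frame stop map equals a naive three-frame scan", {
  set.seed(31)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:120, 1),
                      replace = TRUE), collapse = "")
    expect_identical(stop_map(s), oracle_stop_map(s))
  }
})

test_that("analyze_frame validates its inputs", {
  expect_error(analyze_frame("CCCTAA", "CCCTAA", NULL, 0), "ATG")
  res <- analyze_frame("ATGGCCTAA", "ATGGCCGCAGCC", NULL, 1)
  expect_true(res$no_stop)
  expect_match(res$rule_detail, "no stop")
})

test_that("NMD follows the 55-nt last-junction rule exactly", {
  # planted geometry: junction distance = 7 + 3 * truncation_aa for a
  # frame-offset-1 case with three exons
  at_55 <- make_splice_case(16, 5, 16, n_exons = 3, seed = 9)
  sc <- splice_consequence(at_55$genome, at_55$gene, at_55$variant)
  expect_equal(sc$consequence$nmd_distance_nt, 55L)
  expect_true(sc$consequence$nmd_predicted)

  below <- make_splice_case(16, 5, 15, n_exons = 3, seed = 9)
  scb <- splice_consequence(below$genome, below$gene, below$variant)
  expect_equal(scb$consequence$nmd_distance_nt, 52L)
  expect_false(scb$consequence$nmd_predicted)

  # PTC in the last exon is NMD-negative regardless of distance
  last_exon <- make_splice_case(16, 5, 30, n_exons = 2, seed = 9)
  scl <- splice_consequence(last_exon$genome, last_exon$gene,
                            last_exon$variant)
  expect_false(scl$consequence$nmd_predicted)
  expect_match(scl$consequence$nmd_rule, "last exon")

  # threshold is configurable
  sc56 <- splice_consequence(at_55$genome, at_55$gene, at_55$variant,
                             nmd_threshold = 56L)
  expect_false(sc56$consequence$nmd_predicted)
})

test_that("peptide mass matches independent residue summation", {
  expect_equal(peptide_mass(""), 0.01801528, tolerance = 1e-9)
  expect_equal(round(peptide_mass("G"), 5), 0.07507)
  expect_error(peptide_mass("GXZ"), "unknown")
  set.seed(77)
  aas <- names(splicecase:::AA_AVG_MASS)
  for (i in 1:10) {
    p <- paste(sample(aas, 37, replace = TRUE), collapse = "")
    expect_equal(peptide_mass(p), oracle_peptide_mass_kda(p),
                 tolerance = 1e-12)
  }
  # additivity: mass(ab) = mass(a) + mass(b) - one water
  expect_equal(peptide_mass("ACDEF"),
               peptide_mass("AC") + peptide_mass("DEF") - 0.01801528,
               tolerance = 1e-12)
})

test_that("wild-type identity: no cryptic call reproduces the wild peptide", {
  pc <- make_splice_case(16, 17, 26, seed = 19)
  wild <- reconstruct_transcript(pc$gene, pc$genome)
  tr1 <- splicecase:::translate_to_stop(wild$cds)
  tr2 <- splicecase:::translate_to_stop(
    reconstruct_transcript(pc$gene, pc$genome, NULL)$cds)
  expect_identical(tr1$peptide, tr2$peptide)
  expect_true(tr1$stop_found)
})
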