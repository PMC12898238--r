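test_that("read_fasta concatenates, uppercases and preserves record order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$seq, "ACGTACGT")
  expect_equal(nchar(recs[[1]]$seq), 8L)

  writeLines(c(">a", "AC", ">b", "GT"), f)
  recs <- read_fasta(f)
  expect_equal(names(recs), c("a", "b"))
  expect_equal(recs[[2]]$seq, "GT")
})

test_that("read_fasta rejects empty and malformed input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|format")
  writeLines(c(">x", "ACQT"), f)
  expect_error(read_fasta(f))
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("FASTA write/read round-trips records with origins", {
  set.seed(41)
  f <- withr::local_tempfile(fileext = ".fa")
  for (i in 1:20) {
    recs <- lapply(seq_len(sample(1:3, 1)), function(j) {
      genome_sequence(paste0("ctg", j),
                      paste(sample(c("A", "C", "G", "T", "N"),
                                   sample(5:200, 1), replace = TRUE),
                            collapse = ""),
                      origin = sample(1:10^6, 1))
    })
    write_fasta(recs, f)
    back <- read_fasta(f)
    expect_equal(unname(lapply(back, unclass)), lapply(recs, unclass))
  }
})

test_that("revcomp handles N, is an involution and preserves GC content", {
  expect_equal(revcomp("TTTA"), "TAAA")
  expect_equal(revcomp("ACGTN"), "NACGT")
  expect_error(revcomp("BAAA"), "non-DNA")
  set.seed(7)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
    gc <- function(x) sum(strsplit(x, "")[[1]] %in% c("G", "C"))
    expect_identical(gc(revcomp(s)), gc(s))
  }
})

test_that("variant construction enforces SNV-only and reference match", {
  gs <- genome_sequence("chr1", "ACGT", origin = 10)
  expect_error(variant("chr1", 11, "CC", "T"), "SNV")
  expect_error(variant("chr1", 11, "C", "C"), "differ")
  expect_error(variant("chr1", 11, "G", "T", genome = gs), "does not match")
  v <- variant("chr1", 11, "C", "T", genome = gs)
  expect_equal(v$pos, 11L)
  expect_equal(genomic_base(apply_variant(gs, v), 11), "T")
})

test_that("apply_variant leaves every other base untouched", {
  set.seed(13)
  for (i in 1:10) {
    tm <- random_toy_model(i)
    gs <- tm$genome
    p <- sample(gs$origin:genome_end(gs), 1)
    ref <- genomic_base(gs, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mutated <- apply_variant(gs, variant("chrT", p, ref, alt))
    idx <- p - gs$origin + 1
    expect_equal(substr(mutated$seq, idx, idx), alt)
    expect_equal(substr(mutated$seq, 1, idx - 1), substr(gs$seq, 1, idx - 1))
    expect_equal(substr(mutated$seq, idx + 1, nchar(gs$seq)),
                 substr(gs$seq, idx + 1, nchar(gs$seq)))
  }
})

test_that("parse_hgvs_c reproduces the published acceptor coordinates", {
  gm <- nf1_like_toy()
  res <- parse_hgvs_c("c.61-2A>G", gm)
  expect_equal(res$variant$pos, 31155981L)
  expect_equal(res$variant$ref, "A")
  expect_equal(res$variant$alt, "G")
  expect_equal(res$hgvs$cds_pos, 61L)
  expect_equal(res$hgvs$intron_offset, -2L)
  # the acceptor site itself (c.61 first exonic base) is at 31,155,983
  expect_equal(parse_hgvs_c("c.61C>T", gm)$variant$pos, 31155983L)
})

test_that("parse_hgvs_c maps exonic and donor-side coordinates on toys", {
  gm <- gene_model("G", "T", "chr1", "+",
                   rbind(c(100, 200), c(240, 320)), 100, 300)
  expect_equal(parse_hgvs_c("c.1A>T", gm)$variant$pos, 100L)
  # exon 1 coding end is c.101 at genomic 200; donor+1 is 201
  expect_equal(parse_hgvs_c("c.101+1G>T", gm)$variant$pos, 201L)
  expect_equal(parse_hgvs_c("c.102-1A>G", gm)$variant$pos, 239L)
  expect_error(parse_hgvs_c("c.101+45G>T", gm), "intron bounds")
  expect_error(parse_hgvs_c("c.9999A>T", gm), "beyond CDS")
  expect_error(parse_hgvs_c("c.10_12del", gm), "unsupported")
  expect_error(parse_hgvs_c("c.5-2A>G", gm), "exon start")
})

test_that("minus-strand HGVS emits reverse-complemented plus-strand alleles", {
  gm <- gene_model("G", "T", "chr1", "-",
                   rbind(c(240, 320), c(100, 200)), 300, 120)
  res <- parse_hgvs_c("c.1A>T", gm)
  expect_equal(res$variant$pos, 300L)
  expect_equal(res$variant$ref, "T")   # transcript A on minus strand
  expect_equal(res$variant$alt, "A")
})

test_that("parse_hgvs_c agrees with a brute-force per-base walker", {
  for (seed in 1:100) {
    tm <- random_toy_model(seed)
    gm <- tm$model
    pos_oracle <- oracle_cds_positions(gm)
    n <- length(pos_oracle)
    set.seed(seed + 10^6)
    for (cp in unique(c(1L, n, sample(seq_len(n), 4)))) {
      g <- pos_oracle[cp]
      ref <- "A"  # allele letters are irrelevant to the coordinate walk
      txt <- sprintf("c.%dA>G", cp)
      expect_equal(parse_hgvs_c(txt, gm)$variant$pos, g,
                   info = sprintf("seed %d c.%d", seed, cp))
    }
  }
})

test_that("gene model JSON round-trips and GFF3 respects strand order", {
  gm <- gene_model("G1", "T1", "chr2", "+",
                   rbind(c(10, 30), c(41, 60), c(75, 100)), 15, 90)
  f <- withr::local_tempfile(fileext = ".json")
  write_gene_model_json(gm, f)
  back <- read_gene_model(f)
  expect_equal(unclass(back), unclass(gm))
  expect_equal(n_exons(back), 3L)
  expect_equal(unname(introns(back)), rbind(c(31L, 40L), c(61L, 74L)),
               ignore_attr = TRUE)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr2\tt\tgene\t10\t100\t.\t-\t.\tID=G1",
               "chr2\tt\tmRNA\t10\t100\t.\t-\t.\tID=T1;Parent=G1",
               "chr2\tt\texon\t10\t30\t.\t-\t.\tParent=T1",
               "chr2\tt\texon\t41\t60\t.\t-\t.\tParent=T1",
               "chr2\tt\texon\t75\t100\t.\t-\t.\tParent=T1",
               "chr2\tt\tCDS\t15\t90\t.\t-\t0\tParent=T1"), gff)
  gmm <- read_gene_model(gff)
  expect_equal(gmm$strand, "-")
  # transcript order: descending genomic start on the minus strand
  expect_equal(unname(gmm$exons[, 1]), c(75, 41, 10))
  expect_equal(gmm$cds_start, 90L)
  expect_equal(gmm$cds_end, 15L)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("G", "T", "c", "+", rbind(c(10, 30), c(25, 50)),
                          12, 45), "overlap|order")
  expect_error(gene_model("G", "T", "+", "*", rbind(c(10, 30)), 12, 20),
               "strand")
  expect_error(gene_model("G", "T", "c", "+", rbind(c(10, 30), c(33, 50)),
                          12, 45), "intron")
  expect_error(gene_model("G", "T", "c", "+", rbind(c(10, 30), c(40, 50)),
                          35, 45), "inside exons")
})

test_that("minimal VCF round-trips variants", {
  f <- withr::local_tempfile(fileext = ".vcf")
  vs <- list(variant("chr17", 31155981, "A", "G", id = "rs1131691100"),
             variant("chr17", 31155982, "G", "A"))
  write_vcf(vs, f)
  back <- read_vcf_variants(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$pos, 31155981L)
  expect_equal(back[[1]]$id, "rs1131691100")
  expect_null(back[[2]]$id)
  expect_equal(back[[2]]$ref, "G")
})
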