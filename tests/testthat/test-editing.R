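test_that("the shipped catalog loads and malformed specs are rejected", {
  cat <- default_nuclease_catalog()
  expect_gte(length(cat), 3L)
  names <- vapply(cat, `[[`, "", "name")
  expect_true("Cas12a-CBE" %in% names)
  cas12a <- cat[[which(names == "Cas12a-CBE")]]
  expect_equal(cas12a$motif, "TTTV")
  expect_equal(cas12a$window, c(8L, 14L))

  expect_error(nuclease_spec("x", "NGG", "3prime_of_protospacer", 20,
                             c(9, 8), "CBE"), "window")
  expect_error(nuclease_spec("x", "NQG", "3prime_of_protospacer", 20,
                             c(4, 8), "CBE"), "IUPAC")
  expect_error(nuclease_spec("x", "NGG", "sideways", 20, c(4, 8), "CBE"),
               "motif_side")
})

test_that("catalog write/read round-trips", {
  cat <- default_nuclease_catalog()
  f <- withr::local_tempfile(fileext = ".json")
  write_nuclease_catalog(cat, f)
  back <- load_nuclease_catalog(f)
  expect_equal(lapply(back, unclass), lapply(cat, unclass))
})

test_that("planted editing geometry yields exactly one in-window candidate", {
  ec <- make_editing_case(pam_offset = 9, n_bystanders = 1, hazardous = TRUE,
                          seed = 3)
  cands <- scan_editor_sites(ec$genome, ec$target)
  c12 <- Filter(function(x) x$nuclease == "Cas12a-CBE", cands)
  expect_length(c12, 1L)
  cand <- c12[[1]]
  expect_equal(cand$strand, "-")
  expect_equal(cand$target_window_pos, 9L)
  expect_equal(cand$target_distance_to_pam, 9L)
  # the TAM reads BAAA on the displayed plus strand
  expect_match(cand$pam_seq_plus, "^[CGT]AAA$")

  bys <- enumerate_bystanders(cand, ec$genome, ec$target)
  expect_length(bys, 1L)
  expect_equal(bys[[1]]$substitution, "G>A")
  cl <- classify_bystanders(bys, ec$pathogenic_table, "chrE")
  expect_equal(cl$verdict, "hazardous")
  expect_equal(cl$bystanders[[1]]$matched_id, "rsSYN0001")
})

test_that("a motif-free window yields no candidates", {
  gs <- genome_sequence("c", strrep("A", 61), origin = 1)
  v <- variant("c", 31, "A", "G")
  gs <- apply_variant(gs, v)
  expect_length(scan_editor_sites(gs, v), 0L)
  expect_length(design_prime_edit(gs, v), 0L)
})

test_that("chemistry gating rejects placements that cannot make the
           correction", {
  ec <- make_editing_case(9, 1, hazardous = FALSE, seed = 21)
  # same geometry but a correction (G>C) no CBE/ABE chemistry can perform
  v_odd <- variant("chrE", ec$target$pos, "C", "G")
  expect_length(scan_editor_sites(ec$genome, v_odd), 0L)
  # the real G>A correction routes to the minus-strand CBE only
  cands <- scan_editor_sites(ec$genome, ec$target)
  expect_true(all(vapply(cands, `[[`, "", "strand") == "-"))
  expect_true(all(vapply(cands, `[[`, "", "chemistry") == "CBE"))
})

test_that("IUPAC motif matching equals the k-mer expansion oracle", {
  set.seed(61)
  for (i in 1:200) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    gs <- genome_sequence("c", seq, origin = 1)
    motif <- sample(c("TTTV", "NGG", "BAAA", "NNGRRT"), 1)
    for (strand in c("+", "-")) {
      got <- splicecase:::motif_matches(gs, motif, strand, 1L, 60L)
      want <- oracle_motif_starts(seq, motif, strand)
      expect_equal(sort(got[, 1]), want,
                   info = sprintf("seed-case %d motif %s strand %s", i,
                                  motif, strand))
    }
  }
})

test_that("motif scanning is symmetric under reverse complement", {
  set.seed(62)
  for (i in 1:30) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    gs <- genome_sequence("c", seq, 1)
    gs_rc <- genome_sequence("c", revcomp(seq), 1)
    for (motif in c("TTTV", "NGG")) {
      plus <- splicecase:::motif_matches(gs, motif, "+", 1L, 60L)
      minus_rc <- splicecase:::motif_matches(gs_rc, motif, "-", 1L, 60L)
      # a plus-strand match at [s, e] mirrors to a minus-strand match
      mirrored <- sort(60L + 1L - plus[, 2])
      expect_equal(sort(minus_rc[, 1]), mirrored)
    }
  }
})

test_that("bystander enumeration equals a per-base chemistry oracle", {
  set.seed(63)
  n_checked <- 0L
  for (i in 1:60) {
    ec <- make_editing_case(pam_offset = sample(8:14, 1),
                            n_bystanders = sample(0:5, 1),
                            hazardous = FALSE, seed = i + 500)
    cands <- scan_editor_sites(ec$genome, ec$target)
    c12 <- Filter(function(x) x$nuclease == "Cas12a-CBE", cands)
    expect_length(c12, 1L)
    cand <- c12[[1]]
    bys <- enumerate_bystanders(cand, ec$genome, ec$target)
    got <- sort(vapply(bys, `[[`, 0L, "pos"))
    # oracle: walk every window position, check the minus-strand base is C
    # (G on plus), excluding the target
    want <- integer(0)
    for (j in cand$window[1]:cand$window[2]) {
      coord <- splicecase:::protospacer_coord(cand$pam_span, cand$motif_side,
                                              cand$strand, cand$spacer_length,
                                              j)
      if (coord != ec$target$pos &&
          genomic_base(ec$genome, coord) == "G") {
        want <- c(want, coord)
      }
    }
    expect_equal(got, sort(want))
    expect_equal(got, ec$truth$bystander_positions)
    # a bystander substitution never touches the target base
    expect_false(ec$target$pos %in% got)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 60L)
})

test_that("bystanders absent from the table stay unannotated and clean", {
  ec <- make_editing_case(9, 2, hazardous = FALSE, seed = 8)
  cands <- scan_editor_sites(ec$genome, ec$target)
  cand <- Filter(function(x) x$nuclease == "Cas12a-CBE", cands)[[1]]
  bys <- enumerate_bystanders(cand, ec$genome, ec$target)
  cl <- classify_bystanders(bys, ec$pathogenic_table, "chrE")
  expect_equal(cl$verdict, "clean")
  expect_true(all(vapply(cl$bystanders, `[[`, "", "classification") ==
                    "unannotated"))
  expect_equal(classify_bystanders(list(), ec$pathogenic_table,
                                   "chrE")$verdict, "clean")
})

test_that("malformed pathogenic-table rows are reported by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig\tpos\tref\talt\tid\tsignificance",
               "chr17\t31155982\tG\tA\trs1\tPathogenic",
               "chr17\tnotanumber\tG\tA\trs2\tBenign"), f)
  expect_error(read_pathogenic_table(f), "row 3")
})

test_that("prime design places the nick between protospacer 17 and 18", {
  # single NGG whose nick lands 5 nt from the target: RTT = 5 + 1 + 10
  bases <- rep(c("A", "T"), length.out = 81)
  v <- variant("c", 44, bases[44], "G")
  bases[43] <- "G"; bases[44] <- "G"   # PAM = AGG at 42..44 (target inside)
  gs <- genome_sequence("c", paste(bases, collapse = ""), origin = 1)
  cands <- design_prime_edit(gs, v)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$strand, "+")
  expect_equal(cands[[1]]$pam_pos, 42L)
  expect_equal(cands[[1]]$nick_to_edit_nt, 5L)
  expect_equal(cands[[1]]$rtt_length, 5L + 1L + 10L)
  expect_equal(nchar(cands[[1]]$spacer), 20L)
})

test_that("prime candidate count equals a brute-force NGG distance scan", {
  set.seed(67)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
    gs <- genome_sequence("c", seq, origin = 1)
    v <- variant("c", 60, substr(seq, 60, 60),
                 setdiff(c("A", "C", "G", "T"), substr(seq, 60, 60))[1])
    got <- design_prime_edit(gs, v, max_nick_to_edit = 30)
    # oracle: scan every position for GG (plus) / CC (minus) and apply the
    # nick arithmetic directly
    want <- 0L
    for (p in 1:118) {
      if (substr(seq, p + 1, p + 2) == "GG") {
        d <- 60 - (p - 3)
        if (d >= 0 && d <= 30 && p - 20 >= 1) want <- want + 1L
      }
      if (substr(seq, p, p + 1) == "CC" && p + 2 <= 120) {
        d <- (p + 5) - 60
        if (d >= 0 && d <= 30 && p + 22 <= 120) want <- want + 1L
      }
    }
    expect_length(got, want)
    dists <- vapply(got, `[[`, 0L, "nick_to_edit_nt")
    expect_false(is.unsorted(dists))
    expect_true(all(dists >= 0 & dists <= 30))
  }
})

test_that("strategy ranking demotes hazardous base editing below prime", {
  ec <- make_editing_case(9, 1, hazardous = TRUE, seed = 12)
  cands <- scan_editor_sites(ec$genome, ec$target)
  cand <- Filter(function(x) x$nuclease == "Cas12a-CBE", cands)[[1]]
  bys <- enumerate_bystanders(cand, ec$genome, ec$target)
  cand$verdict <- classify_bystanders(bys, ec$pathogenic_table,
                                      "chrE")$verdict
  fake_prime <- structure(list(spacer = strrep("A", 20), pam_pos = 1L,
                               strand = "+", nick_to_edit_nt = 5L,
                               pbs_length = 13L, rtt_length = 16L),
                          class = "PrimeEditCandidate")
  rep <- rank_strategies(list(cand), list(fake_prime))
  expect_equal(rep$type[1], "prime_editing")
  expect_equal(rep$type[2], "base_editing")
  expect_match(attr(rep, "recommendation"), "prime")

  cand$verdict <- "clean"
  rep2 <- rank_strategies(list(cand), list())
  expect_equal(rep2$type[1], "base_editing")
  expect_match(attr(rep2, "recommendation"), "base")

  rep3 <- rank_strategies(list(), list())
  expect_equal(nrow(rep3), 0L)
  expect_equal(attr(rep3, "recommendation"), "no in-silico strategy")
})
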