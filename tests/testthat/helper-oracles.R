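# Independent brute-force oracles and toy-model builders used across the
# suite. These deliberately re-derive results from first principles
# (per-base walks, k-mer expansion, naive rescans) so they stay
# independent of the implementation paths they check.

# Per-base CDS coordinate walker: enumerate every exonic base in
# transcript orientation and keep those between the coding bounds.
oracle_cds_positions <- function(model) {
  pos <- integer(0)
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1]; e <- model$exons[i, 2]
    pos <- c(pos, if (model$strand == "+") s:e else e:s)
  }
  i_start <- match(model$cds_start, pos)
  i_end <- match(model$cds_end, pos)
  pos[i_start:i_end]
}

# Random toy gene model + matching genome for coordinate properties.
random_toy_model <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(2:5, 1)
  lens <- sample(9:40, n_ex, replace = TRUE)
  gaps <- sample(6:30, n_ex - 1, replace = TRUE)
  origin <- sample(1000:5000, 1)
  starts <- integer(n_ex)
  p <- origin + 5L
  ex <- matrix(0L, n_ex, 2)
  for (i in seq_len(n_ex)) {
    ex[i, ] <- c(p, p + lens[i] - 1L)
    if (i < n_ex) p <- p + lens[i] + gaps[i]
  }
  total_len <- sum(lens)
  # coding region properly inside the exon chain
  c1 <- sample(1:3, 1)
  c2 <- total_len - sample(0:3, 1)
  flat <- unlist(lapply(seq_len(n_ex), function(i) ex[i, 1]:ex[i, 2]))
  if (strand == "-") {
    ex <- ex[n_ex:1, , drop = FALSE]
    flat <- rev(flat)
  }
  model <- gene_model("G", "T", "chrT", strand, ex, flat[c1], flat[c2])
  seq_len_total <- ex[which.max(ex[, 2]), 2] - origin + 20L
  seq <- paste(sample(c("A", "C", "G", "T"), seq_len_total, replace = TRUE),
               collapse = "")
  list(model = model, genome = genome_sequence("chrT", seq, origin))
}

# Naive 3-frame stop scan.
oracle_stop_map <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 1:3) {
    hits <- integer(0)
    p <- as.integer(f)
    while (p + 2L <= nchar(seq)) {
      if (substr(seq, p, p + 2L) %in% stops) hits <- c(hits, p)
      p <- p + 3L
    }
    out[[paste0("frame", f)]] <- hits
  }
  out
}

# IUPAC expansion + plain string search, both strands.
IUPAC <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_expand <- function(motif) {
  sets <- IUPAC[strsplit(motif, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# All start positions (1-based within seq) of IUPAC motif matches on the
# given strand; minus-strand motifs are searched as their reverse
# complement read on the plus strand.
oracle_motif_starts <- function(seq, motif, strand) {
  kmers <- iupac_expand(motif)
  if (strand == "-") kmers <- vapply(kmers, oracle_revcomp, "")
  hits <- integer(0)
  for (km in kmers) {
    p <- 1L
    repeat {
      i <- regexpr(km, substr(seq, p, nchar(seq)), fixed = TRUE)
      if (i == -1L) break
      hits <- c(hits, p + i - 1L)
      p <- p + i
    }
  }
  sort(unique(hits))
}

# Direct recount of methylation calls.
oracle_meth_fraction <- function(calls, site) {
  hit <- calls[calls$pos == site, , drop = FALSE]
  sum(hit$methylated == 1) / nrow(hit)
}

# Regex-expansion homopolymer oracle.
oracle_homopolymer <- function(seq, min_length) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, min_length), seq)[[1]]
    if (m[1] == -1L) next
    for (i in seq_along(m)) {
      out[[length(out) + 1L]] <- data.frame(
        base = b, start = as.integer(m[i]),
        length = attr(m, "match.length")[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(base = character(0), start = integer(0),
                                      length = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start), , drop = FALSE]
}

# Independent average-mass summation (Expasy residue masses).
ORACLE_AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

oracle_peptide_mass_kda <- function(p) {
  (sum(ORACLE_AA_MASS[strsplit(p, "")[[1]]]) + 18.01528) / 1000
}

# NF1-like two-exon toy for HGVS examples: exon 1 carries c.1-60 so exon
# 2's first coding base (c.61) sits at genomic 31,155,983.
nf1_like_toy <- function() {
  gene_model("NF1toy", "TXtoy", "chr17", "+",
             rbind(c(31155903, 31155962),
                   c(31155983, 31156100)),
             31155903, 31156090)
}
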