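#' Single-nucleotide variant in genomic plus-strand coordinates
#'
#' Only SNVs are supported; indels and multi-nucleotide substitutions are
#' rejected. `ref`/`alt` are plus-strand bases regardless of the strand of
#' any gene the variant affects.
#'
#' @param contig Contig name.
#' @param pos 1-based genomic position.
#' @param ref,alt Single plus-strand bases, `ref != alt`.
#' @param id Optional identifier (e.g. an rs number).
#' @param annotations Optional named character vector/list of pass-through
#'   annotations (e.g. externally computed pathogenicity or splice scores);
#'   never computed by this package.
#' @param genome Optional [genome_sequence()]; when supplied, `ref` is
#'   checked against the reference base at `pos`.
#' @return An object of class `Variant`.
#' @examples
#' variant("chr17", 31155981, "A", "G", id = "rs1131691100")
#' @export
variant <- function(contig, pos, ref, alt, id = NULL, annotations = NULL,
                    genome = NULL) {
  pos <- assert_scalar_int(pos, "pos", 1L)
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L) {
    stop("only SNVs are supported (ref/alt must be single bases)", call. = FALSE)
  }
  assert_dna(ref, allow_n = FALSE, what = "ref")
  assert_dna(alt, allow_n = FALSE, what = "alt")
  if (identical(ref, alt)) stop("ref must differ from alt", call. = FALSE)
  v <- structure(list(contig = contig, pos = pos, ref = ref, alt = alt,
                      id = id, annotations = annotations),
                 class = "Variant")
  if (!is.null(genome)) {
    have <- genomic_base(genome, pos)
    if (!identical(have, ref)) {
      stop(sprintf("ref %s does not match reference base %s at %s:%d",
                   ref, have, contig, pos), call. = FALSE)
    }
  }
  v
}

#' @export
print.Variant <- function(x, ...) {
  cat(sprintf("Variant %s:%d %s>%s%s\n", x$contig, x$pos, x$ref, x$alt,
              if (!is.null(x$id)) paste0(" (", x$id, ")") else ""))
  invisible(x)
}

#' Read SNVs from a minimal VCF
#'
#' Parses CHROM, POS, ID, REF and ALT of a VCF v4.2 file (other columns are
#' ignored). Non-SNV records are rejected.
#'
#' @param path Path to a VCF file.
#' @param genome Optional [genome_sequence()] used to check REF alleles.
#' @return List of [variant()] objects in file order.
#' @export
read_vcf_variants <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fix <- vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE))
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  lapply(seq_len(nrow(fix)), function(i) {
    id <- unname(fix[i, "ID"])
    variant(unname(fix[i, "CHROM"]), as.integer(fix[i, "POS"]),
            unname(fix[i, "REF"]), unname(fix[i, "ALT"]),
            id = if (is.na(id) || id == ".") NULL else id,
            genome = genome)
  })
}

#' Write SNVs as a minimal VCF
#'
#' @param variants A `Variant` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  if (inherits(variants, "Variant")) variants <- list(variants)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (v in variants) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$contig, v$pos,
                       if (is.null(v$id)) "." else v$id, v$ref, v$alt), con)
  }
  invisible(path)
}

#' Parse an HGVS c. SNV and map it to genomic coordinates
#'
#' Supports the SNV grammar `c.<pos><ref]>[alt]` with an optional intronic
#' offset, e.g. `"c.61-2A>G"` (2 bases into the intron upstream of coding
#' position 61) or `"c.60+1G>T"` (first base of the intron downstream of
#' coding position 60). The genomic position is computed by walking the
#' coding sequence across the model's exons in transcript orientation and
#' then applying the intronic offset into the adjacent intron. HGVS
#' `ref`/`alt` are transcript-strand bases; the returned [variant()] carries
#' genomic plus-strand bases (reverse-complemented for minus-strand models).
#'
#' @param text HGVS c. string.
#' @param model A [gene_model()].
#' @param genome Optional [genome_sequence()] to verify the reference base.
#' @return A list with elements `hgvs` (class `HgvsC`: `cds_pos`,
#'   `intron_offset`, `ref`, `alt`) and `variant` (class `Variant`).
#' @examples
#' gm <- gene_model("G", "T1", "chr1", "+",
#'                  rbind(c(100, 160), c(200, 260)), 110, 250)
#' parse_hgvs_c("c.1A>T", gm)$variant$pos  # 110
#' @export
parse_hgvs_c <- function(text, model, genome = NULL) {
  m <- regmatches(text,
                  regexec("^c\\.(\\d+)([+-]\\d+)?([ACGTacgt])>([ACGTacgt])$", text))[[1]]
  if (length(m) == 0L) {
    stop("unsupported HGVS expression (SNV c. grammar only): ", text,
         call. = FALSE)
  }
  cds_pos <- as.integer(m[2])
  offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  ref_t <- toupper(m[4]); alt_t <- toupper(m[5])
  if (identical(ref_t, alt_t)) stop("ref must differ from alt", call. = FALSE)

  cds_pos_all <- cds_genomic_positions(model)
  if (cds_pos > length(cds_pos_all)) {
    stop(sprintf("c.%d beyond CDS length %d", cds_pos, length(cds_pos_all)),
         call. = FALSE)
  }
  g0 <- cds_pos_all[cds_pos]
  dir <- if (model$strand == "+") 1L else -1L
  ex <- model$exons
  exon_of <- which(g0 >= ex[, 1] & g0 <= ex[, 2])

  if (offset == 0L) {
    gpos <- g0
  } else if (offset < 0L) {
    # upstream intronic offset: valid only from the first base of a non-first exon
    first_base <- if (model$strand == "+") ex[exon_of, 1] else ex[exon_of, 2]
    if (g0 != first_base || exon_of == 1L) {
      stop(sprintf("c.%d%+d: coding base is not at an acceptor-adjacent exon start",
                   cds_pos, offset), call. = FALSE)
    }
    intr <- introns(model)[exon_of - 1L, ]
    gpos <- g0 + dir * offset  # offset negative: moves upstream in transcript sense
    if (gpos < intr["start"] || gpos > intr["end"]) {
      stop(sprintf("c.%d%+d walks past intron bounds", cds_pos, offset),
           call. = FALSE)
    }
  } else {
    # downstream intronic offset: valid only from the last base of a non-last exon
    last_base <- if (model$strand == "+") ex[exon_of, 2] else ex[exon_of, 1]
    if (g0 != last_base || exon_of == nrow(ex)) {
      stop(sprintf("c.%d%+d: coding base is not at a donor-adjacent exon end",
                   cds_pos, offset), call. = FALSE)
    }
    intr <- introns(model)[exon_of, ]
    gpos <- g0 + dir * offset
    if (gpos < intr["start"] || gpos > intr["end"]) {
      stop(sprintf("c.%d%+d walks past intron bounds", cds_pos, offset),
           call. = FALSE)
    }
  }

  if (model$strand == "+") {
    ref_g <- ref_t; alt_g <- alt_t
  } else {
    ref_g <- comp_base(ref_t); alt_g <- comp_base(alt_t)
  }
  hgvs <- structure(list(cds_pos = cds_pos, intron_offset = offset,
                         ref = ref_t, alt = alt_t), class = "HgvsC")
  list(hgvs = hgvs,
       variant = variant(model$contig, gpos, ref_g, alt_g, genome = genome))
}
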