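# Base-editor PAM/TAM placement scanning, bystander-edit enumeration and
# classification, and simplified prime-editing design.

#' Nuclease / base-editor specification
#'
#' @param name Editor name.
#' @param motif PAM/TAM motif as an IUPAC string on the protospacer strand
#'   (e.g. `"TTTV"`, `"NGG"`).
#' @param motif_side `"5prime_of_protospacer"` (Cas12a-like) or
#'   `"3prime_of_protospacer"` (SpCas9-like).
#' @param spacer_length Protospacer length in nt.
#' @param window Inclusive editing-window positions `c(w_start, w_end)`,
#'   counted from the protospacer 5' end (PAM-proximal for Cas12a,
#'   PAM-distal for SpCas9 — the editor literature's convention).
#' @param chemistry `"CBE"` (C->T) or `"ABE"` (A->G), applied on the
#'   protospacer strand.
#' @return An object of class `NucleaseSpec`.
#' @export
nuclease_spec <- function(name, motif, motif_side, spacer_length, window,
                          chemistry) {
  motif <- toupper(motif)
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  if (!all(strsplit(motif, "")[[1]] %in% iupac)) {
    stop("motif must be an IUPAC DNA string: ", motif, call. = FALSE)
  }
  if (!motif_side %in% c("5prime_of_protospacer", "3prime_of_protospacer")) {
    stop("invalid motif_side: ", motif_side, call. = FALSE)
  }
  spacer_length <- assert_scalar_int(spacer_length, "spacer_length", 1L)
  window <- as.integer(window)
  if (length(window) != 2L || is.na(window[1]) || is.na(window[2]) ||
      window[1] < 1L || window[1] > window[2] || window[2] > spacer_length) {
    stop("window must satisfy 1 <= w_start <= w_end <= spacer_length",
         call. = FALSE)
  }
  if (!chemistry %in% c("CBE", "ABE")) {
    stop("chemistry must be CBE or ABE", call. = FALSE)
  }
  structure(list(name = name, motif = motif, motif_side = motif_side,
                 spacer_length = spacer_length, window = window,
                 chemistry = chemistry), class = "NucleaseSpec")
}

#' Load a nuclease catalog from JSON or YAML
#'
#' @param path Path to a JSON (`.json`) or YAML file holding a list of
#'   objects with fields `name, motif, motif_side, spacer_length, window,
#'   chemistry`.
#' @return List of [nuclease_spec()] objects.
#' @seealso [default_nuclease_catalog()]
#' @export
load_nuclease_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$editors)) raw <- raw$editors
  lapply(raw, function(e) {
    need <- c("name", "motif", "motif_side", "spacer_length", "window",
              "chemistry")
    missing <- setdiff(need, names(e))
    if (length(missing)) {
      stop("catalog entry missing fields: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    nuclease_spec(e$name, e$motif, e$motif_side, e$spacer_length,
                  unlist(e$window), e$chemistry)
  })
}

#' @rdname load_nuclease_catalog
#' @param catalog List of `NucleaseSpec` objects.
#' @export
write_nuclease_catalog <- function(catalog, path) {
  entries <- lapply(catalog, function(s) {
    list(name = s$name, motif = s$motif, motif_side = s$motif_side,
         spacer_length = s$spacer_length, window = as.integer(s$window),
         chemistry = s$chemistry)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The shipped default nuclease catalog
#'
#' A versioned catalog of common base editors (Cas12a CBE with TTTV TAM,
#' SpCas9 CBE/ABE with NGG PAM); window coordinates follow the
#' protospacer-5'-end convention of [nuclease_spec()].
#'
#' @return List of `NucleaseSpec` objects.
#' @export
default_nuclease_catalog <- function() {
  load_nuclease_catalog(default_catalog_path())
}

#' @rdname default_nuclease_catalog
#' @export
default_catalog_path <- function() {
  system.file("extdata", "nuclease_catalog.json", package = "splicecase",
              mustWork = TRUE)
}

# Map an editing-window/protospacer position (1-based from the protospacer
# 5' end) to a genomic plus-strand coordinate.
#' @keywords internal
#' @noRd
protospacer_coord <- function(motif_span, motif_side, strand, spacer_length, j) {
  m1 <- motif_span[1]; m2 <- motif_span[2]
  if (motif_side == "5prime_of_protospacer") {
    if (strand == "+") m2 + j else m1 - j
  } else {
    if (strand == "+") m1 - spacer_length - 1L + j else m2 + spacer_length + 1L - j
  }
}

#' @keywords internal
#' @noRd
protospacer_span <- function(motif_span, motif_side, strand, spacer_length) {
  ends <- c(protospacer_coord(motif_span, motif_side, strand, spacer_length, 1L),
            protospacer_coord(motif_span, motif_side, strand, spacer_length,
                              spacer_length))
  sort(ends)
}

# IUPAC motif matches (motif given on `strand`) returned as plus-strand
# spans within [from, to] of the slice.
#' @keywords internal
#' @noRd
motif_matches <- function(genome, motif, strand, from, to) {
  from <- max(from, genome$origin)
  to <- min(to, genome_end(genome))
  if (to - from + 1L < nchar(motif)) {
    return(matrix(integer(0), ncol = 2L))
  }
  subject <- Biostrings::DNAString(subseq_genomic(genome, from, to))
  pat <- if (strand == "+") Biostrings::DNAString(motif) else
    Biostrings::reverseComplement(Biostrings::DNAString(motif))
  hits <- Biostrings::matchPattern(pat, subject, fixed = "subject")
  if (length(hits) == 0L) return(matrix(integer(0), ncol = 2L))
  cbind(from + Biostrings::start(hits) - 1L, from + Biostrings::end(hits) - 1L)
}

# Required base change on the protospacer strand for the therapeutic
# correction (reverting alt back to ref).
#' @keywords internal
#' @noRd
correction_on_strand <- function(target_variant, strand) {
  if (strand == "+") c(from = target_variant$alt, to = target_variant$ref)
  else c(from = comp_base(target_variant$alt), to = comp_base(target_variant$ref))
}

#' Scan for base-editor placements able to correct a target SNV
#'
#' Searches both strands within `flank_nt` of the target for each
#' catalog entry's PAM/TAM motif, places the protospacer according to the
#' motif side, and keeps a placement when (a) the therapeutic correction
#' (alt back to ref) matches the editor chemistry on the protospacer
#' strand and (b) the target base sits inside the editing window.
#'
#' @param genome A [genome_sequence()] carrying the patient (alternate)
#'   allele at the target.
#' @param target_variant The pathogenic [variant()] (`ref` wild type,
#'   `alt` the allele to correct).
#' @param catalog List of [nuclease_spec()]s; defaults to the shipped
#'   catalog.
#' @param flank_nt Motif search flank around the target (default 20, i.e.
#'   motifs within +/-20 bases).
#' @return List of `EditingCandidate` objects (possibly empty): each has
#'   `nuclease`, `strand` (protospacer strand), `pam_span` and
#'   `protospacer_span` (genomic, plus-strand ascending), `pam_seq_plus`
#'   (the motif as it reads on the displayed plus strand),
#'   `target_window_pos`, `target_distance_to_pam` (bases from target to
#'   the nearest PAM base), `window`, `chemistry`.
#' @export
scan_editor_sites <- function(genome, target_variant,
                              catalog = default_nuclease_catalog(),
                              flank_nt = 20L) {
  v <- target_variant$pos
  out <- list()
  for (spec in catalog) {
    L <- nchar(spec$motif)
    for (strand in c("+", "-")) {
      corr <- correction_on_strand(target_variant, strand)
      chem_ok <- switch(spec$chemistry,
                        CBE = corr["from"] == "C" && corr["to"] == "T",
                        ABE = corr["from"] == "A" && corr["to"] == "G")
      if (!chem_ok) next
      hits <- motif_matches(genome, spec$motif, strand,
                            v - flank_nt - L + 1L, v + flank_nt + L - 1L)
      for (h in seq_len(nrow(hits))) {
        span <- hits[h, ]
        # motif must lie within the +/- flank of the target
        if (span[2] < v - flank_nt || span[1] > v + flank_nt) next
        pspan <- protospacer_span(span, spec$motif_side, strand,
                                  spec$spacer_length)
        if (pspan[1] < genome$origin || pspan[2] > genome_end(genome)) next
        if (v < pspan[1] || v > pspan[2]) next
        # window position of the target
        j <- NA_integer_
        for (p in spec$window[1]:spec$window[2]) {
          if (protospacer_coord(span, spec$motif_side, strand,
                                spec$spacer_length, p) == v) {
            j <- p; break
          }
        }
        if (is.na(j)) next
        cand <- structure(list(
          nuclease = spec$name, strand = strand,
          pam_span = as.integer(span),
          pam_seq_plus = subseq_genomic(genome, span[1], span[2]),
          protospacer_span = as.integer(pspan),
          target_in_window = TRUE,
          target_window_pos = j,
          target_distance_to_pam = min(abs(span - v)),
          window = spec$window, chemistry = spec$chemistry,
          motif_side = spec$motif_side, spacer_length = spec$spacer_length),
          class = "EditingCandidate")
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  out
}

#' Enumerate bystander edits of a base-editing candidate
#'
#' Every base of the editable type (per the candidate chemistry, on the
#' protospacer strand) inside the editing window, other than the target
#' itself, is an unavoidable co-edit.
#'
#' @param candidate An `EditingCandidate` from [scan_editor_sites()].
#' @param genome The same alternate-allele [genome_sequence()].
#' @param target_variant The target [variant()].
#' @return List of `BystanderEdit` objects: `pos` (genomic),
#'   `substitution` (`"X>Y"` on the genomic plus strand),
#'   `classification` (`"unannotated"` until classified), `matched_id`.
#' @export
enumerate_bystanders <- function(candidate, genome, target_variant) {
  stopifnot(inherits(candidate, "EditingCandidate"))
  editable <- if (candidate$chemistry == "CBE") "C" else "A"
  edited_to <- if (candidate$chemistry == "CBE") "T" else "G"
  out <- list()
  for (j in candidate$window[1]:candidate$window[2]) {
    coord <- protospacer_coord(candidate$pam_span, candidate$motif_side,
                               candidate$strand, candidate$spacer_length, j)
    if (coord == target_variant$pos) next
    if (coord < genome$origin || coord > genome_end(genome)) next
    base_plus <- genomic_base(genome, coord)
    base_proto <- if (candidate$strand == "+") base_plus else comp_base(base_plus)
    if (base_proto != editable) next
    sub_plus <- if (candidate$strand == "+") {
      paste0(editable, ">", edited_to)
    } else {
      paste0(comp_base(editable), ">", comp_base(edited_to))
    }
    out[[length(out) + 1L]] <- structure(
      list(pos = coord, substitution = sub_plus, window_pos = j,
           classification = "unannotated", matched_id = NA_character_),
      class = "BystanderEdit")
  }
  out
}

#' Read a pathogenic-variant lookup table
#'
#' Tab-separated columns `contig, pos, ref, alt, id, significance`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_pathogenic_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("contig", "pos", "ref", "alt", "id", "significance")
  if (!all(need %in% names(df))) {
    stop("pathogenic table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (is.na(suppressWarnings(as.integer(df$pos[i]))) ||
        !df$ref[i] %in% c("A", "C", "G", "T") ||
        !df$alt[i] %in% c("A", "C", "G", "T")) {
      stop("malformed pathogenic-table row ", i + 1L, " in ", path,
           call. = FALSE)
    }
  }
  df$pos <- as.integer(df$pos)
  df
}

#' Classify bystander edits against a pathogenic-variant table
#'
#' Exact `(contig, pos, ref, alt)` matches take the table's significance
#' (`pathogenic` vs `annotated_benign`); unmatched bystanders are
#' `unannotated`. The placement verdict is `hazardous` iff any bystander
#' is pathogenic.
#'
#' @param bystanders List of `BystanderEdit`s from [enumerate_bystanders()].
#' @param pathogenic_table Data frame from [read_pathogenic_table()] (or
#'   with the same columns).
#' @param contig Contig of the bystanders.
#' @return List with `bystanders` (annotated) and `verdict`
#'   (`"clean"`/`"hazardous"`).
#' @export
classify_bystanders <- function(bystanders, pathogenic_table, contig) {
  annotated <- lapply(bystanders, function(b) {
    parts <- strsplit(b$substitution, ">", fixed = TRUE)[[1]]
    hit <- pathogenic_table[pathogenic_table$contig == contig &
                              pathogenic_table$pos == b$pos &
                              pathogenic_table$ref == parts[1] &
                              pathogenic_table$alt == parts[2], , drop = FALSE]
    if (nrow(hit)) {
      sig <- tolower(hit$significance[1])
      b$classification <- if (grepl("pathogenic", sig)) "pathogenic"
                          else "annotated_benign"
      b$matched_id <- hit$id[1]
    }
    b
  })
  hazardous <- any(vapply(annotated, function(b)
    identical(b$classification, "pathogenic"), logical(1)))
  list(bystanders = annotated,
       verdict = if (hazardous) "hazardous" else "clean")
}

#' Simplified prime-editing (pegRNA) candidate design
#'
#' Enumerates nCas9 NGG placements on both strands whose nick (between
#' protospacer positions 17 and 18, i.e. 3 nt 5' of the PAM) lies within
#' `max_nick_to_edit` nucleotides of the target, with the edit on the 3'
#' side of the nick. pegRNA lengths are filled from fixed parameters: the
#' RT template covers the nick-to-edit stretch, the edited base and a 3'
#' homology arm.
#'
#' @param genome Alternate-allele [genome_sequence()].
#' @param target_variant The [variant()] to correct.
#' @param max_nick_to_edit Maximum nick-to-edit distance in nt (default 30).
#' @param pbs_length Primer-binding-site length (default 13).
#' @param rtt_3prime_homology Homology arm beyond the edit (default 10).
#' @return List of `PrimeEditCandidate` objects sorted by
#'   `nick_to_edit_nt`: `spacer` (20 nt protospacer-strand sequence),
#'   `pam_pos` (genomic start of the NGG on the plus strand), `strand`,
#'   `nick_to_edit_nt`, `pbs_length`, `rtt_length`.
#' @export
design_prime_edit <- function(genome, target_variant, max_nick_to_edit = 30L,
                              pbs_length = 13L, rtt_3prime_homology = 10L) {
  v <- target_variant$pos
  spacer_len <- 20L
  out <- list()
  reach <- max_nick_to_edit + spacer_len + 6L
  hits_p <- motif_matches(genome, "NGG", "+", v - reach, v + reach)
  hits_m <- motif_matches(genome, "NGG", "-", v - reach, v + reach)
  add <- function(strand, span) {
    p <- span[1]
    if (strand == "+") {
      pspan <- c(p - spacer_len, p - 1L)
      d <- v - (p - 3L)           # first base 3' of the nick is p-3
    } else {
      pspan <- c(p + 3L, p + 2L + spacer_len)
      d <- (p + 5L) - v           # first base 3' of the nick (on -) is p+5
    }
    if (d < 0L || d > max_nick_to_edit) return()
    if (pspan[1] < genome$origin || pspan[2] > genome_end(genome)) return()
    seq_plus <- subseq_genomic(genome, pspan[1], pspan[2])
    spacer <- if (strand == "+") seq_plus else revcomp(seq_plus)
    out[[length(out) + 1L]] <<- structure(list(
      spacer = spacer, pam_pos = as.integer(p), strand = strand,
      nick_to_edit_nt = as.integer(d), pbs_length = as.integer(pbs_length),
      rtt_length = as.integer(d + 1L + rtt_3prime_homology)),
      class = "PrimeEditCandidate")
  }
  for (h in seq_len(nrow(hits_p))) add("+", hits_p[h, ])
  for (h in seq_len(nrow(hits_m))) add("-", hits_m[h, ])
  out[order(vapply(out, `[[`, 0L, "nick_to_edit_nt"))]
}

#' Rank base- and prime-editing strategies for a target
#'
#' Base-editing placements with a hazardous bystander verdict are demoted
#' below every prime-editing candidate; clean base editors rank first
#' (simplest chemistry), then prime editors, then hazardous base editors,
#' each with a per-candidate reason.
#'
#' @param base_candidates List of `EditingCandidate`s, each carrying a
#'   `verdict` element (add the [classify_bystanders()] verdict before
#'   ranking).
#' @param prime_candidates List of `PrimeEditCandidate`s.
#' @return A data.frame of class `StrategyReport` ordered by rank, with a
#'   `recommendation` attribute; zero rows (recommendation
#'   `"no in-silico strategy"`) when both inputs are empty.
#' @export
rank_strategies <- function(base_candidates, prime_candidates) {
  rows <- list()
  for (b in base_candidates) {
    verdict <- if (is.null(b$verdict)) "clean" else b$verdict
    rows[[length(rows) + 1L]] <- data.frame(
      type = "base_editing", strategy = b$nuclease, strand = b$strand,
      verdict = verdict,
      sort_key = b$target_distance_to_pam,
      reason = if (verdict == "hazardous") {
        "pathogenic bystander edit inside the editing window"
      } else {
        sprintf("target at window position %d, no pathogenic bystander",
                b$target_window_pos)
      }, stringsAsFactors = FALSE)
  }
  for (p in prime_candidates) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "prime_editing", strategy = "nCas9-PE", strand = p$strand,
      verdict = "clean", sort_key = p$nick_to_edit_nt,
      reason = sprintf("nick-to-edit distance %d nt; no bystander mechanism",
                       p$nick_to_edit_nt), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    rep <- data.frame(type = character(0), strategy = character(0),
                      strand = character(0), verdict = character(0),
                      sort_key = integer(0), reason = character(0))
    attr(rep, "recommendation") <- "no in-silico strategy"
    class(rep) <- c("StrategyReport", "data.frame")
    return(rep)
  }
  df <- do.call(rbind, rows)
  tier <- ifelse(df$type == "base_editing" & df$verdict != "hazardous", 1L,
                 ifelse(df$type == "prime_editing", 2L, 3L))
  df <- df[order(tier, df$sort_key), , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  attr(df, "recommendation") <- sprintf("%s (%s)", df$type[1], df$strategy[1])
  class(df) <- c("StrategyReport", "data.frame")
  df
}

#' @export
print.StrategyReport <- function(x, ...) {
  cat("Strategy ranking:", attr(x, "recommendation"), "\n")
  if (nrow(x)) print.data.frame(x[, c("rank", "type", "strategy", "strand",
                                      "verdict", "reason")], row.names = FALSE)
  invisible(x)
}
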