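# Consolidated case report: runs the four-stage workflow (variant ->
# primary splicing effect -> secondary consequences -> editing-tool
# selection) plus the optional epigenetic and expression blocks, and
# serializes the result as deterministic JSON.

#' Run a full splice-variant case analysis
#'
#' Executes the workflow stages in order: variant resolution and splice
#' classification; cryptic-acceptor scan with transcript reconstruction,
#' frame/PTC analysis and NMD prediction; CpG delta (plus optional
#' per-read methylation aggregation); base-editing feasibility with
#' bystander classification, prime-editing design and strategy ranking;
#' optional expression statistics. A failing optional stage marks its
#' block `failed` and the run continues; missing mandatory inputs raise a
#' configuration error before any compute.
#'
#' @param config A named list, or path to a YAML/JSON file, with keys:
#'   `fasta` (path) or `genome` (a [genome_sequence()]); `gene_model`
#'   (path or [gene_model()] object; `transcript_id` for multi-mRNA
#'   GFF3); `hgvs` (e.g. `"c.61-2A>G"`) or `vcf` (path, first record
#'   used) or `variant` (list `contig, pos, ref, alt`). Optional:
#'   `max_scan_nt` (100), `nmd_threshold` (55), `flank_nt` (20),
#'   `max_nick_to_edit` (30), `catalog` (path; shipped default
#'   otherwise), `pathogenic_table` (path or data.frame),
#'   `methylation_calls` (path or data.frame) with `methylation_site`,
#'   `tpm` (path or matrix) with `expression_gene` and
#'   `expression_patient_col`, `ct` (path or data.frame) with
#'   `ct_target`, `ct_reference`, `ct_calibrator`.
#' @return A list of class `CaseReport` with blocks `variant`,
#'   `splice_consequence`, `cpg`, `methylation`, `editing`, `expression`
#'   and `provenance`. Optional blocks without inputs are
#'   `list(skipped = TRUE, reason = ...)`.
#' @export
run_case <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  digests <- list()

  # --- mandatory inputs ------------------------------------------------
  genome <- if (!is.null(config$genome)) {
    config$genome
  } else if (!is.null(config$fasta)) {
    digests$fasta <- md5_file(config$fasta)
    read_fasta(config$fasta)[[1]]
  } else stop("config must name a fasta (or genome object)", call. = FALSE)

  model <- if (inherits(config$gene_model, "GeneModel")) {
    config$gene_model
  } else if (is.character(config$gene_model)) {
    digests$gene_model <- md5_file(config$gene_model)
    read_gene_model(config$gene_model, transcript_id = config$transcript_id)
  } else stop("config must name a gene_model", call. = FALSE)

  hgvs <- NULL
  if (!is.null(config$hgvs)) {
    parsed <- parse_hgvs_c(config$hgvs, model, genome = genome)
    v <- parsed$variant
    hgvs <- config$hgvs
  } else if (!is.null(config$vcf)) {
    digests$vcf <- md5_file(config$vcf)
    v <- read_vcf_variants(config$vcf, genome = genome)[[1]]
  } else if (!is.null(config$variant)) {
    vv <- config$variant
    if (inherits(vv, "Variant")) v <- vv
    else v <- variant(vv$contig, vv$pos, vv$ref, vv$alt, id = vv$id,
                      genome = genome)
  } else stop("config must give hgvs, vcf or variant", call. = FALSE)

  max_scan <- if (is.null(config$max_scan_nt)) 100L else as.integer(config$max_scan_nt)
  nmd_thr <- if (is.null(config$nmd_threshold)) 55L else as.integer(config$nmd_threshold)
  flank <- if (is.null(config$flank_nt)) 20L else as.integer(config$flank_nt)
  max_nick <- if (is.null(config$max_nick_to_edit)) 30L
              else as.integer(config$max_nick_to_edit)

  catalog_path <- if (is.null(config$catalog)) default_catalog_path()
                  else config$catalog
  catalog <- load_nuclease_catalog(catalog_path)

  block <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      list(failed = TRUE, stage = label, error = conditionMessage(e))
    })
  }
  skipped <- function(reason) list(skipped = TRUE, reason = reason)

  # --- stage 1-2: variant + primary/secondary splicing consequence ----
  variant_block <- list(contig = v$contig, pos = v$pos, ref = v$ref,
                        alt = v$alt, id = v$id, hgvs = hgvs,
                        annotations = v$annotations)

  sc_block <- block({
    sc <- splice_consequence(genome, model, v, max_scan_nt = max_scan,
                             nmd_threshold = nmd_thr)
    cons <- sc$consequence
    list(classification = sc$classification$class,
         intron_index = sc$classification$intron_index,
         cryptic = list(found = sc$cryptic$found,
                        deletion_nt = sc$cryptic$deletion_length,
                        distance_nt = sc$cryptic$distance_from_variant,
                        ag_pos_genomic = sc$cryptic$ag_pos_genomic),
         frameshift = if (!is.null(cons)) list(
           is_frameshift = cons$is_frameshift,
           frame_offset = cons$frame_offset,
           novel_aa = cons$novel_aa_count,
           ptc_cds_pos = cons$ptc_cds_pos) else NULL,
         truncation_aa = if (!is.null(cons)) cons$wildtype_exon_aa_lost_after_ptc
                         else NULL,
         nmd = if (!is.null(cons)) list(predicted = cons$nmd_predicted,
                                        rule = cons$nmd_rule) else NULL,
         peptide = if (!is.null(cons)) cons$peptide else NULL,
         peptide_mass_kda = if (!is.null(cons)) cons$peptide_mass_kda else NULL,
         stop_map_per_frame = if (!is.null(cons)) cons$stop_map_per_frame
                              else NULL)
  }, "splice_consequence")

  # --- stage 3: epigenetic deltas -------------------------------------
  cpg_block <- block({
    d <- cpg_delta(genome, v)
    list(created_c_pos = d$created, destroyed_c_pos = d$destroyed)
  }, "cpg")

  meth_block <- if (is.null(config$methylation_calls)) {
    skipped("no methylation call table supplied")
  } else block({
    calls <- config$methylation_calls
    if (is.character(calls)) {
      digests$methylation_calls <- md5_file(calls)
      calls <- read_methylation_calls(calls)
    }
    site <- config$methylation_site
    if (is.null(site)) {
      d <- cpg_delta(genome, v)
      if (!length(d$created)) stop("no methylation site given and no created CpG")
      site <- d$created[1]
    }
    s <- methylation_fraction(calls, site, contig = v$contig)
    list(site_pos = s$site_pos, n_reads = s$n_reads,
         n_methylated = s$n_methylated, fraction = s$fraction)
  }, "methylation")

  # --- stage 4: editing feasibility -----------------------------------
  editing_block <- block({
    genome_alt <- apply_variant(genome, v)
    cands <- scan_editor_sites(genome_alt, v, catalog, flank_nt = flank)
    ptab <- config$pathogenic_table
    if (is.character(ptab)) {
      digests$pathogenic_table <- md5_file(ptab)
      ptab <- read_pathogenic_table(ptab)
    }
    base_list <- lapply(cands, function(cand) {
      bys <- enumerate_bystanders(cand, genome_alt, v)
      if (!is.null(ptab)) {
        cl <- classify_bystanders(bys, ptab, v$contig)
        bys <- cl$bystanders
        cand$verdict <- cl$verdict
      } else {
        cand$verdict <- "clean"
      }
      cand$bystanders <- bys
      cand
    })
    primes <- design_prime_edit(genome_alt, v, max_nick_to_edit = max_nick)
    ranking <- rank_strategies(base_list, primes)
    list(
      base = lapply(base_list, function(b) list(
        nuclease = b$nuclease, strand = b$strand,
        pam_seq_plus = b$pam_seq_plus, pam_span = b$pam_span,
        target_window_pos = b$target_window_pos,
        target_distance_to_pam = b$target_distance_to_pam,
        verdict = b$verdict,
        bystanders = lapply(b$bystanders, function(y) list(
          pos = y$pos, substitution = y$substitution,
          classification = y$classification, matched_id = y$matched_id)))),
      prime = lapply(primes, function(p) list(
        spacer = p$spacer, pam_pos = p$pam_pos, strand = p$strand,
        nick_to_edit_nt = p$nick_to_edit_nt, pbs_length = p$pbs_length,
        rtt_length = p$rtt_length)),
      ranking = list(recommendation = attr(ranking, "recommendation"),
                     order = if (nrow(ranking)) ranking$strategy else character(0),
                     table = as.data.frame(ranking)))
  }, "editing")

  # --- optional expression block --------------------------------------
  expr_block <- if (is.null(config$tpm) && is.null(config$ct)) {
    skipped("no expression inputs supplied")
  } else block({
    out <- list()
    if (!is.null(config$tpm)) {
      m <- config$tpm
      if (is.character(m)) {
        digests$tpm <- md5_file(m)
        m <- read_tpm_matrix(m)
      }
      gene <- config$expression_gene
      pcol <- config$expression_patient_col
      if (is.null(gene) || is.null(pcol)) {
        stop("tpm input needs expression_gene and expression_patient_col")
      }
      row <- m[gene, , drop = TRUE]
      controls <- row[setdiff(names(row), pcol)]
      st <- expression_zscore(unname(row[pcol]), controls = as.numeric(controls))
      out$zscore <- list(value_tpm = st$value_tpm,
                         control_mean_tpm = st$control_mean_tpm,
                         control_sd_tpm = st$control_sd_tpm,
                         n_controls = st$n_controls, z = st$z,
                         p_two_tailed = st$p_two_tailed,
                         percentile_normal = st$percentile_normal,
                         percentile_empirical = st$percentile_empirical)
    }
    if (!is.null(config$ct)) {
      ct <- config$ct
      if (is.character(ct)) {
        digests$ct <- md5_file(ct)
        ct <- read_ct_table(ct)
      }
      need <- c("ct_target", "ct_reference", "ct_calibrator")
      if (!all(need %in% names(config))) {
        stop("ct input needs ct_target, ct_reference and ct_calibrator")
      }
      res <- ddct(ct, config$ct_target, config$ct_reference,
                  config$ct_calibrator)
      out$ddct <- as.data.frame(res)
    }
    out
  }, "expression")

  report <- structure(list(
    variant = variant_block,
    splice_consequence = sc_block,
    cpg = cpg_block,
    methylation = meth_block,
    editing = editing_block,
    expression = expr_block,
    provenance = list(
      tool = "splicecase",
      version = as.character(utils::packageVersion("splicecase")),
      catalog = catalog_path,
      catalog_md5 = md5_file(catalog_path),
      input_md5 = digests,
      seed = config$seed)),
    class = "CaseReport")
  report
}

#' @export
print.CaseReport <- function(x, ...) {
  cat("CaseReport for", x$variant$contig, x$variant$pos, x$variant$ref, ">",
      x$variant$alt, "\n")
  for (b in c("splice_consequence", "cpg", "methylation", "editing",
              "expression")) {
    st <- if (isTRUE(x[[b]]$skipped)) "skipped"
          else if (isTRUE(x[[b]]$failed)) "FAILED" else "ok"
    cat(sprintf("  %-18s %s\n", b, st))
  }
  invisible(x)
}

#' Serialize a case report as deterministic JSON
#'
#' @param report A `CaseReport` from [run_case()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_case_report <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Structural validation of a case report
#'
#' Checks the report against the shipped schema contract
#' (`inst/schema/case_report.schema.json`): every block present or
#' explicitly marked skipped/failed, mandatory fields populated.
#'
#' @param report A `CaseReport`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_case_report <- function(report) {
  blocks <- c("variant", "splice_consequence", "cpg", "methylation",
              "editing", "expression", "provenance")
  for (b in blocks) {
    if (is.null(report[[b]])) stop("missing block: ", b, call. = FALSE)
    if (isTRUE(report[[b]]$skipped) && is.null(report[[b]]$reason)) {
      stop("skipped block without reason: ", b, call. = FALSE)
    }
  }
  for (f in c("contig", "pos", "ref", "alt")) {
    if (is.null(report$variant[[f]])) {
      stop("variant block missing field: ", f, call. = FALSE)
    }
  }
  if (!isTRUE(report$splice_consequence$failed) &&
      is.null(report$splice_consequence$classification)) {
    stop("splice_consequence block missing classification", call. = FALSE)
  }
  for (f in c("tool", "version", "catalog_md5")) {
    if (is.null(report$provenance[[f]])) {
      stop("provenance missing field: ", f, call. = FALSE)
    }
  }
  invisible(TRUE)
}
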