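# Cohort z-score statistics, the low-expression filter, 2^-ddCt relative
# quantification and simple pedigree group comparisons.

#' Cohort z-score for a single expression value
#'
#' Standardizes one patient TPM value against a control cohort and derives
#' the two-tailed p-value from the standard normal distribution. Both the
#' empirical percentile (share of controls at or below the value) and the
#' normal-theory percentile are reported when raw controls are supplied;
#' with summary statistics only, the normal percentile alone is available.
#'
#' @param value Patient expression value (TPM).
#' @param controls Optional numeric vector of control values; mean/sd are
#'   then computed with the sample (n-1) estimator.
#' @param mean,sd,n Summary statistics of the control cohort (used when
#'   `controls` is NULL; `sd` must be > 0).
#' @return An object of class `ExpressionStat` with fields `value_tpm`,
#'   `control_mean_tpm`, `control_sd_tpm`, `n_controls`, `z`,
#'   `p_two_tailed`, `percentile_normal`, `percentile_empirical` (NA
#'   without raw controls).
#' @examples
#' s <- expression_zscore(2.94, mean = 4.43, sd = 1.97, n = 609)
#' round(s$z, 2)  # -0.76
#' @export
expression_zscore <- function(value, controls = NULL, mean = NULL, sd = NULL,
                              n = NULL) {
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.null(controls)) {
    if (length(controls) < 2L) stop("need >= 2 control values", call. = FALSE)
    n <- length(controls)
    mean <- base::mean(controls)
    sd <- stats::sd(controls)
    pct_emp <- 100 * base::mean(controls <= value)
  } else {
    if (is.null(mean) || is.null(sd)) {
      stop("supply either raw controls or mean and sd", call. = FALSE)
    }
    pct_emp <- NA_real_
  }
  if (is.na(sd) || sd <= 0) stop("control sd must be > 0", call. = FALSE)
  z <- (value - mean) / sd
  structure(list(value_tpm = value, control_mean_tpm = mean,
                 control_sd_tpm = sd,
                 n_controls = if (is.null(n)) NA_integer_ else n,
                 z = z, p_two_tailed = 2 * stats::pnorm(-abs(z)),
                 percentile_normal = 100 * stats::pnorm(z),
                 percentile_empirical = pct_emp),
            class = "ExpressionStat")
}

#' @export
print.ExpressionStat <- function(x, ...) {
  cat(sprintf("ExpressionStat: value %.3g TPM vs controls %.3g +/- %.3g\n",
              x$value_tpm, x$control_mean_tpm, x$control_sd_tpm))
  cat(sprintf("  Z = %.2g, two-tailed p = %.2g\n", x$z, x$p_two_tailed))
  cat(sprintf("  percentile: normal %.1f%%%s\n", x$percentile_normal,
              if (!is.na(x$percentile_empirical))
                sprintf(", empirical %.1f%%", x$percentile_empirical) else ""))
  invisible(x)
}

#' Low-expression gene filter
#'
#' A gene is removed when strictly more than `sample_fraction` of samples
#' have expression at or below `tpm_threshold` (e.g. TPM <= 1 in more than
#' 90% of samples); a gene at exactly the boundary fraction is retained.
#'
#' @param tpm_matrix Numeric genes-by-samples matrix (rownames are gene
#'   ids) or data.frame.
#' @param tpm_threshold Expression threshold (default 1).
#' @param sample_fraction Removal fraction (default 0.9).
#' @return Character vector of retained gene ids (row indices as character
#'   when the matrix has no rownames).
#' @export
low_expression_filter <- function(tpm_matrix, tpm_threshold = 1,
                                  sample_fraction = 0.9) {
  m <- as.matrix(tpm_matrix)
  if (length(m) == 0L) stop("empty expression matrix", call. = FALSE)
  if (any(m < 0)) stop("TPM values must be non-negative", call. = FALSE)
  frac_low <- rowMeans(m <= tpm_threshold)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  ids[frac_low <= sample_fraction]
}

#' Read a TPM gene-by-sample matrix
#'
#' Tab-separated, first column gene ids, header row of sample names.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with gene rownames.
#' @export
read_tpm_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a long-format qPCR Ct table
#'
#' Tab-separated columns `sample, gene, replicate, ct`.
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Relative expression by the 2^-ddCt method
#'
#' Replicates are averaged per (sample, gene); per sample,
#' `dCt = Ct(target) - Ct(reference)`; `ddCt = dCt(sample) -
#' dCt(calibrator)`; relative expression is `2^-ddCt` with the calibrator
#' at exactly 1. The replicate standard error is propagated through the
#' dCt difference (in quadrature, including the calibrator's) and onto the
#' relative-expression scale.
#'
#' @param ct_table Data frame with columns `sample, gene, replicate, ct`.
#' @param target_gene,reference_gene Gene names in the table.
#' @param calibrator_sample Sample used as the 2^-ddCt calibrator.
#' @return Data frame of class `DdctResult`, one row per sample:
#'   `sample, delta_ct, ddct, relative_expression, percent_change,
#'   replicate_se`.
#' @examples
#' ct <- expand.grid(sample = c("father", "patient"),
#'                   gene = c("NF1", "GAPDH"), replicate = 1:3,
#'                   stringsAsFactors = FALSE)
#' ct$ct <- ifelse(ct$gene == "GAPDH", 20, ifelse(ct$sample == "father", 24, 25))
#' ddct(ct, "NF1", "GAPDH", "father")
#' @export
ddct <- function(ct_table, target_gene, reference_gene, calibrator_sample) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(ct_table$sample)
  if (!calibrator_sample %in% samples) {
    stop("calibrator sample ", calibrator_sample, " absent from table",
         call. = FALSE)
  }
  stat <- function(s, g) {
    x <- ct_table$ct[ct_table$sample == s & ct_table$gene == g]
    if (length(x) == 0L) {
      stop(sprintf("no Ct values for sample %s, gene %s", s, g), call. = FALSE)
    }
    c(mean = base::mean(x),
      se = if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0)
  }
  dct <- function(s) {
    t <- stat(s, target_gene); r <- stat(s, reference_gene)
    c(dct = unname(t["mean"] - r["mean"]),
      se = unname(sqrt(t["se"]^2 + r["se"]^2)))
  }
  cal <- dct(calibrator_sample)
  rows <- lapply(samples, function(s) {
    d <- dct(s)
    dd <- d["dct"] - cal["dct"]
    se_dd <- if (s == calibrator_sample) d["se"] * sqrt(2)
             else sqrt(d["se"]^2 + cal["se"]^2)
    rel <- 2^(-dd)
    data.frame(sample = s,
               delta_ct = unname(d["dct"]),
               delta_ct_calibrator = unname(cal["dct"]),
               ddct = unname(dd),
               relative_expression = unname(rel),
               percent_change = unname((rel - 1) * 100),
               replicate_se = unname(rel * log(2) * se_dd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("DdctResult", "data.frame")
  out
}

#' Two-group t-test or one-way ANOVA from first principles
#'
#' Textbook pooled-variance Student's t for two groups, one-way ANOVA F
#' for more, with Bonferroni-adjusted pairwise post hoc t-tests in the
#' ANOVA case. Implemented directly from the sum-of-squares definitions.
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (>= 2 groups, >= 2 values each).
#' @return List: for two groups `method = "t"`, `statistic`, `df`, `p`;
#'   for more, `method = "anova"`, `statistic` (F), `df = c(between,
#'   within)`, `p`, and `posthoc` (pairwise Bonferroni-adjusted p-values).
#' @export
group_compare <- function(values_by_group) {
  g <- values_by_group
  if (length(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(g, length, 0L) < 2L)) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (is.null(names(g))) names(g) <- paste0("group", seq_along(g))
  pooled_t <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
    if (sp2 == 0) {
      if (base::mean(x) == base::mean(y)) {
        return(list(statistic = 0, df = nx + ny - 2, p = 1))
      }
      stop("degenerate (zero) variance with unequal means", call. = FALSE)
    }
    t <- (base::mean(x) - base::mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
    list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  if (length(g) == 2L) {
    r <- pooled_t(g[[1]], g[[2]])
    return(list(method = "t", statistic = r$statistic, df = r$df, p = r$p))
  }
  all_v <- unlist(g, use.names = FALSE)
  k <- length(g); N <- length(all_v)
  grand <- base::mean(all_v)
  ss_between <- sum(vapply(g, function(x)
    length(x) * (base::mean(x) - grand)^2, 0))
  ss_within <- sum(vapply(g, function(x)
    sum((x - base::mean(x))^2), 0))
  df_b <- k - 1L; df_w <- N - k
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(list(method = "anova", statistic = 0, df = c(df_b, df_w), p = 1,
                  posthoc = NULL))
    }
    stop("degenerate (zero) within-group variance", call. = FALSE)
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  pairs <- utils::combn(names(g), 2L)
  ph <- apply(pairs, 2L, function(pr) pooled_t(g[[pr[1]]], g[[pr[2]]])$p)
  ph <- stats::p.adjust(ph, method = "bonferroni")
  names(ph) <- apply(pairs, 2L, paste, collapse = " vs ")
  list(method = "anova", statistic = f, df = c(df_b, df_w), p = p,
       posthoc = ph)
}
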