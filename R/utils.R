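# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @keywords internal
#' @noRd
assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    stop(what, " contains non-DNA characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  invisible(seq)
}

#' @keywords internal
#' @noRd
assert_scalar_int <- function(x, what, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop(what, " must be a single integer", call. = FALSE)
  }
  if (x < min) stop(what, " must be >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

# Complement lookup avoiding repeated Biostrings round trips on single bases.
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' @keywords internal
#' @noRd
comp_base <- function(b) unname(COMP[b])

#' @keywords internal
#' @noRd
md5_file <- function(path) unname(tools::md5sum(path))

# Deterministic child seed derived from a user seed and a short tag; kept
# well below 2^31 so it is always a valid R integer seed.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, tag) {
  raw <- utf8ToInt(paste0(tag, ":", seed))
  as.integer((sum(raw * seq_along(raw)) + seed * 7919L) %% 2147483L + 1L)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
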