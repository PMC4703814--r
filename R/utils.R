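# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so seeded package operations never clobber a user's stream.
#' A `NULL` seed evaluates `expr` unseeded.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a parent seed and a stage index, kept < 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> base expansion (from Biostrings), as a named list of char sets.
iupac_sets <- function() {
  map <- Biostrings::IUPAC_CODE_MAP
  lapply(map, function(x) strsplit(x, "")[[1]])
}

stopifnot_scalar_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Deterministic distinct barcodes: "AC" + 4 base-4 digits + "GT".
make_barcodes <- function(n) {
  if (n > 256) stop("at most 256 barcodes supported")
  idx <- seq_len(n) - 1L
  digits <- sapply(idx, function(i) {
    d <- integer(4)
    for (k in 4:1) { d[k] <- i %% 4L; i <- i %/% 4L }
    paste(DNA_BASES[d + 1L], collapse = "")
  })
  paste0("AC", digits, "GT")
}

# Phred+33 encoding helpers.
phred_to_chars <- function(q) {
  vapply(q, function(qi) rawToChar(as.raw(qi + 33L)), character(1))
}
chars_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}

# Random protein of length L avoiding a set of forbidden substrings and
# triple identical residues (keeps back-translations homopolymer-safe).
random_protein <- function(L, avoid = character(0)) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  repeat {
    s <- character(L)
    for (i in seq_len(L)) {
      repeat {
        x <- sample(aa, 1)
        if (i < 3 || !(s[i - 1] == x && s[i - 2] == x)) break
      }
      s[i] <- x
    }
    p <- paste(s, collapse = "")
    if (!any(vapply(avoid, function(m) grepl(m, p, fixed = TRUE), logical(1))))
      return(p)
  }
}

mean_phred <- function(qual_string) {
  mean(as.integer(charToRaw(qual_string)) - 33L)
}
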