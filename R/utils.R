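#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Run code with a temporary RNG state so simulators are deterministic given
# their own seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Reverse complement of a DNA/RNA sequence
#'
#' Operates on plain character vectors; RNA input (`U`) is converted to DNA
#' space (`T`) before complementing, matching the convention of reporting
#' microRNA seeds as the sequence present in transcriptome space.
#'
#' @param x Character vector of sequences (A/C/G/T/U/N, case-insensitive).
#' @return Character vector of reverse complements in DNA space.
#' @examples
#' revcomp("AAAGUGCU")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  x <- to_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# uppercase and U -> T
to_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# stop unless x is a single positive finite number
check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
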