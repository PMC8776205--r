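# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

#' Translate a coding sequence to protein
#'
#' Translates from the first position, trimming any trailing partial codon,
#' and returns the peptide up to (not including) the first stop codon plus a
#' flag saying whether a stop was reached.
#'
#' @param cds a DNA string.
#' @return list with `peptide` (character) and `terminated` (logical).
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  n3 <- n - (n %% 3L)
  if (n3 < 3L) return(list(peptide = "", terminated = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n3)),
    no.init.codon = TRUE
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(peptide = substr(aa, 1L, stop_at - 1L), terminated = TRUE)
  } else {
    list(peptide = aa, terminated = FALSE)
  }
}

# Random DNA of a given length (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Codons that encode an amino acid (no stop codons).
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Collapse a sorted vector of integer positions into a matrix of
# (start, end) runs of consecutive values.
positions_to_intervals <- function(pos) {
  stopifnot(!is.unsorted(pos))
  if (length(pos) == 0L) return(matrix(integer(0), ncol = 2L))
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  cbind(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1L]])
}

# Deterministic TSV writer (no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
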