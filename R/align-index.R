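# Exact k-mer seed index over a reference set, both strands.

#' Build a k-mer seed index
#'
#' Indexes every k-mer of every reference on both strands. Minus-strand
#' k-mers are stored in reverse-complement coordinate space: a hit at
#' position `p` on strand `-` of a reference of length `L` means the k-mer
#' matches `revcomp(ref)[p..p+k-1]` (forward interval
#' `[L-p-k+2, L-p+1]`).
#'
#' @param references named character vector of reference sequences (here,
#'   annotated transcript sequences named by their gene).
#' @param k seed length (>= 8).
#' @return an object of class `seed_index`.
#' @export
build_index <- function(references, k = 13L) {
  if (length(references) == 0L) stop("empty reference set")
  if (k < 8L) stop("seed length k must be >= 8")
  refs <- as.character(references)
  names(refs) <- names(references)
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named")

  seqs <- c(refs, stats::setNames(revcomp(refs), names(refs)))
  meta <- data.frame(
    ref = rep(names(refs), 2L),
    strand = rep(c("+", "-"), each = length(refs)),
    length = rep(nchar(refs), 2L),
    stringsAsFactors = FALSE
  )

  keys <- character(0); tid <- integer(0); tpos <- integer(0)
  for (t in seq_along(seqs)) {
    L <- nchar(seqs[[t]])
    if (L < k) next
    n <- L - k + 1L
    keys <- c(keys, substring(seqs[[t]], 1:n, k:(k + n - 1L)))
    tid <- c(tid, rep.int(t, n))
    tpos <- c(tpos, 1:n)
  }
  env <- list2env(split(seq_along(keys), keys), hash = TRUE)

  structure(list(
    k = as.integer(k),
    meta = meta,
    env = env,
    tid = tid, tpos = tpos,
    raw = lapply(seqs, charToRaw),
    xs = Biostrings::DNAStringSet(seqs)
  ), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: k =", x$k, ",", nrow(x$meta) / 2L, "reference(s)\n")
  invisible(x)
}

#' Query a seed index for one k-mer
#'
#' @param index a `seed_index`.
#' @param kmer a string of length `k`.
#' @return data.frame with `ref`, `strand`, `pos` (strand coordinate space,
#'   see [build_index()]); zero rows for an absent k-mer.
#' @export
query_index <- function(index, kmer) {
  if (nchar(kmer) != index$k) stop("query length must equal k")
  ids <- index$env[[kmer]]
  if (is.null(ids))
    return(data.frame(ref = character(0), strand = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  t <- index$tid[ids]
  data.frame(ref = index$meta$ref[t], strand = index$meta$strand[t],
             pos = index$tpos[ids], stringsAsFactors = FALSE)
}
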