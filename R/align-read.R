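# Seed-and-extend read alignment with split (chimeric) support.
#
# Candidate placements come from exact k-mer seed hits at every read offset.
# Full-length placements are reported when the whole read extends with at
# most `max_mismatches`; otherwise two-segment partitions across two
# different genes are enumerated. A bounded rescue step (exact pattern
# matching of short unseeded segments) makes the search equivalent to an
# exhaustive partition/position scan for reads longer than about 2 k(m+1)
# bases: any alignable segment longer than (k-1)(m+1)+m bases necessarily
# contains an exact k-mer seed, so only short opposite-side segments can be
# missed by seeding, and those are recovered exhaustively.

#' Align one read against a seed index
#'
#' @param read read sequence.
#' @param index a `seed_index` built from annotated transcript sequences.
#' @param max_mismatches per-read mismatch budget (substitutions only).
#' @param min_seg minimum segment length of a split alignment; defaults to
#'   the seed length.
#' @param gene_of optional named vector mapping reference names to gene ids
#'   (defaults to the reference names themselves).
#' @return list with `full` (data.frame of full-length placements, best
#'   first), `split` (data.frame of two-segment placements, best first; only
#'   searched when no full-length placement exists), and `n_best_full` /
#'   `n_best_split_pairs` used for multi-mapper handling.
#' @export
align_read <- function(read, index, max_mismatches = 2L, min_seg = NULL,
                       gene_of = NULL) {
  k <- index$k
  min_seg <- as.integer(min_seg %||% k)
  L <- nchar(read)
  if (L < 2L * k) stop("read shorter than two seeds (", 2L * k, " nt)")
  gene_name <- function(ref) if (is.null(gene_of)) ref else unname(gene_of[ref])
  rraw <- charToRaw(read)

  # seed candidates: unique (target, diagonal)
  n_off <- L - k + 1L
  kmers <- substring(read, 1:n_off, k:(k + n_off - 1L))
  hit_t <- integer(0); hit_d <- integer(0)
  for (o in seq_len(n_off)) {
    ids <- index$env[[kmers[o]]]
    if (is.null(ids)) next
    hit_t <- c(hit_t, index$tid[ids])
    hit_d <- c(hit_d, index$tpos[ids] - o + 1L)
  }
  cand_key <- unique(hit_t * 10000000L + (hit_d + 1000L))
  cands <- lapply(cand_key, function(key) {
    t <- key %/% 10000000L
    d <- (key %% 10000000L) - 1000L
    Tlen <- index$meta$length[t]
    jlo <- max(1L, 2L - d)
    jhi <- min(L, Tlen - d + 1L)
    if (jhi < jlo) return(NULL)
    tr <- index$raw[[t]]
    neq <- as.integer(tr[(d + jlo - 1L):(d + jhi - 1L)] != rraw[jlo:jhi])
    cum <- cumsum(neq)
    list(t = t, d = d, jlo = jlo, jhi = jhi, cum = cum, tot = cum[length(cum)],
         ref = index$meta$ref[t], strand = index$meta$strand[t], Tlen = Tlen)
  })
  cands <- Filter(Negate(is.null), cands)

  # full-length placements
  fulls <- Filter(function(cc) cc$jlo == 1L && cc$jhi == L &&
                    cc$tot <= max_mismatches, cands)
  if (length(fulls) > 0L) {
    df <- do.call(rbind, lapply(fulls, function(cc) {
      fwd <- to_forward(cc$d, cc$d + L - 1L, cc$strand, cc$Tlen)
      data.frame(ref = cc$ref, strand = cc$strand,
                 target_start = fwd[1], target_end = fwd[2],
                 read_start = 1L, read_end = L,
                 matched = L - cc$tot, mismatches = cc$tot,
                 stringsAsFactors = FALSE)
    }))
    df <- df[order(df$mismatches, df$ref, df$target_start), , drop = FALSE]
    rownames(df) <- NULL
    n_best <- sum(df$mismatches == df$mismatches[1L])
    return(list(full = df, split = empty_split_df(),
                n_best_full = n_best, n_best_split_pairs = 0L))
  }

  # split placements over seeded candidate pairs (same read orientation,
  # different genes)
  splits <- list()
  add_split <- function(left, dl, right, dr, p, mmL, mmR) {
    splits[[length(splits) + 1L]] <<- list(
      lt = left$t, ld = dl, rt = right$t, rd = dr, p = p,
      mmL = mmL, mmR = mmR,
      lref = left$ref, rref = right$ref, strand = left$strand,
      lTlen = left$Tlen, rTlen = right$Tlen
    )
  }
  left_ok <- Filter(function(cc) cc$jlo == 1L, cands)
  right_ok <- Filter(function(cc) cc$jhi == L, cands)
  for (a in left_ok) {
    for (b in right_ok) {
      if (a$strand != b$strand) next
      if (identical(gene_name(a$ref), gene_name(b$ref))) next
      lo <- max(min_seg, b$jlo - 1L)
      hi <- min(L - min_seg, a$jhi)
      if (hi < lo) next
      p <- lo:hi
      mmL <- a$cum[p]
      idxb <- p - b$jlo + 1L
      cumb <- c(0L, b$cum)
      mmR <- b$tot - cumb[idxb + 1L]
      keep <- which(mmL + mmR <= max_mismatches)
      for (i in keep) add_split(a, a$d, b, b$d, p[i], mmL[i], mmR[i])
    }
  }

  # rescue of short unseeded segments opposite a seeded anchor
  U <- (k - 1L) * (max_mismatches + 1L) + max_mismatches
  same_strand_targets <- function(strand, exclude_gene) {
    which(index$meta$strand == strand &
            vapply(index$meta$ref, function(r)
              !identical(gene_name(r), exclude_gene), logical(1)))
  }
  for (a in left_ok) {            # anchored left, rescue right segment <= U
    lo <- max(min_seg, L - U)
    hi <- min(L - min_seg, a$jhi)
    if (hi < lo) next
    p_range <- lo:hi
    p_range <- p_range[a$cum[p_range] <= max_mismatches]
    tgts <- same_strand_targets(a$strand, gene_name(a$ref))
    for (p in p_range) {
      rem <- max_mismatches - a$cum[p]
      pat <- substr(read, p + 1L, L)
      for (t in tgts) {
        m <- Biostrings::matchPattern(pat, index$xs[[t]], max.mismatch = rem)
        if (length(m) == 0L) next
        nm <- count_view_mismatches(pat, m)
        st <- Biostrings::start(m)
        for (i in seq_along(st)) {
          bb <- list(t = t, ref = index$meta$ref[t],
                     strand = index$meta$strand[t],
                     Tlen = index$meta$length[t])
          add_split(a, a$d, bb, st[i] - p, p, a$cum[p], nm[i])
        }
      }
    }
  }
  for (b in right_ok) {           # anchored right, rescue left segment <= U
    cumb <- c(0L, b$cum)
    lo <- min_seg
    hi <- min(U, L - min_seg)
    if (hi < lo) next
    p_range <- lo:hi
    p_range <- p_range[p_range + 1L >= b$jlo]
    tgts <- same_strand_targets(b$strand, gene_name(b$ref))
    for (p in p_range) {
      mmR <- b$tot - cumb[p - b$jlo + 2L]
      if (mmR > max_mismatches) next
      rem <- max_mismatches - mmR
      pat <- substr(read, 1L, p)
      for (t in tgts) {
        m <- Biostrings::matchPattern(pat, index$xs[[t]], max.mismatch = rem)
        if (length(m) == 0L) next
        nm <- count_view_mismatches(pat, m)
        st <- Biostrings::start(m)
        for (i in seq_along(st)) {
          aa <- list(t = t, ref = index$meta$ref[t],
                     strand = index$meta$strand[t],
                     Tlen = index$meta$length[t])
          add_split(aa, st[i], b, b$d, p, nm[i], mmR)
        }
      }
    }
  }

  if (length(splits) == 0L)
    return(list(full = empty_full_df(), split = empty_split_df(),
                n_best_full = 0L, n_best_split_pairs = 0L))

  sdf <- do.call(rbind, lapply(splits, function(s) {
    lf <- to_forward(s$ld, s$ld + s$p - 1L, s$strand, s$lTlen)
    rf <- to_forward(s$rd + s$p, s$rd + L - 1L, s$strand, s$rTlen)
    data.frame(
      left_ref = s$lref, right_ref = s$rref, strand = s$strand,
      left_target_start = lf[1], left_target_end = lf[2],
      right_target_start = rf[1], right_target_end = rf[2],
      left_read_start = 1L, left_read_end = s$p,
      right_read_start = s$p + 1L, right_read_end = L,
      left_matched = s$p - s$mmL, right_matched = (L - s$p) - s$mmR,
      left_mismatches = s$mmL, right_mismatches = s$mmR,
      mismatches = s$mmL + s$mmR,
      left_diag = s$ld, right_diag = s$rd, partition = s$p,
      stringsAsFactors = FALSE
    )
  }))
  sdf <- sdf[!duplicated(sdf[, c("left_ref", "right_ref", "strand",
                                 "left_diag", "right_diag", "partition")]), ,
             drop = FALSE]
  min_side <- pmin(sdf$partition, L - sdf$partition)
  ord <- order(sdf$mismatches, -min_side, -sdf$partition,
               sdf$left_ref, sdf$left_target_start,
               sdf$right_ref, sdf$right_target_start)
  sdf <- sdf[ord, , drop = FALSE]
  rownames(sdf) <- NULL
  best_min_side <- pmin(sdf$partition, L - sdf$partition)
  top <- sdf$mismatches == sdf$mismatches[1L] &
    best_min_side == best_min_side[1L]
  n_pairs <- length(unique(paste(sdf$left_ref[top], sdf$right_ref[top],
                                 sdf$strand[top])))
  list(full = empty_full_df(), split = sdf,
       n_best_full = 0L, n_best_split_pairs = n_pairs)
}

to_forward <- function(q1, q2, strand, Tlen) {
  if (strand == "+") c(q1, q2) else c(Tlen - q2 + 1L, Tlen - q1 + 1L)
}

empty_full_df <- function() {
  data.frame(ref = character(0), strand = character(0),
             target_start = integer(0), target_end = integer(0),
             read_start = integer(0), read_end = integer(0),
             matched = integer(0), mismatches = integer(0),
             stringsAsFactors = FALSE)
}

empty_split_df <- function() {
  data.frame(left_ref = character(0), right_ref = character(0),
             strand = character(0),
             left_target_start = integer(0), left_target_end = integer(0),
             right_target_start = integer(0), right_target_end = integer(0),
             left_read_start = integer(0), left_read_end = integer(0),
             right_read_start = integer(0), right_read_end = integer(0),
             left_matched = integer(0), right_matched = integer(0),
             left_mismatches = integer(0), right_mismatches = integer(0),
             mismatches = integer(0),
             left_diag = integer(0), right_diag = integer(0),
             partition = integer(0), stringsAsFactors = FALSE)
}

# Mismatch count of each matchPattern hit against the pattern.
count_view_mismatches <- function(pat, views) {
  praw <- charToRaw(pat)
  vapply(as.character(views), function(s) sum(charToRaw(s) != praw),
         integer(1), USE.NAMES = FALSE)
}
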