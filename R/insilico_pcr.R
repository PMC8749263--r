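# In-silico PCR on circular templates.
#
# A primer binds where a semi-global (fitting) alignment places it: the
# primer is consumed in full, the template locally, under unit-cost edits
# (mismatch, single-base template insertion, single-base template deletion).
# Polymerase extension requires a perfectly paired 3' terminus, so the last
# `three_prime_window` primer bases must match the template with zero edits;
# that constraint is imposed structurally (exact suffix match) and the edit
# budget applies to the remaining prefix.

#' The published pan-vertebrate back-to-back primer pair
#'
#' Forward 22-mer and reverse 25-mer targeting the conserved MT-RNR2 region
#' that overlaps the SHLP6-encoding sORF; on the ring their footprints are
#' adjacent with 3' ends pointing away from each other, so a single amplicon
#' traverses the whole circle.
#'
#' @return Named list with elements `fwd` and `rev` (5'->3' strings).
#' @export
published_primers <- function() {
  list(fwd = "TACGTGATCTGAGTTCAGACCG",
       rev = "GTAGGACTTTAATCGTTGAACAAAC")
}

#' The conserved genomic motif targeted by the published pair
#'
#' The 47-nt plus-strand template footprint: reverse complement of the
#' reverse primer immediately followed by the forward primer.
#' @return Nucleotide string of length 47.
#' @export
primer_motif <- function() {
  p <- published_primers()
  paste0(reverse_complement(p$rev), p$fwd)
}

# fitting edit distance of `pattern` ending at every text position.
# Returns numeric vector D[j], j = 1..n: min edits of an alignment consuming
# the whole pattern and ending at text position j. Rows are vectorized; the
# within-row left-to-right dependency (template insertions) is resolved with
# a running-minimum (cummin) pass.
fit_dp_lastrow <- function(pat_chars, txt_chars, compat) {
  n <- length(txt_chars)
  m <- length(pat_chars)
  prev <- rep(0, n + 1L)                 # D[0, 0..n] : free start in text
  for (i in seq_len(m)) {
    cost <- as.numeric(!compat[cbind(pat_chars[i], txt_chars)])
    cur <- pmin(prev[1:n] + cost,        # diagonal
                prev[2:(n + 1)] + 1)     # vertical: template deletion
    cur <- c(prev[1] + 1, cur)
    # horizontal closure: cur[j] = min_k<=j cur[k] + (j - k)
    j <- seq_len(n + 1L)
    cur <- cummin(cur - j) + j
    prev <- cur
  }
  prev[-1]                               # D[m, 1..n]
}

# full DP matrix with traceback on a small window; returns start (1-based in
# window), mismatches, insertions (template bases inserted), deletions
fit_traceback <- function(pat_chars, win_chars, compat) {
  m <- length(pat_chars); n <- length(win_chars)
  D <- matrix(0, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cost <- if (compat[pat_chars[i], win_chars[j]]) 0 else 1
      D[i + 1L, j + 1L] <- min(D[i, j] + cost, D[i, j + 1L] + 1, D[i + 1L, j] + 1)
    }
  }
  i <- m; j <- n; mm <- 0L; ins <- 0L; del <- 0L
  while (i > 0L) {
    cost <- if (j > 0L && compat[pat_chars[i], win_chars[j]]) 0 else 1
    if (j > 0L && D[i + 1L, j + 1L] == D[i, j] + cost) {
      mm <- mm + cost; i <- i - 1L; j <- j - 1L
    } else if (D[i + 1L, j + 1L] == D[i, j + 1L] + 1) {
      del <- del + 1L; i <- i - 1L
    } else {
      ins <- ins + 1L; j <- j - 1L
    }
  }
  list(start = j + 1L, mismatches = mm, insertions = ins, deletions = del,
       edits = mm + ins + del)
}

# right-anchored scan of `pattern` against linear text: last `w` pattern
# bases must match exactly; the prefix is fit with <= max_edits edits.
scan_anchored_right <- function(pattern, text, max_edits, w, compat) {
  m <- nchar(pattern); n <- nchar(text)
  if (m > n) return(NULL)
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(text, "")[[1]]
  w <- min(w, m)
  # candidate end positions: exact (IUPAC-compatible... primers are plain
  # ACGT, templates may carry ambiguity codes) suffix match
  if (w > 0L) {
    ok <- rep(TRUE, n)
    ok[seq_len(w - 1L)] <- FALSE
    sfx <- pc[(m - w + 1L):m]
    for (k in seq_len(w)) {
      idx <- which(ok)
      idx <- idx[compat[cbind(sfx[w - k + 1L], tc[idx - k + 1L])]]
      ok2 <- rep(FALSE, n); ok2[idx] <- TRUE; ok <- ok2
    }
    ends <- which(ok)
  } else {
    ends <- seq_len(n)
  }
  if (length(ends) == 0L) return(NULL)
  mp <- m - w
  if (mp == 0L) {
    res <- lapply(ends, function(j) {
      list(start = j - w + 1L, end = j, mismatches = 0L,
           insertions = 0L, deletions = 0L, edits = 0L)
    })
    return(res)
  }
  lastrow <- fit_dp_lastrow(pc[seq_len(mp)], tc, compat)
  keep <- ends[ends - w >= 1L]
  keep <- keep[lastrow[keep - w] <= max_edits]
  if (length(keep) == 0L) return(NULL)
  lapply(keep, function(j) {
    je <- j - w                                  # prefix alignment end
    wlen <- min(je, mp + max_edits)
    win <- tc[(je - wlen + 1L):je]
    tb <- fit_traceback(pc[seq_len(mp)], win, compat)
    list(start = je - wlen + tb$start, end = j,
         mismatches = tb$mismatches, insertions = tb$insertions,
         deletions = tb$deletions, edits = tb$edits)
  })
}

#' Scan a circular genome for binding sites of one primer
#'
#' Finds every placement on either strand whose semi-global unit-cost edit
#' distance (primer fully consumed) is at most `max_edits` and whose
#' `three_prime_window` terminal primer bases match the template exactly.
#' The search wraps the origin. Overlapping alternative placements of the
#' same site are collapsed to the best one (fewest edits, then lowest
#' position).
#'
#' @param g A [circ_seq].
#' @param primer 5'->3' primer string (plain ACGT) or a named list
#'   `list(name=, seq=)`.
#' @param max_edits Total edit tolerance outside the 3' window (default 2).
#' @param three_prime_window Number of 3'-terminal bases required to match
#'   exactly (default 3).
#' @return Data frame with columns `primer, strand, start, end, mismatches,
#'   insertions, deletions, edits, three_prime_exact` (0-based half-open
#'   plus-strand spans; `end` may exceed L for origin-wrapping sites),
#'   sorted by (edits, start).
#' @export
scan_primer <- function(g, primer, max_edits = 2L, three_prime_window = 3L) {
  stopifnot(inherits(g, "circ_seq"), max_edits >= 0L, three_prime_window >= 0L)
  if (is.character(primer)) primer <- list(name = "primer", seq = primer)
  pseq <- toupper(primer$seq)
  if (!grepl("^[ACGT]+$", pseq)) stop("primer must be plain ACGT")
  m <- nchar(pseq)
  L <- g$length
  if (m > L) stop("primer longer than genome")
  ext <- if (g$circular) min(L, m + max_edits) else 0L
  text <- paste0(g$seq, substr(g$seq, 1L, ext))
  n <- nchar(text)

  collect <- function(strand) {
    if (strand == "+") {
      hits <- scan_anchored_right(pseq, text, max_edits, three_prime_window,
                                  iupac_compat)
      if (is.null(hits)) return(NULL)
      do.call(rbind, lapply(hits, function(h) {
        data.frame(primer = primer$name, strand = "+",
                   start = h$start - 1L, end = h$end,
                   mismatches = h$mismatches, insertions = h$insertions,
                   deletions = h$deletions, edits = h$edits,
                   stringsAsFactors = FALSE)
      }))
    } else {
      # rc(primer) matches the plus strand; the primer 3' end maps to the
      # span START. Reverse both strings and reuse the right-anchored scan.
      prc_rev <- paste(rev(strsplit(reverse_complement(pseq), "")[[1]]), collapse = "")
      trev <- paste(rev(strsplit(text, "")[[1]]), collapse = "")
      hits <- scan_anchored_right(prc_rev, trev, max_edits, three_prime_window,
                                  iupac_compat)
      if (is.null(hits)) return(NULL)
      do.call(rbind, lapply(hits, function(h) {
        data.frame(primer = primer$name, strand = "-",
                   start = n - h$end, end = n - h$start + 1L,
                   mismatches = h$mismatches, insertions = h$insertions,
                   deletions = h$deletions, edits = h$edits,
                   stringsAsFactors = FALSE)
      }))
    }
  }
  out <- rbind(collect("+"), collect("-"))
  if (is.null(out) || nrow(out) == 0L) return(empty_sites(primer$name))
  # map into [0, L); drop duplicates arising from the circular extension
  out$start_mod <- out$start %% L
  out$end <- out$start_mod + (out$end - out$start)
  out$start <- out$start_mod
  out$start_mod <- NULL
  out <- out[!duplicated(out[c("strand", "start", "end")]), , drop = FALSE]
  out <- collapse_overlaps(out, L)
  out$three_prime_exact <- TRUE
  out <- out[order(out$edits, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_sites <- function(name = character(0)) {
  data.frame(primer = character(0), strand = character(0),
             start = integer(0), end = integer(0), mismatches = integer(0),
             insertions = integer(0), deletions = integer(0),
             edits = integer(0), three_prime_exact = logical(0),
             stringsAsFactors = FALSE)
}

# collapse overlapping same-strand placements to the best (min edits, then
# lowest start): alternative alignments of one physical site otherwise show
# up as clusters of shifted spans
collapse_overlaps <- function(sites, L) {
  keep <- rep(TRUE, nrow(sites))
  for (str in unique(sites$strand)) {
    idx <- which(sites$strand == str)
    if (length(idx) < 2) next
    s <- sites[idx, ]
    ord <- order(s$start)
    grp <- integer(length(ord)); gid <- 1L; grp[ord[1]] <- 1L
    max_end <- s$end[ord[1]]
    for (k in seq_along(ord)[-1]) {
      i <- ord[k]
      if (s$start[i] < max_end) grp[i] <- gid
      else { gid <- gid + 1L; grp[i] <- gid }
      max_end <- max(max_end, s$end[i])
    }
    for (gg in unique(grp)) {
      members <- idx[grp == gg]
      if (length(members) == 1) next
      best <- members[order(sites$edits[members], sites$start[members])][1]
      keep[setdiff(members, best)] <- FALSE
    }
  }
  sites[keep, , drop = FALSE]
}

#' Pair forward and reverse binding sites into back-to-back amplicons
#'
#' Retains opposite-strand pairs whose 3' ends point away from each other
#' around the ring. The uncovered gap is the circular distance from the
#' minus-strand site's 5' boundary to the plus-strand site's 5' boundary;
#' back-to-back geometry means a small gap (0 when the footprints are
#' adjacent) and a product that runs the long way round:
#' `product_length + gap == L`.
#'
#' @param sites_fwd,sites_rev Site tables from [scan_primer()] on the same
#'   ring (forward and reverse primer respectively).
#' @param L Ring length.
#' @param max_gap Maximal tolerated uncovered gap in nt (default 50).
#' @return Data frame of amplicon predictions sorted by (total edits, gap,
#'   position): columns `fwd_start, fwd_end, fwd_strand, rev_start, rev_end,
#'   rev_strand, product_start, product_length, gap, total_edits`. Empty
#'   when no valid pair exists.
#' @export
pair_back_to_back <- function(sites_fwd, sites_rev, L, max_gap = 50L) {
  out <- NULL
  for (i in seq_len(nrow(sites_fwd))) for (j in seq_len(nrow(sites_rev))) {
    f <- sites_fwd[i, ]; r <- sites_rev[j, ]
    if (f$strand == r$strand) next             # same-strand pairs: rejected
    plus <- if (f$strand == "+") f else r      # site whose primer reads +
    minus <- if (f$strand == "+") r else f
    gap <- (plus$start - (minus$end %% L)) %% L
    if (gap > max_gap) next                    # inward-facing pairs land here
    out <- rbind(out, data.frame(
      fwd_start = f$start, fwd_end = f$end, fwd_strand = f$strand,
      rev_start = r$start, rev_end = r$end, rev_strand = r$strand,
      product_start = plus$start, product_length = L - gap, gap = gap,
      total_edits = f$edits + r$edits, stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    return(data.frame(fwd_start = integer(0), fwd_end = integer(0),
                      fwd_strand = character(0), rev_start = integer(0),
                      rev_end = integer(0), rev_strand = character(0),
                      product_start = integer(0), product_length = integer(0),
                      gap = integer(0), total_edits = integer(0)))
  }
  out <- out[order(out$total_edits, out$gap, out$product_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the single back-to-back amplicon of a primer pair on a ring
#'
#' Convenience wrapper: scans both primers and keeps the best valid pairing
#' (minimal total edits, then minimal gap, then lowest position).
#'
#' @inheritParams scan_primer
#' @param primers List with `fwd` and `rev` primer strings (defaults to the
#'   published pair).
#' @param max_gap Maximal uncovered gap.
#' @return One-row amplicon data frame (see [pair_back_to_back()]), or the
#'   empty table when the pair finds no back-to-back geometry.
#' @export
predict_amplicon <- function(g, primers = published_primers(), max_edits = 2L,
                             three_prime_window = 3L, max_gap = 50L) {
  sf <- scan_primer(g, list(name = "fwd", seq = primers$fwd), max_edits,
                    three_prime_window)
  sr <- scan_primer(g, list(name = "rev", seq = primers$rev), max_edits,
                    three_prime_window)
  amp <- pair_back_to_back(sf, sr, g$length, max_gap)
  amp[seq_len(min(1L, nrow(amp))), , drop = FALSE]
}

#' Find low-degeneracy windows in a multiple alignment
#'
#' Slides a window over the alignment columns and scores each by the mean
#' per-column count of distinct symbols (an alignment gap counts as a
#' variant). Fully conserved windows score 1. The `top_k` best
#' non-overlapping windows are returned, ties broken leftmost.
#'
#' @param alignment Character vector of aligned rows (equal width), or a
#'   `Biostrings::DNAStringSet`.
#' @param window_len Window width in columns.
#' @param top_k Number of windows to return.
#' @return Data frame `c0, c1, score, taxa` (0-based half-open column
#'   spans), ordered by increasing score.
#' @export
find_conserved_motifs <- function(alignment, window_len = 47L, top_k = 1L) {
  if (!is.character(alignment)) alignment <- as.character(alignment)
  if (length(alignment) < 2L) stop("alignment needs at least two rows")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in width")
  W <- widths[1]
  if (window_len > W) stop("window longer than alignment")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  colvar <- apply(mat, 2L, function(col) length(unique(col)))
  csum <- c(0, cumsum(colvar))
  starts <- seq_len(W - window_len + 1L)
  score <- (csum[starts + window_len] - csum[starts]) / window_len
  ord <- order(score, starts)
  chosen <- integer(0)
  for (s in ord) {
    if (length(chosen) >= top_k) break
    if (all(abs(starts[s] - chosen) >= window_len)) chosen <- c(chosen, starts[s])
  }
  data.frame(c0 = chosen - 1L, c1 = chosen - 1L + window_len,
             score = score[chosen], taxa = length(alignment))
}

#' Majority consensus of a multiple alignment
#'
#' @param alignment Character vector of equal-width aligned rows.
#' @return Consensus string (most frequent symbol per column; ties broken
#'   alphabetically; gap wins only if strictly most frequent).
#' @export
consensus_sequence <- function(alignment) {
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  apply(mat, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    cands <- names(tb)[tb == max(tb)]
    nongap <- setdiff(cands, "-")
    if (length(nongap) > 0) sort(nongap)[1] else "-"
  }) |> paste(collapse = "")
}

#' Derive a back-to-back primer pair from a conserved window
#'
#' Splits the window at an internal junction: the block 5' of the junction,
#' reverse-complemented, becomes the reverse primer and the block 3' of the
#' junction the forward primer, so that the two 3' ends face outward on the
#' genome. With the published pair, the window is exactly
#' `rc(rev primer) + fwd primer` and `junction = rev_len` reproduces the
#' printed oligos.
#'
#' @param window Plus-strand nucleotide string of the conserved window
#'   (gaps, if any, are removed).
#' @param fwd_len,rev_len Primer lengths.
#' @param junction 0-based position of the junction within the window
#'   (default `rev_len`: the two primers are adjacent at the window start).
#' @return Named list `fwd`, `rev` of 5'->3' primer strings.
#' @export
design_back_to_back <- function(window, fwd_len, rev_len, junction = rev_len) {
  window <- gsub("-", "", toupper(window))
  if (nchar(window) < fwd_len + rev_len) stop("window too short for both primers")
  if (junction < rev_len || junction + fwd_len > nchar(window))
    stop("junction leaves no room for a primer block")
  block5 <- substr(window, junction - rev_len + 1L, junction)
  block3 <- substr(window, junction + 1L, junction + fwd_len)
  list(fwd = block3, rev = reverse_complement(block5))
}
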