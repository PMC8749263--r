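# Independent brute-force oracles used to check the package's optimized
# implementations. These deliberately share no code with the package
# internals: adist() Levenshtein distances, plain triple loops, explicit
# string rotation.

random_ring <- function(n, seed) {
  set.seed(seed)
  circ_seq(paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
           id = sprintf("ring%d", seed))
}

# exhaustive per-offset semi-global oracle for primer binding sites:
# every end position whose 3'-window suffix matches exactly and whose
# prefix aligns within max_edits (minimized over footprint lengths) is a
# candidate; overlapping candidates keep the best (fewest edits, lowest
# start). Returns the same columns as scan_primer (minus the profile
# decomposition, which adist does not expose).
oracle_scan <- function(g, primer, max_edits = 2L, w = 3L) {
  L <- g$length
  m <- nchar(primer)
  ext <- min(L, m + max_edits)
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(primer)))
    text <- paste0(g$seq, substr(g$seq, 1L, ext))
    n <- nchar(text)
    # for "-" the primer 3' end maps to the span start: operate on the
    # reversed text/pattern so the suffix anchor logic is shared
    if (strand == "-") {
      pat <- paste(rev(strsplit(pat, "")[[1]]), collapse = "")
      text <- paste(rev(strsplit(text, "")[[1]]), collapse = "")
    }
    sfx <- substr(pat, m - w + 1L, m)
    pfx <- substr(pat, 1L, m - w)
    cands <- NULL
    for (e in seq(m, n)) {
      if (substr(text, e - w + 1L, e) != sfx) next
      best <- Inf; best_l <- NA
      # footprint-length preference on ties mirrors the scanner's traceback:
      # full-length (mismatch) first, then shorter (deletion), then longer
      for (l in intersect(c(m, m - seq_len(max_edits), m + seq_len(max_edits)),
                          seq_len(e))) {
        s <- e - l + 1L
        d <- utils::adist(pfx, substr(text, s, e - w))
        if (d < best) { best <- d; best_l <- l }
      }
      if (best <= max_edits) {
        cands <- rbind(cands, data.frame(start = e - best_l, end = e,
                                         edits = as.integer(best)))
      }
    }
    if (is.null(cands)) next
    if (strand == "-") {   # map reversed coordinates back
      s2 <- n - cands$end
      e2 <- n - cands$start
      cands$start <- s2; cands$end <- e2
    }
    width <- cands$end - cands$start
    cands$start <- cands$start %% L
    cands$end <- cands$start + width
    cands$strand <- strand
    out <- rbind(out, cands)
  }
  if (is.null(out)) return(NULL)
  out <- out[!duplicated(out[c("strand", "start")]), , drop = FALSE]
  # collapse overlapping placements per strand: keep min edits, lowest start
  keep <- rep(TRUE, nrow(out))
  for (strand in unique(out$strand)) {
    idx <- which(out$strand == strand)
    s <- out[idx, ]
    ord <- idx[order(s$start)]
    i <- 1L
    while (i <= length(ord)) {
      j <- i
      max_end <- out$end[ord[i]]
      while (j < length(ord) && out$start[ord[j + 1L]] < max_end) {
        j <- j + 1L
        max_end <- max(max_end, out$end[ord[j]])
      }
      grp <- ord[i:j]
      best <- grp[order(out$edits[grp], out$start[grp])][1]
      keep[setdiff(grp, best)] <- FALSE
      i <- j + 1L
    }
  }
  out <- out[keep, c("strand", "start", "edits")]
  out[order(out$edits, out$start), , drop = FALSE]
}

# brute-force start-to-stop ORF enumeration in 3 frames of one strand
oracle_orfs <- function(window, code_table, starts_set, min_len, max_len) {
  out <- NULL
  W <- nchar(window)
  for (frame in 0:2) {
    pos <- seq(frame + 1L, W - 2L, by = 3L)
    if (length(pos) == 0L) next
    codons <- substring(window, pos, pos + 2L)
    aa <- ifelse(codons %in% names(code_table), code_table[codons], "X")
    for (si in seq_along(codons)) {
      if (!codons[si] %in% starts_set) next
      stop_i <- NA
      k <- si
      while (k <= length(codons)) {
        if (aa[k] == "*") { stop_i <- k; break }
        k <- k + 1L
      }
      len <- (if (is.na(stop_i)) length(codons) + 1L else stop_i) - si
      pep <- c("M", if (len > 1) aa[(si + 1L):(si + len - 1L)])
      out <- rbind(out, data.frame(
        frame = frame, start = pos[si] - 1L,
        length = len, peptide = paste(pep, collapse = ""),
        stop_found = !is.na(stop_i),
        status = if (len < min_len) "below_min_length"
                 else if (len > max_len) "above_max_length" else "intact",
        stringsAsFactors = FALSE))
    }
  }
  out
}

# explicit rotation oracle for circular slices
rotate_string <- function(s, k) {
  n <- nchar(s)
  k <- k %% n
  if (k == 0) return(s)
  paste0(substr(s, k + 1, n), substr(s, 1, k))
}

write_test_genbank <- function(path) {
  writeLines(c(
    "LOCUS       TEST0001            120 bp    DNA     circular VRT 01-JAN-2020",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     gene            11..40",
    '                     /gene="MT-CYB"',
    "     CDS             11..40",
    '                     /gene="MT-CYB"',
    "     tRNA            41..60",
    '                     /product="trnT"',
    "     D-loop          join(101..120,1..10)",
    "     rRNA            complement(61..100)",
    '                     /gene="MT-RNR1"',
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "       61 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), path)
  path
}
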