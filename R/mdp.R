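# Locating, translating and classifying the sORF loci that encode
# mitochondrial-derived peptides (MDPs). A locus is anchored on a genome by
# homology to a catalog reference sORF (seeded fitting alignment on both
# strands), the anchored window is read in the locus' own orientation, and
# the ORF status is called at the aligned reference start.

EXTENDED_STARTS <- c("ATG", "ATA", "ATT", "ATC", "GTG")

#' Load an MDP locus catalog
#'
#' The catalog lists the nine MDP sORF loci (MOTS-c, humanin, SHLP1-6, gau)
#' with host gene, reading sense, genetic code and reference sORF
#' nucleotide/peptide sequences. The shipped default catalog is a synthetic
#' construction (see its header comment); each entry is validated by
#' translating `ref_nt` and comparing with `ref_peptide`.
#'
#' @param path YAML catalog; `NULL` loads the shipped synthetic catalog.
#' @return List with fields `loci` (named list of locus specs), `min_len`,
#'   `max_len`, `flank`.
#' @export
mdp_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mdp_catalog_synthetic.yaml",
                        package = "mitoring")
  }
  cat_raw <- yaml::read_yaml(path)
  loci <- cat_raw$loci
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  check_code <- genetic_code("standard", start_set = EXTENDED_STARTS)
  for (sp in loci) {
    tr <- translate_orf(sp$ref_nt, check_code, "require_listed_start")
    if (tr$status != "translated" || tr$peptide != sp$ref_peptide) {
      stop("catalog entry '", sp$name, "': ref_nt does not translate to ref_peptide")
    }
  }
  list(loci = loci,
       min_len = cat_raw$min_len %||% 8L,
       max_len = cat_raw$max_len %||% 40L,
       flank = cat_raw$flank %||% 30L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nt_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                     baseOnly = FALSE)
    }
    m
  }
})

# fitting alignment (pattern global, subject local) of ref against a window
align_fit <- function(pattern, subject_str) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject_str),
    type = "global-local", substitutionMatrix = nt_submat(),
    gapOpening = 10, gapExtension = 4)
}

#' Anchor a catalog locus on a genome by homology
#'
#' Seeds candidate placements of the reference sORF with 13-mer matches
#' (one mismatch tolerated) on both strands of the doubled ring, refines
#' each candidate with a fitting alignment (reference consumed in full),
#' and returns the best placement padded by `flank` nt on each side. A
#' placement below `min_identity` percent identity means the locus is not
#' locatable on this genome (a value, not an error).
#'
#' @param g A [circ_seq].
#' @param spec One catalog locus entry (`mdp_catalog()$loci[[name]]`).
#' @param min_identity Percent identity threshold (default 60).
#' @param flank Window padding in nt (default 30).
#' @return List: `found`; and when found `strand`, `ref_start`, `ref_end`
#'   (0-based plus-strand span of the aligned reference, `ref_end` may
#'   exceed L), `window_start`, `window_end`, `window_nt` (read in the
#'   locus orientation), `ref_offset` (0-based offset of the reference
#'   start within `window_nt`), `identity`, `indel_parity`.
#' @export
locate_locus <- function(g, spec, min_identity = 60, flank = 30L) {
  ref <- toupper(spec$ref_nt)
  plen <- nchar(ref)
  if (plen < 24L) stop("reference sORF shorter than 24 nt")
  L <- g$length
  doubled <- paste0(g$seq, substr(g$seq, 1L, min(L, plen + 2L * flank + 50L)))
  subj <- Biostrings::DNAString(doubled)

  best <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") ref else reverse_complement(ref)
    starts <- candidate_starts(pat, subj, plen)
    if (length(starts) == 0L) next
    for (cs in starts) {
      w0 <- max(1L, cs - 25L)
      w1 <- min(nchar(doubled), cs + plen + 25L)
      pa <- align_fit(pat, substr(doubled, w0, w1))
      ident <- Biostrings::pid(pa)
      if (is.null(best) || BiocGenerics::score(pa) > best$score) {
        a0 <- w0 + IRanges::start(Biostrings::subject(pa)) - 2L  # 0-based
        a1 <- w0 + IRanges::end(Biostrings::subject(pa)) - 1L
        best <- list(score = BiocGenerics::score(pa), strand = strand,
                     a0 = a0, a1 = a1, identity = ident)
      }
    }
  }
  if (is.null(best) || best$identity < min_identity) return(list(found = FALSE))
  a0 <- best$a0 %% L
  a1 <- a0 + (best$a1 - best$a0)
  w0 <- (a0 - flank) %% L
  w1 <- w0 + (a1 - a0) + 2L * flank
  win <- circular_slice_long(g, w0, w1)
  if (best$strand == "-") win <- reverse_complement(win)
  list(found = TRUE, strand = best$strand, ref_start = a0, ref_end = a1,
       window_start = w0, window_end = w1, window_nt = win,
       ref_offset = flank, identity = best$identity,
       indel_parity = (best$a1 - best$a0 - plen) %% 3L)
}

# slice allowing end - start up to L (end may exceed 2L bound of
# circular_slice after modding); start 0-based in [0, L)
circular_slice_long <- function(g, start, end) {
  L <- g$length
  width <- end - start
  stopifnot(width >= 0, width <= L)
  e <- start + width
  if (e <= L) return(substr(g$seq, start + 1L, e))
  paste0(substr(g$seq, start + 1L, L), substr(g$seq, 1L, e - L))
}

candidate_starts <- function(pat, subj, plen) {
  k <- 13L
  stride <- max(7L, plen %/% 12L)
  offs <- unique(c(seq(1L, max(1L, plen - k + 1L), by = stride), plen - k + 1L))
  hits <- integer(0)
  for (o in offs) {
    seed <- substr(pat, o, o + k - 1L)
    if (nchar(seed) < k) next
    mp <- Biostrings::matchPattern(seed, subj, max.mismatch = 1L)
    if (length(mp) > 0) hits <- c(hits, IRanges::start(mp) - (o - 1L))
  }
  if (length(hits) == 0L) return(integer(0))
  hits <- sort(unique(hits))
  # cluster within half a reference length; keep one representative each
  reps <- hits[1]
  for (h in hits[-1]) if (h - reps[length(reps)] > plen %/% 2L) reps <- c(reps, h)
  reps
}

#' Enumerate start-to-stop sORFs in a window
#'
#' Scans all three frames of the given (already orientation-adjusted)
#' window. Under `"require_listed_start"` every listed start codon opens a
#' candidate ORF running to the next in-frame terminator; nested downstream
#' starts yield their own records. Records without an in-window terminator
#' are flagged truncated.
#'
#' @param window_nt Nucleotide string.
#' @param code A [genetic_code].
#' @param start_policy Start policy (see [translate_orf()]).
#' @param min_len,max_len Peptide length bounds for the `intact` status
#'   (defaults 8 and 40).
#' @return Data frame: `frame, start, end` (0-based half-open nt span in
#'   the window), `length` (aa), `peptide`, `stop_found`, `status`
#'   (`intact`, `below_min_length`, `above_max_length`).
#' @export
scan_sorfs <- function(window_nt, code = genetic_code("standard"),
                       start_policy = c("require_listed_start",
                                        "no_start_required"),
                       min_len = 8L, max_len = 40L) {
  start_policy <- match.arg(start_policy)
  window_nt <- toupper(window_nt)
  W <- nchar(window_nt)
  out <- NULL
  for (frame in 0:2) {
    n <- (W - frame) %/% 3L
    if (n < 1L) next
    codons <- substring(window_nt, frame + 3L * seq_len(n) - 2L,
                        frame + 3L * seq_len(n))
    aa <- vapply(codons, translate_codon, character(1), code = code)
    stops <- which(aa == "*")
    starts <- if (start_policy == "require_listed_start") {
      which(codons %in% code$start_set)
    } else {
      # first codon and every codon following a terminator
      sort(unique(c(1L, stops + 1L)))
    }
    for (s in starts) {
      if (s > n) next
      nxt <- stops[stops >= s]
      stop_found <- length(nxt) > 0
      e <- if (stop_found) nxt[1] else n
      # truncated ORFs (no in-window stop) translate through the last codon
      pep <- aa[seq(s, length.out = e - s + !stop_found)]
      if (length(pep) > 0) pep[1] <- "M"
      len <- length(pep)
      status <- if (len < min_len) "below_min_length"
                else if (len > max_len) "above_max_length" else "intact"
      out <- rbind(out, data.frame(
        frame = frame, start = frame + 3L * (s - 1L),
        end = frame + 3L * e + if (stop_found) 3L else 0L,
        length = len, peptide = paste(pep, collapse = ""),
        stop_found = stop_found, status = status, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), start = integer(0), end = integer(0),
                      length = integer(0), peptide = character(0),
                      stop_found = logical(0), status = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Classify one MDP locus on one genome
#'
#' Anchors the locus ([locate_locus()]), then calls the status at the
#' aligned reference start: a net indel whose length is not a multiple of
#' three within the reference footprint is a `frameshift`; no listed start
#' codon at the reference start is `absent_no_start`; an in-frame stop
#' truncating the peptide below the minimum length is `premature_stop`; a
#' missing or far-downstream terminator is `above_max_length`; otherwise
#' the locus is `intact` with its observed peptide length (which may be a
#' size variant of the reference). Downstream in-frame starts are reported
#' as secondary records in attribute `"secondary"`.
#'
#' @param g A [circ_seq].
#' @param spec Catalog locus entry.
#' @param code A [genetic_code] (default: standard nuclear code, the MDP
#'   translation rule).
#' @param start_set Optional start-set override (e.g. [EXTENDED_STARTS]).
#' @param min_len,max_len,flank,min_identity See [mdp_catalog()].
#' @return One-row data frame: `mdp_name, status, length, peptide, strand,
#'   start, end, identity`.
#' @export
classify_mdp <- function(g, spec, code = genetic_code("standard"),
                         start_set = NULL, min_len = 8L, max_len = 40L,
                         flank = 30L, min_identity = 60) {
  if (!is.null(start_set)) code$start_set <- toupper(start_set)
  rec <- function(status, length = NA_integer_, peptide = NA_character_,
                  strand = NA_character_, start = NA_integer_,
                  end = NA_integer_, identity = NA_real_) {
    data.frame(mdp_name = spec$name, status = status, length = length,
               peptide = peptide, strand = strand, start = start, end = end,
               identity = identity, stringsAsFactors = FALSE)
  }
  loc <- locate_locus(g, spec, min_identity = min_identity, flank = flank)
  if (!loc$found) return(rec("not_locatable"))
  if (loc$indel_parity != 0L) {
    return(rec("frameshift", strand = loc$strand,
               start = loc$ref_start, end = loc$ref_end,
               identity = loc$identity))
  }
  W <- loc$window_nt
  o <- loc$ref_offset
  start_codon <- substr(W, o + 1L, o + 3L)
  orfs <- scan_sorfs(substr(W, o + 1L, nchar(W)), code,
                     "require_listed_start", min_len, max_len)
  secondary <- orfs[orfs$frame == 0L & orfs$start > 0L, , drop = FALSE]
  if (!start_codon %in% code$start_set) {
    out <- rec("absent_no_start", strand = loc$strand,
               start = loc$ref_start, end = loc$ref_end,
               identity = loc$identity)
    attr(out, "secondary") <- secondary
    return(out)
  }
  tr <- translate_orf(substr(W, o + 1L, nchar(W)), code, "require_listed_start")
  len <- nchar(tr$peptide)
  status <- if (!tr$stop_found || len > max_len) "above_max_length"
            else if (len < min_len) "premature_stop"
            else "intact"
  out <- rec(status, length = len, peptide = tr$peptide, strand = loc$strand,
             start = loc$ref_start, end = loc$ref_end,
             identity = loc$identity)
  attr(out, "secondary") <- secondary
  out
}

#' Scan the gau locus under the extended mitochondrial start repertoire
#'
#' The gau sORF sits antisense within MT-CO1 and opens with ATA: under the
#' plain nuclear rule it has no functional start (`absent_no_start`), while
#' the extended vertebrate-mitochondrial start set recovers a dwarf
#' peptide.
#'
#' @param g A [circ_seq].
#' @param spec The gau catalog entry.
#' @param extended_starts Start set (default `ATG, ATA, ATT, ATC, GTG`).
#' @param ... Passed to [classify_mdp()].
#' @return One-row record as from [classify_mdp()].
#' @export
gau_extended_scan <- function(g, spec, extended_starts = EXTENDED_STARTS, ...) {
  classify_mdp(g, spec, code = genetic_code("standard"),
               start_set = extended_starts, ...)
}

#' Species-by-locus MDP conservation matrix
#'
#' One [classify_mdp()] call per (genome, catalog locus), in deterministic
#' row (input) and column (catalog) order. Cells read `intact(<length>)` or
#' the non-intact status.
#'
#' @param genomes List of [circ_seq] objects.
#' @param catalog A catalog from [mdp_catalog()].
#' @param code A [genetic_code] for the primary (nuclear-rule) calls.
#' @return List: `matrix` (data frame, rows = genomes, columns = loci) and
#'   `records` (long data frame of all per-locus records).
#' @export
build_conservation_matrix <- function(genomes, catalog = mdp_catalog(),
                                      code = genetic_code("standard")) {
  stopifnot(length(genomes) >= 1L)
  loci <- catalog$loci
  records <- NULL
  cells <- matrix(NA_character_, nrow = length(genomes), ncol = length(loci),
                  dimnames = list(vapply(genomes, `[[`, character(1), "id"),
                                  names(loci)))
  for (i in seq_along(genomes)) {
    for (locus in names(loci)) {
      r <- classify_mdp(genomes[[i]], loci[[locus]], code = code,
                        min_len = catalog$min_len, max_len = catalog$max_len,
                        flank = catalog$flank)
      r$genome <- genomes[[i]]$id
      records <- rbind(records, r)
      cells[i, locus] <- if (r$status == "intact")
        sprintf("intact(%d)", r$length) else r$status
    }
  }
  list(matrix = as.data.frame(cells, stringsAsFactors = FALSE),
       records = records)
}

#' Longest conserved ungapped core across a set of peptides
#'
#' Aligns the peptides (directly when equal length; otherwise by
#' center-star merging of pairwise global alignments against the longest
#' peptide) and returns the longest run of columns that are identical and
#' ungapped in every row.
#'
#' @param peptides Character vector of amino-acid strings (length >= 2).
#' @return List: `length` (integer, 0 when no column is shared) and `core`
#'   (the conserved residue string).
#' @export
conserved_core <- function(peptides) {
  stopifnot(length(peptides) >= 2L)
  if (any(nchar(peptides) == 0L)) stop("empty peptide in input")
  rows <- if (length(unique(nchar(peptides))) == 1L) {
    peptides
  } else {
    center_star_align(peptides)
  }
  mat <- do.call(rbind, strsplit(rows, ""))
  same <- apply(mat, 2L, function(col) length(unique(col)) == 1L && col[1] != "-")
  best_len <- 0L; best_at <- 0L; run <- 0L
  for (j in seq_along(same)) {
    run <- if (same[j]) run + 1L else 0L
    if (run > best_len) { best_len <- run; best_at <- j }
  }
  core <- if (best_len > 0)
    paste(mat[1, (best_at - best_len + 1L):best_at], collapse = "") else ""
  list(length = best_len, core = core)
}

# simple center-star multiple alignment of short peptides: every sequence
# is globally aligned to the longest one; per-junction insertion counts are
# merged by maximum
center_star_align <- function(peptides) {
  ref_i <- which.max(nchar(peptides))
  ref <- peptides[ref_i]
  n_ref <- nchar(ref)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  sub_mat <- get("BLOSUM62", envir = data_env)
  alns <- lapply(peptides, function(p) {
    if (p == ref) return(list(pat = ref, sub = ref))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p), Biostrings::AAString(ref), type = "global",
      substitutionMatrix = sub_mat, gapOpening = 10, gapExtension = 2)
    list(pat = as.character(Biostrings::alignedPattern(pa)),
         sub = as.character(Biostrings::alignedSubject(pa)))
  })
  # ins[k]: extra columns between ref position k and k+1 (k = 0..n_ref)
  ins <- integer(n_ref + 1L)
  per_seq <- lapply(alns, function(al) {
    sub_c <- strsplit(al$sub, "")[[1]]
    pat_c <- strsplit(al$pat, "")[[1]]
    pos <- cumsum(sub_c != "-")           # ref position at/before column
    k <- ifelse(sub_c == "-", pos, NA)
    list(sub = sub_c, pat = pat_c, refpos = pos)
  })
  for (ps in per_seq) {
    gaps <- table(ps$refpos[ps$sub == "-"])
    for (k in names(gaps)) {
      ki <- as.integer(k) + 1L
      ins[ki] <- max(ins[ki], gaps[[k]])
    }
  }
  vapply(per_seq, function(ps) {
    out <- character(0)
    used <- integer(n_ref + 1L)
    for (j in seq_along(ps$sub)) {
      if (ps$sub[j] == "-") {
        used[ps$refpos[j] + 1L] <- used[ps$refpos[j] + 1L] + 1L
        out <- c(out, ps$pat[j])
      } else {
        k <- ps$refpos[j]
        out <- c(out, rep("-", ins[k] - used[k]), ps$pat[j])
        used[k] <- ins[k]                  # mark junction before pos k filled
      }
    }
    out <- c(out, rep("-", ins[n_ref + 1L] - used[n_ref + 1L]))
    paste(out, collapse = "")
  }, character(1))
}
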