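#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# expansion sets of the IUPAC nucleotide ambiguity codes
iupac_expand <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 15x15 logical: do the expansion sets of two IUPAC codes intersect?
iupac_compat <- local({
  m <- matrix(FALSE, length(IUPAC_CHARS), length(IUPAC_CHARS),
              dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  for (a in IUPAC_CHARS) for (b in IUPAC_CHARS)
    m[a, b] <- length(intersect(iupac_expand[[a]], iupac_expand[[b]])) > 0
  m
})

validate_nt <- function(seq, id = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% IUPAC_CHARS)
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                 chars[bad[1]], id, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Circular (or linear) nucleotide sequence
#'
#' Lightweight container for a mitogenome-scale nucleotide ring. Coordinates
#' throughout the package are 0-based, half-open and plus-strand oriented;
#' on a circular sequence any position arithmetic wraps modulo the length.
#'
#' @param seq Nucleotide string (IUPAC codes; lowercase is uppercased).
#' @param id Record identifier.
#' @param circular Logical; is the molecule a closed ring?
#' @return An object of class `circ_seq` with fields `id`, `seq`, `circular`
#'   and `length`.
#' @examples
#' g <- circ_seq("ACGTACGT", id = "toy")
#' circular_slice(g, 6, 10)  # wraps the origin
#' @export
circ_seq <- function(seq, id = "seq", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  seq <- toupper(seq)
  validate_nt(seq, id)
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 length = nchar(seq)),
            class = "circ_seq")
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("circ_seq '%s': %d nt, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' @export
length.circ_seq <- function(x) x$length

#' Extract a (possibly origin-wrapping) slice of a ring
#'
#' Returns bases `start .. end-1` in 0-based half-open coordinates. On a
#' circular sequence `end` may exceed the length (up to `2L`) or be smaller
#' than `start`, in which case the slice wraps the origin. A zero-length
#' slice is allowed.
#'
#' @param g A [circ_seq].
#' @param start,end 0-based half-open bounds; `0 <= start < L`, `0 <= end <= 2L`.
#' @return A nucleotide string.
#' @export
circular_slice <- function(g, start, end) {
  stopifnot(inherits(g, "circ_seq"))
  L <- g$length
  if (start < 0 || start >= L) stop("start out of range [0, L)")
  if (end < 0 || end > 2L * L) stop("end out of range [0, 2L]")
  if (end < start) end <- end + L
  if (end > L && !g$circular) stop("wrapping slice requested on a non-circular sequence")
  if (end == start) return("")
  if (end <= L) return(substr(g$seq, start + 1L, end))
  paste0(substr(g$seq, start + 1L, L), substr(g$seq, 1L, end - L))
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes are complemented to their mirrored expansion set
#' (e.g. `R` -> `Y`, `N` -> `N`); the operation is an involution.
#'
#' @param s Nucleotide string.
#' @return The reverse complement, same length.
#' @export
reverse_complement <- function(s) {
  if (nchar(s) == 0L) return(s)
  s <- toupper(s)
  validate_nt(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Rotate a ring so it starts at an anchor motif
#'
#' Normalizes the rotation of a circular assembly: the returned ring starts
#' at the first (lowest-position) exact plus-strand occurrence of
#' `anchor_motif`. Length and content are unchanged up to rotation.
#'
#' @param g A circular [circ_seq].
#' @param anchor_motif Exact nucleotide string that must occur on the plus
#'   strand (occurrences wrapping the origin are found).
#' @param annotations Optional feature data frame (`name,start,end,strand`);
#'   if supplied, rotated coordinates are returned in attribute
#'   `"annotations"`.
#' @return A rotated [circ_seq].
#' @export
rotate_to_anchor <- function(g, anchor_motif, annotations = NULL) {
  stopifnot(inherits(g, "circ_seq"))
  if (!g$circular) stop("rotate_to_anchor requires a circular sequence")
  anchor_motif <- toupper(anchor_motif)
  L <- g$length
  doubled <- paste0(g$seq, substr(g$seq, 1L, min(L, nchar(anchor_motif) - 1L)))
  hit <- regexpr(anchor_motif, doubled, fixed = TRUE)[1]
  if (hit < 0) stop(sprintf("anchor motif absent from '%s'", g$id))
  k <- (hit - 1L) %% L                      # 0-based rotation offset
  out <- rotate_ring(g, k)
  if (!is.null(annotations)) {
    attr(out, "annotations") <- rotate_annotations(annotations, k, L)
  }
  out
}

# left-rotate a ring by k (0-based): new ring starts at old position k
rotate_ring <- function(g, k) {
  L <- g$length
  k <- ((k %% L) + L) %% L
  if (k == 0) return(g)
  circ_seq(paste0(substr(g$seq, k + 1L, L), substr(g$seq, 1L, k)),
           id = g$id, circular = g$circular)
}

rotate_annotations <- function(ann, k, L) {
  width <- ann$end - ann$start            # end may be stored > L for wraps
  ann$start <- (ann$start - k) %% L
  ann$end <- ann$start + width            # widths are rotation-invariant
  ann
}

feature_annotation <- function(name, start, end, strand = "+") {
  data.frame(name = name, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a (multi-record) FASTA file of mitogenomes
#'
#' @param path FASTA file.
#' @param circular Default topology for records whose header carries no
#'   `topology=circular` / `topology=linear` token.
#' @return A list of [circ_seq] objects in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    circ <- circular
    if (grepl("topology=circular", header, fixed = TRUE)) circ <- TRUE
    if (grepl("topology=linear", header, fixed = TRUE)) circ <- FALSE
    circ_seq(as.character(set[[i]]), id = id, circular = circ)
  })
}

#' Write circ_seq objects to FASTA
#'
#' @param genomes A [circ_seq] or list of them.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circ_seq")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf(">%s topology=%s", g$id,
                       if (g$circular) "circular" else "linear"), con)
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, g$length)), con)
  }
  invisible(path)
}

# ---- GenBank flat-file reading -------------------------------------------
# Minimal parser for annotated mitogenome records: LOCUS topology, the
# gene/CDS/rRNA/tRNA/D-loop features with simple, complement() and two-part
# join() locations (origin-spanning), and the ORIGIN sequence block.
# GenBank 1-based inclusive spans are converted to 0-based half-open here,
# at the I/O boundary only.

parse_gb_location <- function(loc, L = NA_integer_) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    ivs <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(ivs) == 2L && !is.na(L) && ivs[[1]][2] == L && ivs[[2]][1] == 1L) {
      # two intervals composing an origin-wrapping feature -> single span
      return(list(start = ivs[[1]][1] - 1L,
                  end = L + ivs[[2]][2], strand = strand))
    }
    return(list(start = ivs[[1]][1] - 1L, end = ivs[[length(ivs)]][2],
                strand = strand))
  }
  iv <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(iv) == 1L) iv <- c(iv, iv)
  list(start = iv[1] - 1L, end = iv[2], strand = strand)
}

#' Read a GenBank flat file
#'
#' Parses a single annotated record: topology from the LOCUS line, features
#' of kinds gene/CDS/rRNA/tRNA/D-loop (a D-loop feature is named `NCR`), and
#' the ORIGIN sequence. Feature spans are converted to the package's 0-based
#' half-open convention; a `join()` of two intervals meeting at the origin
#' becomes a single wrapping span with `end > L`.
#'
#' @param path GenBank flat file.
#' @return A list with elements `genome` (a [circ_seq]) and `annotations`
#'   (data frame `name,start,end,strand`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0 && grepl("circular", locus[1], ignore.case = TRUE)
  id <- if (length(locus) > 0) strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1] else "genbank"

  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("GenBank record lacks an ORIGIN block: ", path)
  seq_lines <- lines[(oi[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(seq) == 0L) stop("empty ORIGIN block: ", path)
  L <- nchar(seq)

  fi <- grep("^FEATURES", lines)
  ann <- feature_annotation(character(0), integer(0), integer(0), character(0))
  if (length(fi) > 0) {
    feat_lines <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    keys <- c("gene", "CDS", "rRNA", "tRNA", "D-loop")
    cur_key <- NULL; cur_loc <- NULL; cur_name <- NULL; pending_qual <- FALSE
    flush <- function() {
      if (is.null(cur_key)) return()
      loc <- parse_gb_location(cur_loc, L)
      nm <- if (!is.null(cur_name)) cur_name else if (cur_key == "D-loop") "NCR" else cur_key
      ann <<- rbind(ann, feature_annotation(nm, loc$start, loc$end, loc$strand))
    }
    for (ln in feat_lines) {
      m <- regmatches(ln, regexec("^\\s{1,10}(\\S+)\\s+(\\S.*)$", ln))[[1]]
      is_qual <- grepl("^\\s{11,}/", ln)
      if (!is_qual && length(m) == 3 && m[2] %in% keys) {
        flush()
        cur_key <- m[2]; cur_loc <- trimws(m[3]); cur_name <- NULL
      } else if (!is_qual && !is.null(cur_key) && is.null(cur_name) &&
                 grepl("^\\s{11,}\\S", ln) && !grepl("/", ln)) {
        cur_loc <- paste0(cur_loc, trimws(ln))   # continued location line
      } else if (is_qual && !is.null(cur_key)) {
        q <- regmatches(ln, regexec('/(gene|product)="?([^"]+)"?', ln))[[1]]
        if (length(q) == 3 && is.null(cur_name)) cur_name <- q[3]
      }
    }
    flush()
    # keep one feature per name (gene + CDS duplicates collapse)
    if (nrow(ann) > 0) ann <- ann[!duplicated(ann[c("name", "start")]), , drop = FALSE]
    if (sum(ann$name == "NCR") > 1)
      stop("more than one NCR/D-loop feature in ", path)
    rownames(ann) <- NULL
  }
  list(genome = circ_seq(seq, id = id, circular = circular), annotations = ann)
}

# oriented extraction of an annotated feature: minus-strand features are
# returned reverse-complemented (reading orientation)
feature_seq <- function(g, ann, name) {
  row <- ann[ann$name == name, , drop = FALSE]
  if (nrow(row) == 0L) stop("feature not annotated: ", name)
  s <- circular_slice(g, row$start[1] %% g$length,
                      if (row$end[1] > g$length) row$end[1] else row$end[1])
  if (row$strand[1] == "-") s <- reverse_complement(s)
  s
}
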