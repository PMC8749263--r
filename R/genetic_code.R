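# Codon tables are built here from first principles (TCAG codon enumeration
# plus the documented reassignments of the vertebrate mitochondrial code)
# rather than taken from an external table object: the start-codon policy and
# the stop/terminator semantics are part of the prediction method.

codon_order <- local({
  b <- c("T", "C", "A", "G")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)               # TTT,TTC,TTA,TTG,TCT,...
})

aa_standard <- strsplit(paste0(
  "FFLLSSSSYY**CC*W",   # TTT..TGG
  "LLLLPPPPHHQQRRRR",   # CTT..CGG
  "IIIMTTTTNNKKSSRR",   # ATT..AGG
  "VVVVAAAADDEEGGGG"    # GTT..GGG
), "")[[1]]

# vertebrate mitochondrial reassignments: ATA Ile->Met, TGA Stop->Trp,
# AGA/AGG Arg->Stop
aa_vert_mito <- local({
  aa <- aa_standard
  names(aa) <- codon_order
  aa["ATA"] <- "M"; aa["TGA"] <- "W"; aa["AGA"] <- "*"; aa["AGG"] <- "*"
  unname(aa)
})

#' Genetic code with an explicit start-codon set
#'
#' Two built-in codes are shipped: `"standard"` (the nuclear code under which
#' mitochondrial-derived peptides are translated in the cytoplasm; start set
#' `ATG` only) and `"vertebrate_mito"` (NCBI translation table 2; extended
#' start repertoire `ATG, ATA, ATT, ATC, GTG`).
#'
#' @param name `"standard"` or `"vertebrate_mito"`.
#' @param start_set Optional override of the start-codon set.
#' @return An object of class `genetic_code`: fields `name`, `table` (named
#'   64-entry codon to amino-acid map, `*` = terminator) and `start_set`.
#' @export
genetic_code <- function(name = c("standard", "vertebrate_mito"),
                         start_set = NULL) {
  name <- match.arg(name)
  tab <- if (name == "standard") aa_standard else aa_vert_mito
  tab <- setNames(tab, codon_order)
  if (is.null(start_set)) {
    start_set <- if (name == "standard") "ATG" else c("ATG", "ATA", "ATT", "ATC", "GTG")
  }
  stopifnot(length(tab) == 64L, all(nchar(names(tab)) == 3L), length(start_set) > 0)
  structure(list(name = name, table = tab, start_set = toupper(start_set)),
            class = "genetic_code")
}

# translate one codon; a codon containing any ambiguity code yields X
# (and is never treated as a terminator)
translate_codon <- function(codon, code) {
  if (codon %in% names(code$table)) return(unname(code$table[codon]))
  "X"
}

#' Translate a nucleotide string codon-by-codon (no start scanning)
#'
#' @param nt Nucleotide string; trailing partial codon is ignored.
#' @param code A [genetic_code].
#' @param stop_symbol Symbol used for terminators.
#' @return Amino-acid string (terminators included as `stop_symbol`).
#' @export
translate_nt <- function(nt, code = genetic_code("standard"), stop_symbol = "*") {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- vapply(codons, translate_codon, character(1), code = code)
  aa[aa == "*"] <- stop_symbol
  paste(aa, collapse = "")
}

#' Translate an sORF under a start-codon policy
#'
#' Scans in-frame from position 0 for the first codon in the code's start
#' set (policy `"require_listed_start"`), reports the initiator residue as
#' `M` whatever the start codon, and translates up to (not including) the
#' first terminator.
#'
#' @param nt Nucleotide string, length >= 3.
#' @param code A [genetic_code].
#' @param start_policy `"require_listed_start"` or `"no_start_required"`.
#' @return A list: `status` (`"translated"` or `"absent_no_start"`),
#'   `peptide`, `start_offset` (0-based nt offset of the initiator codon),
#'   `stop_found` (logical: in-frame terminator reached before the end).
#' @export
translate_orf <- function(nt, code = genetic_code("standard"),
                          start_policy = c("require_listed_start",
                                           "no_start_required")) {
  start_policy <- match.arg(start_policy)
  nt <- toupper(nt)
  if (nchar(nt) < 3L) stop("nt shorter than one codon")
  n <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  first <- 1L
  if (start_policy == "require_listed_start") {
    hits <- which(codons %in% code$start_set)
    if (length(hits) == 0L) {
      return(list(status = "absent_no_start", peptide = "",
                  start_offset = NA_integer_, stop_found = FALSE))
    }
    first <- hits[1]
  }
  aa <- vapply(codons[first:n], translate_codon, character(1), code = code)
  stop_at <- which(aa == "*")
  stop_found <- length(stop_at) > 0
  pep <- if (stop_found) aa[seq_len(stop_at[1] - 1L)] else aa
  if (length(pep) > 0 && start_policy == "require_listed_start") pep[1] <- "M"
  list(status = "translated", peptide = paste(pep, collapse = ""),
       start_offset = 3L * (first - 1L), stop_found = stop_found)
}
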