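# Pairwise divergence and candidate amino-acid-site screening.
#
# Divergence is the standard uncorrected p-distance: substitutions counted
# over mutually ungapped columns of a global pairwise alignment, after
# excluding the major noncoding region (control region) by default — the
# NCR evolves too fast and too structurally (tandem repeats, length
# polymorphism) to be informative for delimitation.

#' Uncorrected pairwise divergence between two mitogenomes
#'
#' Globally aligns the two sequences (whole ring with regions excluded, or
#' one annotated gene) and reports percent divergence over the mutually
#' ungapped columns. Scoring (match 2, mismatch -2, gap open 12, gap extend
#' 8) is chosen so that equal-length substitution-only pairs align without
#' spurious gaps.
#'
#' @param a,b [circ_seq] objects.
#' @param annotations_a,annotations_b Feature tables (`name,start,end,strand`)
#'   for `a` and `b`; required when `exclude` or `gene` is used.
#' @param exclude Feature name(s) to exclude (default `"NCR"`); `NULL` or
#'   `character(0)` compares full length.
#' @param gene Restrict the comparison to one annotated gene (oriented
#'   extraction; `exclude` is ignored).
#' @return One-row data frame: `id_a, id_b, region, aligned_columns,
#'   compared_columns, gap_columns, differing_columns, divergence, identity`
#'   (percentages), plus metadata column `distance = "p-distance"`.
#' @export
p_distance <- function(a, b, annotations_a = NULL, annotations_b = NULL,
                       exclude = "NCR", gene = NULL) {
  stopifnot(inherits(a, "circ_seq"), inherits(b, "circ_seq"))
  if (!is.null(gene)) {
    if (is.null(annotations_a) || is.null(annotations_b))
      stop("per-gene distance needs annotations for both genomes")
    sa <- feature_seq(a, annotations_a, gene)
    sb <- feature_seq(b, annotations_b, gene)
    region <- gene
  } else {
    sa <- mask_features(a, annotations_a, exclude)
    sb <- mask_features(b, annotations_b, exclude)
    region <- if (length(exclude %||% character(0)) > 0)
      paste0("mitogenome-", paste(exclude, collapse = ",")) else "mitogenome"
  }
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("empty sequence after region exclusion")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb), type = "global",
    substitutionMatrix = nt_submat(), gapOpening = 12, gapExtension = 8)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  aligned <- length(pc)
  gapcols <- sum(pc == "-" | sc == "-")
  compared <- aligned - gapcols
  diff <- sum(pc != sc & pc != "-" & sc != "-")
  divergence <- 100 * diff / compared
  data.frame(id_a = a$id, id_b = b$id, region = region,
             aligned_columns = aligned, compared_columns = compared,
             gap_columns = gapcols, differing_columns = diff,
             divergence = divergence, identity = 100 - divergence,
             distance = "p-distance", stringsAsFactors = FALSE)
}

mask_features <- function(g, ann, exclude) {
  if (is.null(exclude) || length(exclude) == 0L || is.null(ann)) return(g$seq)
  rows <- ann[ann$name %in% exclude, , drop = FALSE]
  if (nrow(rows) == 0L) return(g$seq)
  keep <- rep(TRUE, g$length)
  for (i in seq_len(nrow(rows))) {
    pos <- (rows$start[i]:(rows$end[i] - 1L)) %% g$length
    keep[pos + 1L] <- FALSE
  }
  paste(strsplit(g$seq, "")[[1]][keep], collapse = "")
}

#' Genetic Species Concept flag
#'
#' Flags a pair as candidate distinct species when MT-CYB divergence
#' strictly exceeds the 11% delimitation threshold.
#'
#' @param mtcyb_divergence_percent Divergence in percent (0-100).
#' @return Logical.
#' @export
species_flag <- function(mtcyb_divergence_percent) {
  stopifnot(mtcyb_divergence_percent >= 0, mtcyb_divergence_percent <= 100)
  mtcyb_divergence_percent > 11.0
}

#' Load a candidate amino-acid-site catalog
#'
#' Sites are recorded as gene-relative 1-based codon indices (with the
#' human mitogenome position kept as metadata where the literature reports
#' one), reference residue, variant residues, and phenotype label.
#'
#' @param path YAML file; `NULL` loads the shipped catalog of the four
#'   cold-adaptation sites and the high-altitude MT-ND1 site.
#' @return Data frame: `gene, codon, ref_residue, variant_residues,
#'   phenotype, human_pos`.
#' @export
candidate_sites <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "candidate_sites.yaml", package = "mitoring")
  }
  raw <- yaml::read_yaml(path)
  do.call(rbind, lapply(raw$sites, function(s) {
    data.frame(gene = s$gene, codon = as.integer(s$codon),
               ref_residue = s$ref_residue,
               variant_residues = paste(unlist(s$variant_residues), collapse = "/"),
               phenotype = s$phenotype,
               human_pos = s$human_pos %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Call the residue at a candidate site in one genome
#'
#' Locates the gene by homology to a reference gene sequence (fitting
#' alignment, both strands), maps the target codon through the alignment
#' columns, requires all three codon positions to be aligned without gaps
#' (otherwise the call is `uncallable` with the reason recorded), and
#' translates under the vertebrate mitochondrial code.
#'
#' @param g A [circ_seq].
#' @param site One row of a [candidate_sites()] table.
#' @param reference_gene_nt Reference nucleotide sequence of the gene
#'   (coding orientation, codon 1 = first three bases).
#' @param code Genetic code used to translate the codon.
#' @param min_identity Anchoring identity threshold in percent.
#' @return One-row data frame: `genome, gene, codon, residue, callable,
#'   reason, identity`.
#' @export
call_candidate_site <- function(g, site, reference_gene_nt,
                                code = genetic_code("vertebrate_mito"),
                                min_identity = 60) {
  ref <- toupper(reference_gene_nt)
  spec <- list(name = site$gene, ref_nt = ref)
  out <- function(residue, callable, reason, identity = NA_real_) {
    data.frame(genome = g$id, gene = site$gene, codon = site$codon,
               residue = residue, callable = callable, reason = reason,
               identity = identity, stringsAsFactors = FALSE)
  }
  loc <- locate_locus(g, spec, min_identity = min_identity, flank = 0L)
  if (!loc$found) return(out(NA_character_, FALSE, "gene not locatable"))
  pa <- align_fit(ref, loc$window_nt)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(pc != "-")
  want <- 3L * (site$codon - 1L) + 1:3
  cols <- match(want, ref_pos)
  cols <- cols[!is.na(cols)]
  if (length(cols) != 3L || any(sc[cols] == "-") || any(diff(cols) != 1L)) {
    return(out(NA_character_, FALSE, "frame-breaking alignment at codon",
               loc$identity))
  }
  codon_nt <- paste(sc[cols], collapse = "")
  out(translate_codon(codon_nt, code), TRUE, "ok", loc$identity)
}

#' Per-group residue frequency table for candidate-site calls
#'
#' Counts called residues per species group per site; no inferential
#' statistics are attached — the contrast is a descriptive table.
#'
#' @param calls Data frame of [call_candidate_site()] rows (one per
#'   genome and site).
#' @param groups Data frame `genome, group` assigning every genome to
#'   exactly one group.
#' @return Data frame: `gene, codon, group, residue, n`.
#' @export
group_contrast <- function(calls, groups) {
  miss <- setdiff(unique(calls$genome), groups$genome)
  if (length(miss) > 0)
    stop("genomes without group assignment: ", paste(miss, collapse = ", "))
  calls$group <- groups$group[match(calls$genome, groups$genome)]
  calls <- calls[calls$callable, , drop = FALSE]
  agg <- stats::aggregate(list(n = calls$genome),
                          by = list(gene = calls$gene, codon = calls$codon,
                                    group = calls$group,
                                    residue = calls$residue),
                          FUN = length)
  agg <- agg[order(agg$gene, agg$codon, agg$group, agg$residue), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
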