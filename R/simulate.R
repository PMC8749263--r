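# Seeded synthetic mitogenome generator.
#
# Emulated features of real vertebrate mitogenomes: circular topology,
# 14-20 kb size, the canonical gene order (two rRNAs, 13 protein genes,
# 22 tRNAs, one major NCR), light/heavy-strand-skewed base composition,
# the conserved back-to-back primer motif inside MT-RNR2 overlapping the
# SHLP6 sORF, catalog MDP loci planted intact or pseudogenized, optional
# NCR tandem repeats, and haplotype pairs of exactly controlled divergence.
# Everything is a pure function of (plan, seed) and every planted feature
# is returned as ground truth.

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

random_nt <- function(n, freqs = c(A = 0.33, C = 0.26, G = 0.13, T = 0.28)) {
  if (n <= 0) return("")
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

# canonical vertebrate mitochondrial gene order with typical lengths
canonical_gene_order <- function() {
  d <- function(name, kind, len, strand = "+")
    data.frame(name = name, kind = kind, length = len, strand = strand,
               stringsAsFactors = FALSE)
  rbind(
    d("trnF", "tRNA", 71), d("MT-RNR1", "rRNA", 950), d("trnV", "tRNA", 69),
    d("MT-RNR2", "rRNA", 1560), d("trnL1", "tRNA", 75),
    d("MT-ND1", "gene", 960), d("trnI", "tRNA", 69), d("trnQ", "tRNA", 72, "-"),
    d("trnM", "tRNA", 68), d("MT-ND2", "gene", 1040), d("trnW", "tRNA", 68),
    d("trnA", "tRNA", 69, "-"), d("trnN", "tRNA", 73, "-"),
    d("trnC", "tRNA", 66, "-"), d("trnY", "tRNA", 66, "-"),
    d("MT-CO1", "gene", 1545), d("trnS1", "tRNA", 72, "-"), d("trnD", "tRNA", 68),
    d("MT-CO2", "gene", 684), d("trnK", "tRNA", 70), d("MT-ATP8", "gene", 165),
    d("MT-ATP6", "gene", 681), d("MT-CO3", "gene", 784), d("trnG", "tRNA", 68),
    d("MT-ND3", "gene", 346), d("trnR", "tRNA", 65), d("MT-ND4L", "gene", 297),
    d("MT-ND4", "gene", 1378), d("trnH", "tRNA", 69), d("trnS2", "tRNA", 60),
    d("trnL2", "tRNA", 71), d("MT-ND5", "gene", 1812),
    d("MT-ND6", "gene", 528, "-"), d("trnE", "tRNA", 69, "-"),
    d("MT-CYB", "gene", 1140), d("trnT", "tRNA", 67), d("trnP", "tRNA", 66, "-"),
    d("NCR", "NCR", NA)
  )
}

# relative placement of the MDP loci within their host genes
locus_layout <- c("MOTS-c" = 0.30, humanin = 0.05, SHLP1 = 0.15, SHLP2 = 0.28,
                  SHLP3 = 0.42, SHLP4 = 0.58, SHLP5 = 0.72, SHLP6 = 0.85,
                  gau = 0.40)

#' Simulation plan for one synthetic mitogenome
#'
#' @param seed Integer seed; the generator is a pure function of the plan.
#' @param genome_length Ring length in nt (drawn uniformly from
#'   14,000-20,000 when `NULL`). Locus and primer plantings are
#'   length-preserving replacements; a planted NCR repeat array is an
#'   insertion and lengthens the ring by `unit_len * copies`.
#' @param primer_plan List: `mode` one of `"exact"`, `"mismatch"`,
#'   `"insertion"`, `"absent"`; `k` number of substitutions for
#'   `"mismatch"`.
#' @param mdp_plan Named character vector over catalog loci with values
#'   `"intact"`, `"absent_no_start"`, `"premature_stop"`, `"frameshift"` or
#'   `"absent"` (locus not planted). Unnamed loci default to `"intact"`.
#' @param variant_nt Named list of replacement sORF nucleotide sequences
#'   for planted-intact loci (species size/sequence variants).
#' @param ncr_repeats `NULL`, or list `unit_len`, `copies` for a planted
#'   tandem-repeat array in the NCR.
#' @param base_freqs Background base composition.
#' @param id Genome identifier.
#' @return Object of class `sim_plan`.
#' @export
sim_plan <- function(seed = 1L, genome_length = NULL,
                     primer_plan = list(mode = "exact", k = 1L),
                     mdp_plan = character(0), variant_nt = list(),
                     ncr_repeats = NULL,
                     base_freqs = c(A = 0.33, C = 0.26, G = 0.13, T = 0.28),
                     id = sprintf("sim_%d", seed)) {
  if (!is.null(genome_length) &&
      (genome_length < 14000L || genome_length > 20000L))
    stop("genome_length outside the vertebrate mitogenome bound 14-20 kb")
  structure(list(seed = seed, genome_length = genome_length,
                 primer_plan = primer_plan, mdp_plan = mdp_plan,
                 variant_nt = variant_nt, ncr_repeats = ncr_repeats,
                 base_freqs = base_freqs, id = id),
            class = "sim_plan")
}

#' Pseudogenize an sORF
#'
#' Realizes one of the three documented loss-of-coding modes on a reference
#' sORF: `absent_no_start` mutates the initiator to ACG (not a start under
#' the standard or the extended mitochondrial repertoire); `premature_stop`
#' replaces an internal codon before both the half-length point and the
#' minimum peptide length with TAA; `frameshift` deletes (or inserts, by
#' seed parity) one base mid-ORF.
#'
#' @param locus_nt Reference sORF (start codon through stop codon).
#' @param mode One of the three modes.
#' @param seed Integer seed.
#' @param min_len Minimal peptide length the premature stop must undercut.
#' @return Mutated nucleotide string.
#' @export
plant_pseudogenization <- function(locus_nt, mode, seed = 1L, min_len = 8L) {
  locus_nt <- toupper(locus_nt)
  n_cod <- nchar(locus_nt) %/% 3L
  n_aa <- n_cod - 1L                     # minus the terminator
  with_seed(seed, {
    if (mode == "absent_no_start") {
      paste0("ACG", substr(locus_nt, 4L, nchar(locus_nt)))
    } else if (mode == "premature_stop") {
      j_max <- min(min_len, n_aa %/% 2L)
      if (j_max < 2L) stop("locus too short for a premature stop")
      j <- sample(2:j_max, 1L)
      paste0(substr(locus_nt, 1L, 3L * (j - 1L)), "TAA",
             substr(locus_nt, 3L * j + 1L, nchar(locus_nt)))
    } else if (mode == "frameshift") {
      if (n_aa < 4L) stop("locus too short for a mid-ORF frameshift")
      p <- 3L * (n_aa %/% 2L) + 1L       # first base of a middle codon
      if (seed %% 2L == 0L) {
        paste0(substr(locus_nt, 1L, p - 1L),
               substr(locus_nt, p + 1L, nchar(locus_nt)))
      } else {
        paste0(substr(locus_nt, 1L, p - 1L), sample(c("A", "C", "G", "T"), 1L),
               substr(locus_nt, p, nchar(locus_nt)))
      }
    } else stop("unknown pseudogenization mode: ", mode)
  })
}

# apply the primer plan to the 47-nt motif; returns the motif sequence to
# embed plus the expected per-primer edit truth
apply_primer_plan <- function(motif, primer_plan) {
  mode <- primer_plan$mode %||% "exact"
  truth <- data.frame(primer = c("fwd", "rev"), mismatches = 0L,
                      insertions = 0L, stringsAsFactors = FALSE)
  if (mode == "exact") return(list(motif = motif, truth = truth))
  if (mode == "mismatch") {
    k <- primer_plan$k %||% 1L
    # inside the forward-primer footprint, away from the 3' window
    pos <- sample(28:43, k) + 1L         # 1-based positions in the motif
    chars <- strsplit(motif, "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
    truth$mismatches[truth$primer == "fwd"] <- k
    return(list(motif = paste(chars, collapse = ""), truth = truth))
  }
  if (mode == "insertion") {
    p <- 36L                             # within the forward footprint
    truth$insertions[truth$primer == "fwd"] <- 1L
    return(list(motif = paste0(substr(motif, 1L, p),
                               sample(c("A", "C", "G", "T"), 1L),
                               substr(motif, p + 1L, nchar(motif))),
                truth = truth))
  }
  stop("unknown primer plan mode: ", mode)
}

#' Generate an annotated synthetic mitogenome with planted ground truth
#'
#' @param plan A [sim_plan].
#' @param catalog MDP locus catalog ([mdp_catalog()]).
#' @return List: `genome` (a [circ_seq]), `annotations` (feature table),
#'   `truth` (list with `loci` data frame of planted statuses/coordinates,
#'   `primers` data frame of expected per-primer edits, `motif_start`,
#'   `ncr_repeats`).
#' @export
generate_mitogenome <- function(plan, catalog = mdp_catalog()) {
  stopifnot(inherits(plan, "sim_plan"))
  with_seed(plan$seed, {
    L_target <- plan$genome_length %||% sample(14000:20000, 1L)
    layout <- canonical_gene_order()
    n_t <- sum(layout$length[layout$kind == "tRNA"], na.rm = TRUE)
    ncr_len <- max(400L, round(0.055 * L_target))
    big <- which(layout$kind %in% c("gene", "rRNA"))
    f <- (L_target - n_t - ncr_len) / sum(layout$length[big])
    if (f < 0.5) stop("planned features overflow the genome length")
    layout$length[big] <- round(layout$length[big] * f)
    layout$length[layout$name == "NCR"] <-
      L_target - sum(layout$length, na.rm = TRUE)

    # default plan: every catalog locus intact
    mdp_plan <- setNames(rep("intact", length(catalog$loci)),
                         names(catalog$loci))
    mdp_plan[names(plan$mdp_plan)] <- plan$mdp_plan
    if ((plan$primer_plan$mode %||% "exact") == "absent")
      mdp_plan["SHLP6"] <- "absent"      # the motif block carries SHLP6

    seqs <- list()
    planted <- NULL                      # locus truth relative to feature
    motif_rel <- NA_integer_             # motif offset within MT-RNR2
    for (i in seq_len(nrow(layout))) {
      nm <- layout$name[i]
      len <- layout$length[i]
      s <- random_nt(len, plan$base_freqs)
      host_loci <- names(catalog$loci)[vapply(catalog$loci, function(sp)
        sp$host == nm, logical(1))]
      if (nm == "NCR" && !is.null(plan$ncr_repeats)) {
        unit <- random_nt(plan$ncr_repeats$unit_len, plan$base_freqs)
        arr <- strrep(unit, plan$ncr_repeats$copies)
        mid <- len %/% 2L
        s <- paste0(substr(s, 1L, mid), arr, substr(s, mid + 1L, len))
      }
      for (locus in host_loci) {
        mode <- mdp_plan[[locus]]
        if (mode == "absent") next
        spec <- catalog$loci[[locus]]
        nt <- plan$variant_nt[[locus]] %||% spec$ref_nt
        if (mode %in% c("absent_no_start", "premature_stop", "frameshift"))
          nt <- plant_pseudogenization(nt, mode, seed = plan$seed + match(locus, names(catalog$loci)))
        block <- nt
        if (locus == "SHLP6") {
          # the sORF tail is the start of the primer motif; append the rest
          motif <- primer_motif()
          pp <- apply_primer_plan(motif, plan$primer_plan)
          overlap <- 17L                 # motif bases inside the sORF
          block <- paste0(substr(nt, 1L, nchar(nt) - overlap),
                          substr(pp$motif, 1L, overlap),
                          substr(pp$motif, overlap + 1L, nchar(pp$motif)))
          primer_truth <- pp$truth
          motif_rel <- round(locus_layout[[locus]] * len) +
            (nchar(nt) - overlap)
        }
        if (spec$sense == "antisense") block <- reverse_complement(block)
        off <- round(locus_layout[[locus]] * len)
        if (off + nchar(block) > nchar(s))
          stop("planned features overflow host gene ", nm)
        s <- paste0(substr(s, 1L, off), block,
                    substr(s, off + nchar(block) + 1L, nchar(s)))
        planted <- rbind(planted, data.frame(
          locus = locus, status = if (mode == "intact") "intact" else mode,
          feature = nm, rel_start = off, len = nchar(nt),
          strand = if (spec$sense == "antisense") "-" else "+",
          stringsAsFactors = FALSE))
      }
      seqs[[nm]] <- s
    }
    if (!exists("primer_truth", inherits = FALSE))
      primer_truth <- data.frame(primer = c("fwd", "rev"),
                                 mismatches = NA_integer_,
                                 insertions = NA_integer_)

    widths <- vapply(seqs, nchar, integer(1))
    starts <- cumsum(c(0L, widths[-length(widths)]))
    names(starts) <- names(widths)
    ann <- data.frame(name = layout$name, start = unname(starts[layout$name]),
                      end = unname(starts[layout$name] + widths[layout$name]),
                      strand = layout$strand, stringsAsFactors = FALSE)
    g <- circ_seq(paste(unlist(seqs), collapse = ""), id = plan$id,
                  circular = TRUE)
    if (!is.null(planted)) {
      planted$start <- starts[planted$feature] + planted$rel_start
      planted$end <- planted$start + planted$len
      # loci absent from the ring
      missing <- setdiff(names(catalog$loci), planted$locus)
    } else missing <- names(catalog$loci)
    if (length(missing) > 0) {
      planted <- rbind(planted, data.frame(
        locus = missing, status = "not_locatable", feature = NA, rel_start = NA,
        len = NA, strand = NA, start = NA, end = NA, stringsAsFactors = FALSE))
    }
    rownames(planted) <- NULL
    list(genome = g, annotations = ann,
         truth = list(loci = planted, primers = primer_truth,
                      motif_start = if (is.na(motif_rel)) NA_integer_
                                    else unname(starts[["MT-RNR2"]] + motif_rel),
                      ncr_repeats = plan$ncr_repeats,
                      genome_length = g$length))
  })
}

#' Derive a haplotype of exactly controlled divergence
#'
#' Plants `round(L * d / 100)` substitutions at uniformly sampled distinct
#' positions (no indels), so the planted p-distance is exact up to
#' rounding. With `region_divergence`, named annotated features receive
#' their own exact substitution counts and `divergence_percent` applies to
#' the remainder of the ring.
#'
#' @param g A [circ_seq].
#' @param divergence_percent Percent divergence in `[0, 30]`.
#' @param seed Integer seed.
#' @param annotations Feature table (needed for `region_divergence`).
#' @param region_divergence Named numeric vector of per-feature divergence
#'   overrides (percent).
#' @param id Identifier of the derived haplotype.
#' @return A [circ_seq] of the same length.
#' @export
mutate_haplotype <- function(g, divergence_percent, seed = 1L,
                             annotations = NULL, region_divergence = NULL,
                             id = paste0(g$id, "_hap")) {
  if (divergence_percent < 0 || divergence_percent > 30)
    stop("divergence_percent outside [0, 30]")
  L <- g$length
  with_seed(seed, {
    chars <- strsplit(g$seq, "")[[1]]
    sub_at <- function(positions, n) {
      n <- min(n, length(positions))
      for (p in sample(positions, n)) {
        chars[p] <<- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
    }
    if (is.null(region_divergence)) {
      sub_at(seq_len(L), round(L * divergence_percent / 100))
    } else {
      stopifnot(!is.null(annotations))
      taken <- rep(FALSE, L)
      for (nm in names(region_divergence)) {
        row <- annotations[annotations$name == nm, , drop = FALSE]
        pos <- ((row$start[1]:(row$end[1] - 1L)) %% L) + 1L
        taken[pos] <- TRUE
        sub_at(pos, round(length(pos) * region_divergence[[nm]] / 100))
      }
      rest <- which(!taken)
      sub_at(rest, round(length(rest) * divergence_percent / 100))
    }
    circ_seq(paste(chars, collapse = ""), id = id, circular = g$circular)
  })
}

#' Overwrite one codon of an annotated plus-strand gene
#'
#' Utility for planting candidate amino-acid-site residues at exact codon
#' positions.
#'
#' @param g A [circ_seq].
#' @param annotations Feature table carrying the gene.
#' @param gene Gene name.
#' @param codon_idx 1-based codon index.
#' @param codon_nt Replacement codon (3 nt).
#' @return The modified [circ_seq].
#' @export
plant_codon <- function(g, annotations, gene, codon_idx, codon_nt) {
  stopifnot(nchar(codon_nt) == 3L)
  row <- annotations[annotations$name == gene, , drop = FALSE]
  if (nrow(row) == 0L) stop("gene not annotated: ", gene)
  if (row$strand[1] != "+") stop("plant_codon supports plus-strand genes only")
  p0 <- row$start[1] + 3L * (codon_idx - 1L)
  if (p0 + 3L > row$end[1]) stop("codon index beyond gene end")
  seq <- g$seq
  substr(seq, p0 + 1L, p0 + 3L) <- toupper(codon_nt)
  circ_seq(seq, id = g$id, circular = g$circular)
}

# codon-level edits of a reference sORF (for species sequence variants)
edit_codons <- function(nt, edits) {
  for (idx in names(edits)) {
    i <- as.integer(idx)
    substr(nt, 3L * (i - 1L) + 1L, 3L * i) <- edits[[idx]]
  }
  nt
}

#' Simulation plans emulating the five-species hibernator study conditions
#'
#' Five synthetic species with the study's qualitative MDP signatures:
#' MOTS-c intact in all five as sequence variants sharing exactly one
#' conserved four-residue core; SHLP4 as a 12-residue dwarf in four species
#' and the long 26-residue form in one, all sharing the first twelve
#' residues; SHLP6 in its 9- and 20-residue size variants; humanin, SHLP1,
#' SHLP3 and SHLP5 pseudogenized throughout (mixed modes); gau intact
#' (ATA start) everywhere; and a single-base insertion at the forward
#' primer binding site in the two dormice.
#'
#' @param seed Base seed; species i uses `seed + i`.
#' @param genome_length Ring length per species (default 16,000 nt).
#' @param catalog MDP catalog supplying the reference sORFs.
#' @return Named list of five [sim_plan] objects.
#' @export
study_plans <- function(seed = 1L, genome_length = 16000L,
                        catalog = mdp_catalog()) {
  motsc <- catalog$loci[["MOTS-c"]]$ref_nt
  shlp4 <- catalog$loci[["SHLP4"]]$ref_nt
  shlp6 <- catalog$loci[["SHLP6"]]$ref_nt
  motsc_var <- list(
    garden_dormouse = motsc,
    alpine_marmot = edit_codons(motsc, list(`4` = "AAA")),            # Q4K
    hazel_dormouse = edit_codons(motsc, list(`9` = "GTC")),           # I9V
    european_ground_squirrel = edit_codons(motsc, list(`2` = "AAA",   # R2K
                                                       `11` = "CAC")),# Y11H
    arctic_ground_squirrel = edit_codons(motsc, list(`13` = "CAA"))   # R13Q
  )
  shlp4_dwarf <- edit_codons(shlp4, list(`13` = "TAA"))               # 12 aa
  shlp6_short <- edit_codons(shlp6, list(`10` = "TAA"))               # 9 aa
  species <- names(motsc_var)
  pseudo <- list(  # humanin, SHLP1, SHLP3, SHLP5 modes per species
    garden_dormouse = c("premature_stop", "absent_no_start", "frameshift",
                        "premature_stop"),
    alpine_marmot = c("absent_no_start", "frameshift", "premature_stop",
                      "absent_no_start"),
    hazel_dormouse = c("frameshift", "premature_stop", "absent_no_start",
                       "frameshift"),
    european_ground_squirrel = c("premature_stop", "absent_no_start",
                                 "frameshift", "premature_stop"),
    arctic_ground_squirrel = c("absent_no_start", "premature_stop",
                               "premature_stop", "absent_no_start")
  )
  primer_modes <- c(garden_dormouse = "insertion", alpine_marmot = "mismatch",
                    hazel_dormouse = "insertion",
                    european_ground_squirrel = "exact",
                    arctic_ground_squirrel = "exact")
  plans <- lapply(seq_along(species), function(i) {
    sp <- species[i]
    ps <- pseudo[[sp]]
    variant <- list("MOTS-c" = motsc_var[[sp]])
    if (sp != "garden_dormouse") variant$SHLP4 <- shlp4_dwarf
    if (sp %in% c("alpine_marmot", "european_ground_squirrel"))
      variant$SHLP6 <- shlp6_short
    sim_plan(seed = seed + i, genome_length = genome_length,
             primer_plan = list(mode = primer_modes[[sp]], k = 1L),
             mdp_plan = c(humanin = ps[1], SHLP1 = ps[2], SHLP3 = ps[3],
                          SHLP5 = ps[4]),
             variant_nt = variant,
             ncr_repeats = list(unit_len = 12L, copies = 4L),
             id = sp)
  })
  names(plans) <- species
  plans
}
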