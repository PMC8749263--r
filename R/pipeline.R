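# Stage orchestration: primer scanning, MDP prediction, all-pairs
# divergence and candidate-site screening over a set of genomes, with
# diff-able TSV reports (single commented header block carrying tool
# version, seed and a config hash).

write_stage_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mitoring %s",
                     as.character(utils::packageVersion("mitoring"))), con)
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  writeLines(json, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline over a set of genomes
#'
#' Executes primer scanning and amplicon prediction, MDP matrix
#' construction, all-pairs NCR-excluded divergence (with MT-CYB distance
#' and Genetic Species Concept flag when annotations carry the gene), and
#' optional candidate-site screening; writes one TSV per stage plus a JSON
#' summary into `out_dir`.
#'
#' @param genomes Named list of [circ_seq] objects, or a directory/file
#'   path of FASTA input.
#' @param annotations Optional named list of feature tables (names matching
#'   genome ids).
#' @param catalog MDP catalog.
#' @param primers Primer pair (`list(fwd=, rev=)`).
#' @param sites Optional [candidate_sites()] table.
#' @param site_refs Named list of reference gene sequences for the sites.
#' @param groups Optional `genome, group` assignment for [group_contrast()].
#' @param out_dir Output directory (created).
#' @param seed Seed recorded in every report header.
#' @param max_edits,three_prime_window,max_gap Scanner settings.
#' @return Invisibly, a list with the per-stage data frames and the summary.
#' @export
run_full <- function(genomes, annotations = NULL, catalog = mdp_catalog(),
                     primers = published_primers(), sites = NULL,
                     site_refs = NULL, groups = NULL, out_dir = "mitoring_out",
                     seed = 1L, max_edits = 2L, three_prime_window = 3L,
                     max_gap = 50L) {
  if (is.character(genomes)) {
    paths <- if (dir.exists(genomes))
      list.files(genomes, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    else genomes
    if (length(paths) == 0L) stop("no FASTA input found in ", genomes)
    genomes <- unlist(lapply(sort(paths), read_fasta), recursive = FALSE)
  }
  if (length(genomes) == 0L) stop("no input genomes")
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = seed,
               config = config_hash(list(
                 n_genomes = length(genomes), primers = primers,
                 max_edits = max_edits,
                 three_prime_window = three_prime_window,
                 max_gap = max_gap)))

  scan_rows <- NULL
  for (g in genomes) {
    sf <- scan_primer(g, list(name = "fwd", seq = primers$fwd), max_edits,
                      three_prime_window)
    sr <- scan_primer(g, list(name = "rev", seq = primers$rev), max_edits,
                      three_prime_window)
    amp <- pair_back_to_back(sf, sr, g$length, max_gap)
    amp1 <- amp[seq_len(min(1L, nrow(amp))), , drop = FALSE]
    both <- rbind(sf, sr)
    if (nrow(both) > 0) {
      both$genome_id <- g$id
      both$gap <- if (nrow(amp1) > 0) amp1$gap else NA_integer_
      both$product_length <- if (nrow(amp1) > 0) amp1$product_length
                             else NA_integer_
      scan_rows <- rbind(scan_rows, both)
    }
  }
  scan_cols <- c("genome_id", "primer", "strand", "start", "end",
                 "mismatches", "insertions", "deletions", "gap",
                 "product_length")
  scan_df <- if (is.null(scan_rows))
    setNames(data.frame(matrix(ncol = length(scan_cols), nrow = 0)), scan_cols)
  else scan_rows[scan_cols]
  write_stage_tsv(scan_df, file.path(out_dir, "scan_primers.tsv"), meta)

  mdp <- build_conservation_matrix(genomes, catalog)
  mat_df <- cbind(genome_id = rownames(mdp$matrix), mdp$matrix)
  write_stage_tsv(mat_df, file.path(out_dir, "mdp_matrix.tsv"), meta)
  jsonlite::write_json(mdp$matrix, file.path(out_dir, "mdp_matrix.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")

  div_df <- NULL
  ids <- names(genomes)
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      ann_i <- annotations[[ids[i]]]
      ann_j <- annotations[[ids[j]]]
      d <- p_distance(genomes[[ids[i]]], genomes[[ids[j]]], ann_i, ann_j)
      if (!is.null(ann_i) && !is.null(ann_j) &&
          "MT-CYB" %in% ann_i$name && "MT-CYB" %in% ann_j$name) {
        dc <- p_distance(genomes[[ids[i]]], genomes[[ids[j]]], ann_i, ann_j,
                         gene = "MT-CYB")
        d$mtcyb_divergence <- dc$divergence
        d$species_flag <- species_flag(dc$divergence)
      } else {
        d$mtcyb_divergence <- NA_real_
        d$species_flag <- NA
      }
      div_df <- rbind(div_df, d)
    }
    write_stage_tsv(div_df, file.path(out_dir, "divergence.tsv"), meta)
  }

  sites_df <- NULL
  contrast_df <- NULL
  if (!is.null(sites)) {
    for (g in genomes) for (k in seq_len(nrow(sites))) {
      site <- sites[k, ]
      ref <- site_refs[[site$gene]]
      if (is.null(ref)) next
      sites_df <- rbind(sites_df, call_candidate_site(g, site, ref))
    }
    if (!is.null(sites_df)) {
      write_stage_tsv(sites_df, file.path(out_dir, "screen_sites.tsv"), meta)
      if (!is.null(groups)) {
        contrast_df <- group_contrast(sites_df, groups)
        write_stage_tsv(contrast_df, file.path(out_dir, "group_contrast.tsv"),
                        meta)
      }
    }
  }

  summary <- list(version = as.character(utils::packageVersion("mitoring")),
                  seed = seed, config = meta$config,
                  n_genomes = length(genomes),
                  n_primer_sites = nrow(scan_df),
                  n_divergence_pairs = if (is.null(div_df)) 0L else nrow(div_df),
                  n_site_calls = if (is.null(sites_df)) 0L else nrow(sites_df))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scan = scan_df, mdp = mdp, divergence = div_df,
                 sites = sites_df, contrast = contrast_df, summary = summary))
}
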