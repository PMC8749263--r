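catalog <- mdp_catalog()

test_that("generation is a pure function of the plan", {
  plan <- sim_plan(seed = 101, primer_plan = list(mode = "mismatch", k = 2),
                   ncr_repeats = list(unit_len = 10, copies = 3))
  a <- generate_mitogenome(plan, catalog)
  b <- generate_mitogenome(plan, catalog)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$loci, b$truth$loci)
  expect_identical(a$annotations, b$annotations)
})

test_that("drawn genome lengths stay inside the vertebrate bound", {
  lens <- vapply(1:40, function(s)
    generate_mitogenome(sim_plan(seed = s), catalog)$genome$length,
    integer(1))
  expect_true(all(lens >= 14000 & lens <= 20000))
  expect_gt(length(unique(lens)), 10)
  expect_error(sim_plan(genome_length = 12000), "bound")
})

test_that("annotations tile the ring in canonical order", {
  sim <- generate_mitogenome(sim_plan(seed = 102, genome_length = 16000),
                             catalog)
  ann <- sim$annotations
  expect_equal(ann$name[1], "trnF")
  expect_equal(ann$name[nrow(ann)], "NCR")
  expect_equal(ann$start[1], 0)
  expect_equal(ann$end[nrow(ann)], sim$genome$length)
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  expect_equal(sum(ann$name == "NCR"), 1)
})

test_that("the primer plan is realized in the planted motif", {
  p <- published_primers()
  for (mode in c("exact", "mismatch", "insertion")) {
    sim <- generate_mitogenome(sim_plan(seed = 103, genome_length = 16000,
                                        primer_plan = list(mode = mode, k = 1)),
                               catalog)
    sf <- scan_primer(sim$genome, list(name = "fwd", seq = p$fwd))
    truth <- sim$truth$primers
    expect_equal(sf$mismatches[1], truth$mismatches[truth$primer == "fwd"])
    expect_equal(sf$insertions[1], truth$insertions[truth$primer == "fwd"])
    amp <- predict_amplicon(sim$genome)
    expect_equal(amp$product_length + amp$gap, sim$genome$length)
  }
})

test_that("NCR tandem repeats are planted inside the control region", {
  plan <- sim_plan(seed = 104, genome_length = 16000,
                   ncr_repeats = list(unit_len = 15, copies = 4))
  sim <- generate_mitogenome(plan, catalog)
  ncr <- sim$annotations[sim$annotations$name == "NCR", ]
  ncr_seq <- circular_slice(sim$genome, ncr$start %% sim$genome$length,
                            ncr$end %% sim$genome$length)
  # a 15-mer repeated four times in tandem must occur within the NCR
  found <- FALSE
  for (i in seq_len(nchar(ncr_seq) - 60)) {
    u <- substr(ncr_seq, i, i + 14)
    if (substr(ncr_seq, i, i + 59) == strrep(u, 4)) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("haplotype mutation plants exact substitution counts", {
  g <- random_ring(16000, 105)
  expect_identical(mutate_haplotype(g, 0, seed = 1)$seq, g$seq)
  h <- mutate_haplotype(g, 9.9, seed = 2)
  diffs <- sum(strsplit(g$seq, "")[[1]] != strsplit(h$seq, "")[[1]])
  expect_equal(diffs, round(16000 * 0.099))  # 1584
  expect_equal(nchar(h$seq), 16000)
  expect_error(mutate_haplotype(g, 35, seed = 3), "outside")
})

test_that("planted divergence is recovered by p-distance on small rings", {
  g <- random_ring(4000, 106)
  for (d in c(1, 5, 10)) {
    h <- mutate_haplotype(g, d, seed = d)
    got <- p_distance(g, h, exclude = NULL)$divergence
    expect_lt(abs(got - d), 0.2)
  }
})

test_that("pseudogenization modes have the documented structure", {
  nt <- catalog$loci[["humanin"]]$ref_nt
  no_start <- plant_pseudogenization(nt, "absent_no_start", seed = 1)
  expect_false(substr(no_start, 1, 3) %in%
                 c("ATG", "ATA", "ATT", "ATC", "GTG"))
  expect_equal(substr(no_start, 4, nchar(nt)), substr(nt, 4, nchar(nt)))

  ps <- plant_pseudogenization(nt, "premature_stop", seed = 2)
  aa <- translate_nt(ps, genetic_code("standard"))
  stop_at <- regexpr("*", aa, fixed = TRUE)[1]
  expect_lt(stop_at, 8 + 1)               # stop before the 8-aa minimum
  expect_lt(stop_at, nchar(nt) / 6)       # and before half-length

  fs <- plant_pseudogenization(nt, "frameshift", seed = 3)
  expect_true(abs(nchar(fs) - nchar(nt)) == 1)
  expect_error(plant_pseudogenization("ATGTAA", "premature_stop", seed = 4),
               "too short")
})

test_that("the five-species study plans carry the published signatures", {
  plans <- study_plans(seed = 200)
  expect_length(plans, 5)
  sims <- lapply(plans, generate_mitogenome, catalog = catalog)
  m <- build_conservation_matrix(lapply(sims, `[[`, "genome"), catalog)
  mat <- m$matrix
  # humanin, SHLP1, SHLP3, SHLP5: no intact sORF in any species
  for (locus in c("humanin", "SHLP1", "SHLP3", "SHLP5")) {
    expect_false(any(grepl("intact", mat[[locus]])), info = locus)
  }
  # MOTS-c intact everywhere; SHLP4 12 aa in four species and 26 in one
  expect_true(all(mat[["MOTS-c"]] == "intact(16)"))
  expect_equal(sum(mat[["SHLP4"]] == "intact(12)"), 4)
  expect_equal(sum(mat[["SHLP4"]] == "intact(26)"), 1)
  expect_setequal(unique(mat[["SHLP6"]]), c("intact(9)", "intact(20)"))
})
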