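plant_site <- function(g, seq_ins, pos) {
  # overwrite (not insert) at 0-based pos
  s <- g$seq
  substr(s, pos + 1, pos + nchar(seq_ins)) <- seq_ins
  circ_seq(s, id = g$id)
}

test_that("an exact planted site is found with a clean edit profile", {
  p <- published_primers()
  g <- plant_site(random_ring(2000, 1), p$fwd, 100)
  sites <- scan_primer(g, list(name = "fwd", seq = p$fwd))
  hit <- sites[sites$start == 100, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$strand, "+")
  expect_equal(hit$end, 100 + nchar(p$fwd))
  expect_equal(c(hit$mismatches, hit$insertions, hit$deletions), c(0, 0, 0))
})

test_that("a single extra template base in the footprint reports insertions=1", {
  p <- published_primers()
  g0 <- random_ring(2000, 2)
  with_ins <- paste0(substr(p$fwd, 1, 10), "A", substr(p$fwd, 11, 22))
  g <- plant_site(g0, with_ins, 500)
  sites <- scan_primer(g, list(name = "fwd", seq = p$fwd))
  hit <- sites[sites$start == 500, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$insertions, 1)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$end - hit$start, nchar(p$fwd) + 1)  # span = len + ins
})

test_that("scanner agrees with the exhaustive per-offset oracle", {
  p <- published_primers()
  modes <- c("exact", "mismatch", "insertion")
  for (seed in 1:12) {
    g0 <- random_ring(2000, seed)
    mode <- modes[(seed %% 3) + 1]
    set.seed(seed * 7)
    pos <- sample(0:1900, 1)
    planted <- switch(mode,
      exact = p$rev,
      mismatch = {
        ch <- strsplit(p$rev, "")[[1]]
        ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
        paste(ch, collapse = "")
      },
      insertion = paste0(substr(p$rev, 1, 12), "G", substr(p$rev, 13, 25)))
    g <- plant_site(g0, planted, pos)
    mine <- scan_primer(g, list(name = "rev", seq = p$rev))
    orc <- oracle_scan(g, p$rev)
    expect_equal(nrow(mine), nrow(orc), info = paste("seed", seed))
    expect_equal(mine$strand, orc$strand)
    expect_equal(mine$start, orc$start)
    expect_equal(mine$edits, orc$edits)
  }
})

test_that("sites wrapping the origin are found", {
  p <- published_primers()
  mot <- primer_motif()
  g <- circ_seq(paste0(substr(mot, 25, 47),
                       random_ring(1500, 5)$seq,
                       substr(mot, 1, 24)), id = "wrap")
  sf <- scan_primer(g, list(name = "fwd", seq = p$fwd))
  sr <- scan_primer(g, list(name = "rev", seq = p$rev))
  expect_equal(sf$start[1], 1)
  expect_equal(sr$strand[1], "-")
  expect_gt(sr$end[1], g$length)  # wrapping span
  amp <- pair_back_to_back(sf, sr, g$length)
  expect_equal(amp$gap[1], 0)
  expect_equal(amp$product_length[1], g$length)
})

test_that("binding positions are rotation-equivariant with unchanged edits", {
  p <- published_primers()
  g <- plant_site(random_ring(2000, 6), primer_motif(), 700)
  s1 <- scan_primer(g, list(name = "fwd", seq = p$fwd))
  k <- 1234
  g2 <- circ_seq(rotate_string(g$seq, k), id = "rot")
  s2 <- scan_primer(g2, list(name = "fwd", seq = p$fwd))
  expect_equal((s1$start - k) %% g$length, s2$start)
  expect_equal(s1$edits, s2$edits)
})

test_that("3'-terminal mismatches abolish a site", {
  p <- published_primers()
  ch <- strsplit(p$fwd, "")[[1]]
  ch[22] <- setdiff(c("A", "C", "G", "T"), ch[22])[1]
  g <- plant_site(random_ring(2000, 7), paste(ch, collapse = ""), 300)
  sites <- scan_primer(g, list(name = "fwd", seq = p$fwd),
                       max_edits = 0, three_prime_window = 3)
  expect_false(300 %in% sites$start)
})

test_that("a primer longer than the genome is an error", {
  g <- circ_seq("ACGTACGTAC")
  expect_error(scan_primer(g, list(name = "x", seq = strrep("ACGT", 5))),
               "longer than genome")
})

test_that("back-to-back pairing enforces the amplicon geometry", {
  site <- function(strand, start, end, edits = 0) {
    data.frame(primer = "p", strand = strand, start = start, end = end,
               mismatches = edits, insertions = 0, deletions = 0,
               edits = edits, three_prime_exact = TRUE)
  }
  L <- 16000
  # adjacent opposite-strand sites: gap 0, product the full circle
  amp <- pair_back_to_back(site("+", 1000, 1022), site("-", 975, 1000), L)
  expect_equal(amp$gap, 0)
  expect_equal(amp$product_length, L)
  # gap 5 on a 1 kb ring
  amp2 <- pair_back_to_back(site("+", 105, 127), site("-", 75, 100), 1000,
                            max_gap = 50)
  expect_equal(amp2$gap, 5)
  expect_equal(amp2$product_length, 995)
  # same-strand pair rejected
  expect_equal(nrow(pair_back_to_back(site("+", 1000, 1022),
                                      site("+", 975, 1000), L)), 0)
  # inward-facing pair (reverse site downstream) rejected by the gap bound
  expect_equal(nrow(pair_back_to_back(site("+", 1000, 1022),
                                      site("-", 8000, 8025), L)), 0)
})

test_that("identical alignment rows make every window fully conserved", {
  rows <- rep(paste(rep("ACGT", 25), collapse = ""), 3)
  w <- find_conserved_motifs(rows, window_len = 10, top_k = 2)
  expect_equal(w$score, c(1, 1))
  expect_equal(w$c0[1], 0)   # leftmost first
  expect_error(find_conserved_motifs(rows, window_len = 1000), "longer")
})

test_that("a planted invariant block is the top conserved window", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  block <- primer_motif()
  rows <- vapply(1:6, function(i) {
    ch <- strsplit(base, "")[[1]]
    for (pp in sample(400, 80)) ch[pp] <- sample(c("A", "C", "G", "T"), 1)
    s <- paste(ch, collapse = "")
    paste0(substr(s, 1, 200), block, substr(s, 201, 400))
  }, character(1))
  w <- find_conserved_motifs(rows, window_len = 47, top_k = 1)
  expect_equal(w$score, 1)
  # flank columns untouched in all rows can extend the fully conserved
  # stretch by a few columns; the window must still sit on the block
  expect_lte(abs(w$c0 - 200), 5)
})

test_that("splitting the published window reproduces the printed oligos", {
  p <- published_primers()
  window <- paste0(reverse_complement(p$rev), p$fwd)
  des <- design_back_to_back(window, fwd_len = 22, rev_len = 25)
  expect_identical(des$fwd, "TACGTGATCTGAGTTCAGACCG")
  expect_identical(des$rev, "GTAGGACTTTAATCGTTGAACAAAC")
  expect_error(design_back_to_back("ACGTACGT", 22, 25), "too short")
})

test_that("designed primers amplify the window's host genome with gap 0", {
  for (seed in c(21, 22)) {
    g <- random_ring(2000, seed)
    window <- circular_slice(g, 600, 650)
    des <- design_back_to_back(window, fwd_len = 20, rev_len = 22)
    amp <- predict_amplicon(g, primers = des)
    expect_equal(amp$gap, 0)
    expect_equal(amp$product_length, g$length)
  }
})
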