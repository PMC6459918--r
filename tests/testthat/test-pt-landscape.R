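test_that("motif scanning reports every plus-strand occurrence", {
  expect_equal(nrow(scan_gatc_loci(c(x = "AAAAAAAA"))), 0)
  loci <- scan_gatc_loci(c(x = "GATCGATC"))
  expect_equal(loci$start, c(0L, 4L))
  # loci overlapping an N are excluded
  expect_equal(nrow(scan_gatc_loci(c(x = "GANCGATC"))), 1)
  expect_error(scan_gatc_loci(c(x = "ACGT"), motif = "GAAC"),
               "palindromic")
  # overlapping occurrences of a palindromic motif each reported
  loci2 <- scan_gatc_loci(c(x = "ATATAT"), motif = "ATAT")
  expect_equal(loci2$start, c(0L, 2L))
})

test_that("duplex-state classification pairs calls by integer arithmetic", {
  genome <- c(chr = "TTGATCTTTTGATCTTGATCTT")
  loci <- scan_gatc_loci(genome)
  expect_equal(loci$start, c(2L, 10L, 16L))

  none <- classify_duplex_states(loci, data.frame(contig = character(0),
                                                  pos = integer(0),
                                                  strand = character(0)))
  expect_true(all(none$state == "none"))

  calls <- data.frame(contig = "chr", pos = c(2L, 5L, 10L),
                      strand = c("+", "-", "+"))
  cl <- classify_duplex_states(loci, calls)
  expect_equal(cl$state, c("full", "hemi_plus", "none"))

  dup <- rbind(calls, calls[1, ])
  expect_error(classify_duplex_states(loci, dup), "duplicate")

  orphan <- data.frame(contig = "chr", pos = 0L, strand = "+")
  expect_warning(res <- classify_duplex_states(loci, orphan), "no scanned")
  expect_equal(nrow(attr(res, "orphans")), 1)
})

test_that("summary statistics equal an independent brute-force recount", {
  for (seed in 1:10) {
    fx <- make_pt_fixture(seed, n_motifs = sample(20:60, 1),
                          n_full = sample(3:8, 1),
                          n_hemi_plus = sample(0:5, 1),
                          n_hemi_minus = sample(0:5, 1))
    loci <- classify_duplex_states(scan_gatc_loci(fx$genome), fx$calls)
    s <- summarize_pt(loci, fx$genome)

    # recount directly from the call table and an oracle motif scan
    starts <- count_motif_oracle(fx$genome[[1]])
    plus <- fx$calls$pos[fx$calls$strand == "+"]
    minus <- fx$calls$pos[fx$calls$strand == "-"] - 3L
    n_full <- length(intersect(plus, minus))
    n_mod <- length(union(plus, minus))
    expect_equal(s$n_motifs, length(starts))
    expect_equal(s$n_full, n_full)
    expect_equal(s$n_modified_loci, n_mod)
    expect_equal(s$pct_modified, round(100 * n_mod / length(starts), 1))
    expect_equal(s$pct_hemi, round(100 * (n_mod - n_full) / n_mod))
    expect_equal(s$n_plus_calls, length(plus))
    # conservation: states partition the motif set
    expect_equal(sum(table(loci$state)), s$n_motifs)
  }
})

test_that("classification recovers the planted composition and strand swap
           symmetry holds", {
  for (seed in 1:25) {
    fx <- make_pt_fixture(100 + seed, n_motifs = 50,
                          n_full = sample(0:10, 1),
                          n_hemi_plus = sample(0:10, 1),
                          n_hemi_minus = sample(0:10, 1))
    loci <- classify_duplex_states(scan_gatc_loci(fx$genome), fx$calls)
    got <- merge(loci, fx$truth, by = "start")
    expect_true(all(got$state.x == got$state.y))

    # swapping all strand labels swaps hemi_plus and hemi_minus
    swapped <- fx$calls
    swapped$strand <- ifelse(swapped$strand == "+", "-", "+")
    swapped$pos <- ifelse(fx$calls$strand == "+", fx$calls$pos + 3L,
                          fx$calls$pos - 3L)
    loci2 <- classify_duplex_states(scan_gatc_loci(fx$genome), swapped)
    t1 <- table(factor(loci$state,
                       levels = c("none", "hemi_plus", "hemi_minus", "full")))
    t2 <- table(factor(loci2$state,
                       levels = c("none", "hemi_plus", "hemi_minus", "full")))
    expect_equal(unname(t1[["full"]]), unname(t2[["full"]]))
    expect_equal(unname(t1[["none"]]), unname(t2[["none"]]))
    expect_equal(unname(t1[["hemi_plus"]]), unname(t2[["hemi_minus"]]))
    expect_equal(unname(t1[["hemi_minus"]]), unname(t2[["hemi_plus"]]))
  }
})

test_that("spacing statistics follow the declared strand modes", {
  genome <- c(chr = paste(c("AA", "GATC", strrep("T", 3996), "GATC",
                            strrep("A", 100)), collapse = ""))
  loci <- scan_gatc_loci(genome)
  calls <- data.frame(contig = "chr", pos = loci$start, strand = "+")
  cl <- classify_duplex_states(loci, calls)
  sp <- spacing_stats(cl)
  expect_equal(sp$distances, 4000)

  one <- classify_duplex_states(loci, calls[1, , drop = FALSE])
  expect_error(spacing_stats(one), "at least 2")

  # interleaved strands differ between per_strand and combined modes
  fx <- make_pt_fixture(55, n_motifs = 40, n_full = 0, n_hemi_plus = 8,
                        n_hemi_minus = 8)
  cl2 <- classify_duplex_states(scan_gatc_loci(fx$genome), fx$calls)
  per <- spacing_stats(cl2, "per_strand")
  comb <- spacing_stats(cl2, "combined")
  expect_equal(length(comb$distances), 15)
  expect_equal(length(per$distances), 14)
  expect_lte(comb$spacing_min, per$spacing_min)
})

test_that("context bias recovers planted flank preferences", {
  # eight loci, flank bases set by hand: modified loci all preceded by T,
  # background spread evenly over A/C/G/T
  pre <- c("T", "T", "A", "A", "C", "C", "G", "G")
  post <- rep("A", 8)
  blocks <- vapply(seq_along(pre),
                   function(i) paste0(pre[i], "GATC", post[i], "TTTT"),
                   character(1))
  genome <- c(chr = paste0("TTT", paste(blocks, collapse = "")))
  loci <- scan_gatc_loci(genome)
  expect_equal(nrow(loci), 8)
  calls <- data.frame(contig = "chr", pos = loci$start[1:2], strand = "+")
  cl <- classify_duplex_states(loci, calls)
  cb <- context_bias(cl, genome)
  tm1 <- cb[cb$offset == -1 & cb$base == "T", ]
  expect_equal(tm1$obs_freq, 1.0)
  expect_equal(tm1$bg_freq, 0.25)
  expect_equal(tm1$log2_enrichment, 2)

  # modified = all loci gives zero enrichment everywhere it is defined
  all_mod <- classify_duplex_states(
    loci, data.frame(contig = "chr", pos = loci$start, strand = "+"))
  cb2 <- context_bias(all_mod, genome)
  expect_true(all(cb2$log2_enrichment[!is.na(cb2$log2_enrichment)] == 0))

  none <- classify_duplex_states(loci, data.frame(contig = character(0),
                                                  pos = integer(0),
                                                  strand = character(0)))
  expect_error(context_bias(none, genome), "zero modified")
})
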