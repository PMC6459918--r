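test_that("generators are deterministic in the configuration", {
  cfg <- sim_config(seed = 9, genome_len = 20000, n_motifs = 50L,
                    n_full = 10L, n_hemi_plus = 5L, n_hemi_minus = 5L,
                    n_strains = 10L)
  a <- gen_genome_with_motifs(cfg); b <- gen_genome_with_motifs(cfg)
  expect_identical(a, b)
  expect_identical(gen_pt_calls(a$positions, cfg),
                   gen_pt_calls(b$positions, cfg))
  expect_identical(gen_defence_annotations(cfg),
                   gen_defence_annotations(cfg))
  rm <- gen_protein(60, 1); rr <- gen_protein(50, 2)
  expect_identical(gen_protein_family_pairs(rm, rr, cfg),
                   gen_protein_family_pairs(rm, rr, cfg))
})

test_that("planted motif counts are exact under a sliding-window scan", {
  cfg0 <- sim_config(seed = 2, genome_len = 3000, n_motifs = 0L,
                     n_full = 0L, n_hemi_plus = 0L, n_hemi_minus = 0L)
  g0 <- gen_genome_with_motifs(cfg0)
  expect_length(count_motif_oracle(g0$genome[[1]]), 0)

  cfg <- sim_config(seed = 4, genome_len = 1e5, n_motifs = 100L,
                    n_full = 0L, n_hemi_plus = 0L, n_hemi_minus = 0L)
  g <- gen_genome_with_motifs(cfg)
  found <- count_motif_oracle(g$genome[[1]])
  expect_length(found, 100)
  expect_equal(found, g$positions)
  expect_true(all(diff(g$positions) >= 4))

  bad <- sim_config(seed = 1, genome_len = 700, n_motifs = 100L,
                    n_full = 0L, n_hemi_plus = 0L, n_hemi_minus = 0L)
  expect_error(gen_genome_with_motifs(bad), "infeasible")
})

test_that("PT call generation matches the requested duplex composition", {
  fx <- make_pt_fixture(5, n_motifs = 30, n_full = 1, n_hemi_plus = 0,
                        n_hemi_minus = 0)
  expect_equal(nrow(fx$calls), 2)     # one locus, both strands
  expect_equal(diff(sort(fx$calls$pos)), 3L)

  fx2 <- make_pt_fixture(6, n_motifs = 200, n_full = 60, n_hemi_plus = 25,
                         n_hemi_minus = 15, genome_len = 20000)
  expect_equal(nrow(fx2$calls), 2 * 60 + 40)
  expect_equal(sum(fx2$truth$state == "full"), 60)

  cfg <- sim_config(seed = 1, genome_len = 5000, n_motifs = 10L,
                    n_full = 5L, n_hemi_plus = 5L, n_hemi_minus = 0L)
  g <- gen_genome_with_motifs(cfg)
  cfg_over <- cfg; cfg_over$n_full <- 20L
  expect_error(gen_pt_calls(g$positions, cfg_over), "exceed")
})

test_that("generated feature tables are pairwise disjoint", {
  genome <- gen_genome_with_motifs(
    sim_config(seed = 3, genome_len = 50000, n_motifs = 10L, n_full = 0L,
               n_hemi_plus = 0L, n_hemi_minus = 0L))$genome
  feats <- gen_feature_table(genome, n_cds = 20, n_rrna = 3, n_pseudo = 5,
                             seed = 8)
  expect_equal(nrow(feats), 28)
  expect_equal(sum(feats$kind == "CDS"), 20)
  o <- order(feats$start)
  expect_true(all(feats$end[o][-28] <= feats$start[o][-1]))

  expect_error(gen_feature_table(genome, n_cds = 1000, n_rrna = 0,
                                 n_pseudo = 0, seed = 1), "infeasible")
})

test_that("defence-annotation planting respects window boundaries", {
  cfg <- sim_config(seed = 2,
                    category_counts = c(pbe_dnd_only = 3L, pbe_both = 2L),
                    gap_range = c(100, 5000))
  ann <- gen_defence_annotations(cfg)
  truth <- attr(ann, "truth")
  expect_equal(nrow(truth), 5)
  expect_equal(length(unique(ann$genome_id)), 5)

  over <- sim_config(seed = 2, category_counts = c(pbe_dnd_only = 1L),
                     gap_range = c(100, 10001))
  expect_error(gen_defence_annotations(over), "window")
  # non-strict mode allows it
  expect_silent(gen_defence_annotations(over, strict = FALSE))

  # the full category-count vector emits one genome per planted instance
  big <- sim_config(seed = 3,
                    category_counts = c(pbe_dnd_only = 12L,
                                        pbe_mtase_only = 15L,
                                        pbe_both = 10L, pbe_solitary = 16L),
                    gap_range = c(1, 9000))
  tb <- attr(gen_defence_annotations(big), "truth")
  expect_equal(as.vector(table(tb$category)[c("pbe_dnd_only",
                                              "pbe_mtase_only", "pbe_both",
                                              "pbe_solitary")]),
               c(12L, 15L, 10L, 16L))
})

test_that("protein-family pairs hit the requested divergence structure", {
  rm <- gen_protein(120, 21); rr <- gen_protein(100, 22)

  como <- gen_protein_family_pairs(rm, rr, sim_config(
    seed = 5, divergence_corr = 1, n_strains = 20L))
  expect_equal(spearman_oracle(como$true_d_mod, como$true_d_res), 1)

  mid <- gen_protein_family_pairs(rm, rr, sim_config(
    seed = 6, divergence_corr = 0.6, n_strains = 200L))
  expect_lt(abs(spearman_oracle(mid$true_d_mod, mid$true_d_res) - 0.6), 0.1)

  # a zero substitution fraction leaves the sequence identical
  chars <- strsplit(rm, "")[[1]]
  d <- round(0.004 * nchar(rm))  # rounds to zero substitutions
  expect_equal(d, 0)
  tiny <- gen_protein_family_pairs(rm, rr, sim_config(
    seed = 7, divergence_corr = 0, n_strains = 5L,
    sub_rate_range = c(0.001, 0.004)))
  expect_true(all(tiny$mod_seq == rm))
})

test_that("homology-hit decoys violate exactly one filter rule", {
  ann <- gen_defence_annotations(sim_config(
    seed = 4, category_counts = c(dnd_with_dndFGH = 5L),
    gap_range = c(1, 9000)))
  hits <- gen_homology_hits(ann, n_true = 5, n_decoy = 5, seed = 9)
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$is_true))
  decoys <- hits[!hits$is_true, ]
  viol_e <- decoys$evalue > 1e-10
  viol_l <- decoys$length / decoys$query_len < 0.30
  expect_true(all(xor(viol_e, viol_l)))
})
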