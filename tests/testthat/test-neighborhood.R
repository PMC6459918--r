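mk_hit <- function(evalue, length, query_len = 100) {
  data.frame(qseqid = "q", sseqid = "s", pident = 90, length = length,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = length,
             sstart = 1L, send = length, evalue = evalue, bitscore = 100,
             query_len = query_len, stringsAsFactors = FALSE)
}

mk_ann <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(genome_id = r[[1]], symbol = r[[2]], contig = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               strand = "+", stringsAsFactors = FALSE)))
}

test_that("hit filtering applies both thresholds inclusively", {
  expect_equal(nrow(filter_hits(mk_hit(1e-10, 50))), 1)   # e boundary kept
  expect_equal(nrow(filter_hits(mk_hit(1.1e-10, 50))), 0)
  expect_equal(nrow(filter_hits(mk_hit(1e-50, 30))), 1)   # 30% boundary kept
  expect_equal(nrow(filter_hits(mk_hit(1e-50, 29))), 0)
  # the documented alternative reading drops the exact 30% boundary
  expect_equal(nrow(filter_hits(mk_hit(1e-50, 30), len_boundary = "gt")), 0)

  ann <- gen_defence_annotations(sim_config(
    seed = 12, category_counts = c(dnd_with_dndFGH = 10L),
    gap_range = c(1, 9000)))
  hits <- gen_homology_hits(ann, n_true = 50, n_decoy = 50, seed = 13)
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 50)
  expect_true(all(kept$is_true))
})

test_that("gene_gap matches an exhaustive edge-distance oracle", {
  expect_equal(gene_gap(0, 10, 10, 20), 0)   # abutting
  expect_equal(gene_gap(0, 10, 15, 20), 5)
  expect_equal(gene_gap(15, 20, 0, 10), 5)   # symmetric
  expect_equal(gene_gap(0, 10, 5, 20), 0)    # overlapping
  expect_true(is.na(gene_gap(0, 10, 15, 20, "c1", "c2")))
  set.seed(31)
  for (k in 1:50) {
    s1 <- sample(0:40, 1); e1 <- s1 + sample(1:10, 1)
    s2 <- sample(0:40, 1); e2 <- s2 + sample(1:10, 1)
    expect_equal(gene_gap(s1, e1, s2, e2), gene_gap_oracle(s1, e1, s2, e2))
  }
})

test_that("dndC/dndD pairing honours the gap limit and nearest-tie rule", {
  a <- mk_ann(list("g1", "dndC", "c1", 1000, 2200),
              list("g1", "dndD", "c1", 2300, 4300))
  loci <- locate_dndCD_pairs(a)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$pair_gap, 100)
  expect_equal(loci$start, 1000L); expect_equal(loci$end, 4300L)

  far <- mk_ann(list("g1", "dndC", "c1", 1000, 2200),
                list("g1", "dndD", "c1", 7201, 9200))  # gap 5001
  none <- locate_dndCD_pairs(far)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(attr(none, "unpaired")), 2)

  # two candidates at the same gap: the smaller start wins
  tie <- mk_ann(list("g1", "dndC", "c1", 5000, 6000),
                list("g1", "dndD", "c1", 2900, 4900),   # gap 100, left
                list("g1", "dndD", "c1", 6100, 8100))   # gap 100, right
  lt <- locate_dndCD_pairs(tie)
  expect_equal(nrow(lt), 1)
  expect_equal(lt$start, 2900L)
})

test_that("dnd-system classification follows the flanking-window rules", {
  base <- mk_ann(list("g1", "dndC", "c1", 10000, 11200),
                 list("g1", "dndD", "c1", 11300, 13300))
  fgh <- mk_ann(list("g1", "dndF", "c1", 14300, 16300),
                list("g1", "dndG", "c1", 16400, 17400),
                list("g1", "dndH", "c1", 17500, 19000))
  loci <- locate_dndCD_pairs(base)

  cls <- classify_dnd_system(loci, rbind(base, fgh))
  expect_equal(cls$category, "dndFGH")

  # all three restriction genes are required
  partial <- rbind(base, fgh[1:2, ])
  expect_equal(classify_dnd_system(loci, partial)$category, "none")

  both <- rbind(base, fgh,
                mk_ann(list("g1", "pbeA", "c1", 2000, 4400),
                       list("g1", "pbeC", "c1", 4500, 6000)))
  expect_equal(classify_dnd_system(loci, both)$category, "both")

  # window monotonicity: a larger window never loses a flag
  narrow <- classify_dnd_system(loci, both, fgh_window = 500)
  wide <- classify_dnd_system(loci, both, fgh_window = 20000)
  expect_true(all(wide$has_dndFGH >= narrow$has_dndFGH))
  expect_true(all(wide$has_pbeAC >= narrow$has_pbeAC))
})

test_that("pbe neighbourhood categories partition the input", {
  pbe <- mk_ann(list("g1", "pbeA", "c1", 20000, 22400),
                list("g1", "pbeC", "c1", 22500, 24000))
  dnd <- mk_ann(list("g1", "dndC", "c1", 24500, 25700),
                list("g1", "dndD", "c1", 25800, 27800))
  loci <- locate_pbeAC_pairs(pbe)
  expect_equal(nrow(loci), 1)

  expect_equal(classify_pbe_neighborhood(loci, rbind(pbe, dnd))$category,
               "dnd_only")
  expect_equal(classify_pbe_neighborhood(loci, pbe)$category, "solitary")
  withmt <- rbind(pbe, mk_ann(list("g1", "mtase", "c1", 25000, 26000)))
  expect_equal(classify_pbe_neighborhood(loci, withmt)$category,
               "mtase_only")
  expect_setequal(
    unique(c("dnd_only", "mtase_only", "both", "solitary")),
    c("dnd_only", "mtase_only", "both", "solitary"))
})

test_that("classifier output matches planted categories across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    lo <- sample(1:2000, 1)
    cc <- c(pbe_dnd_only = 2L, pbe_mtase_only = 2L, pbe_both = 2L,
            pbe_solitary = 2L, dnd_with_dndFGH = 2L, dnd_alone = 2L,
            dnd_with_pbe = 2L, dnd_with_both = 2L)
    cfg <- sim_config(seed = 1000 + seed, category_counts = cc,
                      gap_range = c(lo, lo + sample(500:4000, 1)))
    ann <- gen_defence_annotations(cfg)
    truth <- attr(ann, "truth")

    pc <- classify_pbe_neighborhood(locate_pbeAC_pairs(ann), ann)
    tp <- truth[startsWith(truth$category, "pbe_"), ]
    m <- merge(pc, tp, by = "genome_id")
    expect_equal(nrow(m), 8)
    expect_true(all(m$category.x == PBE_TRUTH_MAP[m$category.y]))

    dc <- classify_dnd_system(locate_dndCD_pairs(ann), ann)
    td <- truth[startsWith(truth$category, "dnd_"), ]
    md <- merge(dc, td, by = "genome_id")
    expect_equal(nrow(md), 8)
    expect_true(all(md$category.x == DND_TRUTH_MAP[md$category.y]))

    # partition property
    cs <- cooccurrence_summary(dc)
    expect_equal(sum(cs$count), nrow(dc))
  }
})

test_that("co-occurrence summary reports counts and one-decimal percents", {
  x <- data.frame(category = rep("pbe", 7))
  s <- cooccurrence_summary(x)
  expect_equal(s$percent, 100.0)
  expect_error(cooccurrence_summary(x[0, , drop = FALSE]), "no classifications")

  y <- data.frame(category = rep(c("a", "b"), c(1132, 2322 - 1132)))
  s2 <- cooccurrence_summary(y)
  expect_equal(s2$percent[s2$category == "a"], 48.8)
})

test_that("best kept hit per genome and query becomes one annotation", {
  ann <- gen_defence_annotations(sim_config(
    seed = 21, category_counts = c(dnd_with_dndFGH = 4L),
    gap_range = c(1, 9000)))
  hits <- gen_homology_hits(ann, n_true = 40, n_decoy = 10, seed = 22)
  kept <- filter_hits(hits)
  out <- hits_to_annotations(kept)
  expect_true(all(!duplicated(paste(out$genome_id, out$symbol))))
  expect_true(all(out$symbol %in% ann$symbol))
  # annotations point back at planted gene coordinates
  key_out <- paste(out$genome_id, out$symbol, out$start, out$end)
  key_ann <- paste(ann$genome_id, ann$symbol, ann$start, ann$end)
  expect_true(all(key_out %in% key_ann))
})
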