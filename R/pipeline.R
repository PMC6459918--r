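## End-to-end orchestration: simulate -> ptmap -> mine -> coevolve ->
## tree -> assay, with one seed fanned out to per-stage seeds and a
## versioned JSON report echoing every threshold used.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; per-stage seeds are derived from it by a
#'   stable string hash of the stage name, so stages are individually
#'   reproducible and do not share streams.
#' @param sim A [sim_config()] describing the synthetic inputs.  The
#'   default is a demonstration-scale configuration (a 200 kb genome
#'   with 2,000 motifs and tens of genomes per category) so a full run
#'   completes in seconds; pass a full-scale `sim_config()` for
#'   study-scale numbers.
#' @param e_max,min_len_frac Homology-hit filter thresholds.
#' @param dnd_max_gap dndC-dndD pairing gap limit (bp).
#' @param fgh_window,pbe_window Neighbourhood windows (bp).
#' @param gap_open,gap_extend Aligner gap penalties.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("thioscape_run_"),
                            seed = 1L,
                            sim = sim_config(
                              seed = seed, genome_len = 2e5,
                              n_motifs = 2000L, n_full = 131L,
                              n_hemi_plus = 57L, n_hemi_minus = 57L,
                              category_counts = c(pbe_dnd_only = 13L,
                                                  pbe_mtase_only = 16L,
                                                  pbe_both = 11L,
                                                  pbe_solitary = 17L,
                                                  dnd_with_dndFGH = 12L,
                                                  dnd_alone = 10L,
                                                  dnd_with_pbe = 8L),
                              n_strains = 25L),
                            e_max = 1e-10, min_len_frac = 0.30,
                            dnd_max_gap = 5000, fgh_window = 20000,
                            pbe_window = 10000,
                            gap_open = 10, gap_extend = 0.5) {
  stopifnot(e_max > 0, min_len_frac > 0, dnd_max_gap > 0, fgh_window > 0,
            pbe_window > 0, gap_open > 0, gap_extend > 0,
            inherits(sim, "sim_config"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 e_max = e_max, min_len_frac = min_len_frac,
                 dnd_max_gap = dnd_max_gap, fgh_window = fgh_window,
                 pbe_window = pbe_window, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "pipeline_config")
}

stage_cfg <- function(cfg, stage) {
  sim <- cfg$sim
  sim$seed <- hash_seed(cfg$seed, stage)
  sim
}

#' Run the full synthetic-to-report pipeline
#'
#' Executes simulate, ptmap, mine, coevolve, tree and assay in order on
#' synthetic inputs, writes stage outputs under `cfg$out_dir`, and
#' writes `report.json` echoing every threshold used.  Identical
#' configurations produce byte-identical reports.  A stage failure
#' aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return The report, invisibly (a named list mirroring the JSON).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$out_dir, ...)
  report <- list(
    tool = "thioscape",
    version = as.character(utils::packageVersion("thioscape")),
    seed = cfg$seed,
    thresholds = cfg[c("e_max", "min_len_frac", "dnd_max_gap",
                       "fgh_window", "pbe_window", "gap_open",
                       "gap_extend")])
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  sim <- run_stage("simulate", function() {
    gcfg <- stage_cfg(cfg, "simulate")
    gen <- gen_genome_with_motifs(gcfg)
    calls <- gen_pt_calls(gen$positions, gcfg, names(gen$genome))
    feats <- gen_feature_table(gen$genome,
                               n_cds = max(1L, round(gcfg$genome_len / 4000)),
                               n_rrna = 3L, n_pseudo = 5L,
                               seed = gcfg$seed)
    ann <- gen_defence_annotations(gcfg)
    hits <- gen_homology_hits(ann, n_true = min(nrow(ann), 200L),
                              n_decoy = min(nrow(ann), 200L),
                              seed = gcfg$seed)
    write_genome_fasta(gen$genome, path("genome.fasta"))
    write_pt_calls(calls, path("pt_calls.tsv"))
    write_feature_table(feats, path("features.tsv"))
    write_homology_table(hits, path("hits.tsv"))
    list(gen = gen, calls = calls, feats = feats, ann = ann, hits = hits)
  })
  report$simulate <- list(genome_len = cfg$sim$genome_len,
                          n_motifs = length(sim$gen$positions),
                          n_calls = nrow(sim$calls),
                          n_genomes = length(unique(sim$ann$genome_id)))

  ptres <- run_stage("ptmap", function() {
    genome <- read_genome_fasta(path("genome.fasta"))
    calls <- read_pt_calls(path("pt_calls.tsv"), genome)
    feats <- read_feature_table(path("features.tsv"), genome)
    loci <- classify_duplex_states(scan_gatc_loci(genome), calls)
    summ <- summarize_pt(loci, genome, feats)
    bed <- data.frame(contig = loci$contig, start = loci$start,
                      end = loci$start + 4L, state = loci$state)
    write.table(bed, path("pt_loci.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    summ
  })
  report$ptmap <- unclass(ptres)[c("n_motifs", "n_modified_loci",
                                   "pct_modified", "n_full", "n_hemi",
                                   "pct_hemi", "n_plus_calls",
                                   "n_minus_calls", "calls_per_10kb")]
  report$ptmap$features_with_pt <- as.list(ptres$features_with_pt)

  mine <- run_stage("mine", function() {
    qlens <- setNames(rep(400, length(unique(sim$hits$qseqid))),
                      unique(sim$hits$qseqid))
    hits <- read_homology_table(path("hits.tsv"), qlens)
    kept <- filter_hits(hits, cfg$e_max, cfg$min_len_frac)
    dnd_loci <- locate_dndCD_pairs(sim$ann, cfg$dnd_max_gap)
    dnd_cls <- classify_dnd_system(dnd_loci, sim$ann, cfg$fgh_window)
    pbe_loci <- locate_pbeAC_pairs(sim$ann, cfg$dnd_max_gap)
    pbe_cls <- classify_pbe_neighborhood(pbe_loci, sim$ann, cfg$pbe_window,
                                         cfg$dnd_max_gap)
    write.table(dnd_cls, path("dnd_classifications.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pbe_cls, path("pbe_classifications.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(n_hits = nrow(hits), n_kept = nrow(kept),
         dnd = cooccurrence_summary(dnd_cls),
         pbe = cooccurrence_summary(pbe_cls))
  })
  report$mine <- list(n_hits = mine$n_hits, n_kept = mine$n_kept,
                      dnd_categories = mine$dnd, pbe_categories = mine$pbe)

  coev <- run_stage("coevolve", function() {
    ccfg <- stage_cfg(cfg, "coevolve")
    ref_mod <- gen_protein(350, ccfg$seed)
    ref_res <- gen_protein(300, ccfg$seed + 1L)
    fam <- gen_protein_family_pairs(ref_mod, ref_res, ccfg)
    tab <- similarity_rates(fam, ref_mod, ref_res,
                            gap_open = cfg$gap_open,
                            gap_extend = cfg$gap_extend)
    write.table(tab, path("similarity_pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(fam = fam, fit = coevolution_fit(tab))
  })
  report$coevolve <- list(n = coev$fit$n, rho = coev$fit$rho,
                          r = coev$fit$r, slope = coev$fit$slope,
                          intercept = coev$fit$intercept)

  treed <- run_stage("tree", function() {
    k <- min(8L, nrow(coev$fam))
    seqs <- setNames(coev$fam$mod_seq[seq_len(k)],
                     coev$fam$strain_id[seq_len(k)])
    dm <- distance_matrix(seqs, gap_open = cfg$gap_open,
                          gap_extend = cfg$gap_extend)
    tree <- nj_tree(dm)
    write_newick(tree, path("tree.nwk"))
    list(n_taxa = k, total_branch_length = sum(tree$edge.length))
  })
  report$tree <- treed

  report$assay <- run_stage("assay", function() {
    set.seed(hash_seed(cfg$seed, "assay"))
    t_ref <- 10^runif(1, 5, 7)
    protection <- 10^runif(1, 3.5, 4.5)
    list(eop = eop(t_ref / protection, t_ref),
         fold_viral_load = relative_viral_load(ct_radA = 24,
                                               ct_repA = 24 - runif(1, 1, 5)),
         unadsorbed_final_pct = unadsorbed_pct(t_ref * runif(1, 0.1, 0.4),
                                               t_ref))
  })

  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
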