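## Seeded synthetic-data generators.  Every generator is deterministic in
## its configuration (including the seed) and stores machine-readable
## ground truth alongside its output, so downstream classifiers can be
## scored without reference to generator internals.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators.  Defaults encode
#' the study conditions the analyses are exercised under: a haloarchaeal
#' chromosome-scale genome carrying 94,316 GATC duplex loci of which
#' 1,310 are fully and 1,141 hemi PT-modified; 553 pbeAC-centred genome
#' neighbourhoods partitioned 128/155/105/165 across co-occurrence
#' categories; and protein-family pairs whose substitution fractions have
#' rank correlation 0.582 across 261 strains.
#'
#' @param seed Integer seed; identical configurations give identical
#'   outputs.
#' @param genome_len Genome length in bp.
#' @param gc GC fraction of the background sequence.
#' @param n_motifs Number of plus-strand GATC occurrences to plant.
#' @param n_full,n_hemi_plus,n_hemi_minus Counts of duplex loci carrying
#'   PT on both strands, only the plus strand, or only the minus strand.
#' @param n_genomes Number of genomes for multi-genome fixtures.
#' @param category_counts Named integer vector of planted defence-system
#'   categories; names from `pbe_dnd_only`, `pbe_mtase_only`, `pbe_both`,
#'   `pbe_solitary`, `dnd_with_dndFGH`, `dnd_alone`, `dnd_with_pbe`,
#'   `dnd_with_both`.
#' @param gap_range Length-2 numeric, min/max bp gap drawn between a
#'   planted cluster and its neighbourhood partner.
#' @param divergence_corr Target rank correlation of paired substitution
#'   fractions in `[-1, 1]`.
#' @param n_strains Number of strains for protein-family pairs.
#' @param sub_rate_range Length-2 numeric within (0, 0.6): min/max
#'   substitution fraction per site.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_len = 4e6,
                       gc = 0.62,
                       n_motifs = 94316L,
                       n_full = 1310L,
                       n_hemi_plus = 571L,
                       n_hemi_minus = 570L,
                       n_genomes = 1L,
                       category_counts = c(pbe_dnd_only = 128L,
                                           pbe_mtase_only = 155L,
                                           pbe_both = 105L,
                                           pbe_solitary = 165L),
                       gap_range = c(1, 9000),
                       divergence_corr = 0.582,
                       n_strains = 261L,
                       sub_rate_range = c(0.05, 0.5)) {
  cfg <- list(seed = as.integer(seed), genome_len = genome_len, gc = gc,
              n_motifs = as.integer(n_motifs), n_full = as.integer(n_full),
              n_hemi_plus = as.integer(n_hemi_plus),
              n_hemi_minus = as.integer(n_hemi_minus),
              n_genomes = as.integer(n_genomes),
              category_counts = category_counts, gap_range = gap_range,
              divergence_corr = divergence_corr,
              n_strains = as.integer(n_strains),
              sub_rate_range = sub_rate_range)
  with(cfg, {
    stopifnot(length(seed) == 1, !is.na(seed),
              genome_len >= 0, gc >= 0, gc <= 1,
              n_motifs >= 0, n_full >= 0, n_hemi_plus >= 0,
              n_hemi_minus >= 0, n_genomes >= 1,
              length(gap_range) == 2, gap_range[1] <= gap_range[2],
              gap_range[1] >= 0,
              divergence_corr >= -1, divergence_corr <= 1,
              n_strains >= 0, length(sub_rate_range) == 2,
              sub_rate_range[1] > 0, sub_rate_range[2] < 0.6,
              sub_rate_range[1] <= sub_rate_range[2])
    if (n_full + n_hemi_plus + n_hemi_minus > n_motifs)
      stop_fmt("n_full + n_hemi_plus + n_hemi_minus exceeds n_motifs")
    if (!is.null(names(category_counts))) {
      known <- c("pbe_dnd_only", "pbe_mtase_only", "pbe_both",
                 "pbe_solitary", "dnd_with_dndFGH", "dnd_alone",
                 "dnd_with_pbe", "dnd_with_both")
      bad <- setdiff(names(category_counts), known)
      if (length(bad) > 0)
        stop_fmt("unknown category: %s", paste(bad, collapse = ", "))
    }
  })
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate a genome with an exact number of planted GATC motifs
#'
#' Draws a random background at the configured GC content, plants
#' `n_motifs` copies of GATC at sorted positions at least 4 bp apart, and
#' destroys every spontaneous GATC occurrence by resampling a single free
#' base, iterating until the plus strand carries exactly `n_motifs`
#' occurrences.  Exact counts keep worked-example denominators exact.
#'
#' @param cfg A [sim_config()].
#' @param contig Contig id of the generated sequence.
#' @return List with `genome` (named character vector of length 1) and
#'   `positions` (sorted 0-based starts of the planted motifs).
#' @export
gen_genome_with_motifs <- function(cfg, contig = "sim_contig") {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_motifs; len <- as.integer(cfg$genome_len)
  if (n > 0 && n * 8 >= len)
    stop_fmt("infeasible placement: n_motifs * 8 must be < genome_len")
  set.seed(cfg$seed)
  p_base <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  s <- sample(BASES, len, replace = TRUE, prob = p_base)
  if (n > 0) {
    # Spacing construction: distinct draws + 4*(rank-1) guarantees
    # pairwise separation >= 5 bp between motif starts.
    slack <- len - 4L - 4L * (n - 1L)
    pos <- sort(sample.int(slack + 1L, n) - 1L) + 4L * (0:(n - 1L))
    idx <- rep(pos, each = 4L) + rep(0:3, times = n) + 1L
    s[idx] <- rep(c("G", "A", "T", "C"), times = n)
    protected <- logical(len)
    protected[idx] <- TRUE
  } else {
    pos <- integer(0)
    protected <- logical(len)
  }
  find_gatc <- function(s) {
    which(s[seq_len(length(s) - 3L)] == "G" &
          s[2:(length(s) - 2L)] == "A" &
          s[3:(length(s) - 1L)] == "T" &
          s[4:length(s)] == "C") - 1L
  }
  for (iter in 1:100) {
    spont <- setdiff(find_gatc(s), pos)
    if (length(spont) == 0) break
    if (iter == 100) stop_fmt("failed to eliminate spontaneous motifs")
    for (p in spont) {
      free <- (p + 1):(p + 4)
      free <- free[!protected[free]]
      if (length(free) == 0) stop_fmt("spontaneous motif locked by planted ones")
      j <- free[sample.int(length(free), 1)]
      s[j] <- sample(setdiff(BASES, s[j]), 1)
    }
  }
  genome <- setNames(paste(s, collapse = ""), contig)
  attr(genome, "circular") <- FALSE
  list(genome = genome, positions = pos)
}

#' Generate PT calls with a chosen duplex composition
#'
#' Assigns `n_full`, `n_hemi_plus` and `n_hemi_minus` duplex states to
#' motif loci uniformly at random and emits the corresponding
#' strand-level calls: a full locus at start `p` yields a `+` call at `p`
#' and a `-` call at `p + 3`; hemi loci yield one call each.
#'
#' @param positions Sorted 0-based motif starts (from
#'   [gen_genome_with_motifs()]).
#' @param cfg A [sim_config()].
#' @param contig Contig id carried on every call.
#' @return PT call `data.frame` sorted by position, with attribute
#'   `truth`: a `data.frame` of `(start, state)` for every motif locus.
#' @export
gen_pt_calls <- function(positions, cfg, contig = "sim_contig") {
  stopifnot(inherits(cfg, "sim_config"))
  nf <- cfg$n_full; np <- cfg$n_hemi_plus; nm <- cfg$n_hemi_minus
  if (nf + np + nm > length(positions))
    stop_fmt("modified-locus counts exceed available motifs (%d)",
             length(positions))
  set.seed(cfg$seed + 1L)
  state <- rep("none", length(positions))
  pick <- sample.int(length(positions), nf + np + nm)
  state[pick[seq_len(nf)]] <- "full"
  state[pick[nf + seq_len(np)]] <- "hemi_plus"
  state[pick[nf + np + seq_len(nm)]] <- "hemi_minus"
  plus <- positions[state %in% c("full", "hemi_plus")]
  minus <- positions[state %in% c("full", "hemi_minus")] + 3L
  calls <- data.frame(contig = contig,
                      pos = c(plus, minus),
                      strand = rep(c("+", "-"), c(length(plus), length(minus))),
                      stringsAsFactors = FALSE)
  calls <- calls[order(calls$contig, calls$pos), ]
  rownames(calls) <- NULL
  attr(calls, "truth") <- data.frame(start = positions, state = state,
                                     stringsAsFactors = FALSE)
  calls
}

#' Generate a non-overlapping feature table
#'
#' Places the requested numbers of CDS, rRNA and pseudogene features as
#' pairwise-disjoint intervals on the genome, with strand chosen at
#' random.
#'
#' @param genome Named character vector of length 1.
#' @param n_cds,n_rrna,n_pseudo Feature counts.
#' @param seed Integer seed.
#' @param mean_len Named lengths (bp) used for each feature kind.
#' @return Feature `data.frame` (see [read_feature_table()]).
#' @export
gen_feature_table <- function(genome, n_cds, n_rrna, n_pseudo, seed = 1L,
                              mean_len = c(CDS = 900, rRNA = 1500,
                                           pseudogene = 600)) {
  len <- nchar(genome[[1]])
  kinds <- rep(c("CDS", "rRNA", "pseudogene"), c(n_cds, n_rrna, n_pseudo))
  n <- length(kinds)
  if (n == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      kind = character(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  kinds <- sample(kinds)
  widths <- pmax(50L, as.integer(round(mean_len[kinds] * runif(n, 0.5, 1.5))))
  total <- sum(widths)
  if (total > len)
    stop_fmt("infeasible: total feature span %d exceeds genome length %d",
             total, len)
  # Distribute the slack between consecutive features at random.
  slack <- len - total
  cuts <- sort(sample.int(slack + 1L, n) - 1L)
  starts <- cuts + c(0L, cumsum(widths[-n]))
  feats <- data.frame(contig = names(genome)[1],
                      start = starts, end = starts + widths,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      kind = kinds,
                      label = sprintf("feat_%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
  validate_features(feats, genome)
}

# Nominal gene lengths (bp) used when planting defence-gene clusters.
GENE_LEN <- c(dndC = 1200L, dndD = 2000L, dndE = 350L, dndA = 1000L,
              pbeA = 2400L, pbeB = 200L, pbeC = 1500L, pbeD = 460L,
              dndF = 2000L, dndG = 1000L, dndH = 1500L, mtase = 1000L)
INTRA_GAP <- 60L  # gap between consecutive genes inside one cluster

plant_cluster <- function(genome_id, contig, at, symbols, strand = "+") {
  starts <- integer(length(symbols))
  cur <- as.integer(at)
  for (i in seq_along(symbols)) {
    starts[i] <- cur
    cur <- cur + GENE_LEN[[symbols[i]]] + INTRA_GAP
  }
  data.frame(genome_id = genome_id, symbol = symbols, contig = contig,
             start = starts, end = starts + GENE_LEN[symbols],
             strand = strand, stringsAsFactors = FALSE)
}

cluster_span <- function(ann) c(min(ann$start), max(ann$end))

# Width of a planted cluster from its first gene start to its last gene end.
cluster_width <- function(symbols) {
  sum(GENE_LEN[symbols]) + INTRA_GAP * (length(symbols) - 1L)
}

#' Plant defence-gene neighbourhoods with known categories
#'
#' Emits one synthetic genome per requested category instance.  Each
#' genome carries the clusters its category implies, with the gap between
#' the focal cluster and its neighbourhood partner drawn uniformly from
#' `cfg$gap_range`; the drawn gap is exactly the edge-to-edge gap the
#' window classifiers measure.  Categories prefixed `pbe_` are
#' pbeAC-centred (the 10 kb neighbourhood rule); categories prefixed
#' `dnd_` are dndCD-centred (the 20 kb flanking rule).  In strict mode
#' the generator refuses gap ranges under which a planted partner (up to
#' the far edge of its farthest required gene) could cross the category's
#' window boundary, so planted ground truth is never ambiguous.
#'
#' @param cfg A [sim_config()]; `category_counts` selects what to plant.
#' @param strict Refuse gap ranges that could cross a window boundary
#'   (default `TRUE`).
#' @return `data.frame` of gene annotations (`genome_id`, `symbol`,
#'   `contig`, `start`, `end`, `strand`) with attribute `truth`: a
#'   `data.frame` of `(genome_id, category)`.
#' @export
gen_defence_annotations <- function(cfg, strict = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- cfg$category_counts
  gr <- cfg$gap_range
  # Extra reach beyond the drawn gap to the start of the farthest gene the
  # window rule requires (0 when the rule is cluster- or single-gene-level).
  reach <- c(pbe_dnd_only = 0, pbe_mtase_only = 0, pbe_both = 0,
             pbe_solitary = 0, dnd_alone = 0,
             dnd_with_dndFGH = cluster_width(c("dndF", "dndG")) + INTRA_GAP,
             dnd_with_pbe = cluster_width(c("pbeA", "pbeB")) + INTRA_GAP,
             dnd_with_both = max(cluster_width(c("dndF", "dndG")),
                                 cluster_width(c("pbeA", "pbeB"))) +
                             INTRA_GAP)
  if (strict) {
    for (cat in names(counts)) {
      win <- if (startsWith(cat, "pbe_")) 10000 else 20000
      needs_gap <- !cat %in% c("pbe_solitary", "dnd_alone")
      if (needs_gap && counts[[cat]] > 0 && gr[2] + reach[[cat]] > win)
        stop_fmt(
          "gap_range max %g (+%g bp partner reach) crosses the %d bp window of '%s'",
          gr[2], reach[[cat]], win, cat)
    }
  }
  set.seed(cfg$seed + 2L)
  base <- as.integer(gr[2] + 10000)  # room for one partner on the left
  ann <- vector("list", sum(counts)); truth <- ann; g <- 0L
  rgap <- function() round(runif(1, gr[1], gr[2]))
  pbe_genes <- c("pbeA", "pbeB", "pbeC", "pbeD")
  for (cat in names(counts)) {
    for (k in seq_len(counts[[cat]])) {
      g <- g + 1L
      id <- sprintf("g%05d", g)
      contig <- "c1"
      if (startsWith(cat, "pbe_")) {
        pbe <- plant_cluster(id, contig, base, pbe_genes)
        # pbeAC locus span runs from pbeA start to pbeC end; the trailing
        # pbeD lies beyond it, so a right-hand partner may overlap pbeD
        # at small gaps -- harmless for window classification.
        ac_end <- pbe$end[pbe$symbol == "pbeC"]
        extra <- list()
        if (cat %in% c("pbe_dnd_only", "pbe_both"))
          extra <- c(extra, list(plant_cluster(id, contig, ac_end + rgap(),
                                               c("dndC", "dndD", "dndE",
                                                 "dndA"))))
        if (cat %in% c("pbe_mtase_only", "pbe_both")) {
          gp <- rgap()
          extra <- c(extra, list(plant_cluster(
            id, contig, base - gp - GENE_LEN[["mtase"]], "mtase")))
        }
        rows <- do.call(rbind, c(list(pbe), extra))
      } else {
        dnd <- plant_cluster(id, contig, base, c("dndC", "dndD"))
        right <- max(dnd$end)
        extra <- list()
        if (cat %in% c("dnd_with_dndFGH", "dnd_with_both"))
          extra <- c(extra, list(plant_cluster(id, contig, right + rgap(),
                                               c("dndF", "dndG", "dndH"))))
        if (cat %in% c("dnd_with_pbe", "dnd_with_both")) {
          gp <- rgap()
          extra <- c(extra, list(plant_cluster(
            id, contig, base - gp - cluster_width(pbe_genes), pbe_genes)))
        }
        rows <- do.call(rbind, c(list(dnd), extra))
      }
      if (any(rows$start < 0))
        stop_fmt("infeasible left-hand placement for category '%s'", cat)
      ann[[g]] <- rows
      truth[[g]] <- data.frame(genome_id = id, category = cat,
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, ann)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a random protein sequence
#'
#' @param n Length in residues.
#' @param seed Integer seed.
#' @return Single protein string over the 20 standard residues.
#' @export
gen_protein <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, d) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round(d * length(chars))
  if (k == 0) return(seq)
  at <- sample.int(length(chars), k)
  chars[at] <- vapply(chars[at],
                      function(a) sample(setdiff(AA20, a), 1), character(1))
  paste(chars, collapse = "")
}

#' Generate protein-family pairs with correlated divergence
#'
#' For each strain, draws a pair of substitution fractions from a
#' Gaussian copula whose parameter is chosen so the population Spearman
#' correlation equals `cfg$divergence_corr`, with uniform margins on
#' `cfg$sub_rate_range`.  Each strain's sequences derive from the
#' references by substitutions only (no indels) at those fractions.
#'
#' @param ref_mod,ref_res Reference protein strings for the modification
#'   and partner (restriction/exclusion) families.
#' @param cfg A [sim_config()]; uses `n_strains`, `divergence_corr`,
#'   `sub_rate_range`, `seed`.
#' @return `data.frame` with columns `strain_id`, `mod_seq`, `res_seq`,
#'   `true_d_mod`, `true_d_res`.
#' @export
gen_protein_family_pairs <- function(ref_mod, ref_res, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nchar(ref_mod) > 0,
            nchar(ref_res) > 0)
  n <- cfg$n_strains
  set.seed(cfg$seed + 3L)
  # Gaussian-copula parameter giving the requested Spearman correlation.
  rho_g <- 2 * sin(pi * cfg$divergence_corr / 6)
  z1 <- rnorm(n)
  z2 <- rho_g * z1 + sqrt(max(0, 1 - rho_g^2)) * rnorm(n)
  lo <- cfg$sub_rate_range[1]; hi <- cfg$sub_rate_range[2]
  d_mod <- lo + (hi - lo) * pnorm(z1)
  d_res <- lo + (hi - lo) * pnorm(z2)
  data.frame(strain_id = sprintf("strain_%03d", seq_len(n)),
             mod_seq = vapply(d_mod, mutate_protein, character(1),
                              seq = ref_mod),
             res_seq = vapply(d_res, mutate_protein, character(1),
                              seq = ref_res),
             true_d_mod = d_mod, true_d_res = d_res,
             stringsAsFactors = FALSE)
}

#' Generate homology-hit rows with planted filter labels
#'
#' Emits `n_true` rows satisfying both filter rules (e-value below the
#' threshold and aligned length at least the minimum query fraction) and
#' `n_decoy` rows violating exactly one rule, in shuffled order, with a
#' logical ground-truth column `is_true`.  Subject ids encode the subject
#' location as `genome|contig|start-end|strand|prot` so kept hits can be
#' converted to gene annotations.
#'
#' @param truth Gene-annotation `data.frame` the true hits point into
#'   (see [gen_defence_annotations()]); one true hit is emitted per row
#'   of `truth` cycled up to `n_true`.
#' @param n_true,n_decoy Row counts.
#' @param seed Integer seed.
#' @param e_max,min_len_frac Filter thresholds being emulated.
#' @param query_len Nominal query length (aa) for every query symbol.
#' @return Hit `data.frame` in the 12-column dialect plus `query_len` and
#'   `is_true`.
#' @export
gen_homology_hits <- function(truth, n_true = nrow(truth), n_decoy = n_true,
                              seed = 1L, e_max = 1e-10,
                              min_len_frac = 0.30, query_len = 400L) {
  stopifnot(nrow(truth) > 0, n_true >= 0, n_decoy >= 0)
  set.seed(seed)
  src <- truth[rep_len(seq_len(nrow(truth)), n_true + n_decoy), ]
  n <- n_true + n_decoy
  is_true <- rep(c(TRUE, FALSE), c(n_true, n_decoy))
  # True rows: e <= e_max and aln_len/query_len >= min_len_frac.
  ev <- 10^-runif(n, 11, 120)
  frac <- runif(n, min_len_frac, 1)
  if (n_decoy > 0) {
    bad <- which(!is_true)
    bad_e <- bad[seq_len(ceiling(length(bad) / 2))]
    bad_l <- setdiff(bad, bad_e)
    ev[bad_e] <- 10^-runif(length(bad_e), 0, 9.9)   # e-value too large
    frac[bad_l] <- runif(length(bad_l), 0.05, 0.29) # aligned length short
  }
  aln <- pmax(1L, as.integer(round(frac * query_len)))
  hits <- data.frame(
    qseqid = src$symbol,
    sseqid = sprintf("%s|%s|%d-%d|%s|%s_p", src$genome_id, src$contig,
                     src$start, src$end, src$strand, src$symbol),
    pident = round(runif(n, 30, 100), 1),
    length = aln,
    mismatch = as.integer(round(aln * runif(n, 0, 0.5))),
    gapopen = 0L,
    qstart = 1L, qend = aln,
    sstart = 1L, send = aln,
    evalue = ev,
    bitscore = round(runif(n, 50, 900), 1),
    query_len = query_len,
    is_true = is_true,
    stringsAsFactors = FALSE)
  hits <- hits[sample.int(n), ]
  rownames(hits) <- NULL
  hits
}
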