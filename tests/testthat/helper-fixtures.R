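## Shared fixtures and independent oracles, built in code.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                  collapse = "")

# Overlap-aware motif scan oracle, independent of the package scanner.
count_motif_oracle <- function(seq, motif = "GATC") {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(integer(0))
  starts <- which(vapply(seq_len(n - k + 1),
                         function(i) substr(seq, i, i + k - 1) == motif,
                         logical(1)))
  starts - 1L  # 0-based
}

# Brute-force optimal affine-gap global alignment score by exhaustive
# enumeration of every monotone alignment path (no DP, no memoisation).
# A gap run of length L costs open + (L - 1) * ext unless it touches the
# first or last alignment column and free_ends is TRUE.
brute_align_score <- function(a, b, smat, gap_open = 10, gap_extend = 0.5,
                              free_ends = TRUE) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  score_path <- function(moves) {
    s <- 0; i <- 0; j <- 0; k <- 1; L <- length(moves)
    while (k <= L) {
      mv <- moves[k]
      if (mv == "D") {
        i <- i + 1; j <- j + 1
        s <- s + smat[ca[i], cb[j]]
        k <- k + 1
      } else {
        k2 <- k
        while (k2 <= L && moves[k2] == mv) k2 <- k2 + 1
        run <- k2 - k
        free <- free_ends && (k == 1 || k2 == L + 1)
        if (!free) s <- s - (gap_open + (run - 1) * gap_extend)
        if (mv == "U") i <- i + run else j <- j + run
        k <- k2
      }
    }
    s
  }
  rec <- function(i, j, moves) {
    if (i == n && j == m) {
      sc <- score_path(moves)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, c(moves, "D"))
    if (i < n) rec(i + 1, j, c(moves, "U"))
    if (j < m) rec(i, j + 1, c(moves, "L"))
  }
  rec(0L, 0L, character(0))
  best
}

# Exhaustive edge-gap oracle on integer intervals [s, e): 0 on overlap,
# else the count of integer positions strictly between the intervals.
gene_gap_oracle <- function(s1, e1, s2, e2) {
  p1 <- s1:(e1 - 1); p2 <- s2:(e2 - 1)
  if (length(intersect(p1, p2)) > 0) return(0)
  lo <- min(max(p1), max(p2)); hi <- max(min(p1), min(p2))
  if (hi - lo <= 1) return(0)  # abutting
  length(setdiff(seq(lo + 1, hi - 1), c(p1, p2)))
}

# Independent Spearman rho for untied columns: Pearson correlation of
# explicitly counted ranks.
spearman_oracle <- function(x, y) {
  rk <- function(v) vapply(v, function(vi) 1 + sum(v < vi), numeric(1))
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small classified PT fixture: genome, planted composition, calls.
make_pt_fixture <- function(seed, n_motifs = 40, n_full = 8,
                            n_hemi_plus = 5, n_hemi_minus = 4,
                            genome_len = 5000) {
  cfg <- sim_config(seed = seed, genome_len = genome_len, gc = 0.5,
                    n_motifs = n_motifs, n_full = n_full,
                    n_hemi_plus = n_hemi_plus, n_hemi_minus = n_hemi_minus)
  g <- gen_genome_with_motifs(cfg)
  calls <- gen_pt_calls(g$positions, cfg, names(g$genome))
  list(cfg = cfg, genome = g$genome, positions = g$positions,
       calls = calls, truth = attr(calls, "truth"))
}

# Mapping from planted generator categories to classifier categories.
PBE_TRUTH_MAP <- c(pbe_dnd_only = "dnd_only", pbe_mtase_only = "mtase_only",
                   pbe_both = "both", pbe_solitary = "solitary")
DND_TRUTH_MAP <- c(dnd_with_dndFGH = "dndFGH", dnd_alone = "none",
                   dnd_with_pbe = "pbe", dnd_with_both = "both")
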