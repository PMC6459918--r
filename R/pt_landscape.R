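## Genome-wide PT landscape: motif scanning, duplex-state classification,
## summary statistics, spacing and flanking-base context bias.
##
## A duplex locus is one plus-strand occurrence of the palindromic GATC
## motif considered together with its minus-strand complement.  The
## modified G of the minus strand lies opposite the plus-strand C, three
## bases downstream of the plus-strand G, so a plus call at position p
## and a minus call at p + 3 describe the same duplex locus.

#' Scan a genome for GATC duplex loci
#'
#' Reports every plus-strand occurrence of the motif as an unclassified
#' duplex locus (state `none`).  Occurrences overlapping an `N` are
#' excluded.  Duplex semantics require a palindromic motif (equal to its
#' reverse complement); GATC satisfies this.
#'
#' @param genomes Named character vector of genome sequences.
#' @param motif Motif string, by default `"GATC"`.
#' @param duplex Enforce that the motif is its own reverse complement
#'   (default `TRUE`); disable only for plain single-strand scans.
#' @return `data.frame` with columns `contig`, `start` (0-based position
#'   of the motif's first base), `state` (all `"none"`), sorted by
#'   `(contig, start)`.
#' @export
scan_gatc_loci <- function(genomes, motif = "GATC", duplex = TRUE) {
  check_genomes(genomes)
  if (!nzchar(motif)) stop_fmt("motif must be non-empty")
  if (duplex && !identical(motif, revcomp(motif)))
    stop_fmt("duplex mode requires a palindromic motif; '%s' is not", motif)
  res <- lapply(names(genomes), function(ct) {
    m <- Biostrings::matchPattern(motif, Biostrings::BString(genomes[[ct]]))
    if (length(m) == 0) return(NULL)
    data.frame(contig = ct, start = Biostrings::start(m) - 1L,
               state = "none", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      state = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

#' Classify duplex loci into modification states
#'
#' Pairs strand-resolved PT calls onto duplex loci by integer arithmetic:
#' a `+` call at position `p` belongs to the locus starting at `p`, a `-`
#' call at `q` to the locus starting at `q - 3`.  A locus with calls on
#' both strands is `full`; exactly one call gives `hemi_plus` or
#' `hemi_minus`; no call leaves `none`.  Calls that map to no scanned
#' locus are returned in the `orphans` attribute (with a warning), never
#' silently dropped.  Two identical strand calls at one locus raise an
#' error.
#'
#' @param loci Locus `data.frame` from [scan_gatc_loci()].
#' @param calls PT call `data.frame` (`contig`, `pos`, `strand`).
#' @return The locus `data.frame` with `state` filled in and attribute
#'   `orphans` holding unmatched calls.
#' @export
classify_duplex_states <- function(loci, calls) {
  stopifnot(all(c("contig", "start") %in% names(loci)),
            all(c("contig", "pos", "strand") %in% names(calls)))
  key <- function(ct, p) paste(ct, p, sep = "\r")
  if (anyDuplicated(key(paste(calls$contig, calls$strand), calls$pos))) {
    d <- which(duplicated(key(paste(calls$contig, calls$strand), calls$pos)))[1]
    stop_fmt("duplicate call at (%s, %d, %s)", calls$contig[d],
             calls$pos[d], calls$strand[d])
  }
  locus_start <- ifelse(calls$strand == "+", calls$pos, calls$pos - 3L)
  hit <- match(key(calls$contig, locus_start), key(loci$contig, loci$start))
  orphans <- calls[is.na(hit), , drop = FALSE]
  rownames(orphans) <- NULL
  if (nrow(orphans) > 0)
    warning(sprintf("%d PT call(s) map to no scanned locus", nrow(orphans)),
            call. = FALSE)
  ok <- !is.na(hit)
  plus_hit <- unique(hit[ok & calls$strand == "+"])
  minus_hit <- unique(hit[ok & calls$strand == "-"])
  state <- rep("none", nrow(loci))
  state[plus_hit] <- "hemi_plus"
  state[minus_hit] <- "hemi_minus"
  state[intersect(plus_hit, minus_hit)] <- "full"
  loci$state <- state
  attr(loci, "orphans") <- orphans
  loci
}

#' Summarise a classified PT landscape
#'
#' Computes the genome-wide PT summary: motif and modified-locus counts,
#' percent of motifs modified (1 decimal), full/hemi partition with the
#' hemi percentage rounded to the nearest integer, strand-level call
#' counts, strand-level calls per 10 kb of double-stranded genome,
#' per-strand spacing range, and the number of features of each kind
#' whose interval intersects at least one modified locus footprint
#' `[start, start + 4)`.
#'
#' `calls_per_10kb` is a genome-wide density proxy computed from called
#' sites; it is not comparable to bulk biochemical (LC-MS) PT frequency
#' measurements.
#'
#' @param loci Classified locus `data.frame`.
#' @param genomes Named character vector of genome sequences.
#' @param features Optional feature `data.frame`.
#' @return Object of class `pt_summary` (a list).
#' @export
summarize_pt <- function(loci, genomes, features = NULL) {
  check_genomes(genomes)
  if (nrow(loci) == 0) stop_fmt("empty locus collection")
  n_motifs <- nrow(loci)
  n_full <- sum(loci$state == "full")
  n_hp <- sum(loci$state == "hemi_plus")
  n_hm <- sum(loci$state == "hemi_minus")
  n_hemi <- n_hp + n_hm
  n_mod <- n_full + n_hemi
  glen <- sum(nchar(genomes))
  spacing <- if (n_full + n_hp >= 2 || n_full + n_hm >= 2)
    spacing_stats(loci, "per_strand") else list(spacing_min = NA_real_,
                                                spacing_max = NA_real_)
  features_with_pt <- NULL
  if (!is.null(features) && nrow(features) > 0) {
    mod <- loci[loci$state != "none", , drop = FALSE]
    hit <- logical(nrow(features))
    for (ct in unique(features$contig)) {
      fi <- which(features$contig == ct)
      mi <- mod$start[mod$contig == ct]
      if (length(mi) == 0) next
      fr <- IRanges::IRanges(start = features$start[fi] + 1L,
                             end = features$end[fi])
      mr <- IRanges::IRanges(start = mi + 1L, end = mi + 4L)
      hit[fi] <- IRanges::countOverlaps(fr, mr) > 0
    }
    features_with_pt <- tapply(hit, features$kind, sum)
    features_with_pt <- setNames(as.integer(features_with_pt),
                                 names(features_with_pt))
  }
  structure(list(
    n_motifs = n_motifs,
    n_modified_loci = n_mod,
    pct_modified = round(100 * n_mod / n_motifs, 1),
    n_full = n_full,
    n_hemi = n_hemi,
    pct_hemi = if (n_mod > 0) round(100 * n_hemi / n_mod) else NA_real_,
    n_plus_calls = n_full + n_hp,
    n_minus_calls = n_full + n_hm,
    calls_per_10kb = (2 * n_full + n_hemi) / (2 * glen) * 1e4,
    spacing_min = spacing$spacing_min,
    spacing_max = spacing$spacing_max,
    features_with_pt = features_with_pt), class = "pt_summary")
}

#' @export
print.pt_summary <- function(x, ...) {
  cat("PT landscape summary\n")
  cat(sprintf("  GATC duplex loci:      %d\n", x$n_motifs))
  cat(sprintf("  modified loci:         %d (%.1f%%)\n",
              x$n_modified_loci, x$pct_modified))
  cat(sprintf("  full / hemi:           %d / %d (hemi %d%%)\n",
              x$n_full, x$n_hemi, x$pct_hemi))
  cat(sprintf("  strand calls (+/-):    %d / %d\n",
              x$n_plus_calls, x$n_minus_calls))
  cat(sprintf("  calls per 10 kb (ds):  %.3f\n", x$calls_per_10kb))
  if (!is.na(x$spacing_min))
    cat(sprintf("  per-strand spacing:    %g - %g bp\n",
                x$spacing_min, x$spacing_max))
  if (!is.null(x$features_with_pt)) {
    cat("  features with >=1 PT: ",
        paste(sprintf("%s=%d", names(x$features_with_pt),
                      x$features_with_pt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spacing between consecutive modified sites
#'
#' Computes differences between consecutive modified-G coordinates on a
#' linear genome.  In `per_strand` mode (default) the plus-strand Gs
#' (locus starts of `full`/`hemi_plus` loci) and minus-strand Gs (locus
#' start + 3 of `full`/`hemi_minus` loci) are treated separately per
#' contig; in `combined` mode all modified-G coordinates are pooled.
#'
#' @param loci Classified locus `data.frame`.
#' @param strand_mode `"per_strand"` or `"combined"`.
#' @return List with `spacing_min`, `spacing_max` and the vector of
#'   `distances`.
#' @export
spacing_stats <- function(loci, strand_mode = c("per_strand", "combined")) {
  strand_mode <- match.arg(strand_mode)
  plus <- loci[loci$state %in% c("full", "hemi_plus"), c("contig", "start")]
  minus <- loci[loci$state %in% c("full", "hemi_minus"), c("contig", "start")]
  minus$start <- minus$start + 3L
  diffs_by_contig <- function(df) {
    unlist(lapply(split(df$start, df$contig),
                  function(p) if (length(p) >= 2) diff(sort(p)) else numeric(0)),
           use.names = FALSE)
  }
  d <- if (strand_mode == "per_strand") {
    c(diffs_by_contig(plus), diffs_by_contig(minus))
  } else {
    diffs_by_contig(rbind(plus, minus))
  }
  if (length(d) == 0)
    stop_fmt("need at least 2 modified calls on the relevant strand(s)")
  list(spacing_min = min(d), spacing_max = max(d), distances = d)
}

#' Flanking-base context bias at modified loci
#'
#' For each offset (by default the base immediately 5' and 3' of the
#' motif) tabulates base frequencies among modified loci (`obs_freq`)
#' against all scanned loci (`bg_freq`) and their log2 ratio.  Loci
#' lacking the flank (at a contig edge) are excluded from both numerator
#' and background; cells with zero background or zero observed frequency
#' have `log2_enrichment = NA` (undefined).
#'
#' @param loci Classified locus `data.frame`.
#' @param genomes Named character vector of genome sequences.
#' @param offsets Integer offsets relative to the motif: `-1` is the base
#'   before the first motif base, `+1` the base after the last.
#' @param motif_len Motif length in bp (4 for GATC).
#' @return `data.frame` with columns `offset`, `base`, `obs_freq`,
#'   `bg_freq`, `log2_enrichment`.
#' @export
context_bias <- function(loci, genomes, offsets = c(-1L, 1L),
                         motif_len = 4L) {
  check_genomes(genomes)
  if (!any(loci$state != "none")) stop_fmt("zero modified loci")
  out <- list()
  for (off in offsets) {
    at <- if (off < 0) loci$start + off else loci$start + motif_len + off - 1L
    len <- nchar(genomes)[loci$contig]
    keep <- at >= 0 & at < len
    base <- substr(genomes[loci$contig[keep]], at[keep] + 1L, at[keep] + 1L)
    mod <- loci$state[keep] != "none"
    if (!any(mod)) stop_fmt("zero modified loci with flank at offset %d", off)
    bg_tab <- table(factor(base, levels = BASES))
    obs_tab <- table(factor(base[mod], levels = BASES))
    bg <- as.numeric(bg_tab) / sum(bg_tab)
    obs <- as.numeric(obs_tab) / sum(obs_tab)
    l2 <- ifelse(bg > 0 & obs > 0, log2(obs / bg), NA_real_)
    out[[length(out) + 1L]] <-
      data.frame(offset = off, base = BASES, obs_freq = obs, bg_freq = bg,
                 log2_enrichment = l2, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
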