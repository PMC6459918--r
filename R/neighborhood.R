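## Defence-gene neighbourhood mining: homology-hit filtering, dndC/dndD
## pairing, flanking-window searches and co-occurrence classification.
##
## Window semantics: "within 1 bp - W kb" is read as edge-to-edge gene
## gap in [0, W], so overlapping or abutting genes count as present.
## Windows are measured from the edges of the focal locus span.

#' Filter homology hits on e-value and aligned query fraction
#'
#' Keeps a hit iff its e-value is at most `e_max` and its aligned length
#' is at least `min_len_frac` of the query protein length.  Both
#' boundaries are inclusive by default (`len_boundary = "ge"`); set
#' `len_boundary = "gt"` to drop hits at exactly the length threshold.
#' Row order is preserved.
#'
#' @param hits Hit `data.frame` with columns `evalue`, `length`,
#'   `query_len` (see [read_homology_table()]).
#' @param e_max Maximum e-value (default `1e-10`).
#' @param min_len_frac Minimum aligned fraction of the query
#'   (default `0.30`).
#' @param len_boundary `"ge"` (keep at exactly the threshold) or `"gt"`.
#' @return The kept subset of `hits`.
#' @export
filter_hits <- function(hits, e_max = 1e-10, min_len_frac = 0.30,
                        len_boundary = c("ge", "gt")) {
  len_boundary <- match.arg(len_boundary)
  if (nrow(hits) == 0) return(hits)
  if (any(hits$query_len <= 0)) stop_fmt("query_len must be positive")
  frac <- hits$length / hits$query_len
  keep_len <- if (len_boundary == "ge") frac >= min_len_frac
              else frac > min_len_frac
  out <- hits[hits$evalue <= e_max & keep_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge-to-edge gap between two intervals
#'
#' Zero when the 0-based half-open intervals overlap or abut, otherwise
#' the distance between their nearest edges.  Intervals on different
#' contigs are not comparable and return `NA`.
#'
#' @param start1,end1,start2,end2 Interval coordinates (vectorised).
#' @param contig1,contig2 Optional contig ids; mismatches give `NA`.
#' @return Numeric gap(s) in bp.
#' @export
gene_gap <- function(start1, end1, start2, end2,
                     contig1 = NULL, contig2 = NULL) {
  gap <- pmax(0, pmax(start1 - end2, start2 - end1))
  if (!is.null(contig1) && !is.null(contig2))
    gap[contig1 != contig2] <- NA_real_
  gap
}

#' Pair dndC with its nearest dndD into modification loci
#'
#' For each `dndC` annotation finds the nearest `dndD` on the same
#' contig of the same genome with edge gap at most `max_gap`; ties are
#' broken towards the `dndD` with the smaller start.  Genes that cannot
#' be paired are reported in the `unpaired` attribute.
#'
#' @param annotations Gene-annotation `data.frame` (`genome_id`,
#'   `symbol`, `contig`, `start`, `end`, `strand`).
#' @param max_gap Maximum dndC-dndD edge gap in bp (default 5000).
#' @return `data.frame` of loci (`genome_id`, `contig`, `start`, `end`,
#'   `pair_gap`) spanning both genes, with attribute `unpaired`.
#' @export
locate_dndCD_pairs <- function(annotations, max_gap = 5000) {
  cs <- annotations[annotations$symbol == "dndC", , drop = FALSE]
  ds <- annotations[annotations$symbol == "dndD", , drop = FALSE]
  loci <- list(); paired_d <- character(0)
  for (i in seq_len(nrow(cs))) {
    cand <- ds[ds$genome_id == cs$genome_id[i] &
               ds$contig == cs$contig[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    gaps <- gene_gap(cs$start[i], cs$end[i], cand$start, cand$end)
    ok <- which(gaps <= max_gap)
    if (length(ok) == 0) next
    best <- ok[order(gaps[ok], cand$start[ok])][1]
    loci[[length(loci) + 1L]] <- data.frame(
      genome_id = cs$genome_id[i], contig = cs$contig[i],
      start = min(cs$start[i], cand$start[best]),
      end = max(cs$end[i], cand$end[best]),
      pair_gap = gaps[best], stringsAsFactors = FALSE)
    paired_d <- c(paired_d, rownames(cand)[best])
  }
  out <- if (length(loci) > 0) do.call(rbind, loci) else
    data.frame(genome_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), pair_gap = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  paired_c <- unique(out$genome_id)
  unpaired <- rbind(cs[!cs$genome_id %in% out$genome_id, , drop = FALSE],
                    ds[!rownames(ds) %in% paired_d &
                       !ds$genome_id %in% out$genome_id, , drop = FALSE])
  rownames(unpaired) <- NULL
  attr(out, "unpaired") <- unpaired
  out
}

# Gap from a locus span to every annotation row of a given symbol in the
# same genome/contig; numeric(0) when the symbol is absent.
gaps_to_symbol <- function(locus, annotations, symbol) {
  a <- annotations[annotations$genome_id == locus$genome_id &
                   annotations$contig == locus$contig &
                   annotations$symbol == symbol, , drop = FALSE]
  if (nrow(a) == 0) return(numeric(0))
  gene_gap(locus$start, locus$end, a$start, a$end)
}

#' Classify a dndCD locus by its flanking defence partners
#'
#' Searches the flanking window around the dndCD span for the
#' restriction cassette (`dndF`, `dndG` and `dndH`, all three required)
#' and the exclusion proxy genes (`pbeA` and `pbeC`, both required) and
#' assigns the co-occurrence category `pbe`, `dndFGH`, `both` or `none`.
#'
#' @param loci dndCD locus `data.frame` from [locate_dndCD_pairs()].
#' @param annotations Gene-annotation `data.frame`.
#' @param fgh_window Window in bp measured from the locus edges
#'   (default 20000), applied to both cassettes.
#' @return `data.frame` (`genome_id`, `has_dndFGH`, `has_pbeAC`,
#'   `category`).
#' @export
classify_dnd_system <- function(loci, annotations, fgh_window = 20000) {
  res <- lapply(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    within <- function(sym) {
      g <- gaps_to_symbol(locus, annotations, sym)
      any(g <= fgh_window)
    }
    fgh <- within("dndF") && within("dndG") && within("dndH")
    pbe <- within("pbeA") && within("pbeC")
    data.frame(genome_id = locus$genome_id, has_dndFGH = fgh,
               has_pbeAC = pbe,
               category = if (fgh && pbe) "both" else if (fgh) "dndFGH"
                          else if (pbe) "pbe" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pair pbeA with its nearest pbeC into exclusion loci
#'
#' Analogue of [locate_dndCD_pairs()] for the pbeAC query proxies.
#'
#' @inheritParams locate_dndCD_pairs
#' @return `data.frame` of loci (`genome_id`, `contig`, `start`, `end`,
#'   `pair_gap`).
#' @export
locate_pbeAC_pairs <- function(annotations, max_gap = 5000) {
  relabel <- annotations[annotations$symbol %in% c("pbeA", "pbeC"), ,
                         drop = FALSE]
  relabel$symbol[relabel$symbol == "pbeA"] <- "dndC"
  relabel$symbol[relabel$symbol == "pbeC"] <- "dndD"
  out <- locate_dndCD_pairs(relabel, max_gap = max_gap)
  attr(out, "unpaired") <- NULL
  out
}

#' Classify a pbeAC locus by nearby modification partners
#'
#' Searches the neighbourhood window around a pbeAC locus for a dndCD
#' modification locus (a paired dndC/dndD cluster, located with
#' [locate_dndCD_pairs()]) and for MTase genes, and assigns the category
#' `dnd_only`, `mtase_only`, `both` or `solitary`.  The four categories
#' partition any input set.
#'
#' @param pbe_loci pbeAC locus `data.frame` from [locate_pbeAC_pairs()].
#' @param annotations Gene-annotation `data.frame`.
#' @param window Neighbourhood window in bp (default 10000).
#' @param dnd_max_gap Maximum dndC-dndD pairing gap (default 5000).
#' @return `data.frame` (`genome_id`, `has_dndCD`, `has_mtase`,
#'   `category`).
#' @export
classify_pbe_neighborhood <- function(pbe_loci, annotations, window = 10000,
                                      dnd_max_gap = 5000) {
  dnd_loci <- locate_dndCD_pairs(annotations, max_gap = dnd_max_gap)
  res <- lapply(seq_len(nrow(pbe_loci)), function(i) {
    locus <- pbe_loci[i, ]
    dl <- dnd_loci[dnd_loci$genome_id == locus$genome_id &
                   dnd_loci$contig == locus$contig, , drop = FALSE]
    has_dnd <- nrow(dl) > 0 &&
      any(gene_gap(locus$start, locus$end, dl$start, dl$end) <= window)
    mg <- gaps_to_symbol(locus, annotations, "mtase")
    has_mt <- any(mg <= window)
    data.frame(genome_id = locus$genome_id, has_dndCD = has_dnd,
               has_mtase = has_mt,
               category = if (has_dnd && has_mt) "both"
                          else if (has_dnd) "dnd_only"
                          else if (has_mt) "mtase_only" else "solitary",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Co-occurrence category counts and percentages
#'
#' @param classifications `data.frame` with a `category` column, e.g.
#'   from [classify_dnd_system()] or [classify_pbe_neighborhood()].
#' @return `data.frame` (`category`, `count`, `percent`), percentages of
#'   the classified total rounded to 1 decimal.
#' @export
cooccurrence_summary <- function(classifications) {
  if (is.null(classifications) || nrow(classifications) == 0)
    stop_fmt("no classifications to summarise")
  tab <- table(classifications$category)
  data.frame(category = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / nrow(classifications), 1),
             stringsAsFactors = FALSE)
}

#' Reduce kept homology hits to one annotation per genome and query
#'
#' The best kept hit (lowest e-value, ties broken by higher bitscore)
#' per `(subject_genome, query)` pair becomes a gene annotation at the
#' subject location encoded in its subject id.  Hits without a decodable
#' subject location are dropped with a warning.
#'
#' @param hits Filtered hit `data.frame` carrying the decomposed
#'   `subject_*` columns (see [read_homology_table()]).
#' @return Gene-annotation `data.frame`.
#' @export
hits_to_annotations <- function(hits) {
  if (nrow(hits) == 0)
    return(data.frame(genome_id = character(0), symbol = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  if (!"subject_genome" %in% names(hits))
    hits <- cbind(hits, decode_subject_ids(hits$sseqid))
  bad <- is.na(hits$subject_genome)
  if (any(bad)) {
    warning(sprintf("%d hit(s) without decodable subject location dropped",
                    sum(bad)), call. = FALSE)
    hits <- hits[!bad, , drop = FALSE]
  }
  hits <- hits[order(hits$evalue, -hits$bitscore), ]
  key <- paste(hits$subject_genome, hits$qseqid)
  best <- hits[!duplicated(key), , drop = FALSE]
  out <- data.frame(genome_id = best$subject_genome, symbol = best$qseqid,
                    contig = best$subject_contig, start = best$subject_start,
                    end = best$subject_end, strand = best$subject_strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$start), ]
  rownames(out) <- NULL
  out
}
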