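## Readers and writers for the external formats the pipeline touches.
##
## Coordinate convention: all intervals are 0-based half-open [start, end);
## single-base coordinates (PT calls) are 0-based.  GFF3 input (1-based
## inclusive) is converted on read.

#' Read a genome FASTA file
#'
#' Reads nucleotide FASTA into a named character vector of upper-case
#' sequences over the alphabet \{A,C,G,T,N\}.  RNA (`U`) and other
#' characters are rejected, as are duplicate or empty record ids.  The id
#' of a record is the first whitespace-delimited token of its header.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical flag stored as an attribute on the result;
#'   downstream analyses treat genomes as linear unless told otherwise.
#' @return Named character vector of sequences with attribute `circular`.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0) stop_fmt("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(grepl("U", seqs, fixed = TRUE)))
    stop_fmt("RNA base 'U' found in '%s'; DNA expected", path)
  names(seqs) <- ids
  check_genomes(seqs)
  attr(seqs, "circular") <- isTRUE(circular)
  seqs
}

#' Write genome sequences to FASTA
#'
#' @param genomes Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genomes, path, width = 70L) {
  check_genomes(genomes)
  set <- Biostrings::BStringSet(genomes)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of upper-case protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0) stop_fmt("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop_fmt("duplicate sequence ids in '%s'", path)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to FASTA
#'
#' @inheritParams write_genome_fasta
#' @param seqs Named character vector of protein sequences.
#' @export
write_protein_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read strand-resolved PT calls
#'
#' Reads a tab-separated table of phosphorothioate calls with columns
#' `contig`, `pos`, `strand` (`#` starts a comment line).  `pos` is the
#' 0-based plus-strand coordinate of the base physically carrying the
#' modified guanine: for a `+` call the genome reads `GATC` starting at
#' `pos`; for a `-` call the plus-strand base at `pos` is the `C` of a
#' `GATC` beginning at `pos - 3` (the modified G lies opposite it on the
#' minus strand).  Every call is validated against the genome and the
#' offending line is named on failure.
#'
#' @param path Path to the TSV file.
#' @param genomes Named character vector of genome sequences used for
#'   validation (see [read_genome_fasta()]).
#' @return `data.frame` with columns `contig`, `pos`, `strand`, sorted by
#'   `(contig, pos)`.
#' @export
read_pt_calls <- function(path, genomes) {
  check_genomes(genomes)
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("contig", "pos", "strand"),
                    colClasses = c("character", "integer", "character"),
                    blank.lines.skip = TRUE)
  validate_pt_calls(raw, genomes, src = path)
}

# Shared validator for PT call tables (used by the reader and generators).
validate_pt_calls <- function(calls, genomes, src = "<calls>") {
  need <- c("contig", "pos", "strand")
  if (!all(need %in% names(calls)))
    stop_fmt("PT call table must have columns %s", paste(need, collapse = ", "))
  for (i in seq_len(nrow(calls))) {
    ct <- calls$contig[i]; p <- calls$pos[i]; st <- calls$strand[i]
    if (!ct %in% names(genomes))
      stop_fmt("%s line %d: unknown contig '%s'", src, i, ct)
    if (!st %in% c("+", "-"))
      stop_fmt("%s line %d: strand must be '+' or '-'", src, i)
    g <- genomes[[ct]]
    ctx <- if (st == "+") substr(g, p + 1, p + 4) else substr(g, p - 2, p + 1)
    if (!identical(ctx, "GATC"))
      stop_fmt("%s line %d: call (%s, %d, %s) has context '%s', not GATC",
               src, i, ct, p, st, ctx)
  }
  out <- calls[order(calls$contig, calls$pos), need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write PT calls to TSV
#'
#' @param calls PT call `data.frame` (`contig`, `pos`, `strand`).
#' @param path Output path.
#' @export
write_pt_calls <- function(calls, path) {
  write.table(calls[, c("contig", "pos", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome feature table
#'
#' Accepts either a 6-column TSV (`contig`, `start`, `end`, `strand`,
#' `kind`, `label`; already 0-based half-open) or a GFF3 file (1-based
#' inclusive, converted on read; requires the rtracklayer package).
#' Feature kinds outside \{CDS, rRNA, tRNA, pseudogene\} map to `other`.
#'
#' @param path Path to the table.
#' @param genomes Optional genome set; when given, intervals are checked
#'   against contig bounds.
#' @return `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `kind`, `label`.
#' @export
read_feature_table <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  first <- readLines(path, n = 1L)
  kinds <- c("CDS", "rRNA", "tRNA", "pseudogene")
  if (grepl("\\.gff3?$", path, ignore.case = TRUE) ||
      grepl("^##gff-version", first)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_fmt("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    kind <- as.character(gr$type)
    kind[!kind %in% kinds] <- "other"
    lab <- gr$ID %||% gr$Name %||% rep("", length(gr))
    lab[is.na(lab)] <- ""
    df <- as.data.frame(gr)
    feats <- data.frame(contig = as.character(df$seqnames),
                        start = df$start - 1L,
                        end = df$end,
                        strand = as.character(df$strand),
                        kind = kind, label = lab,
                        stringsAsFactors = FALSE)
    feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  } else {
    feats <- read.delim(path, header = FALSE, comment.char = "#",
                        col.names = c("contig", "start", "end", "strand",
                                      "kind", "label"),
                        colClasses = c("character", "integer", "integer",
                                       "character", "character", "character"))
    feats$kind[!feats$kind %in% kinds] <- "other"
  }
  validate_features(feats, genomes)
}

validate_features <- function(feats, genomes = NULL) {
  bad <- feats$start < 0 | feats$start >= feats$end
  if (any(bad))
    stop_fmt("feature %d: require 0 <= start < end", which(bad)[1])
  if (!is.null(genomes)) {
    for (i in seq_len(nrow(feats))) {
      ct <- feats$contig[i]
      if (!ct %in% names(genomes))
        stop_fmt("feature %d: unknown contig '%s'", i, ct)
      if (feats$end[i] > nchar(genomes[[ct]]))
        stop_fmt("feature %d: end %d beyond contig '%s' length %d",
                 i, feats$end[i], ct, nchar(genomes[[ct]]))
    }
  }
  rownames(feats) <- NULL
  feats
}

#' Write a feature table as 6-column TSV
#'
#' @param feats Feature `data.frame` (see [read_feature_table()]).
#' @param path Output path.
#' @export
write_feature_table <- function(feats, path) {
  write.table(feats[, c("contig", "start", "end", "strand", "kind", "label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# Canonical column order of the 12-column tabular homology-hit dialect.
HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular homology-hit file
#'
#' Parses the standard 12-column tabular layout (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) and joins per-query protein lengths from a side table, which
#' are required by the aligned-length filter.  Rows are preserved in
#' input order.  Subject ids of the form
#' `genome|contig|start-end|strand|prot` (as emitted by
#' [gen_homology_hits()]) are additionally decomposed into
#' `subject_genome`, `subject_contig`, `subject_start`, `subject_end` and
#' `subject_strand` columns; other subject ids leave those columns `NA`.
#'
#' @param path Path to the tabular hit file.
#' @param query_lengths Named numeric vector mapping `qseqid` to query
#'   protein length in amino acids.
#' @return `data.frame` with the 12 standard columns plus `query_len` and
#'   the decomposed subject-location columns.
#' @export
read_homology_table <- function(path, query_lengths) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  hits <- read.delim(path, header = FALSE, comment.char = "#",
                     col.names = HIT_COLUMNS,
                     colClasses = c("character", "character", "character",
                                    "integer", "integer", "integer",
                                    "integer", "integer", "integer",
                                    "integer", "character", "character"))
  for (col in c("pident", "evalue", "bitscore")) {
    v <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(v) && !anyNA(hits[[col]]))
      stop_fmt("%s line %d: non-numeric %s '%s'", path,
               which(is.na(v))[1], col, hits[[col]][which(is.na(v))[1]])
    hits[[col]] <- v
  }
  if (any(hits$evalue < 0)) stop_fmt("negative e-value in '%s'", path)
  if (any(hits$length < 1)) stop_fmt("aligned length < 1 in '%s'", path)
  miss <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(miss) > 0)
    stop_fmt("query length missing for: %s", paste(miss, collapse = ", "))
  hits$query_len <- as.numeric(query_lengths[hits$qseqid])
  cbind(hits, decode_subject_ids(hits$sseqid))
}

decode_subject_ids <- function(sseqid) {
  parts <- strsplit(sseqid, "|", fixed = TRUE)
  ok <- lengths(parts) == 5
  out <- data.frame(subject_genome = NA_character_,
                    subject_contig = NA_character_,
                    subject_start = NA_integer_, subject_end = NA_integer_,
                    subject_strand = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, length(sseqid)), ]
  if (any(ok)) {
    m <- do.call(rbind, parts[ok])
    coords <- do.call(rbind, strsplit(m[, 3], "-", fixed = TRUE))
    out$subject_genome[ok] <- m[, 1]
    out$subject_contig[ok] <- m[, 2]
    out$subject_start[ok] <- as.integer(coords[, 1])
    out$subject_end[ok] <- as.integer(coords[, 2])
    out$subject_strand[ok] <- m[, 4]
  }
  rownames(out) <- NULL
  out
}

#' Write homology hits in the 12-column tabular dialect
#'
#' @param hits Hit `data.frame` carrying at least the 12 standard columns.
#' @param path Output path.
#' @export
write_homology_table <- function(hits, path) {
  write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Validates that the tree has at least two uniquely labelled leaves and
#' branch lengths, then writes standard Newick terminated by `;`.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop_fmt("tree must be a 'phylo' object")
  if (length(tree$tip.label) < 2) stop_fmt("tree must have >= 2 leaves")
  if (anyDuplicated(tree$tip.label))
    stop_fmt("duplicate leaf labels: %s",
             paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                   collapse = ", "))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop_fmt("tree must have finite branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}
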