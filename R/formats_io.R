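# Readers and writers for the external tables the pipeline touches.
# All genomic coordinates are BED-style internally: 0-based, half-open.

.check_interval <- function(chrom, start, end, where = "") {
  bad <- which(is.na(chrom) | !nzchar(chrom))
  if (length(bad) > 0L)
    stop("empty chromosome name", where, " (row ", bad[1L], ")", call. = FALSE)
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad) > 0L)
    stop("invalid interval (need 0 <= start < end)", where,
         " (row ", bad[1L], ")", call. = FALSE)
  invisible(TRUE)
}

#' Read eccDNA intervals from a BED file
#'
#' Parses BED3/BED4 (tab-separated: chrom, start, end, optional name) into a
#' table of eccDNA records. Coordinates are kept verbatim in BED semantics
#' (0-based, half-open). When the name column is absent, identifiers
#' `ecc_0`, `ecc_1`, ... are synthesized in file order.
#'
#' @param path Path to a BED3+ file. Lines starting with `#`, `track` or
#'   `browser` are skipped.
#' @param dataset Dataset / cancer-type label attached to every record.
#' @return A data.frame with columns `chrom`, `start`, `end`, `ecc_id`,
#'   `dataset`, one row per eccDNA, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr11\t100\t1000\te1", "chr11\t2000\t5000\te2"), bed)
#' read_ecc_bed(bed, dataset = "demo")
#' @export
read_ecc_bed <- function(path, dataset = "default") {
  if (!file.exists(path)) stop("eccDNA BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      ecc_id = character(), dataset = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 columns",
         call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L)
    stop("BED line ", lineno[bad[1L]], ": non-integer coordinates", call. = FALSE)
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0L)
    stop("BED line ", lineno[bad[1L]], ": end <= start (or negative start)",
         call. = FALSE)
  ids <- ifelse(nf >= 4L,
                vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                       character(1)),
                NA_character_)
  ids[is.na(ids) | !nzchar(ids)] <- paste0("ecc_", which(is.na(ids) | !nzchar(ids)) - 1L)
  if (anyDuplicated(ids))
    stop("duplicate eccDNA ids within dataset: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  data.frame(chrom = chrom, start = start, end = end, ecc_id = ids,
             dataset = dataset, stringsAsFactors = FALSE)
}

#' Read an enhancer table with scored candidate target genes
#'
#' Reads a tab-separated table with columns `chrom`, `start`, `end`,
#' `enh_id`, `gene_id`, `score` (one row per enhancer-target pair; a
#' GeneHancer-like export). Rows are grouped by enhancer and the targets of
#' each enhancer are ordered by gene-enhancer interaction score (S_GE)
#' descending, ties by gene id ascending, so the first row per enhancer is
#' its top-1 target.
#'
#' @param path Path to the TSV file (header optional; detected by a
#'   non-numeric `start` field in line 1).
#' @return A data.frame with columns `chrom`, `start`, `end`, `enh_id`,
#'   `gene_id`, `score`, grouped by enhancer (first appearance order) and
#'   sorted within enhancer as above.
#' @export
read_enhancers <- function(path) {
  if (!file.exists(path)) stop("enhancer file not found: ", path, call. = FALSE)
  df <- .read_tsv_optheader(path, c("chrom", "start", "end", "enh_id", "gene_id", "score"))
  if (nrow(df) == 0L) return(df)
  df$start <- .as_num_or_stop(df$start, "enhancer start")
  df$end <- .as_num_or_stop(df$end, "enhancer end")
  df$score <- .as_num_or_stop(df$score, "S_GE score")
  .check_interval(df$chrom, df$start, df$end, " in enhancer table")
  if (any(!is.finite(df$score) | df$score < 0))
    stop("S_GE scores must be finite and >= 0", call. = FALSE)
  coords <- split(paste(df$chrom, df$start, df$end), df$enh_id)
  inconsistent <- names(coords)[vapply(coords, function(x) length(unique(x)) > 1L, logical(1))]
  if (length(inconsistent) > 0L)
    stop("enhancer ", inconsistent[1L],
         " has inconsistent coordinates across its rows", call. = FALSE)
  grp <- match(df$enh_id, unique(df$enh_id))
  df <- df[order(grp, -df$score, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.read_tsv_optheader <- function(path, cols, numeric_col = 2L) {
  # header detected by probing a column that must be numeric in data rows
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][numeric_col])))
  df <- tryCatch(
    read.table(path, sep = "\t", header = has_header, stringsAsFactors = FALSE,
               quote = "", comment.char = "#", colClasses = "character"),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    return(df)
  }
  if (ncol(df) < length(cols))
    stop("expected ", length(cols), " columns (", paste(cols, collapse = ", "),
         ") in ", path, call. = FALSE)
  df <- df[, seq_along(cols), drop = FALSE]
  names(df) <- cols
  df
}

.as_num_or_stop <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out))
    stop("non-numeric ", what, ": '", x[which(is.na(out))[1L]], "'", call. = FALSE)
  out
}

#' Read a transcript annotation
#'
#' Accepts either a 6/7-column TSV (`chrom`, `start`, `end`, `strand`,
#' `transcript_id`, `gene_id`, optional `biotype`; BED-style 0-based
#' half-open coordinates) or a GTF/GFF file (1-based closed coordinates,
#' converted on read; requires the rtracklayer package). Strand must be
#' `+`, `-` or `*`/`.` (unknown).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"gtf"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `gene_id`, `biotype` (BED semantics).
#' @export
read_transcripts <- function(path, format = c("tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("transcript file not found: ", path, call. = FALSE)
  if (format == "gtf") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF requires the rtracklayer package", call. = FALSE)
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "transcript"]
    bt <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) gr$gene_biotype
          else if ("transcript_biotype" %in% names(S4Vectors::mcols(gr))) gr$transcript_biotype
          else NA_character_
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     transcript_id = gr$transcript_id,
                     gene_id = gr$gene_id,
                     biotype = bt,
                     stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv_optheader(path, c("chrom", "start", "end", "strand",
                                      "transcript_id", "gene_id"))
    raw <- read.table(path, sep = "\t", header = FALSE, nrows = 1L,
                      stringsAsFactors = FALSE, quote = "")
    full <- tryCatch(
      read.table(path, sep = "\t",
                 header = is.na(suppressWarnings(as.numeric(raw[[2L]]))),
                 stringsAsFactors = FALSE, quote = "", comment.char = "#",
                 colClasses = "character"),
      error = function(e) NULL)
    if (!is.null(full) && ncol(full) >= 7L) df$biotype <- full[[7L]]
    else df$biotype <- NA_character_
    if (nrow(df) > 0L) {
      df$start <- .as_num_or_stop(df$start, "transcript start")
      df$end <- .as_num_or_stop(df$end, "transcript end")
    }
  }
  if (nrow(df) > 0L) {
    df$strand[df$strand %in% c(".", "")] <- "*"
    bad <- !df$strand %in% c("+", "-", "*")
    if (any(bad)) stop("invalid strand '", df$strand[bad][1L], "'", call. = FALSE)
    if (any(is.na(df$gene_id) | !nzchar(df$gene_id)))
      stop("transcript with empty gene_id", call. = FALSE)
    .check_interval(df$chrom, df$start, df$end, " in transcript table")
  }
  df
}

#' Read a weighted PPI edge list
#'
#' Reads a tab-separated edge list (`gene_a`, `gene_b`, `confidence`),
#' drops edges below a confidence threshold on the file's native scale,
#' removes self-loops, and collapses duplicate/reciprocal edges into one
#' undirected edge keeping the maximum confidence.
#'
#' @param path Path to the TSV edge list.
#' @param min_confidence Minimum confidence to retain an edge; default 700
#'   on a STRING-like 0-1000 scale.
#' @return A data.frame with columns `gene_a`, `gene_b`, `confidence`
#'   (one row per undirected edge, `gene_a` < `gene_b`, sorted).
#' @export
read_ppi <- function(path, min_confidence = 700) {
  if (!file.exists(path)) stop("PPI file not found: ", path, call. = FALSE)
  df <- .read_tsv_optheader(path, c("gene_a", "gene_b", "confidence"),
                            numeric_col = 3L)
  if (nrow(df) > 0L) df$confidence <- .as_num_or_stop(df$confidence, "confidence")
  ppi_edges(df, min_confidence = min_confidence)
}

#' Normalize a PPI edge table
#'
#' Applies the confidence threshold, self-loop removal and undirected
#' deduplication rules to an in-memory edge data.frame (columns `gene_a`,
#' `gene_b`, `confidence`).
#'
#' @inheritParams read_ppi
#' @param edges A data.frame of edges.
#' @return A normalized edge data.frame (see [read_ppi()]).
#' @export
ppi_edges <- function(edges, min_confidence = 0) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (nrow(edges) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  if (any(is.na(edges$gene_a) | !nzchar(edges$gene_a) |
          is.na(edges$gene_b) | !nzchar(edges$gene_b)))
    stop("empty node name in PPI edge list", call. = FALSE)
  edges <- edges[edges$confidence >= min_confidence, , drop = FALSE]
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(edges$confidence, key, max)
  keys <- sort(names(conf))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[[`, character(1), 1L),
             gene_b = vapply(parts, `[[`, character(1), 2L),
             confidence = as.numeric(conf[keys]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a differential-expression table or a bare gene list
#'
#' A 3-column TSV (`gene_id`, `log2FC`, `q_value`) is read as a DEG table;
#' a 1-column file is read as a precomputed gene list (returned as a
#' data.frame with `log2FC` and `q_value` set to `NA`).
#'
#' @param path Path to the file.
#' @return A data.frame with columns `gene_id`, `log2FC`, `q_value`.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("DEG file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  ncols <- length(strsplit(first, "\t", fixed = TRUE)[[1L]])
  if (ncols == 1L) {
    genes <- readLines(path)
    genes <- trimws(genes[nzchar(trimws(genes))])
    if (identical(tolower(genes[1L]), "gene_id")) genes <- genes[-1L]
    return(data.frame(gene_id = genes, log2FC = NA_real_, q_value = NA_real_,
                      stringsAsFactors = FALSE))
  }
  df <- .read_tsv_optheader(path, c("gene_id", "log2FC", "q_value"))
  if (nrow(df) > 0L) {
    df$log2FC <- .as_num_or_stop(df$log2FC, "log2FC")
    df$q_value <- .as_num_or_stop(df$q_value, "q_value")
    if (any(df$q_value < 0 | df$q_value > 1))
      stop("q_value outside [0, 1]", call. = FALSE)
    if (anyDuplicated(df$gene_id))
      stop("duplicate gene in DEG table: ",
           df$gene_id[duplicated(df$gene_id)][1L], call. = FALSE)
  }
  df
}

#' Read a genes-by-samples expression matrix
#'
#' @param path Tab-separated matrix with gene ids in the first column and
#'   sample ids in the header.
#' @return A numeric matrix (genes in rows, samples in columns).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in expression matrix", call. = FALSE)
  m
}

#' Write a table deterministically
#'
#' Writes a tab-separated file with a header, no quoting and no row names,
#' so repeated runs over the same data are byte-identical. Callers sort
#' rows before writing; this function does not reorder.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write eccDNA records back to BED4
#'
#' @param ecc A data.frame as returned by [read_ecc_bed()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ecc_bed <- function(ecc, path) {
  writeLines(paste(ecc$chrom, ecc$start, ecc$end, ecc$ecc_id, sep = "\t"), path)
  invisible(path)
}
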