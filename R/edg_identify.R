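# EDG calling: full-containment tests, transcript padding, EEG/ERG/EDG
# calls, biotype partition and the cross-dataset CEDG intersection.

.granges_from_bed <- function(df) {
  # internal BED (0-based half-open) -> IRanges (1-based closed)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

#' Find elements contained in (or overlapping) eccDNA intervals
#'
#' The "full" strategy requires the entire element to lie on the eccDNA
#' (same chromosome, `ecc.start <= elem.start` and `elem.end <= ecc.end`);
#' the "partial" strategy of overlap-based methods requires at least 1 bp
#' of overlap. Strand is ignored for containment.
#'
#' @param eccdnas Data.frame of eccDNA records (`chrom`, `start`, `end`,
#'   `ecc_id`).
#' @param elements Data.frame of elements (`chrom`, `start`, `end`) plus an
#'   identifier column named by `id_col`.
#' @param mode `"full"` (strict containment, default) or `"partial"`
#'   (>= 1 bp overlap).
#' @param id_col Name of the element identifier column.
#' @return A data.frame with columns `ecc_id`, `element_id`, one row per
#'   (eccDNA, element) pair satisfying the mode, ordered by `ecc_id` then
#'   `element_id`.
#' @examples
#' ecc <- data.frame(chrom = "chr1", start = 100, end = 1000, ecc_id = "e1")
#' enh <- data.frame(chrom = "chr1", start = 200, end = 300, enh_id = "E1")
#' contained_elements(ecc, enh, mode = "full", id_col = "enh_id")
#' @export
contained_elements <- function(eccdnas, elements, mode = c("full", "partial"),
                               id_col = "element_id") {
  mode <- match.arg(mode)
  empty <- data.frame(ecc_id = character(), element_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(eccdnas) == 0L || nrow(elements) == 0L) return(empty)
  stopifnot(id_col %in% names(elements))
  hits <- GenomicRanges::findOverlaps(
    .granges_from_bed(elements), .granges_from_bed(eccdnas),
    type = if (mode == "full") "within" else "any",
    minoverlap = 1L)
  if (length(hits) == 0L) return(empty)
  out <- data.frame(
    ecc_id = eccdnas$ecc_id[S4Vectors::subjectHits(hits)],
    element_id = elements[[id_col]][S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$ecc_id, out$element_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pad transcripts upstream of the transcription start site
#'
#' Extends each transcript by `pad_bp` base pairs upstream of its TSS:
#' on the `+` strand the start moves left (clamped at 0), on the `-`
#' strand the end moves right. The pad models the minimal core promoter
#' needed for transcription initiation; the default of 35 bp follows
#' base-pair-resolution models of human promoter initiation activity.
#'
#' @param transcripts Data.frame with `chrom`, `start`, `end`, `strand`
#'   (BED semantics; strand `+`, `-` or `*`).
#' @param pad_bp Non-negative pad in bp (default 35).
#' @param assume_plus If `TRUE`, transcripts with unknown strand (`*`) are
#'   padded as `+` with a warning; if `FALSE` (default) they are an error.
#' @return The input data.frame with `start`/`end` replaced by the padded
#'   coordinates.
#' @export
pad_transcript <- function(transcripts, pad_bp = 35, assume_plus = FALSE) {
  stopifnot(pad_bp >= 0)
  if (nrow(transcripts) == 0L) return(transcripts)
  strand <- transcripts$strand
  unk <- strand == "*"
  if (any(unk)) {
    if (!assume_plus)
      stop("transcript with unknown strand; set assume_plus = TRUE to pad ",
           "such transcripts as '+'", call. = FALSE)
    warning(sum(unk), " transcript(s) with unknown strand padded as '+'",
            call. = FALSE)
    strand[unk] <- "+"
  }
  out <- transcripts
  plus <- strand == "+"
  out$start[plus] <- pmax(0, out$start[plus] - pad_bp)
  out$end[!plus] <- out$end[!plus] + pad_bp
  out
}

#' Call eccDNA-encoded genes (EEGs)
#'
#' A gene is an EEG when any of its transcripts, padded `pad_bp` bp
#' upstream of the TSS, lies entirely (mode `"full"`) on at least one
#' eccDNA of the dataset.
#'
#' @inheritParams contained_elements
#' @inheritParams pad_transcript
#' @param transcripts Transcript table as from [read_transcripts()].
#' @return A list with `genes` (sorted character vector) and `evidence`
#'   (data.frame `gene_id`, `transcript_id`, `ecc_id`, one row per
#'   supporting pair).
#' @export
call_eegs <- function(eccdnas, transcripts, pad_bp = 35,
                      mode = c("full", "partial"), assume_plus = FALSE) {
  mode <- match.arg(mode)
  empty <- list(genes = character(),
                evidence = data.frame(gene_id = character(),
                                      transcript_id = character(),
                                      ecc_id = character(),
                                      stringsAsFactors = FALSE))
  if (nrow(eccdnas) == 0L || nrow(transcripts) == 0L) return(empty)
  padded <- pad_transcript(transcripts, pad_bp = pad_bp, assume_plus = assume_plus)
  pairs <- contained_elements(eccdnas, padded, mode = mode,
                              id_col = "transcript_id")
  if (nrow(pairs) == 0L) return(empty)
  ev <- data.frame(
    gene_id = transcripts$gene_id[match(pairs$element_id, transcripts$transcript_id)],
    transcript_id = pairs$element_id,
    ecc_id = pairs$ecc_id,
    stringsAsFactors = FALSE)
  ev <- ev[order(ev$gene_id, ev$transcript_id, ev$ecc_id), , drop = FALSE]
  rownames(ev) <- NULL
  list(genes = sort(unique(ev$gene_id)), evidence = ev)
}

#' Call eccDNA-regulated genes (ERGs)
#'
#' For every enhancer lying entirely (mode `"full"`) on an eccDNA, the
#' single candidate target with the highest gene-enhancer interaction
#' score (S_GE) is called an ERG; score ties are broken by ascending gene
#' id. Genes targeted by several contained enhancers are reported once
#' with merged evidence.
#'
#' @inheritParams contained_elements
#' @param enhancers Enhancer table as from [read_enhancers()] (one row per
#'   enhancer-target pair, targets sorted by score descending then gene id).
#' @return A list with `genes` (sorted character vector) and `evidence`
#'   (data.frame `gene_id`, `enh_id`, `ecc_id`, `score`).
#' @export
call_ergs <- function(eccdnas, enhancers, mode = c("full", "partial")) {
  mode <- match.arg(mode)
  empty <- list(genes = character(),
                evidence = data.frame(gene_id = character(),
                                      enh_id = character(),
                                      ecc_id = character(),
                                      score = numeric(),
                                      stringsAsFactors = FALSE))
  if (nrow(eccdnas) == 0L || nrow(enhancers) == 0L) return(empty)
  # top-1 target per enhancer: highest S_GE, ties by ascending gene_id
  o <- order(enhancers$enh_id, -enhancers$score, enhancers$gene_id)
  sorted <- enhancers[o, , drop = FALSE]
  top1 <- sorted[!duplicated(sorted$enh_id), , drop = FALSE]
  uniq <- top1[, c("chrom", "start", "end", "enh_id")]
  pairs <- contained_elements(eccdnas, uniq, mode = mode, id_col = "enh_id")
  if (nrow(pairs) == 0L) return(empty)
  idx <- match(pairs$element_id, top1$enh_id)
  ev <- data.frame(gene_id = top1$gene_id[idx],
                   enh_id = pairs$element_id,
                   ecc_id = pairs$ecc_id,
                   score = top1$score[idx],
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$gene_id, ev$enh_id, ev$ecc_id), , drop = FALSE]
  rownames(ev) <- NULL
  list(genes = sort(unique(ev$gene_id)), evidence = ev)
}

#' Call eccDNA-driven genes (EDGs) for one dataset
#'
#' EDGs are the union of EEGs and ERGs. Protein-coding EDGs form the
#' "coding" partition used for downstream analysis; all other biotypes
#' (and genes missing from the biotype table, with a warning) form the
#' "non_coding" partition.
#'
#' @inheritParams call_eegs
#' @inheritParams call_ergs
#' @param biotypes Either a data.frame with columns `gene_id`, `biotype`
#'   or a named character vector mapping gene id to biotype.
#' @param dataset Dataset label stored in the catalog.
#' @return An object of class `edg_catalog`: a list with `dataset`,
#'   `calls` (data.frame `gene_id`, `classes`, `biotype`, `coding`,
#'   `n_supporting_ecc`, `supporting_elements`), `coding` / `non_coding`
#'   gene vectors, and the raw `eeg` / `erg` evidence.
#' @export
call_edgs <- function(eccdnas, transcripts, enhancers, biotypes,
                      pad_bp = 35, mode = c("full", "partial"),
                      dataset = "default", assume_plus = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(biotypes)) {
    biomap <- setNames(biotypes$biotype, biotypes$gene_id)
  } else {
    biomap <- biotypes
  }
  eeg <- call_eegs(eccdnas, transcripts, pad_bp = pad_bp, mode = mode,
                   assume_plus = assume_plus)
  erg <- if (is.null(enhancers) || nrow(enhancers) == 0L) {
    list(genes = character(),
         evidence = data.frame(gene_id = character(), enh_id = character(),
                               ecc_id = character(), score = numeric(),
                               stringsAsFactors = FALSE))
  } else {
    call_ergs(eccdnas, enhancers, mode = mode)
  }
  genes <- sort(unique(c(eeg$genes, erg$genes)))
  if (length(genes) > 0L) {
    classes <- vapply(genes, function(g) {
      paste(c(if (g %in% eeg$genes) "EEG", if (g %in% erg$genes) "ERG"),
            collapse = ";")
    }, character(1))
    bt <- unname(biomap[genes])
    missing_bt <- is.na(bt)
    if (any(missing_bt)) {
      warning(sum(missing_bt), " EDG(s) missing from the biotype table; ",
              "assigned to the non-coding partition", call. = FALSE)
      bt[missing_bt] <- "unknown"
    }
    ecc_by_gene <- lapply(genes, function(g) {
      sort(unique(c(eeg$evidence$ecc_id[eeg$evidence$gene_id == g],
                    erg$evidence$ecc_id[erg$evidence$gene_id == g])))
    })
    elem_by_gene <- lapply(genes, function(g) {
      sort(unique(c(eeg$evidence$transcript_id[eeg$evidence$gene_id == g],
                    erg$evidence$enh_id[erg$evidence$gene_id == g])))
    })
    calls <- data.frame(
      gene_id = genes,
      classes = classes,
      biotype = bt,
      coding = bt == "protein_coding",
      n_supporting_ecc = lengths(ecc_by_gene),
      supporting_elements = vapply(elem_by_gene, paste, character(1),
                                   collapse = ";"),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    calls <- data.frame(gene_id = character(), classes = character(),
                        biotype = character(), coding = logical(),
                        n_supporting_ecc = integer(),
                        supporting_elements = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(dataset = dataset, calls = calls,
                 coding = calls$gene_id[calls$coding],
                 non_coding = calls$gene_id[!calls$coding],
                 eeg = eeg, erg = erg, mode = mode, pad_bp = pad_bp),
            class = "edg_catalog")
}

#' @export
print.edg_catalog <- function(x, ...) {
  cat("EDG catalog [", x$dataset, "] mode=", x$mode, " pad=", x$pad_bp,
      " bp\n", sep = "")
  cat("  ", nrow(x$calls), " EDGs (", length(x$coding), " coding, ",
      length(x$non_coding), " non-coding); ",
      length(x$eeg$genes), " EEGs, ", length(x$erg$genes), " ERGs\n", sep = "")
  invisible(x)
}

#' Intersect coding EDG calls across datasets into common EDGs (CEDGs)
#'
#' A gene is a common EDG when its coding EDG status recurs in more than
#' (`strict = TRUE`, default) or at least (`strict = FALSE`) a fraction
#' `min_fraction` of the datasets. `min_fraction = 1, strict = FALSE`
#' gives the exact intersection.
#'
#' @param catalogs A list of `edg_catalog` objects from [call_edgs()],
#'   one per dataset (at least two).
#' @param min_fraction Fraction of datasets required, in (0, 1].
#' @param strict If `TRUE`, require strictly more than `min_fraction`.
#' @return A sorted character vector of common coding EDG gene ids.
#' @export
common_edgs <- function(catalogs, min_fraction = 0.5, strict = TRUE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (length(catalogs) < 2L)
    stop("common_edgs needs >= 2 dataset catalogs; ",
         "use call_edgs for a single dataset", call. = FALSE)
  coding_sets <- lapply(catalogs, function(ct) unique(ct$coding))
  tab <- table(unlist(coding_sets))
  frac <- as.numeric(tab) / length(catalogs)
  keep <- if (strict) frac > min_fraction else frac >= min_fraction
  sort(names(tab)[keep])
}
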