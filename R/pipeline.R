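# Configured end-to-end run: EDG calling per dataset, cross-dataset
# intersection, driver ranking, and optional benchmarking / signature
# scoring, with every effective parameter logged in a run manifest.

.default_config <- function() {
  list(mode = "full", pad_bp = 35, min_confidence = 700,
       lfc_threshold = 1.0, q_threshold = 0.01, top_m = 100,
       min_fraction = 0.5, strict_fraction = TRUE, restrict_to_local = TRUE,
       seed = 1)
}

#' Read a flat key=value run-configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines are
#' skipped. Values that parse as numbers become numeric; `true`/`false`
#' become logical.
#'
#' @param path Path to the file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}

# polynomial rolling hash of the deparsed effective configuration;
# provenance tag only, not cryptographic
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline from a configuration
#'
#' Executes EDG calling for each eccDNA dataset, optionally intersects the
#' coding calls into common EDGs, ranks candidate drivers by EGIS, and
#' optionally benchmarks the candidates and scores an expression matrix
#' with the 17-gene signature. All outputs are tab-separated files in
#' `out_dir` plus a `manifest.json` recording every effective parameter,
#' a configuration hash, and the files written.
#'
#' Configuration keys (defaults in parentheses): `ecc` (named character
#' vector or list of BED paths, one per dataset), `transcripts`,
#' `enhancers`, `biotypes`, `ppi`, `deg` (file paths), optional
#' `benchmark` (truth gene list) and `expression`; `mode` ("full"),
#' `pad_bp` (35), `min_confidence` (700), `lfc_threshold` (1),
#' `q_threshold` (0.01), `top_m` (100), `min_fraction` (0.5), `seed` (1).
#'
#' @param config Named list (or a path read with [read_run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  eff <- utils::modifyList(.default_config(), config)
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in c("transcripts", "ppi", "deg")) {
    if (is.null(eff[[key]]))
      stop("missing required config key: ", key, call. = FALSE)
  }
  paths <- unlist(eff[names(eff) %in%
                        c("ecc", "transcripts", "enhancers", "biotypes",
                          "ppi", "deg", "benchmark", "expression")])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file not found: ", missing[1L], call. = FALSE)

  transcripts <- read_transcripts(eff$transcripts)
  enhancers <- if (is.null(eff$enhancers)) NULL else read_enhancers(eff$enhancers)
  biotypes <- if (is.null(eff$biotypes)) {
    setNames(transcripts$biotype, transcripts$gene_id)
  } else {
    bt <- read.table(eff$biotypes, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    setNames(bt$biotype, bt$gene_id)
  }
  ecc_paths <- eff$ecc
  if (is.null(names(ecc_paths)) || any(!nzchar(names(ecc_paths))))
    names(ecc_paths) <- paste0("dataset_", seq_along(ecc_paths))
  outputs <- character()
  catalogs <- list()
  for (ds in names(ecc_paths)) {
    ecc <- read_ecc_bed(ecc_paths[[ds]], dataset = ds)
    ct <- call_edgs(ecc, transcripts, enhancers, biotypes,
                    pad_bp = eff$pad_bp, mode = eff$mode, dataset = ds)
    p <- file.path(out_dir, paste0("edg_calls.", ds, ".tsv"))
    calls <- ct$calls
    calls$dataset <- ds
    write_tsv(calls[order(calls$gene_id), , drop = FALSE], p)
    outputs <- c(outputs, p)
    catalogs[[ds]] <- ct
  }
  if (length(catalogs) >= 2L) {
    cedg <- common_edgs(catalogs, min_fraction = eff$min_fraction,
                        strict = isTRUE(eff$strict_fraction))
    p <- file.path(out_dir, "common_edgs.txt")
    writeLines(cedg, p)
    outputs <- c(outputs, p)
  }
  edg_union <- sort(unique(unlist(lapply(catalogs, `[[`, "coding"))))
  ppi <- ppi_graph(read_ppi(eff$ppi, min_confidence = eff$min_confidence))
  deg <- read_deg_table(eff$deg)
  ranking <- rank_drivers(edg_union, ppi, deg, top_m = eff$top_m,
                          lfc_threshold = eff$lfc_threshold,
                          q_threshold = eff$q_threshold,
                          restrict_to_local = isTRUE(eff$restrict_to_local))
  p <- file.path(out_dir, "driver_rank.tsv")
  write_tsv(as.data.frame(ranking), p)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "driver_rank.top.tsv")
  write_tsv(as.data.frame(ranking)[ranking$candidate, , drop = FALSE], p)
  outputs <- c(outputs, p)
  bench <- NULL
  if (!is.null(eff$benchmark)) {
    truth <- readLines(eff$benchmark)
    truth <- trimws(truth[nzchar(trimws(truth))])
    universe <- igraph::V(ppi)$name
    bench <- confusion_metrics(ranking$gene_id[ranking$candidate],
                               truth, universe)
    p <- file.path(out_dir, "benchmark.tsv")
    write_tsv(data.frame(metric = c("TP", "FP", "FN", "TN", "accuracy",
                                    "precision", "recall"),
                         value = c(bench$TP, bench$FP, bench$FN, bench$TN,
                                   bench$accuracy, bench$precision,
                                   bench$recall)), p)
    outputs <- c(outputs, p)
  }
  if (!is.null(eff$expression)) {
    expr <- read_expression(eff$expression)
    risk <- score_signature(expr, strict = FALSE)
    p <- file.path(out_dir, "cedg_risk.tsv")
    write_tsv(risk[order(risk$sample_id), , drop = FALSE], p)
    outputs <- c(outputs, p)
  }
  manifest <- list(
    config = eff[order(names(eff))],
    config_hash = .config_hash(eff[order(names(eff))]),
    n_datasets = length(catalogs),
    n_edgs = length(edg_union),
    n_candidates = sum(ranking$candidate),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
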