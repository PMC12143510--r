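# Seeded generators for every input the pipeline consumes, with planted
# structure (contained elements, partial-overlap decoys, a DEG-enriched
# driver, signature genes) so identification, ranking and scoring are
# testable end to end without external downloads.
#
# Each generator uses one explicitly seeded RNG stream and restores the
# caller's RNG state on exit, so generators are pure functions of their
# arguments.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of the structure planted into synthetic fixtures
#'
#' @param n_planted_eeg,n_planted_erg Numbers of genes made callable as
#'   EEG / ERG via full containment.
#' @param n_decoy_partial Number of elements overlapping an eccDNA by at
#'   least 1 bp without being contained (callable only in partial mode).
#' @param n_background Number of eccDNAs containing no element.
#' @param driver_gene Id of the planted high-influence EDG (assigned by
#'   [make_ppi_and_degs()] when `NULL`).
#' @param p_near Probability that a node within two hops of the driver is
#'   a DEG.
#' @param p_background DEG probability elsewhere; must be strictly below
#'   `p_near`.
#' @param driver_extra_degree Extra neighbors wired to the driver on top
#'   of the random graph.
#' @param seed RNG seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_planted_eeg = 3, n_planted_erg = 3,
                       n_decoy_partial = 2, n_background = 3,
                       driver_gene = NULL, p_near = 0.9,
                       p_background = 0.05, driver_extra_degree = 15,
                       seed = 1) {
  stopifnot(n_planted_eeg >= 0, n_planted_erg >= 0, n_decoy_partial >= 0,
            n_background >= 0, driver_extra_degree >= 0)
  if (!(p_background >= 0 && p_background < p_near && p_near <= 1))
    stop("need 0 <= p_background < p_near <= 1", call. = FALSE)
  structure(list(n_planted_eeg = n_planted_eeg, n_planted_erg = n_planted_erg,
                 n_decoy_partial = n_decoy_partial,
                 n_background = n_background, driver_gene = driver_gene,
                 p_near = p_near, p_background = p_background,
                 driver_extra_degree = driver_extra_degree, seed = seed),
            class = "plant_spec")
}

#' Generate a synthetic annotation: transcripts, biotypes and enhancers
#'
#' Places non-overlapping transcripts and enhancers by slab allocation
#' along one chromosome (each element sits alone inside its own slab, with
#' a 50 bp margin so upstream padding and planted eccDNA margins never
#' cross slab boundaries). Strands are random; about 80% of genes are
#' protein-coding; each enhancer receives 1-3 candidate targets with
#' distinct gene-enhancer interaction scores.
#'
#' @param n_genes Number of genes (one transcript each); >= 1.
#' @param chrom_length Chromosome length in bp.
#' @param seed RNG seed.
#' @param n_enhancers Number of enhancers (default `n_genes`).
#' @param prop_coding Proportion of protein-coding genes.
#' @param chrom Chromosome name.
#' @return A list with `transcripts`, `biotypes`, `enhancers` data.frames
#'   and the internal `slabs` table (used by [make_eccdna()]).
#' @export
make_annotation <- function(n_genes, chrom_length = 1e6, seed = 1,
                            n_enhancers = n_genes, prop_coding = 0.8,
                            chrom = "chrS") {
  stopifnot(n_genes >= 1, n_enhancers >= 0)
  n_slabs <- n_genes + n_enhancers
  slab_w <- floor(chrom_length / n_slabs)
  margin <- 50L
  if (slab_w < 2L * margin + 40L)
    stop("chromosome too short to place ", n_slabs,
         " non-overlapping elements", call. = FALSE)
  .with_seed(seed, {
    kind <- rep(c("gene", "enhancer"), length.out = n_slabs)
    kind[seq_len(n_slabs)] <- sample(c(rep("gene", n_genes),
                                       rep("enhancer", n_enhancers)))
    slab_start <- (seq_len(n_slabs) - 1L) * slab_w
    inner_w <- slab_w - 2L * margin
    len <- pmin(inner_w, 40L + floor(runif(n_slabs) * (inner_w - 39L)))
    offset <- floor(runif(n_slabs) * (inner_w - len + 1L))
    el_start <- slab_start + margin + offset
    el_end <- el_start + len
    gidx <- which(kind == "gene")
    eidx <- which(kind == "enhancer")
    gene_ids <- sprintf("G%03d", seq_along(gidx))
    transcripts <- data.frame(
      chrom = chrom, start = el_start[gidx], end = el_end[gidx],
      strand = sample(c("+", "-"), length(gidx), replace = TRUE),
      transcript_id = sprintf("T%03d", seq_along(gidx)),
      gene_id = gene_ids, biotype = NA_character_,
      stringsAsFactors = FALSE)
    biotypes <- data.frame(
      gene_id = gene_ids,
      biotype = ifelse(runif(length(gidx)) < prop_coding,
                       "protein_coding", "lncRNA"),
      stringsAsFactors = FALSE)
    transcripts$biotype <- biotypes$biotype
    enh_rows <- list()
    for (j in seq_along(eidx)) {
      k <- sample(1:3, 1L)
      targets <- sample(gene_ids, min(k, length(gene_ids)))
      scores <- round(sort(runif(length(targets), 1, 20), decreasing = TRUE) +
                        seq_along(targets) * 1e-3, 4)  # distinct by construction
      enh_rows[[j]] <- data.frame(
        chrom = chrom, start = el_start[eidx[j]], end = el_end[eidx[j]],
        enh_id = sprintf("E%03d", j), gene_id = targets, score = scores,
        stringsAsFactors = FALSE)
    }
    enhancers <- if (length(enh_rows) > 0L) do.call(rbind, enh_rows)
      else data.frame(chrom = character(), start = numeric(), end = numeric(),
                      enh_id = character(), gene_id = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    if (nrow(enhancers) > 0L) {
      grp <- match(enhancers$enh_id, unique(enhancers$enh_id))
      enhancers <- enhancers[order(grp, -enhancers$score, enhancers$gene_id), ,
                             drop = FALSE]
      rownames(enhancers) <- NULL
    }
    slabs <- data.frame(kind = kind, slab_start = slab_start,
                        slab_end = slab_start + slab_w,
                        el_start = el_start, el_end = el_end,
                        id = NA_character_, stringsAsFactors = FALSE)
    slabs$id[gidx] <- transcripts$transcript_id
    slabs$id[eidx] <- unique(enhancers$enh_id)[seq_along(eidx)]
    list(transcripts = transcripts, biotypes = biotypes,
         enhancers = enhancers, slabs = slabs, chrom = chrom,
         margin = margin)
  })
}

#' Generate eccDNA intervals with planted containment structure
#'
#' For each planted EEG, emits one eccDNA strictly containing the padded
#' transcript; for each planted ERG, one eccDNA strictly containing an
#' enhancer (whose top-scoring target becomes the expected ERG); for each
#' decoy, one eccDNA overlapping an element by >= 1 bp without containing
#' it (decoys alternate between transcripts and enhancers); plus
#' background eccDNAs containing nothing. Slab allocation guarantees no
#' accidental containment, so full-mode calls on the output equal the
#' planted truth exactly.
#'
#' @param annotation Output of [make_annotation()].
#' @param plant A [plant_spec()].
#' @param pad_bp Upstream pad the EEG eccDNAs must cover (default 35).
#' @param dataset Dataset label for the records.
#' @return A list with `eccdnas` (data.frame `chrom`, `start`, `end`,
#'   `ecc_id`, `dataset`) and `truth` (list `eeg_genes`, `erg_genes`,
#'   `decoy_transcripts`, `decoy_enhancers`, plus the partial-only gene
#'   sets `partial_extra_eeg` / `partial_extra_erg` the decoys add).
#' @export
make_eccdna <- function(annotation, plant, pad_bp = 35, dataset = "synthetic") {
  stopifnot(inherits(plant, "plant_spec"))
  tx <- annotation$transcripts
  enh <- annotation$enhancers
  enh_ids <- unique(enh$enh_id)
  top1 <- enh[!duplicated(enh$enh_id), , drop = FALSE]  # pre-sorted by score
  n_decoy_tx <- ceiling(plant$n_decoy_partial / 2)
  n_decoy_enh <- plant$n_decoy_partial - n_decoy_tx
  if (plant$n_planted_eeg + n_decoy_tx > nrow(tx))
    stop("not enough transcripts for the requested plants and decoys",
         call. = FALSE)
  if (plant$n_planted_erg + n_decoy_enh > length(enh_ids))
    stop("not enough enhancers for the requested plants and decoys",
         call. = FALSE)
  .with_seed(plant$seed + 1L, {
    tx_pick <- sample(seq_len(nrow(tx)), plant$n_planted_eeg + n_decoy_tx)
    eeg_tx <- tx_pick[seq_len(plant$n_planted_eeg)]
    decoy_tx <- setdiff(tx_pick, eeg_tx)
    enh_pick <- sample(seq_along(enh_ids), plant$n_planted_erg + n_decoy_enh)
    erg_enh <- enh_pick[seq_len(plant$n_planted_erg)]
    decoy_enh <- setdiff(enh_pick, erg_enh)
    rows <- list()
    add <- function(start, end) {
      rows[[length(rows) + 1L]] <<- c(start, end)
    }
    truth_decoy_tx <- character()
    truth_decoy_enh <- character()
    for (i in eeg_tx) {
      # cover transcript plus the upstream pad, with a strict margin
      pad_lo <- if (tx$strand[i] == "+") pad_bp else 0L
      pad_hi <- if (tx$strand[i] == "-") pad_bp else 0L
      m <- sample(1:10, 2L, replace = TRUE)
      add(max(0, tx$start[i] - pad_lo - m[1L]), tx$end[i] + pad_hi + m[2L])
    }
    for (j in erg_enh) {
      e <- top1[top1$enh_id == enh_ids[j], ]
      m <- sample(1:10, 2L, replace = TRUE)
      add(max(0, e$start - m[1L]), e$end + m[2L])
    }
    for (i in decoy_tx) {
      # overlap the transcript body by >= 1 bp from the left, never contain
      cut <- tx$start[i] + max(1L, floor((tx$end[i] - tx$start[i]) / 2))
      add(max(0, tx$start[i] - sample(1:10, 1L)), cut)
      truth_decoy_tx <- c(truth_decoy_tx, tx$transcript_id[i])
    }
    for (j in decoy_enh) {
      e <- top1[top1$enh_id == enh_ids[j], ]
      cut <- e$start + max(1L, floor((e$end - e$start) / 2))
      add(max(0, e$start - sample(1:10, 1L)), cut)
      truth_decoy_enh <- c(truth_decoy_enh, e$enh_id)
    }
    # background circles inside inter-slab margins: contain nothing
    slabs <- annotation$slabs
    for (b in seq_len(min(plant$n_background, nrow(slabs)))) {
      s <- slabs[b, ]
      add(s$slab_start + 2L, s$slab_start + 2L + sample(10:30, 1L))
    }
    mat <- do.call(rbind, rows)
    eccdnas <- data.frame(
      chrom = annotation$chrom, start = as.integer(mat[, 1L]),
      end = as.integer(mat[, 2L]),
      ecc_id = sprintf("ecc_%03d", seq_len(nrow(mat)) - 1L),
      dataset = dataset, stringsAsFactors = FALSE)
    decoy_top <- top1$gene_id[match(truth_decoy_enh, top1$enh_id)]
    truth <- list(
      eeg_genes = sort(unique(tx$gene_id[eeg_tx])),
      erg_genes = sort(unique(top1$gene_id[match(enh_ids[erg_enh],
                                                 top1$enh_id)])),
      decoy_transcripts = truth_decoy_tx,
      decoy_enhancers = truth_decoy_enh,
      partial_extra_eeg = sort(unique(tx$gene_id[decoy_tx])),
      partial_extra_erg = sort(unique(decoy_top)))
    list(eccdnas = eccdnas, truth = truth)
  })
}

#' Generate a random PPI network with a planted DEG-enriched driver
#'
#' Draws an Erdős–Rényi (or preferential-attachment) graph, wires the
#' planted driver to extra neighbors, labels nodes as DEGs with
#' probability `p_near` within two hops of the driver and `p_background`
#' elsewhere, and synthesizes log2 fold changes and q-values consistent
#' with the labels under the strict thresholds |log2FC| > 1 and q < 0.01.
#'
#' @param n_nodes Number of genes (>= 3).
#' @param mean_degree Average degree of the random graph; must be below
#'   `n_nodes`.
#' @param plant A [plant_spec()]; `driver_gene` defaults to the first
#'   node.
#' @param model `"erdos_renyi"` (default) or `"preferential"`.
#' @return A list with `edges` (data.frame `gene_a`, `gene_b`,
#'   `confidence` on a 0-1000 scale), `deg_table` (`gene_id`, `log2FC`,
#'   `q_value`), `driver` (gene id), `deg_genes` (planted DEG labels) and
#'   `graph` (the igraph).
#' @export
make_ppi_and_degs <- function(n_nodes = 200, mean_degree = 6, plant = plant_spec(),
                              model = c("erdos_renyi", "preferential")) {
  model <- match.arg(model)
  stopifnot(inherits(plant, "plant_spec"), n_nodes >= 3)
  if (mean_degree >= n_nodes)
    stop("mean_degree must be below n_nodes", call. = FALSE)
  .with_seed(plant$seed + 2L, {
    ids <- sprintf("g%03d", seq_len(n_nodes))
    g <- if (model == "erdos_renyi") {
      igraph::sample_gnm(n_nodes, round(n_nodes * mean_degree / 2))
    } else {
      igraph::sample_pa(n_nodes, m = max(1L, round(mean_degree / 2)),
                        directed = FALSE)
    }
    igraph::V(g)$name <- ids
    driver <- if (is.null(plant$driver_gene)) ids[1L] else plant$driver_gene
    stopifnot(driver %in% ids)
    cur <- igraph::V(g)$name[igraph::neighbors(g, driver)]
    pool <- setdiff(ids, c(driver, cur))
    extra <- sample(pool, min(plant$driver_extra_degree, length(pool)))
    if (length(extra) > 0L)
      g <- igraph::add_edges(g, rbind(driver, extra))
    g <- igraph::simplify(g)
    near <- igraph::V(g)$name[
      igraph::distances(g, v = driver)[1L, ] <= 2 &
        igraph::V(g)$name != driver]
    p <- ifelse(ids %in% near, plant$p_near, plant$p_background)
    is_deg <- rbinom(n_nodes, 1L, p) == 1L
    lfc <- ifelse(is_deg,
                  sample(c(-1, 1), n_nodes, replace = TRUE) * runif(n_nodes, 1.5, 5),
                  runif(n_nodes, -0.8, 0.8))
    q <- ifelse(is_deg, runif(n_nodes, 1e-8, 0.005), runif(n_nodes, 0.05, 1))
    deg_table <- data.frame(gene_id = ids, log2FC = round(lfc, 4),
                            q_value = signif(q, 4), stringsAsFactors = FALSE)
    edges_m <- igraph::as_edgelist(g)
    edges <- ppi_edges(data.frame(
      gene_a = edges_m[, 1L], gene_b = edges_m[, 2L],
      confidence = round(runif(nrow(edges_m), 700, 999)),
      stringsAsFactors = FALSE))
    list(edges = edges, deg_table = deg_table, driver = driver,
         deg_genes = ids[is_deg], graph = ppi_graph(edges, nodes = ids))
  })
}

#' Generate a synthetic genes-by-samples expression matrix
#'
#' Gaussian expression with per-gene mean shifts, deterministic under the
#' seed. When used for signature tests, `genes` should include all 17
#' signature genes.
#'
#' @param genes Character vector of gene ids (rows).
#' @param n_samples Number of samples (>= 2).
#' @param effect_vector Per-gene mean shift, recycled to `length(genes)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return A numeric matrix with `genes` as rownames and samples
#'   `S001`, ... as colnames.
#' @export
make_expression <- function(genes, n_samples, effect_vector = 0,
                            noise_sd = 1, seed = 1) {
  if (n_samples < 2L) stop("need at least 2 samples", call. = FALSE)
  effect <- rep_len(effect_vector, length(genes))
  .with_seed(seed + 3L, {
    m <- matrix(rnorm(length(genes) * n_samples, sd = noise_sd),
                nrow = length(genes)) + effect
    dimnames(m) <- list(genes, sprintf("S%03d", seq_len(n_samples)))
    m
  })
}

#' Emit a complete synthetic input set to a directory
#'
#' Writes BED/TSV files for a preset scenario plus a `truth.json` with the
#' planted structure, so a full pipeline run can be checked against known
#' answers.
#'
#' @param preset `"small"` (containment-focused), `"driver-recovery"`
#'   (200-node PPI with a planted driver) or `"signature"` (expression
#'   matrix carrying the 17 signature genes).
#' @param seed RNG seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
synth_make <- function(preset = c("small", "driver-recovery", "signature"),
                       seed = 1, out_dir = tempfile("synth")) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  w <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  if (preset %in% c("small", "driver-recovery")) {
    plant <- plant_spec(seed = seed)
    ann <- make_annotation(n_genes = 20, chrom_length = 1e6, seed = seed)
    ecc <- make_eccdna(ann, plant)
    w("eccdna.bed", function(p) write_ecc_bed(ecc$eccdnas, p))
    w("transcripts.tsv", function(p)
      write_tsv(ann$transcripts[, c("chrom", "start", "end", "strand",
                                    "transcript_id", "gene_id", "biotype")], p))
    w("enhancers.tsv", function(p) write_tsv(ann$enhancers, p))
    w("biotypes.tsv", function(p) write_tsv(ann$biotypes, p))
    truth <- ecc$truth
    if (preset == "driver-recovery") {
      net <- make_ppi_and_degs(n_nodes = 200, mean_degree = 6,
                               plant = plant_spec(seed = seed))
      w("ppi.tsv", function(p) write_tsv(net$edges, p))
      w("deg.tsv", function(p) write_tsv(net$deg_table, p))
      truth$driver <- net$driver
      truth$deg_genes <- net$deg_genes
    }
  } else {
    genes <- unique(c(cedg17_model()$gene, sprintf("BG%03d", 1:33)))
    expr <- make_expression(genes, n_samples = 60,
                            effect_vector = rnorm_effects(genes, seed),
                            seed = seed)
    w("expression.tsv", function(p) {
      df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
      write_tsv(df, p)
    })
    truth <- list(signature_genes = cedg17_model()$gene)
  }
  w("truth.json", function(p)
    jsonlite::write_json(truth, p, auto_unbox = TRUE, pretty = TRUE))
  invisible(paths)
}

# deterministic per-gene mean shifts for the signature preset
rnorm_effects <- function(genes, seed) {
  .with_seed(seed + 4L, round(rnorm(length(genes), 0, 2), 3))
}
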