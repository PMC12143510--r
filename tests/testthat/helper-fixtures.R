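# Small in-code fixtures shared across test files.

toy_ppi <- function() {
  # S-u1, S-d1, u1-d2, u1-d3; DEGs d1, d2, d3
  ppi_graph(ppi_edges(data.frame(
    gene_a = c("S", "S", "u1", "u1"),
    gene_b = c("u1", "d1", "d2", "d3"),
    confidence = 900, stringsAsFactors = FALSE)))
}

toy_degs <- function() c("d1", "d2", "d3")

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

small_fixture <- function(seed, n_genes = 12) {
  ann <- make_annotation(n_genes, chrom_length = 1e6, seed = seed)
  ecc <- make_eccdna(ann, plant_spec(seed = seed))
  list(ann = ann, ecc = ecc)
}
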