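# Independent oracles and small generators used across the suite.

# Brute-force Venn region by set algebra: C_i is the intersection of the
# experiments whose bit is 1 minus the union of those whose bit is 0.
# Deliberately computed by per-region intersect/setdiff, a different route
# from the per-gene bitmask classification the package uses.
oracle_region <- function(gene_sets, i) {
  n <- length(gene_sets)
  bits <- as.integer(intToBits(i))[seq_len(n)]
  s <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  for (j in seq_len(n)) {
    s <- if (bits[j] == 1L) intersect(s, gene_sets[[j]])
         else setdiff(s, gene_sets[[j]])
  }
  sort(s)
}

# Build a vw_experiment without touching the filesystem (one synthetic
# transcript per gene).
mk_experiment <- function(name, genes) {
  genes <- unique(genes)
  structure(list(
    name = name,
    records = data.frame(transcript_id = paste0("tx_", genes),
                         gene_symbol = genes, stringsAsFactors = FALSE),
    genes = sort(genes)), class = "vw_experiment")
}

# Random list of n gene sets over a universe of given size.
random_gene_sets <- function(n, universe_size) {
  universe <- sprintf("g%03d", seq_len(universe_size))
  lapply(seq_len(n), function(j) {
    sample(universe, sample.int(universe_size, 1L))
  })
}

# Random Erdos-Renyi PPI graph over m named nodes.
random_graph <- function(m, p = 0.05) {
  nodes <- sprintf("n%03d", seq_len(m))
  pairs <- utils::combn(m, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- data.frame(node_a = nodes[pairs[1L, keep]],
                      node_b = nodes[pairs[2L, keep]],
                      combined_score = 999, stringsAsFactors = FALSE)
  induce_ppi_graph(edges, nodes)
}

# Write a DEG file for a set of (transcript, symbol) rows.
write_deg_rows <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}
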