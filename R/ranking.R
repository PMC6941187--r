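#' Rank candidate genes by propagation score
#'
#' Converts the converged score vector into the ranked gene table. Seed
#' genes are always excluded from the ranking -- they trivially carry the
#' restart mass and would crowd out the candidates the analysis is meant to
#' prioritize. Optionally the ranking is restricted to genes whose Venn
#' region lies in `restrict_to`, the "focus on one region" reading: e.g.
#' seed on region 2, rank only region 1, discarding the shared region.
#'
#' Rows are sorted by descending score with ties broken by ascending gene
#' symbol, and ranks are strict ordinals `1..m` (no gaps, no shared ranks).
#' Zero-score genes (isolates unreachable from any seed) stay at the bottom
#' of the table rather than being dropped, so the output always covers the
#' whole candidate set.
#'
#' @param scores A `vw_scores` object from [propagate()], or a named
#'   numeric vector aligned to the graph's node ordering.
#' @param graph The `vw_ppigraph` the scores were computed on.
#' @param regionmap The `vw_regionmap` of the experiments.
#' @param seed_genes Character vector of seed gene symbols (excluded).
#' @param restrict_to Optional integer vector of region indices; when
#'   given, only genes from those regions are ranked.
#' @return data.frame with columns `rank`, `gene`, `score`, `region`
#'   (e.g. `"C1"`), `is_seed` (always `FALSE`; seeds never appear),
#'   `degree` (node degree in the induced graph).
#' @export
rank_genes <- function(scores, graph, regionmap, seed_genes,
                       restrict_to = NULL) {
  if (inherits(scores, "vw_scores")) scores <- scores$score
  stopifnot(inherits(graph, "vw_ppigraph"), inherits(regionmap, "vw_regionmap"))
  if (!identical(names(scores), graph$nodes)) {
    vw_usage_error("scores are not aligned to the graph's node ordering")
  }
  candidates <- setdiff(graph$nodes, seed_genes)
  region_idx <- unname(regionmap$region_of[candidates])
  if (!is.null(restrict_to)) {
    keep <- !is.na(region_idx) & region_idx %in% restrict_to
    candidates <- candidates[keep]
    region_idx <- region_idx[keep]
  }
  if (length(candidates) == 0L) vw_analysis_error("no candidate genes")

  sc <- unname(scores[candidates])
  ord <- order(-sc, candidates)
  deg <- node_degrees(graph)
  data.frame(
    rank = seq_along(ord),
    gene = candidates[ord],
    score = sc[ord],
    region = ifelse(is.na(region_idx[ord]), NA_character_,
                    paste0("C", region_idx[ord])),
    is_seed = FALSE,
    degree = unname(deg[candidates[ord]]),
    stringsAsFactors = FALSE)
}

#' Write the ranked gene table
#'
#' Tab-separated, header included, scores printed with 6 significant
#' digits. Identical inputs always produce byte-identical files.
#'
#' @param table data.frame from [rank_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_table <- function(table, path) {
  out <- table
  out$score <- formatC(out$score, digits = 6, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
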