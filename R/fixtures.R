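# Synthetic data with planted structure. The generator emulates the three
# input files the pipeline consumes -- per-experiment DEG lists, a
# STRING-style scored edge list, and an identifier alias table -- and
# records ground truth sufficient to recompute every intermediate count.

# Run `code` under a fixed RNG seed without disturbing global RNG state.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic fixture
#'
#' Defines a planted-structure instance: genes are assigned to Venn
#' regions by `region_weights` (the remainder of the probability mass is
#' non-DEG background), and the interaction network is a planted-partition
#' (stochastic block) graph in which a `linked_fraction` of the
#' target-region genes -- the "linked" genes -- connect to seed-region
#' genes with probability `module_edge_prob_within` while every other pair
#' connects with probability `module_edge_prob_between`. Linked genes are
#' therefore functionally tied to the seed region, which is exactly the
#' structure a region-seeded propagation should recover.
#'
#' Combined scores are drawn uniformly on \[400, 1000\] for planted
#' (linked-to-seed) edges and on \[0, 1000\] for background edges, so the
#' high-confidence threshold filter is exercised nontrivially.
#'
#' @param n_experiments Number of experiments (default 2).
#' @param universe_size Total genes, DEG and background (default 300).
#' @param region_weights Named numeric vector: names are region indices,
#'   values are assignment probabilities summing to at most 1. Default for
#'   `n = 2`: `C1 = 0.2`, `C2 = 0.15`, `C3 = 0.45`, leaving 0.2 background
#'   -- two related experiments sharing most of their DEGs, with minority
#'   condition-specific regions. Keeping the seed region a minority of the
#'   network matters for benchmarking: a size-matched random seed set then
#'   consists mostly of genes outside the true seed region, so comparing
#'   region seeds against random seeds actually contrasts different
#'   hypotheses rather than resampling the same one.
#' @param module_edge_prob_within Edge probability between a linked
#'   target-region gene and a seed-region gene (default 0.3).
#' @param module_edge_prob_between Edge probability for every other pair
#'   (default 0.02).
#' @param seed_region,target_region Region indices of the planted link
#'   (defaults 2 and 1).
#' @param linked_fraction Fraction of target-region genes planted as
#'   linked (default 0.5).
#' @param rng_seed Single integer controlling all randomness (default 42).
#' @return A `vw_fixture_spec` list.
#' @export
fixture_spec <- function(n_experiments = 2L, universe_size = 300L,
                         region_weights = NULL,
                         module_edge_prob_within = 0.3,
                         module_edge_prob_between = 0.02,
                         seed_region = 2L, target_region = 1L,
                         linked_fraction = 0.5, rng_seed = 42L) {
  n_regions <- 2^n_experiments - 1L
  if (is.null(region_weights)) {
    region_weights <- if (n_experiments == 2L) {
      c("1" = 0.2, "2" = 0.15, "3" = 0.45)
    } else {
      stats::setNames(rep(0.8 / n_regions, n_regions), as.character(seq_len(n_regions)))
    }
  }
  idx <- as.integer(names(region_weights))
  if (anyNA(idx) || any(idx < 1L | idx > n_regions)) {
    vw_usage_error("region_weights names must be region indices in range")
  }
  if (sum(region_weights) > 1 + 1e-12) {
    vw_usage_error("region_weights must sum to at most 1")
  }
  if (any(region_weights < 0) || linked_fraction < 0 || linked_fraction > 1 ||
      module_edge_prob_within < 0 || module_edge_prob_within > 1 ||
      module_edge_prob_between < 0 || module_edge_prob_between > 1) {
    vw_usage_error("probabilities and fractions must lie in [0, 1]")
  }
  if (!seed_region %in% seq_len(n_regions) ||
      !target_region %in% seq_len(n_regions)) {
    vw_usage_error("seed_region and target_region must be valid region indices")
  }
  structure(list(
    n_experiments = as.integer(n_experiments),
    universe_size = as.integer(universe_size),
    region_weights = region_weights,
    module_edge_prob_within = module_edge_prob_within,
    module_edge_prob_between = module_edge_prob_between,
    seed_region = as.integer(seed_region),
    target_region = as.integer(target_region),
    linked_fraction = linked_fraction,
    rng_seed = as.integer(rng_seed)), class = "vw_fixture_spec")
}

#' Generate a synthetic fixture directory
#'
#' Writes, under `dir`: one DEG list per experiment (`deg_<j>_E<j>.tsv`,
#' with a header row, each gene represented by 1-3 synthetic transcript
#' IDs), a STRING-style
#' edge list `edges.txt` (protein identifiers, header line, both
#' directions listed as STRING does), and a 2-column alias table
#' `alias.tsv` mapping protein identifiers to gene symbols. Fully
#' reproducible: the same `rng_seed` yields byte-identical files.
#'
#' @param spec A `vw_fixture_spec`.
#' @param dir Output directory (created if missing).
#' @return List with `deg_files`, `edge_file`, `alias_file`, `labels`, and
#'   `truth` -- a list recording per-gene region assignment (`region_of`,
#'   0 = background), the planted `linked_genes`, per-experiment DEG
#'   counts, and edge counts before/after the score-700 threshold.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "vw_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_experiments
  u <- spec$universe_size
  genes <- sprintf("GEN%04d", seq_len(u))
  prots <- sprintf("PROT%04d", seq_len(u))

  with_rng_seed(spec$rng_seed, {
    w <- spec$region_weights
    regions_avail <- c(0L, as.integer(names(w)))
    probs <- c(1 - sum(w), unname(w))
    region_of <- stats::setNames(
      sample(regions_avail, u, replace = TRUE, prob = probs), genes)

    target_genes <- genes[region_of == spec$target_region]
    n_linked <- round(spec$linked_fraction * length(target_genes))
    linked <- sort(sample(target_genes, n_linked))
    seed_genes <- genes[region_of == spec$seed_region]

    # DEG lists: experiment j holds genes whose region bit j is set.
    deg_files <- character(n)
    labels <- paste0("E", seq_len(n))
    deg_counts <- integer(n)
    for (j in seq_len(n)) {
      members <- genes[bitwAnd(region_of, bitwShiftL(1L, j - 1L)) > 0L]
      deg_counts[j] <- length(members)
      ntx <- sample(1:3, length(members), replace = TRUE)
      rows <- data.frame(
        transcript_id = unlist(mapply(function(g, k) sprintf("TX_%s_%d", g, seq_len(k)),
                                      members, ntx, SIMPLIFY = FALSE),
                               use.names = FALSE),
        gene_symbol = rep(members, ntx))
      deg_files[j] <- file.path(dir, sprintf("deg_%d_%s.tsv", j, labels[j]))
      utils::write.table(rows, deg_files[j], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }

    # Planted-partition edges over all unordered pairs.
    pairs <- utils::combn(u, 2L)
    i1 <- pairs[1L, ]; i2 <- pairs[2L, ]
    is_linked1 <- genes[i1] %in% linked; is_linked2 <- genes[i2] %in% linked
    is_seed1 <- region_of[i1] == spec$seed_region
    is_seed2 <- region_of[i2] == spec$seed_region
    planted <- (is_linked1 & is_seed2) | (is_linked2 & is_seed1)
    p_edge <- ifelse(planted, spec$module_edge_prob_within,
                     spec$module_edge_prob_between)
    present <- stats::runif(length(p_edge)) < p_edge
    e1 <- i1[present]; e2 <- i2[present]; e_planted <- planted[present]
    score <- integer(length(e1))
    score[e_planted] <- sample(400:1000, sum(e_planted), replace = TRUE)
    score[!e_planted] <- sample(0:1000, sum(!e_planted), replace = TRUE)

    edge_file <- file.path(dir, "edges.txt")
    both <- data.frame(
      protein1 = c(prots[e1], prots[e2]),
      protein2 = c(prots[e2], prots[e1]),
      combined_score = c(score, score))
    both <- both[order(both$protein1, both$protein2), ]
    con <- file(edge_file, "wt")
    writeLines("protein1 protein2 combined_score", con)
    writeLines(sprintf("%s %s %d", both$protein1, both$protein2,
                       both$combined_score), con)
    close(con)

    alias_file <- file.path(dir, "alias.tsv")
    utils::write.table(data.frame(prots, genes), alias_file, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    truth <- list(
      region_of = region_of,
      linked_genes = linked,
      seed_region_genes = sort(seed_genes),
      deg_counts = stats::setNames(deg_counts, labels),
      n_deg_genes = sum(region_of > 0L),
      n_edges_unique = length(e1),
      n_edges_above_700 = sum(score > 700L),
      n_planted_edges = sum(e_planted),
      n_planted_edges_above_700 = sum(e_planted & score > 700L))

    list(deg_files = deg_files, edge_file = edge_file,
         alias_file = alias_file, labels = labels, truth = truth)
  })
}

#' Planted region sizes of a fixture
#'
#' @param truth The `truth` element of a [generate_fixture()] result.
#' @param n_experiments Number of experiments the fixture was built for.
#' @return Named integer vector: exact planted gene count of every region
#'   `1..2^n - 1` (background genes, region 0, excluded).
#' @export
expected_region_counts <- function(truth, n_experiments) {
  n_regions <- 2^n_experiments - 1L
  counts <- stats::setNames(integer(n_regions), paste0("C", seq_len(n_regions)))
  tab <- table(truth$region_of[truth$region_of > 0L])
  counts[paste0("C", names(tab))] <- as.integer(tab)
  counts
}
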