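#' Binary membership code of a Venn region
#'
#' Region `C_i` of an `n`-set Venn diagram is indexed by the binary
#' expansion of `i`, with digit `b_j` recording membership in experiment
#' `E_j`. Digit `b_1` is the *least-significant* bit and corresponds to the
#' first experiment, so for `n = 3`, `C_1` has code `b = (1, 0, 0)`:
#' genes in `E_1` only.
#'
#' @param i Region index in `[1, 2^n - 1]`.
#' @param n Number of experiments.
#' @return Integer vector of length `n`; element `j` is `b_j`.
#' @export
region_bits <- function(i, n) {
  stopifnot(length(i) == 1L, i >= 1L, i <= 2^n - 1)
  as.integer(intToBits(i))[seq_len(n)]
}

#' Partition experiments into disjoint Venn regions
#'
#' Assigns every gene appearing in any experiment to exactly one of the
#' `2^n - 1` disjoint regions `C_i`: gene `g` belongs to `C_i` iff for every
#' experiment `j`, `g` is in `E_j` exactly when digit `b_j` of `i` is 1.
#' Genes in a single region are the "condition-specific" genes of that
#' membership combination. Empty regions are materialized as empty sets so
#' downstream region indexing is total.
#'
#' @param experiments List of `vw_experiment` objects (from
#'   [load_experiments()]); list order fixes the bit positions.
#' @return An object of class `vw_regionmap`: list with `n`, `labels`
#'   (experiment names), `regions` (list of `2^n - 1` sorted character
#'   vectors, element `i` being `C_i`), and `region_of` (named integer
#'   vector mapping each gene to its region index).
#' @examples
#' f1 <- tempfile(); writeLines(c("t1\ta", "t2\tb"), f1)
#' f2 <- tempfile(); writeLines(c("t3\tb", "t4\tc"), f2)
#' rm <- venn_partition(load_experiments(c(f1, f2), labels = c("E1", "E2")))
#' rm$regions  # C1 = {a}, C2 = {c}, C3 = {b}
#' @export
venn_partition <- function(experiments) {
  n <- length(experiments)
  if (n < 2L) vw_usage_error("need at least 2 experiments to partition")
  stopifnot(all(vapply(experiments, inherits, TRUE, "vw_experiment")))
  labels <- vapply(experiments, `[[`, "", "name")

  universe <- sort(unique(unlist(lapply(experiments, `[[`, "genes"),
                                 use.names = FALSE)))
  # Membership bitmask per gene: bit j-1 set iff gene is in experiment j.
  mask <- integer(length(universe))
  for (j in seq_len(n)) {
    mask <- mask + bitwShiftL(as.integer(universe %in% experiments[[j]]$genes),
                              j - 1L)
  }
  names(mask) <- universe

  regions <- lapply(seq_len(2^n - 1L), function(i) universe[mask == i])
  names(regions) <- paste0("C", seq_along(regions))
  structure(list(n = n, labels = labels, regions = regions, region_of = mask),
            class = "vw_regionmap")
}

#' Parse a region-selection expression
#'
#' Region expressions are '+'-joined region tokens, e.g. `"C2+C4"` selects
#' the union of regions 2 and 4. Only union is supported: the regions are
#' pairwise disjoint, so intersection or difference of regions is vacuous.
#'
#' @param expr Expression string.
#' @param n Number of experiments (bounds valid indices at `2^n - 1`).
#' @return Sorted integer vector of distinct region indices.
#' @export
parse_region_expression <- function(expr, n) {
  tokens <- vw_trim(strsplit(expr, "+", fixed = TRUE)[[1L]])
  if (length(tokens) == 0L || any(tokens == "")) {
    vw_usage_error(sprintf("malformed region expression '%s'", expr))
  }
  m <- regmatches(tokens, regexec("^[Cc]([0-9]+)$", tokens))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    vw_usage_error(sprintf(
      "malformed region token '%s' (expected e.g. 'C2' or 'C2+C4')",
      tokens[bad][1L]))
  }
  idx <- as.integer(vapply(m, `[[`, "", 2L))
  out_of_range <- idx < 1L | idx > 2^n - 1
  if (any(out_of_range)) {
    vw_usage_error(sprintf(
      "region token 'C%d' out of range: with %d experiments indices run 1..%d",
      idx[out_of_range][1L], n, 2^n - 1L))
  }
  sort(unique(idx))
}

#' Genes of a union of Venn regions
#'
#' @param regionmap A `vw_regionmap` from [venn_partition()].
#' @param indices Nonempty integer vector of region indices.
#' @return Sorted character vector: the (disjoint) union of the selected
#'   regions' gene sets.
#' @export
region_genes <- function(regionmap, indices) {
  stopifnot(inherits(regionmap, "vw_regionmap"))
  if (length(indices) == 0L) vw_usage_error("no region indices given")
  bad <- indices < 1L | indices > length(regionmap$regions)
  if (any(bad)) {
    vw_usage_error(sprintf("region index %d out of range", indices[bad][1L]))
  }
  sort(unique(unlist(regionmap$regions[indices], use.names = FALSE)))
}

# Region code as a digit string. b_1 (first experiment) is the
# least-significant digit; lsb_first prints b_1 first.
region_code <- function(i, n, lsb_first = TRUE) {
  bits <- region_bits(i, n)
  if (!lsb_first) bits <- rev(bits)
  paste(bits, collapse = "")
}

#' Region summary table
#'
#' One row per region, sorted by descending gene count (ties by ascending
#' region index). The membership code is printed in both digit orders:
#' `code_b1_first` lists digit `b_1` (first experiment) first;
#' `code_msb_first` is the conventional binary numeral of the index.
#'
#' @param regionmap A `vw_regionmap`.
#' @return data.frame with columns `region_index`, `code_b1_first`,
#'   `code_msb_first`, `member_experiments`, `gene_count`, `genes`
#'   (semicolon-joined).
#' @export
region_summary <- function(regionmap) {
  stopifnot(inherits(regionmap, "vw_regionmap"))
  n <- regionmap$n
  idx <- seq_along(regionmap$regions)
  members <- vapply(idx, function(i) {
    paste(regionmap$labels[region_bits(i, n) == 1L], collapse = ",")
  }, "")
  df <- data.frame(
    region_index = paste0("C", idx),
    code_b1_first = vapply(idx, region_code, "", n = n, lsb_first = TRUE),
    code_msb_first = vapply(idx, region_code, "", n = n, lsb_first = FALSE),
    member_experiments = members,
    gene_count = lengths(regionmap$regions),
    genes = vapply(regionmap$regions, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  df[order(-df$gene_count, idx), , drop = FALSE]
}

#' Write the region summary report
#'
#' @param regionmap A `vw_regionmap`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_summary <- function(regionmap, path) {
  df <- region_summary(regionmap)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# region codes: digit j records membership in experiment %s; code_b1_first lists b_1 (first experiment, least-significant digit) first",
    paste(seq_len(regionmap$n), "=", regionmap$labels, collapse = ", ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.vw_regionmap <- function(x, ...) {
  cat(sprintf("<Venn partition of %d experiments: %d regions, %d genes>\n",
              x$n, length(x$regions), length(x$region_of)))
  invisible(x)
}
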