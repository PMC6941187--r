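#' Parse a differential-expression gene list file
#'
#' Reads one experiment's DEG list: delimited text with the transcript (or
#' gene) identifier in column 1 and the gene symbol in column 2. Extra
#' columns are ignored; the identifier column is treated as opaque.
#' Multiple transcript identifiers annotating the same gene symbol collapse
#' to a single gene, so the experiment is ultimately a *set* of symbols.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param label Experiment name; defaults to the file name without extension.
#'   Must be unique within one run.
#' @param delim Single-character field delimiter (default tab).
#' @param header One of `"auto"`, `"yes"`, `"no"`. With `"auto"` (default)
#'   the first row is skipped iff its second cell does not reappear as a
#'   gene symbol anywhere else in the file. Note the sharp edge: in a
#'   headerless file whose first gene has a single transcript, that row
#'   looks like a header under this rule; pass `header = "no"` when the
#'   file is known to carry no header.
#' @param case_insensitive If `TRUE`, gene symbols are folded to upper case
#'   at parse time. Default `FALSE`: symbols such as mouse `Tlr2` are
#'   case-meaningful, so matching is exact after whitespace trimming.
#'
#' @return An object of class `vw_experiment`: a list with elements
#'   `name`, `records` (data.frame of `transcript_id`, `gene_symbol`), and
#'   `genes` (sorted character vector of distinct symbols).
#'
#' @details A transcript identifier mapped to two different symbols is an
#'   input error rather than silently resolved: there is no defensible
#'   precedence rule, and the conflict usually signals a malformed file.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("tx1\tGeneA", "tx2\tGeneA", "tx3\tGeneB"), f)
#' exp <- parse_deg_file(f, label = "demo")
#' exp$genes  # "GeneA" "GeneB"
#' @export
parse_deg_file <- function(path, label = NULL,
                           delim = "\t",
                           header = c("auto", "yes", "no"),
                           case_insensitive = FALSE) {
  header <- match.arg(header)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^[[:space:]]*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    vw_input_error(sprintf("DEG file '%s' is empty", path))
  }

  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    vw_input_error(sprintf(
      "DEG file '%s': line %d has %d column(s); at least 2 required",
      path, line_no[bad[1L]], nf[bad[1L]]))
  }
  tx <- vw_trim(vapply(fields, `[[`, "", 1L))
  sym <- vw_trim(vapply(fields, `[[`, "", 2L))

  if (header == "yes" || (header == "auto" && length(sym) > 1L &&
                          !(sym[1L] %in% sym[-1L]))) {
    tx <- tx[-1L]
    sym <- sym[-1L]
    line_no <- line_no[-1L]
  }
  if (length(sym) == 0L) {
    vw_input_error(sprintf("DEG file '%s' has a header but no data rows", path))
  }
  empty <- which(sym == "")
  if (length(empty) > 0L) {
    vw_input_error(sprintf(
      "DEG file '%s': line %d has an empty gene symbol",
      path, line_no[empty[1L]]))
  }
  if (case_insensitive) sym <- toupper(sym)

  # One transcript ID annotating two different symbols is irreconcilable.
  conflict <- tapply(sym, tx, function(s) length(unique(s)))
  if (any(conflict > 1L)) {
    id <- names(conflict)[conflict > 1L][1L]
    vw_input_error(sprintf(
      "DEG file '%s': transcript ID '%s' maps to multiple gene symbols (%s)",
      path, id, paste(unique(sym[tx == id]), collapse = ", ")))
  }

  records <- unique(data.frame(transcript_id = tx, gene_symbol = sym,
                               stringsAsFactors = FALSE))
  structure(
    list(name = label, records = records,
         genes = sort(unique(records$gene_symbol))),
    class = "vw_experiment")
}

#' Load two or more DEG list files as experiments
#'
#' The order of `paths` fixes the experiment index `j` used by the Venn
#' region encoding: the first file is experiment 1, whose membership is
#' recorded in the *least-significant* binary digit of a region index.
#'
#' @param paths Character vector of at least two DEG file paths.
#' @param labels Optional experiment names, same length as `paths`;
#'   defaults to file names without extension. Must be unique.
#' @param max_experiments Upper cap on the number of experiments
#'   (default 8; the region count grows as `2^n - 1`).
#' @inheritParams parse_deg_file
#' @return Named list of `vw_experiment` objects, in input order.
#' @export
load_experiments <- function(paths, labels = NULL, max_experiments = 8L,
                             delim = "\t", header = "auto",
                             case_insensitive = FALSE) {
  n <- length(paths)
  if (n < 2L) {
    vw_usage_error("at least 2 DEG files are required for a Venn comparison")
  }
  if (n > max_experiments) {
    vw_usage_error(sprintf(
      "%d DEG files given but the configured maximum is %d", n, max_experiments))
  }
  if (is.null(labels)) labels <- sub("\\.[^.]*$", "", basename(paths))
  if (length(labels) != n) {
    vw_usage_error("'labels' must have one entry per DEG file")
  }
  if (anyDuplicated(labels)) {
    vw_usage_error(sprintf("duplicate experiment label '%s'",
                           labels[duplicated(labels)][1L]))
  }
  exps <- mapply(parse_deg_file, paths, labels,
                 MoreArgs = list(delim = delim, header = header,
                                 case_insensitive = case_insensitive),
                 SIMPLIFY = FALSE)
  names(exps) <- labels
  exps
}

#' Write an experiment's records back to a DEG file
#'
#' Inverse of [parse_deg_file()] up to row order: re-parsing the written
#' file recovers the same gene set.
#'
#' @param experiment A `vw_experiment`.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_deg_file <- function(experiment, path, delim = "\t") {
  stopifnot(inherits(experiment, "vw_experiment"))
  utils::write.table(experiment$records, path, sep = delim,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.vw_experiment <- function(x, ...) {
  cat(sprintf("<experiment '%s': %d records, %d distinct genes>\n",
              x$name, nrow(x$records), length(x$genes)))
  invisible(x)
}
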