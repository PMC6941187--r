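test_that("region bits follow the least-significant-first convention", {
  expect_identical(region_bits(1L, 3), c(1L, 0L, 0L))
  expect_identical(region_bits(2L, 3), c(0L, 1L, 0L))
  expect_identical(region_bits(7L, 3), c(1L, 1L, 1L))
})

test_that("three experiments yield seven regions and the full-intersection region", {
  e1 <- mk_experiment("E1", c("a", "ab", "ac", "abc"))
  e2 <- mk_experiment("E2", c("b", "ab", "bc", "abc"))
  e3 <- mk_experiment("E3", c("c", "ac", "bc", "abc"))
  rm <- venn_partition(list(e1, e2, e3))
  expect_length(rm$regions, 7L)
  expect_true(all(lengths(rm$regions) == 1L))  # every combination occupied
  expect_identical(rm$regions$C7, "abc")       # E1 n E2 n E3
  expect_identical(rm$regions$C1, "a")
  expect_identical(rm$regions$C6, "bc")
})

test_that("full overlap puts everything in the intersection region", {
  rm <- venn_partition(list(mk_experiment("E1", "a"), mk_experiment("E2", "a")))
  expect_identical(rm$regions$C3, "a")
  expect_identical(rm$regions$C1, character(0))
  expect_identical(rm$regions$C2, character(0))
})

test_that("partition matches the set-algebra oracle with disjointness and coverage", {
  set.seed(101)
  for (trial in 1:60) {
    n <- sample(2:6, 1)
    sets <- random_gene_sets(n, sample(20:200, 1))
    exps <- lapply(seq_len(n), function(j) mk_experiment(paste0("E", j), sets[[j]]))
    rm <- venn_partition(exps)

    for (i in seq_len(2^n - 1)) {
      expect_identical(rm$regions[[i]], oracle_region(sets, i))
    }
    all_genes <- unlist(rm$regions, use.names = FALSE)
    expect_false(anyDuplicated(all_genes) > 0)                 # disjoint
    expect_setequal(all_genes, unique(unlist(sets)))           # coverage
    expect_identical(sum(lengths(rm$regions)),
                     length(unique(unlist(sets))))             # cardinality
  }
})

test_that("permuting experiment order relabels regions by the bit permutation", {
  set.seed(7)
  sets <- random_gene_sets(3, 50)
  exps <- lapply(1:3, function(j) mk_experiment(paste0("E", j), sets[[j]]))
  rm1 <- venn_partition(exps)
  perm <- c(3L, 1L, 2L)  # new position j holds old experiment perm[j]
  rm2 <- venn_partition(exps[perm])
  for (i in seq_len(7)) {
    bits_new <- region_bits(i, 3)
    bits_old <- integer(3)
    bits_old[perm] <- bits_new          # membership travels with experiments
    i_old <- sum(bits_old * 2^(0:2))
    expect_identical(rm2$regions[[i]], rm1$regions[[i_old]])
  }
})

test_that("region expressions parse, collapse duplicates, and reject bad tokens", {
  expect_identical(parse_region_expression("C2+C4", 3), c(2L, 4L))
  expect_identical(parse_region_expression("C1", 2), 1L)
  expect_identical(parse_region_expression(" c3 + C3 + C1 ", 2), c(1L, 3L))
  expect_error(parse_region_expression("C9", 3), "out of range",
               class = "vw_usage_error")
  expect_error(parse_region_expression("C0", 3), class = "vw_usage_error")
  expect_error(parse_region_expression("C2-C1", 3), class = "vw_usage_error")
  expect_error(parse_region_expression("", 3), class = "vw_usage_error")
})

test_that("region_genes unions selected regions and covers everything when all are chosen", {
  set.seed(11)
  sets <- random_gene_sets(3, 80)
  exps <- lapply(1:3, function(j) mk_experiment(paste0("E", j), sets[[j]]))
  rm <- venn_partition(exps)
  expect_setequal(region_genes(rm, 1:7), unique(unlist(sets)))
  expect_identical(region_genes(rm, 7L), oracle_region(sets, 7L))
  pick <- c(2L, 5L)
  expect_identical(region_genes(rm, pick),
                   sort(union(oracle_region(sets, 2L), oracle_region(sets, 5L))))
  expect_error(region_genes(rm, integer(0)), class = "vw_usage_error")
})

test_that("region summary is sorted by size and written reports re-read cleanly", {
  e1 <- mk_experiment("E1", c("a", "b", "c", "x"))
  e2 <- mk_experiment("E2", c("x", "y"))
  rm <- venn_partition(list(e1, e2))
  df <- region_summary(rm)
  expect_identical(df$region_index[1], "C1")  # largest region first
  expect_true(all(diff(df$gene_count) <= 0))
  expect_identical(df$code_b1_first[df$region_index == "C1"], "10")
  expect_identical(df$code_msb_first[df$region_index == "C1"], "01")

  path <- tempfile()
  write_region_summary(rm, path)
  back <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     colClasses = c(code_b1_first = "character",
                                    code_msb_first = "character"))
  expect_identical(back$region_index, df$region_index)
  expect_identical(back$gene_count, df$gene_count)
})
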