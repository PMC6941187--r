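two_node_graph <- function() {
  induce_ppi_graph(
    data.frame(node_a = "a", node_b = "b", combined_score = 900),
    c("a", "b"))
}

test_that("seed vectors put uniform mass on present seeds only", {
  set.seed(3)
  g <- random_graph(20, 0.2)
  seeds <- g$nodes[1:4]
  p0 <- make_seed_vector(g, seeds)
  expect_equal(unname(p0[seeds]), rep(0.25, 4))
  expect_equal(sum(p0), 1)
  expect_true(all(p0[setdiff(g$nodes, seeds)] == 0))

  expect_warning(p0b <- make_seed_vector(g, c(g$nodes[1:3], "zz1", "zz2")),
                 "absent")
  expect_equal(unname(p0b[g$nodes[1:3]]), rep(1 / 3, 3))
  expect_identical(attr(p0b, "dropped"), c("zz1", "zz2"))

  expect_error(make_seed_vector(g, "nope"),
               "no seed genes present in network", class = "vw_analysis_error")
})

test_that("a seeded single node with self-loop is a fixed point", {
  g <- induce_ppi_graph(
    data.frame(node_a = character(), node_b = character(),
               combined_score = numeric()), "solo")
  res <- propagate(transition_matrix(g), c(solo = 1))
  expect_equal(unname(res$score), 1)
  expect_identical(res$iterations, 1L)
  expect_true(res$converged)
})

test_that("two-node single-edge graph reaches (2/3, 1/3) by both routes", {
  g <- two_node_graph()
  Ap <- transition_matrix(g)
  p0 <- make_seed_vector(g, "a")
  it <- propagate(Ap, p0, r = 0.5)
  cf <- rwr_closed_form(Ap, p0, r = 0.5)
  expect_equal(unname(cf), c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(it$score), c(2 / 3, 1 / 3), tolerance = 1e-3)
  expect_true(it$converged)
})

test_that("r = 1 recovers the seed vector exactly", {
  set.seed(21)
  g <- random_graph(30, 0.1)
  p0 <- make_seed_vector(g, g$nodes[1:3])
  expect_equal(rwr_closed_form(transition_matrix(g), p0, r = 1),
               stats::setNames(as.numeric(p0), g$nodes))
  res <- propagate(transition_matrix(g), p0, r = 1)
  expect_equal(res$score, stats::setNames(as.numeric(p0), g$nodes))
})

test_that("iterative fixed point matches the linear-solve oracle on random graphs", {
  set.seed(31)
  for (trial in 1:15) {
    m <- sample(20:200, 1)
    g <- random_graph(m, p = runif(1, 0.02, 0.15))
    Ap <- transition_matrix(g)
    k <- sample.int(max(m %/% 10, 1), 1)
    p0 <- make_seed_vector(g, sample(g$nodes, k))
    r <- runif(1, 0.2, 0.9)

    it <- propagate(Ap, p0, r = r, tol = 1e-6)
    cf <- rwr_closed_form(Ap, p0, r = r)
    expect_lt(max(abs(it$score - cf)), 1e-5)        # 10 * tol
    expect_equal(sum(it$score), 1, tolerance = 1e-9)
    expect_equal(sum(cf), 1, tolerance = 1e-9)
  }
})

test_that("mass is conserved at every iteration and convergence is geometric", {
  set.seed(41)
  g <- random_graph(100, 0.05)
  Ap <- transition_matrix(g)
  p0 <- make_seed_vector(g, sample(g$nodes, 5))
  p <- as.numeric(p0)
  for (t in 1:30) {
    p <- as.numeric(0.5 * (Ap %*% p) + 0.5 * as.numeric(p0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # contraction: ||p^t - p*||_1 <= (1-r)^t ||p^0 - p*||_1
  pstar <- rwr_closed_form(Ap, p0, r = 0.5)
  p <- as.numeric(p0)
  gap0 <- sum(abs(p - pstar))
  for (t in 1:10) {
    p <- as.numeric(0.5 * (Ap %*% p) + 0.5 * as.numeric(p0))
    expect_lte(sum(abs(p - pstar)), 0.5^t * gap0 + 1e-12)
  }
  expect_lte(propagate(Ap, p0, r = 0.5, tol = 1e-4)$iterations, 25L)
})

test_that("nodes symmetric about the seed set score equally (complete graph)", {
  m <- 6
  nodes <- letters[1:m]
  pairs <- utils::combn(m, 2)
  e <- data.frame(node_a = nodes[pairs[1, ]], node_b = nodes[pairs[2, ]],
                  combined_score = 900, stringsAsFactors = FALSE)
  g <- induce_ppi_graph(e, nodes)
  p0 <- make_seed_vector(g, "a")
  cf <- rwr_closed_form(transition_matrix(g), p0, r = 0.5)
  non_seed <- cf[-1]
  expect_true(max(non_seed) - min(non_seed) < 1e-12)
  expect_gt(cf[["a"]], max(non_seed))
})

test_that("invalid parameters and dimension mismatches are rejected", {
  g <- two_node_graph()
  Ap <- transition_matrix(g)
  p0 <- make_seed_vector(g, "a")
  expect_error(propagate(Ap, p0, r = 0), class = "vw_usage_error")
  expect_error(propagate(Ap, p0, r = 1.5), class = "vw_usage_error")
  expect_error(propagate(Ap, p0, tol = 0), class = "vw_usage_error")
  expect_error(propagate(Ap, c(a = 1)), class = "vw_usage_error")
  expect_warning(propagate(Ap, p0, tol = 1e-12, max_iter = 3L), "converge")
})
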