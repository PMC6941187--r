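#' Build the seed probability vector
#'
#' Seed genes receive equal initial probability mass: `1/k` on each of the
#' `k` seed genes present in the graph, zero elsewhere, so the vector sums
#' to 1. Seed genes absent from the network are dropped with a warning
#' (they carry no topological information).
#'
#' @param graph A `vw_ppigraph`.
#' @param seed_genes Character vector of gene symbols.
#' @return Named numeric vector `p0` over the graph's node ordering;
#'   attribute `"dropped"` holds seeds absent from the graph.
#' @export
make_seed_vector <- function(graph, seed_genes) {
  stopifnot(inherits(graph, "vw_ppigraph"))
  seed_genes <- unique(seed_genes)
  present <- intersect(seed_genes, graph$nodes)
  if (length(present) == 0L) {
    vw_analysis_error("no seed genes present in network")
  }
  dropped <- setdiff(seed_genes, present)
  if (length(dropped) > 0L) {
    warning(sprintf("%d seed gene(s) absent from the network dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  p0 <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  p0[present] <- 1 / length(present)
  attr(p0, "dropped") <- dropped
  p0
}

#' Random walk with restart by power iteration
#'
#' Iterates the restart-walk update
#' \deqn{p^{t+1} = (1 - r) A' p^t + r p^0}
#' from `p^0` until the L1 difference between consecutive iterates falls
#' below `tol`, or `max_iter` is reached. `A'` is the column-stochastic
#' transition matrix, so total probability mass is conserved at every step;
#' the fixed point scores each node by its proximity to the seed set.
#'
#' The map is a contraction with factor `1 - r` in L1, so convergence is
#' geometric: at the default `r = 0.5`, `tol = 1e-4`, at most about 20
#' iterations are ever needed.
#'
#' @param A_prime Column-stochastic transition matrix from
#'   [transition_matrix()].
#' @param p0 Seed vector from [make_seed_vector()] (sums to 1).
#' @param r Restart rate in `(0, 1]`, default 0.5. Each step a fraction
#'   `r` of the mass restarts at the seed distribution; larger `r` keeps
#'   scores more local to the seeds. `r = 1` returns `p0` itself.
#' @param tol L1 convergence tolerance on consecutive iterates,
#'   default `1e-4`.
#' @param max_iter Safety cap on iterations, default 10000 (unreachable
#'   for stochastic `A_prime`; guards pathological user matrices).
#' @return Object of class `vw_scores`: list with `score` (named numeric
#'   vector over the node ordering), `iterations`, `converged`.
#' @examples
#' # two nodes joined by one edge, seed on node 1, r = 0.5:
#' # stationary scores are (2/3, 1/3)
#' g <- induce_ppi_graph(
#'   data.frame(node_a = "a", node_b = "b", combined_score = 900),
#'   c("a", "b"))
#' propagate(transition_matrix(g), c(a = 1, b = 0))$score
#' @export
propagate <- function(A_prime, p0, r = 0.5, tol = 1e-4, max_iter = 10000L) {
  if (!(r > 0 && r <= 1)) vw_usage_error("restart rate r must be in (0, 1]")
  if (!(tol > 0)) vw_usage_error("tol must be positive")
  if (max_iter < 1L) vw_usage_error("max_iter must be >= 1")
  if (nrow(A_prime) != length(p0)) {
    vw_usage_error("dimension mismatch between transition matrix and seed vector")
  }
  nm <- names(p0)
  p <- as.numeric(p0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_next <- as.numeric((1 - r) * (A_prime %*% p) + r * as.numeric(p0))
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("propagation did not converge within %d iterations", max_iter))
  }
  structure(list(score = stats::setNames(p, nm),
                 iterations = iter, converged = converged),
            class = "vw_scores")
}

#' Closed-form stationary solution of the restart walk
#'
#' The fixed point of the restart-walk update satisfies the linear system
#' \deqn{(I - (1 - r) A') p = r\, p^0,} which is nonsingular for any
#' `r > 0` when `A'` is column-stochastic (the spectral radius of
#' `(1-r)A'` is at most `1-r < 1`). Solving it directly gives the exact
#' stationary scores; this is the independent oracle used to validate the
#' power iteration in the test suite.
#'
#' @inheritParams propagate
#' @return Named numeric vector of exact stationary scores.
#' @export
rwr_closed_form <- function(A_prime, p0, r = 0.5) {
  if (!(r > 0 && r <= 1)) vw_usage_error("restart rate r must be in (0, 1]")
  n <- length(p0)
  M <- Matrix::Diagonal(n) - (1 - r) * A_prime
  p <- tryCatch(as.numeric(Matrix::solve(M, r * as.numeric(p0))),
                error = function(e) {
    stop(sprintf("internal error: restart-walk system is singular (%s)",
                 conditionMessage(e)))
  })
  stats::setNames(p, names(p0))
}

#' @export
print.vw_scores <- function(x, ...) {
  cat(sprintf("<propagation scores: %d nodes, %d iterations, converged=%s>\n",
              length(x$score), x$iterations, x$converged))
  invisible(x)
}
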