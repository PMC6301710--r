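# Orthogonal collocation utilities: Gauss-type nodes of the classical
# polynomial families and the Lagrange interpolation derivative matrix.

#' Collocation nodes of a classical orthogonal polynomial family
#'
#' Returns the roots of the degree-`n` orthogonal polynomial of the chosen
#' family, affinely mapped to the integration interval.  Nodes are computed
#' by the Golub-Welsch eigenvalue method on the Jacobi (three-term
#' recurrence) matrix, except for the Chebyshev families where the closed
#' forms are used.  For the families with unbounded natural support
#' (Laguerre, Hermite) the root span, padded by one part in `n`, is mapped
#' to the interval so that all nodes stay strictly interior.
#'
#' @param family one of `"legendre"`, `"chebyshev1"`, `"chebyshev2"`,
#'   `"laguerre"`, `"hermite"`
#' @param n number of nodes (>= 2)
#' @param interval numeric length-2 integration interval (default `[-1, 1]`)
#' @return sorted numeric vector of `n` nodes strictly inside `interval`
#' @export
collocation_nodes <- function(family = c("legendre", "chebyshev1",
                                         "chebyshev2", "laguerre",
                                         "hermite"),
                              n, interval = c(-1, 1)) {
  family <- match.arg(family)
  if (n < 2) stop("'n' must be at least 2")
  roots <- switch(family,
    chebyshev1 = cos((2 * seq_len(n) - 1) * pi / (2 * n)),
    chebyshev2 = cos(seq_len(n) * pi / (n + 1)),
    legendre = {
      k <- seq_len(n - 1)
      b <- k / sqrt(4 * k^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1)] <- b
      J[cbind(k + 1, k)] <- b
      eigen(J, symmetric = TRUE, only.values = TRUE)$values
    },
    laguerre = {
      k <- seq_len(n - 1)
      J <- diag(2 * seq_len(n) - 1)
      J[cbind(k, k + 1)] <- k
      J[cbind(k + 1, k)] <- k
      eigen(J, symmetric = TRUE, only.values = TRUE)$values
    },
    hermite = {
      k <- seq_len(n - 1)
      b <- sqrt(k / 2)
      J <- matrix(0, n, n)
      J[cbind(k, k + 1)] <- b
      J[cbind(k + 1, k)] <- b
      eigen(J, symmetric = TRUE, only.values = TRUE)$values
    })
  roots <- sort(roots)
  # natural interval of the family
  span <- switch(family,
    legendre = , chebyshev1 = , chebyshev2 = c(-1, 1),
    laguerre = c(0, max(roots) * (1 + 1 / n)),
    hermite = c(-1, 1) * max(abs(roots)) * (1 + 1 / n))
  a <- interval[1]; b <- interval[2]
  if (!(b > a)) stop("'interval' must be increasing")
  a + (roots - span[1]) / (span[2] - span[1]) * (b - a)
}

#' Lagrange interpolation derivative matrix
#'
#' For distinct nodes `x_1 < ... < x_m`, returns the matrix `D` with
#' `D[a, b] = l_b'(x_a)`, the derivative of the `b`-th Lagrange basis
#' polynomial at node `a`.  Applying `D` to samples of any polynomial of
#' degree `< m` reproduces its derivative exactly at the nodes.
#'
#' @param nodes numeric vector of distinct interpolation nodes
#' @return an `m x m` derivative matrix
#' @export
lagrange_derivative_matrix <- function(nodes) {
  m <- length(nodes)
  if (anyDuplicated(nodes)) stop("duplicated nodes")
  # barycentric weights c_k = prod_{j != k} (x_k - x_j)
  dif <- outer(nodes, nodes, "-")
  diag(dif) <- 1
  cw <- apply(dif, 1, prod)
  D <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      if (a != b) D[a, b] <- (cw[a] / cw[b]) / (nodes[a] - nodes[b])
    }
    D[a, a] <- sum(1 / (nodes[a] - nodes[-a]))
  }
  D
}

# Lagrange basis evaluation matrix: L[i, b] = l_b(x_i) for new points x
.lagrange_eval_matrix <- function(nodes, x) {
  m <- length(nodes)
  L <- matrix(0, length(x), m)
  for (b in seq_len(m)) {
    num <- rep(1, length(x))
    den <- 1
    for (j in seq_len(m)[-b]) {
      num <- num * (x - nodes[j])
      den <- den * (nodes[b] - nodes[j])
    }
    L[, b] <- num / den
  }
  L
}
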