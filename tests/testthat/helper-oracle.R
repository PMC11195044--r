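# Independent oracle: exact stationary distribution of the allocation chain
# on tiny instances, computed without the package's sampler.
#
# The chain alternates pi ~ Dirichlet(x + delta) with a fresh allocation of
# every peptide's abundance (mixed over the error indicator in PEP mode), so
# its transition kernel on the latent totals x is
#   T(x -> x') = E_{pi ~ Dir(x + delta)} P(x' | pi),
# where P(x' | pi) is the convolution over peptides of the per-peptide
# multinomial allocation laws with weights pi_p / M_p (and does not depend
# on x). The expectation is evaluated by Gauss-Legendre quadrature over the
# simplex (P = 2 or 3), the stationary law is the eigenvector of T at
# eigenvalue 1, and the stationary mean of pi follows from the Dirichlet
# conditional mean: sum_x stat(x) (x + delta) / sum(x + delta).

oracle_compositions <- function(total, k) {
  if (k == 1) return(matrix(as.integer(total), 1, 1))
  out <- NULL
  for (j in 0:total) {
    sub <- oracle_compositions(total - j, k - 1)
    out <- rbind(out, cbind(as.integer(j), sub))
  }
  unname(out)
}

# allocation distribution over total x vectors at a fixed pi;
# returns a named numeric vector, keys are comma-joined x vectors
oracle_x_dist <- function(pi, y, psi, m, pep) {
  P <- length(pi)
  dist <- stats::setNames(1, paste(integer(P), collapse = ","))
  for (i in seq_along(y)) {
    s <- psi[[i]]
    w <- pi[s] / m[s]
    w <- if (sum(w) <= 0) rep(1 / length(s), length(s)) else w / sum(w)
    comps <- oracle_compositions(y[i], length(s))
    outcomes_x <- vector("list", 0)
    outcomes_p <- numeric(0)
    keep_p <- 1 - pep[i]
    for (r in seq_len(nrow(comps))) {
      xv <- integer(P)
      xv[s] <- comps[r, ]
      outcomes_x <- c(outcomes_x, list(xv))
      outcomes_p <- c(outcomes_p, keep_p * stats::dmultinom(comps[r, ], prob = w))
    }
    if (pep[i] > 0) {  # sampled as mistakenly detected: zero contribution
      outcomes_x <- c(outcomes_x, list(integer(P)))
      outcomes_p <- c(outcomes_p, pep[i])
    }
    nd <- new.env(parent = emptyenv())
    for (key in names(dist)) {
      x0 <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      p0 <- dist[[key]]
      for (o in seq_along(outcomes_p)) {
        k2 <- paste(x0 + outcomes_x[[o]], collapse = ",")
        prev <- if (is.null(nd[[k2]])) 0 else nd[[k2]]
        nd[[k2]] <- prev + p0 * outcomes_p[o]
      }
    }
    dist <- unlist(as.list(nd))
  }
  dist
}

oracle_simplex_nodes <- function(P, n = 64) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  if (P == 2) {
    list(pts = cbind(gl$x, 1 - gl$x), w = gl$w)
  } else if (P == 3) {
    pts <- matrix(0, n * n, 3)
    wts <- numeric(n * n)
    r <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      r <- r + 1
      p1 <- gl$x[i]
      p2 <- (1 - gl$x[i]) * gl$x[j]
      pts[r, ] <- c(p1, p2, 1 - p1 - p2)
      wts[r] <- gl$w[i] * gl$w[j] * (1 - gl$x[i])  # jacobian of the map
    }
    list(pts = pts, w = wts)
  } else stop("oracle supports P = 2 or 3 only")
}

oracle_ddirichlet <- function(pi, alpha) {
  exp(sum((alpha - 1) * log(pi)) + lgamma(sum(alpha)) - sum(lgamma(alpha)))
}

# stationary mean of pi for the implemented chain; delta defaults to flat
oracle_stationary <- function(y, psi, m, delta, pep = rep(0, length(y)),
                              n_nodes = 64) {
  P <- length(delta)
  nodes <- oracle_simplex_nodes(P, n_nodes)
  nq <- length(nodes$w)

  # state space = support of the allocation distribution (pi-independent)
  support <- oracle_x_dist(rep(1 / P, P), y, psi, m, pep)
  keys <- names(support)
  S <- length(keys)
  states <- lapply(keys, function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))

  # D[q, x']: allocation distribution at each quadrature node
  D <- matrix(0, nq, S, dimnames = list(NULL, keys))
  for (q in seq_len(nq)) {
    d <- oracle_x_dist(nodes$pts[q, ], y, psi, m, pep)
    D[q, names(d)] <- d
  }

  Tmat <- matrix(0, S, S, dimnames = list(keys, keys))
  for (si in seq_len(S)) {
    alpha <- states[[si]] + delta
    dens <- apply(nodes$pts, 1L, oracle_ddirichlet, alpha = alpha)
    row <- colSums(D * (nodes$w * dens))
    Tmat[si, ] <- row / sum(row)  # absorb quadrature normalization
  }

  ev <- eigen(t(Tmat))
  i <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i])
  stat <- stat / sum(stat)
  stopifnot(all(stat > -1e-8))

  mean_pi <- numeric(P)
  mean_x <- numeric(P)
  for (si in seq_len(S)) {
    x <- states[[si]]
    mean_pi <- mean_pi + stat[si] * (x + delta) / sum(x + delta)
    mean_x <- mean_x + stat[si] * x
  }
  list(mean_pi = mean_pi, mean_x = mean_x, stationary = stat, states = states)
}
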