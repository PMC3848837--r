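# DEC pruning likelihood.
#
# Conditional likelihoods are propagated tip-to-root over the full state
# space (including the absorbing empty range, which has zero likelihood at
# every tip). At an internal node in ancestor state R the daughters'
# down-branch likelihoods are combined over all cladogenetic outcomes of R,
# equally weighted. The root likelihood is the plain sum of the root
# conditional likelihoods over the allowed root states (all non-empty
# states, or the constraint set), so constraining the root can never raise
# the likelihood. Per-node rescaling keeps 200-tip likelihoods in range.

# Precompute everything that does not depend on (d, e).
dec_engine <- function(phy, tip_ranges, space) {
  nch <- tabulate(phy$edge[, 1L])
  if (!ape::is.rooted(phy) || any(nch[nch > 0] != 2L))
    stop("tree contains polytomies (or is unrooted); the DEC model ",
         "requires a rooted, fully bifurcating tree - resolve polytomies ",
         "before fitting")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- ape::Ntip(phy)
  missing_tips <- setdiff(phy$tip.label, names(tip_ranges))
  if (length(missing_tips))
    stop("no range coded for tip(s): ", paste(missing_tips, collapse = ", "))
  tip_states <- state_index(space, tip_ranges[phy$tip.label])
  if (any(!nzchar(space$states[tip_states])))
    stop("tips cannot be coded with the empty range")

  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  # child edge rows for each internal node, in postorder node order
  nodes <- unique(edge[, 1L])  # postorder: children precede parents
  child_rows <- lapply(nodes, function(n) which(edge[, 1L] == n))

  out <- cladogenetic_outcomes(space)
  K <- length(space$states)
  anc_idx <- state_index(space, out$ancestor)
  l_idx <- state_index(space, out$left)
  r_idx <- state_index(space, out$right)
  A <- matrix(0, K, nrow(out))  # aggregate outcome products by ancestor
  A[cbind(anc_idx, seq_len(nrow(out)))] <- out$weight
  nonempty <- which(nzchar(space$states))

  list(phy = phy, space = space, ntip = ntip, edge = edge, elen = elen,
       nodes = nodes, child_rows = child_rows, tip_states = tip_states,
       outcomes = out, anc_idx = anc_idx, l_idx = l_idx, r_idx = r_idx,
       A = A, K = K, nonempty = nonempty)
}

# All per-edge transition probability matrices for a given Q, as a
# K*K x nedge matrix (column b = vec(P_b)). Eigendecomposition fast path
# with fallback to Matrix::expm when Q is close to defective.
edge_prob_matrices <- function(Q, elen) {
  K <- nrow(Q)
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(ev)) {
    Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      recon <- Re(ev$vectors %*% (ev$values * Vi))
      scale <- max(abs(Q), 1e-12)
      use_eigen <- max(abs(recon - Q)) <= 1e-9 * max(scale, 1)
    }
  }
  if (use_eigen) {
    # P(t)[i,j] = sum_k C_k[i,j] exp(lambda_k t); stack C_k column-wise
    Cmat <- matrix(0 + 0i, K * K, K)
    for (k in seq_len(K))
      Cmat[, k] <- as.vector(outer(ev$vectors[, k], Vi[k, ]))
    E <- exp(outer(ev$values, elen))
    P <- Re(Cmat %*% E)
  } else {
    P <- matrix(0, K * K, length(elen))
    ut <- unique(elen)
    for (t in ut) {
      Pm <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
      P[, elen == t] <- as.vector(Pm)
    }
  }
  P[P < 0] <- 0
  P
}

# Up-pass: scaled conditional likelihoods and log scale factors.
# Returns clik (K x nnodes), sublog (cumulative log-scale of each subtree),
# and the per-edge P matrices.
dec_uppass <- function(eng, d, e) {
  Q <- build_rate_matrix(eng$space, d, e)
  Pall <- edge_prob_matrices(Q, eng$elen)
  K <- eng$K
  ntot <- eng$ntip + eng$phy$Nnode
  clik <- matrix(0, K, ntot)
  clik[cbind(eng$tip_states, seq_len(eng$ntip))] <- 1
  sublog <- numeric(ntot)
  down <- matrix(0, K, ntot)  # down-branch likelihood at top of each branch
  for (ni in seq_along(eng$nodes)) {
    n <- eng$nodes[ni]
    rows <- eng$child_rows[[ni]]
    dsum <- 0
    dprod <- NULL
    for (r in rows) {
      child <- eng$edge[r, 2L]
      Pb <- matrix(Pall[, r], K, K)
      dv <- as.vector(Pb %*% clik[, child])
      down[, child] <- dv
      dsum <- dsum + sublog[child]
      dprod <- if (is.null(dprod)) list(dv) else c(dprod, list(dv))
    }
    v <- dprod[[1L]][eng$l_idx] * dprod[[2L]][eng$r_idx]
    cl <- as.vector(eng$A %*% v)
    s <- sum(cl)
    if (!is.finite(s) || s <= 0) {
      clik[, n] <- 0
      sublog[n] <- -Inf
      next
    }
    clik[, n] <- cl / s
    sublog[n] <- dsum + log(s)
  }
  list(Q = Q, Pall = Pall, clik = clik, sublog = sublog, down = down)
}

root_state_set <- function(eng, root_constraint) {
  if (is.null(root_constraint)) return(eng$nonempty)
  idx <- state_index(eng$space, root_constraint)
  if (any(!nzchar(eng$space$states[idx])))
    stop("root constraint cannot include the empty range")
  idx
}

dec_negloglik <- function(eng, d, e, root_states) {
  up <- dec_uppass(eng, d, e)
  root <- eng$ntip + 1L
  L <- sum(up$clik[root_states, root])
  if (!is.finite(L) || L <= 0 || !is.finite(up$sublog[root])) return(Inf)
  -(log(L) + up$sublog[root])
}

#' DEC pruning likelihood of a time tree
#'
#' Negative log-likelihood of tip ranges under the
#' dispersal-extinction-cladogenesis model, computed by Felsenstein pruning
#' over range states with cladogenetic range splitting at internal nodes.
#'
#' @param phy Strictly bifurcating ultrametric `phylo` tree (branch lengths
#'   in Ma).
#' @param tip_ranges Named character vector mapping every tip label to a
#'   non-empty allowed range state (e.g. `"A"`, `"AB"`).
#' @param space A `range_state_space`.
#' @param d,e Dispersal and extinction rates (per Ma).
#' @param root_constraint Optional character vector of range states the root
#'   is restricted to; default all non-empty states.
#' @return The negative log-likelihood (a single number).
#' @export
tree_likelihood <- function(phy, tip_ranges, space, d, e,
                            root_constraint = NULL) {
  eng <- dec_engine(phy, tip_ranges, space)
  dec_negloglik(eng, d, e, root_state_set(eng, root_constraint))
}

#' Maximum-likelihood estimation of DEC rates
#'
#' Maximizes the DEC likelihood over `(log d, log e)` with derivative-free
#' Nelder-Mead simplex from multiple jittered grid starts.
#'
#' @inheritParams tree_likelihood
#' @param n_starts Number of optimizer starts (taken in order from a
#'   `{0.001, 0.01, 0.1}` grid of rate combinations, multiplicatively
#'   jittered).
#' @param jitter Half-width of the uniform log-jitter applied to starts.
#' @param reltol Convergence tolerance on the negative log-likelihood.
#' @return A list of class `dec_fit` with elements `d`, `e`, `neg_loglik`,
#'   and a per-start `convergence` data frame.
#' @export
fit_dec <- function(phy, tip_ranges, space, root_constraint = NULL,
                    n_starts = 5, jitter = 0.25, reltol = 1e-8) {
  eng <- dec_engine(phy, tip_ranges, space)
  rs <- root_state_set(eng, root_constraint)
  fn <- function(p) {
    if (any(p > 15) || any(p < -25)) return(1e10)
    v <- dec_negloglik(eng, exp(p[1L]), exp(p[2L]), rs)
    if (!is.finite(v)) 1e10 else v
  }
  grid <- rbind(c(0.01, 0.01), c(0.1, 0.01), c(0.001, 0.001),
                c(0.1, 0.1), c(0.01, 0.001), c(0.001, 0.01),
                c(0.1, 0.001), c(0.01, 0.1), c(0.001, 0.1))
  n_starts <- min(n_starts, nrow(grid))
  res <- vector("list", n_starts)
  conv <- data.frame(start_d = numeric(0), start_e = numeric(0),
                     neg_loglik = numeric(0), converged = logical(0))
  for (i in seq_len(n_starts)) {
    st <- log(grid[i, ]) + runif(2, -jitter, jitter)
    o <- tryCatch(
      optim(st, fn, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = 2000)),
      error = function(e) NULL)
    res[[i]] <- o
    conv <- rbind(conv, data.frame(
      start_d = exp(st[1L]), start_e = exp(st[2L]),
      neg_loglik = if (is.null(o)) NA_real_ else o$value,
      converged = !is.null(o) && o$convergence == 0))
  }
  ok <- !vapply(res, is.null, TRUE) & is.finite(conv$neg_loglik)
  if (!any(ok)) stop("DEC optimization failed from every start")
  if (!any(conv$converged[ok]))
    warning("no optimizer start reported convergence; returning best found")
  best <- res[[which.min(ifelse(ok, conv$neg_loglik, Inf))]]
  structure(list(d = exp(best$par[1L]), e = exp(best$par[2L]),
                 neg_loglik = best$value, convergence = conv,
                 root_constraint = root_constraint),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC fit: d = %.5g, e = %.5g, -lnL = %.4f\n",
              x$d, x$e, x$neg_loglik))
  invisible(x)
}
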