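#' Ancestral split scenarios and daughter-branch range probabilities
#'
#' Scores every cladogenetic split scenario at every internal node by the
#' likelihood of the whole tree conditional on that scenario occurring at
#' that node, and normalizes within the node to relative probabilities.
#' Scenarios within `window` log-likelihood units of the node's best are
#' flagged as retained; per-daughter-branch marginal range probabilities
#' (summing scenario probabilities that share the daughter range) below
#' `floor` are flagged sub-threshold but still reported.
#'
#' @inheritParams tree_likelihood
#' @param window Log-likelihood retention window per node (default 2).
#' @param floor Marginal-probability plotting floor (default 0.1).
#' @return A list of class `dec_ancestral` with `node_scenarios`,
#'   `branch_marginals`, `root_states`, `neg_loglik`, `d`, `e`.
#' @export
ancestral_splits <- function(phy, tip_ranges, space, d, e, window = 2,
                             floor = 0.1, root_constraint = NULL) {
  eng <- dec_engine(phy, tip_ranges, space)
  rs <- root_state_set(eng, root_constraint)
  up <- dec_uppass(eng, d, e)
  K <- eng$K
  root <- eng$ntip + 1L
  Lroot <- sum(up$clik[rs, root])
  if (!is.finite(Lroot) || Lroot <= 0)
    stop("zero likelihood; check tip ranges and rates")
  neg_loglik <- -(log(Lroot) + up$sublog[root])

  out <- eng$outcomes
  nout <- nrow(out)
  B <- matrix(0, K, nout)  # aggregate by this-side daughter state
  B[cbind(eng$l_idx, seq_len(nout))] <- 1

  ntot <- eng$ntip + eng$phy$Nnode
  G <- matrix(0, K, ntot)
  abovelog <- rep(-Inf, ntot)
  G[rs, root] <- 1
  abovelog[root] <- 0

  scen_list <- list()
  marg_list <- list()
  # preorder = reverse postorder over internal nodes
  for (ni in rev(seq_along(eng$nodes))) {
    n <- eng$nodes[ni]
    rows <- eng$child_rows[[ni]]
    cl <- eng$edge[rows[1L], 2L]
    cr <- eng$edge[rows[2L], 2L]
    gv <- G[, n]
    val <- gv[eng$anc_idx] * out$weight *
      up$down[eng$l_idx, cl] * up$down[eng$r_idx, cr]
    tot <- sum(val)
    relp <- val / tot
    lnl <- ifelse(val > 0,
                  log(val) + up$sublog[cl] + up$sublog[cr] + abovelog[n],
                  -Inf)
    best <- max(lnl)
    scen_list[[length(scen_list) + 1L]] <- data.frame(
      node = n, ancestor = out$ancestor, left = out$left, right = out$right,
      left_node = cl, right_node = cr, lnL = lnl, rel_prob = relp,
      retained = lnl >= best - window, stringsAsFactors = FALSE)
    for (side in 1:2) {
      child <- if (side == 1L) cl else cr
      sidx <- if (side == 1L) eng$l_idx else eng$r_idx
      m <- vapply(seq_len(K), function(k) sum(relp[sidx == k]), 0)
      keep <- nzchar(space$states) & m > 0
      marg_list[[length(marg_list) + 1L]] <- data.frame(
        node = child, parent = n, range = space$states[keep],
        prob = m[keep], sub_threshold = m[keep] < floor,
        stringsAsFactors = FALSE)
      # down-pass recursion into internal children
      if (child > eng$ntip) {
        sib <- if (side == 1L) cr else cl
        sib_side_idx <- eng$r_idx  # child treated as left slot below
        vals <- out$weight * gv[eng$anc_idx] * up$down[sib_side_idx, sib]
        H <- as.vector(B %*% vals)
        r <- rows[side]
        Pb <- matrix(up$Pall[, r], K, K)
        g <- as.vector(crossprod(Pb, H))
        sc <- sum(g)
        if (sc > 0) {
          G[, child] <- g / sc
          abovelog[child] <- abovelog[n] + up$sublog[sib] + log(sc)
        }
      }
    }
  }
  node_scenarios <- do.call(rbind, scen_list)
  branch_marginals <- do.call(rbind, marg_list)
  rsc <- node_scenarios[node_scenarios$node == root, ]
  root_states <- aggregate(rel_prob ~ ancestor, rsc, sum)
  names(root_states) <- c("range", "prob")
  root_states <- root_states[order(-root_states$prob), ]
  rownames(root_states) <- NULL
  structure(list(node_scenarios = node_scenarios,
                 branch_marginals = branch_marginals,
                 root_states = root_states, neg_loglik = neg_loglik,
                 d = d, e = e, window = window, floor = floor,
                 root_node = root, phy = phy),
            class = "dec_ancestral")
}

#' @export
print.dec_ancestral <- function(x, ...) {
  cat(sprintf("DEC ancestral reconstruction: -lnL = %.4f (d = %.4g, e = %.4g)\n",
              x$neg_loglik, x$d, x$e))
  cat("Root state probabilities:\n")
  print(x$root_states, row.names = FALSE)
  invisible(x)
}
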