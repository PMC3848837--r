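# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the matrix exponential is a truncated
# Taylor series, the DEC likelihood is an exhaustive enumeration over joint
# cladogenetic scenario assignments, and summary statistics are naive
# two-pass formulas.

series_expm <- function(M) {
  P <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in 1:300) {
    term <- term %*% M / k
    P <- P + term
    if (max(abs(term)) < 1e-18) break
  }
  P
}

# Exhaustive-enumeration DEC likelihood (and per-node scenario posteriors)
# for trees of <= 5 tips. Enumerates every assignment of a cladogenetic
# scenario to every internal node; branch factors come from the series
# matrix exponential.
oracle_dec <- function(phy, tip_ranges, space, d, e, root_states = NULL,
                       posteriors = FALSE) {
  Q <- build_rate_matrix(space, d, e)
  out <- cladogenetic_outcomes(space)
  states <- space$states
  if (is.null(root_states)) root_states <- states[nzchar(states)]
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  internal <- (ntip + 1L):(ntip + phy$Nnode)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(out))),
                                      length(internal))))
  lidx <- match(out$left, states)
  ridx <- match(out$right, states)
  aidx <- match(out$ancestor, states)
  w <- exp(rowSums(matrix(log(out$weight[combos]), nrow(combos))))
  ok <- out$ancestor[combos[, match(root, internal)]] %in% root_states
  pr <- rep(1, nrow(combos))
  for (r in seq_len(nrow(phy$edge))) {
    par <- phy$edge[r, 1L]
    ch <- phy$edge[r, 2L]
    P <- series_expm(Q * phy$edge.length[r])
    ps <- combos[, match(par, internal)]
    side <- which(phy$edge[phy$edge[, 1L] == par, 2L] == ch)
    top <- if (side == 1L) lidx[ps] else ridx[ps]
    bottom <- if (ch <= ntip)
      rep(match(tip_ranges[phy$tip.label[ch]], states), nrow(combos))
    else aidx[combos[, match(ch, internal)]]
    pr <- pr * P[cbind(top, bottom)]
  }
  contrib <- w * pr * ok
  total <- sum(contrib)
  res <- list(neg_loglik = -log(total), total = total)
  if (posteriors) {
    res$post <- lapply(seq_along(internal), function(ni) {
      as.vector(rowsum(contrib, combos[, ni])[
        as.character(seq_len(nrow(out))), 1L]) / total
    })
    names(res$post) <- internal
  }
  res
}

naive_mean_ci <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  half <- qt(0.975, n - 1) * sqrt(v / n)
  c(mean = m, lower = m - half, upper = m + half)
}

naive_welch <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  vx <- sum((x - mx)^2) / (length(x) - 1)
  vy <- sum((y - my)^2) / (length(y) - 1)
  sex <- vx / length(x); sey <- vy / length(y)
  t <- (mx - my) / sqrt(sex + sey)
  df <- (sex + sey)^2 /
    (sex^2 / (length(x) - 1) + sey^2 / (length(y) - 1))
  c(t = t, df = df)
}

hub_space <- function() {
  build_state_space(c(Amazon = "A", Andes = "B", `Atlantic Forest` = "C"),
                    max_size = 2,
                    adjacency = list(c("A", "B"), c("A", "C")))
}

two_area_space <- function() build_state_space(c("A", "B"), max_size = 2)

random_case <- function(space, ntip) {
  phy <- ape::rcoal(ntip)
  nonempty <- space$states[nzchar(space$states)]
  tips <- setNames(sample(nonempty, ntip, replace = TRUE), phy$tip.label)
  list(phy = phy, tips = tips,
       d = runif(1, 0.01, 0.5), e = runif(1, 0.01, 0.3))
}
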