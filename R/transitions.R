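#' Classify branch range calls by a certainty threshold
#'
#' Each daughter branch gets the range with the highest marginal probability
#' from the ancestral reconstruction; the call is certain when that
#' probability reaches `threshold` (>=, so a marginal exactly at the
#' threshold is certain). The root node's ancestor-state call is included so
#' transitions on the root's daughter branches can be polarized.
#'
#' @param recon A `dec_ancestral` object from [ancestral_splits()].
#' @param threshold Certainty threshold on the marginal probability
#'   (default 0.75).
#' @return Data frame with columns `node`, `range`, `prob`, `certain`.
#' @export
classify_branch_ranges <- function(recon, threshold = 0.75) {
  stopifnot(inherits(recon, "dec_ancestral"),
            threshold >= 0, threshold <= 1)
  bm <- recon$branch_marginals
  calls <- do.call(rbind, lapply(split(bm, bm$node), function(b) {
    b <- b[order(-b$prob), ]
    data.frame(node = b$node[1L], range = b$range[1L], prob = b$prob[1L])
  }))
  rs <- recon$root_states
  calls <- rbind(calls, data.frame(node = recon$root_node,
                                   range = rs$range[1L], prob = rs$prob[1L]))
  calls$certain <- calls$prob >= threshold
  rownames(calls) <- NULL
  calls[order(calls$node), ]
}

focal_membership <- function(range, focal) {
  areas <- strsplit(range, "", fixed = TRUE)[[1L]]
  intersect(focal, areas)
}

#' Detect biogeographic transitions between two focal regions
#'
#' A transition is emitted wherever a daughter branch's called range differs
#' from its parent branch's called range in focal-region membership (a gain
#' or loss of one of the two focal areas). Polarity is the parent's focal
#' region -> the daughter's new focal region when the parent call is
#' certain; otherwise the search walks rootward over uncertain calls up to
#' three branches back (attribution depths i/ii/iii) for the earliest
#' certain ancestor. If the parent call is uncertain but every candidate
#' parent range (optionally taken from `marginals`) implies the same source
#' region, polarity is still emitted with a note. The event window spans
#' from the age of the node where the certain ancestral state was last held
#' (earliest bound, stem) down to the age of the daughter node (latest
#' bound, crown; 0 for a tip).
#'
#' @param calls Data frame from [classify_branch_ranges()] covering every
#'   branch (and the root).
#' @param phy The time tree the calls refer to.
#' @param focal Character vector of the two focal area codes,
#'   `c(source-lowland, highland)` order only affects labels (default
#'   `c("A", "B")`, Amazon and Andes).
#' @param marginals Optional `branch_marginals` data frame used to list
#'   candidate parent ranges when the parent call is uncertain.
#' @param max_depth Attribution cap in branches walked rootward (default 3
#'   = depth iii).
#' @return Data frame of transition events (possibly 0 rows) with polarity,
#'   attribution depth, bounds, kind, and supporting probabilities.
#' @export
detect_transitions <- function(calls, phy, focal = c("A", "B"),
                               marginals = NULL, max_depth = 3) {
  stopifnot(length(focal) == 2L)
  ages <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  call_range <- setNames(calls$range, calls$node)
  call_prob <- setNames(calls$prob, calls$node)
  call_certain <- setNames(calls$certain, calls$node)
  parent_of <- setNames(phy$edge[, 1L], phy$edge[, 2L])
  events <- list()
  depth_labels <- c("i", "ii", "iii")

  for (n in as.integer(names(parent_of))) {
    p <- parent_of[[as.character(n)]]
    rn <- call_range[[as.character(n)]]
    rp <- call_range[[as.character(p)]]
    if (is.null(rn) || is.null(rp)) stop("calls do not cover every branch")
    mn <- focal_membership(rn, focal)
    mp <- focal_membership(rp, focal)
    if (setequal(mn, mp)) next
    gained <- setdiff(mn, mp)
    lost <- setdiff(mp, mn)
    kind <- if (length(gained) && length(lost)) "shift"
            else if (length(gained)) "expansion" else "contraction"
    dest <- if (length(gained)) gained[1L] else mn[1L]
    if (is.na(dest)) next  # focal membership vanished entirely

    # walk rootward for the earliest certain ancestor (depth i..max_depth)
    anc <- p
    depth <- 1L
    src <- NA_character_
    note <- NA_character_
    support <- call_prob[[as.character(p)]]
    while (depth <= max_depth) {
      if (isTRUE(call_certain[[as.character(anc)]])) {
        m <- focal_membership(call_range[[as.character(anc)]], focal)
        m <- setdiff(m, dest)
        if (length(m) == 1L) src <- m
        support <- call_prob[[as.character(anc)]]
        break
      }
      if (anc == root) break
      anc <- parent_of[[as.character(anc)]]
      depth <- depth + 1L
    }
    candidates <- character(0)
    if (is.na(src)) {
      depth <- 1L
      anc <- p
      # candidate source regions implied by plausible parent ranges
      cand_ranges <- if (!is.null(marginals))
        marginals$range[marginals$node == p & marginals$prob > 0]
      else rp
      candidates <- unique(unlist(lapply(cand_ranges, function(r)
        setdiff(focal_membership(r, focal), dest))))
      candidates <- candidates[!is.na(candidates)]
      if (length(candidates) == 1L) {
        src <- candidates
        note <- "polarity inferred: all candidate parent ranges agree"
      }
    }
    polarity <- if (!is.na(src)) paste(src, dest, sep = "->") else "uncertain"
    events[[length(events) + 1L]] <- data.frame(
      node = n, parent = p, kind = kind,
      from_range = rp, to_range = rn,
      polarity = polarity,
      candidate_sources = paste(candidates, collapse = ","),
      depth = depth_labels[min(depth, max_depth)],
      earliest = ages[anc], latest = ages[n],
      midpoint = (ages[anc] + ages[n]) / 2,
      support = support, note = note, stringsAsFactors = FALSE)
  }
  if (!length(events))
    return(data.frame(node = integer(0), parent = integer(0),
                      kind = character(0), from_range = character(0),
                      to_range = character(0), polarity = character(0),
                      candidate_sources = character(0), depth = character(0),
                      earliest = numeric(0), latest = numeric(0),
                      midpoint = numeric(0), support = numeric(0),
                      note = character(0)))
  do.call(rbind, events)
}

#' The three transition-age bins
#'
#' Type 3: 2.5 Ma or younger, either polarity (Plio-Pleistocene climate
#' cycling). Type 2: older than 2.5 and up to 7.5 Ma, with Andean origins
#' expected (lowland recolonization after the Pebas wetlands receded).
#' Type 1: older than 7.5 Ma, with Amazonian origins expected (colonization
#' of the uplifting Andes). The polarity expectations are annotations, not
#' filters.
#'
#' @return Data frame with `type`, `min_age`, `max_age`, `width`,
#'   `expected_polarity`.
#' @export
transition_type_bins <- function() {
  data.frame(type = c(3L, 2L, 1L),
             min_age = c(0, 2.5, 7.5),
             max_age = c(2.5, 7.5, Inf),
             width = c(2.5, 5, Inf),
             expected_polarity = c("either", "Andes-to-Amazon",
                                   "Amazon-to-Andes"),
             stringsAsFactors = FALSE)
}

#' Assign a transition age to a type bin
#'
#' Bins are left-open/right-closed so every non-negative age falls in
#' exactly one bin: type 3 for ages <= 2.5 Ma, type 2 for (2.5, 7.5] Ma,
#' type 1 above 7.5 Ma.
#'
#' @param age Transition age(s) in Ma (>= 0); by convention the window
#'   midpoint.
#' @param polarity Optional polarity string(s) recorded alongside.
#' @return Data frame with `age`, `type`, bin bounds, `expected_polarity`,
#'   and `polarity` if given.
#' @export
assign_type <- function(age, polarity = NULL) {
  if (any(age < 0)) stop("transition age must be non-negative")
  bins <- transition_type_bins()
  idx <- ifelse(age <= 2.5, 1L, ifelse(age <= 7.5, 2L, 3L))
  res <- cbind(data.frame(age = age), bins[idx, , drop = FALSE])
  if (!is.null(polarity)) res$polarity <- polarity
  rownames(res) <- NULL
  res
}
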