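#' Build a DEC range state space
#'
#' Enumerates the geographic range states allowed under the DEC model: all
#' single-area ranges, plus every multi-area range up to `max_size` whose
#' areas form a connected set under the adjacency relation, plus the empty
#' (globally extinct) range. With the Amazon-hub adjacency used for the
#' Andes/Amazon/Atlantic Forest analysis, `{B,C}` (Andes + Atlantic Forest)
#' is excluded because those areas only connect through the Amazon.
#'
#' States are ordered by range size then lexicographically, with the empty
#' range first.
#'
#' @param areas Character vector of single-letter area codes, optionally
#'   named by the full area name (e.g. `c(Amazon = "A", Andes = "B")`).
#' @param max_size Maximum number of areas in a range (>= 1).
#' @param adjacency `NULL` for all-pairs adjacency, or a two-column
#'   matrix/data frame (or list of length-2 vectors) of adjacent area pairs;
#'   the relation is symmetrized.
#' @return An object of class `range_state_space`.
#' @export
build_state_space <- function(areas, max_size = 2, adjacency = NULL) {
  codes <- unname(as.character(areas))
  if (any(nchar(codes) != 1L)) stop("area codes must be single characters")
  if (anyDuplicated(codes)) stop("area codes must be unique")
  if (length(codes) < 1L) stop("need at least one area")
  if (max_size < 1L) stop("max_size must be >= 1")
  area_names <- if (!is.null(names(areas))) names(areas) else codes

  n <- length(codes)
  adj <- matrix(FALSE, n, n, dimnames = list(codes, codes))
  if (is.null(adjacency)) {
    adj[] <- TRUE
  } else {
    if (is.list(adjacency) && !is.data.frame(adjacency))
      adjacency <- do.call(rbind, adjacency)
    adjacency <- as.matrix(adjacency)
    bad <- setdiff(unique(as.vector(adjacency)), codes)
    if (length(bad))
      stop("adjacency refers to unknown area(s): ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(adjacency))) {
      a <- adjacency[i, 1L]; b <- adjacency[i, 2L]
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  diag(adj) <- TRUE

  connected <- function(set) {
    if (length(set) <= 1L) return(TRUE)
    seen <- set[1L]
    repeat {
      nb <- set[colSums(adj[seen, set, drop = FALSE]) > 0]
      nb <- union(seen, nb)
      if (length(nb) == length(seen)) break
      seen <- nb
    }
    length(seen) == length(set)
  }

  sets <- list(character(0))
  for (k in seq_len(min(max_size, n))) {
    combs <- utils::combn(sort(codes), k, simplify = FALSE)
    sets <- c(sets, Filter(connected, combs))
  }
  states <- vapply(sets, paste0, "", collapse = "")
  ord <- order(lengths(sets), states)
  sets <- sets[ord]
  states <- states[ord]

  structure(list(codes = codes, area_names = area_names, adjacency = adj,
                 max_size = max_size, states = states, sets = sets),
            class = "range_state_space")
}

#' @export
print.range_state_space <- function(x, ...) {
  cat("DEC range state space:", length(x$codes), "areas (",
      paste(x$codes, collapse = ", "), "), max range size", x$max_size, "\n")
  cat("States:", paste(ifelse(nzchar(x$states), x$states, "(empty)"),
                       collapse = " "), "\n")
  invisible(x)
}

#' Read an area/adjacency configuration
#'
#' YAML config with fields `areas` (list of `code`/`name`), `adjacency`
#' (list of pairs, or the string `all`), and `max_range_size`.
#'
#' @param file Path to the YAML file.
#' @return A `range_state_space`.
#' @export
read_area_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  codes <- vapply(cfg$areas, function(a) as.character(a$code), "")
  nms <- vapply(cfg$areas, function(a) as.character(a$name %||% a$code), "")
  areas <- setNames(codes, nms)
  adjacency <- cfg$adjacency
  if (identical(adjacency, "all")) adjacency <- NULL
  build_state_space(areas, max_size = cfg$max_range_size %||% 2,
                    adjacency = adjacency)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

state_index <- function(space, ranges) {
  idx <- match(ranges, space$states)
  if (anyNA(idx))
    stop("range(s) not in state space: ",
         paste(unique(ranges[is.na(idx)]), collapse = ", "))
  idx
}

#' Anagenetic DEC rate matrix
#'
#' Off-diagonal entries: a range `R` gains area `a` (when `R + a` is an
#' allowed state) at rate `d` times the number of areas in `R` adjacent to
#' `a`; `R` loses any one of its areas at rate `e` (singletons decay into
#' the absorbing empty range). Diagonal entries make rows sum to zero; the
#' empty-range row is zero.
#'
#' @param space A `range_state_space`.
#' @param d Dispersal rate (area gains per Ma).
#' @param e Extinction rate (area losses per Ma).
#' @return Square rate matrix with states as dimnames.
#' @export
build_rate_matrix <- function(space, d, e) {
  stopifnot(is.finite(d), is.finite(e), d >= 0, e >= 0)
  K <- length(space$states)
  Q <- matrix(0, K, K, dimnames = list(space$states, space$states))
  for (i in seq_len(K)) {
    R <- space$sets[[i]]
    if (!length(R)) next  # empty range is absorbing
    for (a in setdiff(space$codes, R)) {
      target <- paste0(sort(c(R, a)), collapse = "")
      j <- match(target, space$states)
      if (!is.na(j)) Q[i, j] <- Q[i, j] + d * sum(space$adjacency[R, a])
    }
    for (a in R) {
      target <- paste0(sort(setdiff(R, a)), collapse = "")
      j <- match(target, space$states)
      Q[i, j] <- Q[i, j] + e
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Branch transition probabilities
#'
#' Matrix exponential `expm(Q t)` of the anagenetic rate matrix over a
#' branch of duration `t` Ma, computed by scaling-and-squaring with a Pade
#' approximant ([Matrix::expm()]). Tiny negative entries from roundoff are
#' clamped to zero.
#'
#' @param Q Rate matrix from [build_rate_matrix()].
#' @param t Branch duration in Ma (>= 0).
#' @return Row-stochastic matrix of the same dimension as `Q`.
#' @export
branch_transition_probs <- function(Q, t) {
  if (!all(is.finite(Q))) stop("non-finite entries in rate matrix")
  stopifnot(t >= 0)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  if (min(P) < -1e-9)
    warning("matrix exponential produced negative entries below -1e-9")
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

#' Cladogenetic outcomes of the DEC model
#'
#' For a single-area ancestor both daughters inherit the range. For a
#' multi-area ancestor `R` the allowed splits are vicariance (one daughter
#' takes one area, the other the complement, when the complement is an
#' allowed state) and peripheral-isolate sympatry (one daughter takes a
#' single area of `R`, the other inherits all of `R`). All outcomes of an
#' ancestor are equally weighted.
#'
#' @param space A `range_state_space`.
#' @return Data frame with columns `ancestor`, `left`, `right`, `weight`.
#' @export
cladogenetic_outcomes <- function(space) {
  rows <- list()
  for (i in seq_along(space$states)) {
    R <- space$sets[[i]]
    if (!length(R)) next
    st <- space$states[i]
    if (length(R) == 1L) {
      out <- matrix(c(st, st), 1L)
    } else {
      pairs <- character(0)
      for (a in R) {
        rest <- paste0(sort(setdiff(R, a)), collapse = "")
        if (rest %in% space$states) {
          pairs <- c(pairs, paste(a, rest, sep = "\r"),
                     paste(rest, a, sep = "\r"))
        }
        pairs <- c(pairs, paste(a, st, sep = "\r"), paste(st, a, sep = "\r"))
      }
      pairs <- unique(pairs)
      out <- do.call(rbind, strsplit(pairs, "\r", fixed = TRUE))
    }
    rows[[st]] <- data.frame(ancestor = st, left = out[, 1L],
                             right = out[, 2L],
                             weight = 1 / nrow(out),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
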