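#' Read the packaged compendium of dated highland-lowland transitions
#'
#' One row per individual transition, with the raw age string preserved.
#' The default file is the package's curated literature compendium of
#' Andes/Amazon transitions across mammals, birds, amphibians and insects.
#'
#' @param file Path to a TSV with columns `class`, `group`, `taxa`,
#'   `highest_elevation_m`, `polarity`, `age_raw`, `source`.
#' @return Data frame of transition records.
#' @export
read_transition_records <- function(file = system.file(
    "extdata", "table5_transitions.tsv", package = "decrange")) {
  rec <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("class", "group", "taxa", "polarity", "age_raw")
  miss <- setdiff(needed, names(rec))
  if (length(miss))
    stop("compendium file lacks column(s): ", paste(miss, collapse = ", "))
  ok <- rec$polarity %in% c("Andes-to-Amazon", "Amazon-to-Andes")
  if (!all(ok))
    stop("unknown polarity value(s): ",
         paste(unique(rec$polarity[!ok]), collapse = ", "))
  rec
}

#' Normalize a raw transition-age string to a point age
#'
#' Rules: a plain age is used as is (`point`); a range `"x-y"` becomes its
#' midpoint (`midpoint`); `"< 1 Ma"` becomes 0.5 Ma (`half-Ma`);
#' `"not dated"` is excluded; a percent-divergence annotation defers to its
#' parenthesized Ma value (e.g. `"12.7% in cyt-b (6.4 Ma)"` -> 6.4,
#' `point`).
#'
#' @param raw Character vector of raw age strings.
#' @return Data frame with numeric `age` (`NA` when excluded) and the
#'   `rule` applied (`point`, `midpoint`, `half-Ma`, `excluded`).
#' @export
normalize_age <- function(raw) {
  raw <- as.character(raw)
  one <- function(x) {
    s <- trimws(x)
    if (!nzchar(s)) stop("empty age string")
    if (grepl("not dated", s, ignore.case = TRUE))
      return(c(NA_real_, "excluded"))
    # percent divergence with parenthesized Ma value
    m <- regmatches(s, regexec("\\(([0-9.]+)\\s*Ma\\)", s))[[1L]]
    if (length(m) == 2L) return(c(as.numeric(m[2L]), "point"))
    s <- sub("\\s*Ma$", "", s)
    if (grepl("^<", s)) {
      v <- as.numeric(trimws(sub("^<", "", s)))
      if (is.na(v)) stop("unparseable age string: ", x)
      return(c(v / 2, "half-Ma"))
    }
    if (grepl("^[0-9.]+\\s*[-–]\\s*[0-9.]+$", s)) {
      parts <- as.numeric(strsplit(s, "\\s*[-–]\\s*")[[1L]])
      return(c(mean(parts), "midpoint"))
    }
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("unparseable age string: ", x)
    c(v, "point")
  }
  res <- lapply(raw, one)
  age <- as.numeric(vapply(res, `[`, "", 1L))
  rule <- vapply(res, `[`, "", 2L)
  if (any(!is.na(age) & age <= 0))
    stop("normalized age must be positive: ",
         paste(raw[!is.na(age) & age <= 0], collapse = ", "))
  data.frame(age = age, rule = rule, stringsAsFactors = FALSE)
}

dated_ages_by_polarity <- function(records) {
  na <- normalize_age(records$age_raw)
  split(na$age[!is.na(na$age)], records$polarity[!is.na(na$age)])
}

#' Per-polarity counts, mean transition ages and 95% confidence intervals
#'
#' Counts are over dated records (undated records are listed separately);
#' the CI is `mean +/- t(n-1, 0.975) * sd / sqrt(n)`.
#'
#' @param records Transition records (see [read_transition_records()]).
#' @return Data frame with one row per polarity: `n_dated`, `n_undated`,
#'   `mean_age`, `sd_age`, `ci_lower`, `ci_upper`.
#' @export
summarize_polarity <- function(records) {
  na <- normalize_age(records$age_raw)
  pols <- c("Andes-to-Amazon", "Amazon-to-Andes")
  do.call(rbind, lapply(pols, function(p) {
    ages <- na$age[records$polarity == p & !is.na(na$age)]
    n_un <- sum(records$polarity == p & is.na(na$age))
    if (length(ages) >= 2L) {
      m <- mean(ages); s <- sd(ages)
      half <- qt(0.975, length(ages) - 1L) * s / sqrt(length(ages))
      ci <- m + c(-1, 1) * half
    } else {
      m <- if (length(ages)) mean(ages) else NA_real_
      s <- NA_real_; ci <- c(NA_real_, NA_real_)
    }
    data.frame(polarity = p, n_dated = length(ages), n_undated = n_un,
               mean_age = m, sd_age = s, ci_lower = ci[1L],
               ci_upper = ci[2L], stringsAsFactors = FALSE)
  }))
}

#' Monte Carlo goodness-of-fit test of polarity balance
#'
#' Chi-square statistic of the two polarity counts against an equal (50:50)
#' expectation, with the p-value simulated by drawing binomial counts under
#' the null and using the add-one `(r + 1) / (N + 1)` estimator.
#'
#' @param counts Integer vector of length 2 (counts per polarity).
#' @param replicates Number of Monte Carlo replicates (default 10000).
#' @param seed Optional integer seed, recorded in the output.
#' @return List with `statistic`, `p_value`, `replicates`, `seed`,
#'   `expected`.
#' @export
polarity_chisq <- function(counts, replicates = 10000, seed = NULL) {
  stopifnot(length(counts) == 2L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  expected <- total / 2
  stat <- sum((counts - expected)^2 / expected)
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(replicates, total, 0.5)
  sim <- 2 * (x - expected)^2 / expected
  p <- (sum(sim >= stat - 1e-12) + 1) / (replicates + 1)
  list(statistic = stat, p_value = p, replicates = replicates, seed = seed,
       expected = expected)
}

#' Welch two-sample comparison of transition-age means by polarity
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, Andes-origin ages minus Amazon-origin ages.
#'
#' @param records Transition records.
#' @return List with `t`, `df`, `p_value`, and the per-polarity means.
#' @export
compare_age_means <- function(records) {
  ag <- dated_ages_by_polarity(records)
  x <- ag[["Andes-to-Amazon"]]
  y <- ag[["Amazon-to-Andes"]]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 dated records per polarity")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate samples: zero statistic when the means coincide
    tt <- list(statistic = if (mean(x) == mean(y)) 0 else
                 sign(mean(x) - mean(y)) * Inf,
               parameter = length(x) + length(y) - 2,
               p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    tt <- t.test(x, y, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       mean_andes_origin = mean(x), mean_amazon_origin = mean(y),
       n = c(length(x), length(y)))
}

#' Transition counts, percentages and per-Ma rates by type bin
#'
#' Dated records are assigned to the type bins of
#' [transition_type_bins()]; counts are split by polarity, percentages are
#' over all dated records in the (optionally class-filtered) set, and rates
#' divide the count by the bin width in Ma (undefined for the open-ended
#' type 1 bin).
#'
#' @param records Transition records.
#' @param class_filter Optional class name (e.g. `"Birds"`) to restrict to.
#' @return Data frame with one row per bin x polarity.
#' @export
bin_analysis <- function(records, class_filter = NULL) {
  if (!is.null(class_filter)) records <- records[records$class %in% class_filter, ]
  na <- normalize_age(records$age_raw)
  dated <- !is.na(na$age)
  ages <- na$age[dated]
  pol <- records$polarity[dated]
  total <- length(ages)
  bins <- transition_type_bins()
  typed <- assign_type(ages)$type
  grid <- expand.grid(type = bins$type,
                      polarity = c("Andes-to-Amazon", "Amazon-to-Andes"),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(ty, p) sum(typed == ty & pol == p),
                   grid$type, grid$polarity)
  grid$percent <- 100 * grid$n / total
  grid$width <- bins$width[match(grid$type, bins$type)]
  grid$rate_per_ma <- ifelse(is.finite(grid$width), grid$n / grid$width,
                             NA_real_)
  grid$total_dated <- total
  grid
}

#' Convert percent sequence divergence to an age
#'
#' Applies a molecular-clock conversion (default 2% cyt-b divergence per
#' Ma): `age = divergence / rate`. For display the result is rounded
#' half-up to 1 decimal (so 12.7% -> 6.4 Ma under the default clock); set
#' `round = FALSE` for the exact value.
#'
#' @param p_divergence Percent sequence divergence (>= 0).
#' @param rate Clock rate in percent per Ma (> 0).
#' @param round Round half-up to 1 decimal for display (default `TRUE`).
#' @return Age(s) in Ma.
#' @export
divergence_to_age <- function(p_divergence, rate = 2, round = TRUE) {
  if (rate <= 0) stop("rate must be positive")
  if (any(p_divergence < 0)) stop("divergence must be non-negative")
  age <- p_divergence / rate
  if (round) round_half_up(age, 1) else age
}

#' Round half-up (decimal)
#'
#' Unlike [base::round()] (banker's rounding on binary doubles), exact
#' decimal halves round away from zero: `round_half_up(6.35, 1)` is 6.4.
#' Intended for non-negative display values.
#'
#' @param x Non-negative numeric vector.
#' @param digits Number of decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5 + sqrt(.Machine$double.eps)) / f
}
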