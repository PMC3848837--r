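#' Read a tip-range coding table
#'
#' TSV with two columns, `tip` and `areas`, where `areas` is the
#' concatenated area codes of the tip's range (e.g. `AB`).
#'
#' @param file Path to the TSV.
#' @return Named character vector of ranges.
#' @export
read_tip_ranges <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("tip", "areas") %in% names(x)))
    stop("tip-range table needs columns 'tip' and 'areas'")
  if (anyDuplicated(x$tip))
    stop("duplicate tip(s) in range table")
  setNames(toupper(trimws(x$areas)), x$tip)
}

#' Write a tip-range coding table
#'
#' @param ranges Named character vector of ranges.
#' @param file Output path.
#' @export
write_tip_ranges <- function(ranges, file) {
  write.table(data.frame(tip = names(ranges), areas = unname(ranges)),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @importFrom utils write.table
NULL
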