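#' Construct and validate a marker map
#'
#' A marker map places biallelic SNP markers on the 19 chromosomes of the
#' allotetraploid *Brassica napus* genome (A01--A10 from the *B. rapa* A
#' subgenome, C01--C09 from the *B. oleracea* C subgenome).  Positions are
#' 1-based base pairs and must be strictly increasing within a chromosome;
#' marker ids must be unique.  Scaled-down maps using a leading subset of
#' chromosome names (e.g. A01, A02, C01, C02) are valid.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom character vector of chromosome names from
#'   `A01..A10, C01..C09`.
#' @param pos integer vector of 1-based physical positions (bp).
#' @return A `data.frame` of class `marker_map` with columns
#'   `marker_id`, `chrom`, `pos`, ordered by (chrom, pos).
#' @export
marker_map <- function(marker_id, chrom, pos) {
  map <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    stringsAsFactors = FALSE
  )
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  validate_marker_map(map)
  map
}

#' @keywords internal
valid_chromosomes <- function() {
  c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
}

validate_marker_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("marker_id", "chrom", "pos") %in% names(map)))
  if (anyDuplicated(map$marker_id)) {
    dup <- unique(map$marker_id[duplicated(map$marker_id)])
    stop("duplicated marker ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- setdiff(unique(map$chrom), valid_chromosomes())
  if (length(bad)) {
    stop("unknown chromosome name(s): ", paste(bad, collapse = ", "))
  }
  if (any(is.na(map$pos)) || any(map$pos < 1)) {
    stop("marker positions must be positive 1-based integers")
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      stop("positions not strictly increasing on chromosome ", ch)
    }
  }
  invisible(map)
}

#' Subgenome of a chromosome
#'
#' Maps each chromosome name to subgenome "A" or "C" by its first character.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of "A"/"C".
#' @export
subgenome <- function(chrom) {
  sg <- substr(chrom, 1L, 1L)
  bad <- setdiff(unique(sg), c("A", "C"))
  if (length(bad)) stop("chromosome(s) not in subgenome A or C: ",
                        paste(bad, collapse = ", "))
  sg
}

#' Read a marker map from TSV
#'
#' Expects a header line `marker_id  chrom  pos` (tab-separated).
#'
#' @param path path to the TSV file.
#' @return a validated [marker_map()].
#' @export
read_marker_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  marker_map(df$marker_id, df$chrom, df$pos)
}

#' Write a marker map to TSV
#'
#' @param map a [marker_map()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_marker_map <- function(map, path) {
  validate_marker_map(map)
  utils::write.table(as.data.frame(map)[, c("marker_id", "chrom", "pos")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
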