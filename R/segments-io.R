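#' Assemble an IBD segment table
#'
#' @param sample_a,sample_b line names per segment.
#' @param chrom chromosome names.
#' @param start_bp,end_bp 1-based inclusive positions of the first/last
#'   supporting marker.
#' @param n_markers compared (non-missing-in-both) markers inside.
#' @param n_mismatch discordant markers tolerated inside.
#' @return data.frame with a derived `length_mb = (end_bp - start_bp)/1e6`
#'   column, sorted by (chrom, start_bp, pair).
#' @export
ibd_segments <- function(sample_a, sample_b, chrom, start_bp, end_bp,
                         n_markers = NA_integer_, n_mismatch = 0L) {
  n <- length(chrom)
  df <- data.frame(sample_a = rep_len(as.character(sample_a), n),
                   sample_b = rep_len(as.character(sample_b), n),
                   chrom = as.character(chrom),
                   start_bp = as.integer(start_bp),
                   end_bp = as.integer(end_bp),
                   n_markers = rep_len(as.integer(n_markers), n),
                   n_mismatch = rep_len(as.integer(n_mismatch), n),
                   stringsAsFactors = FALSE)
  if (n && any(df$start_bp > df$end_bp)) stop("segment start_bp > end_bp")
  df$length_mb <- (df$end_bp - df$start_bp) / 1e6
  df <- df[order(df$chrom, df$start_bp, df$sample_a, df$sample_b), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write IBD segments as BED6
#'
#' Internal coordinates are 1-based inclusive marker positions; BED is
#' 0-based half-open, so a segment `[start_bp, end_bp]` is written as
#' `start_bp - 1, end_bp`.  The name field is `sampleA|sampleB`, score is
#' the number of supporting markers (0 if unknown), strand ".".  Rows are
#' sorted by (chrom, start, pair) for byte-stable output.
#'
#' @param segments a segment table from [ibd_segments()] or [pairwise_ibd()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(segments$start_bp <= segments$end_bp))
  ord <- order(segments$chrom, segments$start_bp,
               segments$sample_a, segments$sample_b)
  s <- segments[ord, , drop = FALSE]
  score <- s$n_markers
  score[is.na(score)] <- 0L
  bed <- data.frame(chrom = s$chrom,
                    start = s$start_bp - 1L,
                    end = s$end_bp,
                    name = paste(s$sample_a, s$sample_b, sep = "|"),
                    score = score,
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read IBD segments from BED6
#'
#' Inverse of [write_segments_bed()]: converts 0-based half-open BED back
#' to 1-based inclusive coordinates and splits the `sampleA|sampleB` name.
#'
#' @param path BED path.
#' @return a segment data.frame as from [ibd_segments()].
#' @export
read_segments_bed <- function(path) {
  if (file.size(path) == 0) {
    return(ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0)))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected BED6")
  pair <- strsplit(bed[[4]], "|", fixed = TRUE)
  ok <- lengths(pair) == 2
  if (!all(ok)) stop("BED name field must be 'sampleA|sampleB'")
  ibd_segments(sample_a = vapply(pair, `[`, "", 1),
               sample_b = vapply(pair, `[`, "", 2),
               chrom = bed[[1]],
               start_bp = bed[[2]] + 1L,
               end_bp = bed[[3]],
               n_markers = ifelse(bed[[5]] > 0, bed[[5]], NA_integer_))
}

#' Read QTL or gene intervals
#'
#' Two layouts are accepted:
#' * `format = "tsv"`: header `feature_id  kind  trait  chrom  start  end`
#'   with 1-based inclusive coordinates;
#' * `format = "bed"`: BED with `chrom  start  end  name` (0-based
#'   half-open, converted on read) and an optional 7th `trait` column;
#'   `kind` is then taken from the `kind` argument.
#'
#' @param path input path.
#' @param format `"tsv"` or `"bed"`.
#' @param kind default feature kind (`"QTL"` or `"gene"`) for BED input.
#' @return data.frame `feature_id, kind, trait, chrom, start, end`.
#' @export
read_features <- function(path, format = c("tsv", "bed"), kind = "gene") {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "kind", "trait", "chrom", "start", "end")
    if (!all(need %in% names(df))) {
      stop("feature TSV needs columns: ", paste(need, collapse = ", "))
    }
    df <- df[, need]
  } else {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    df <- data.frame(feature_id = bed[[4]], kind = kind,
                     trait = if (ncol(bed) >= 7) bed[[7]] else NA_character_,
                     chrom = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
                     stringsAsFactors = FALSE)
  }
  validate_features(df)
}

validate_features <- function(df) {
  traits <- c("flowering_time", "oil", "glucosinolate", "erucic_acid",
              "protein", "root_P")
  bad <- setdiff(stats::na.omit(unique(df$trait)), traits)
  if (length(bad)) stop("unknown trait label(s): ", paste(bad, collapse = ", "))
  if (any(df$start > df$end)) stop("feature start > end")
  if (!all(df$kind %in% c("QTL", "gene"))) stop("feature kind must be QTL or gene")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  rownames(df) <- NULL
  df
}

#' Write features to the package TSV layout
#' @param features data.frame as returned by [read_features()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(
    features[, c("feature_id", "kind", "trait", "chrom", "start", "end")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
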