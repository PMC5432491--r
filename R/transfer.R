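#' Aggregate per-pair IBD totals by transfer path
#'
#' Takes ancestor-to-final-cultivar IBD summaries (block counts and total
#' sizes), classifies each pair as a direct or indirect transfer over the
#' pedigree with [classify_path()], and sums counts and sizes within each
#' path type per final cultivar.  Pairs with no pedigree path are
#' flagged and excluded from the subtotals.
#'
#' @param records data.frame with columns `ancestor`, `descendant`,
#'   `n_ibd`, `total_size_mb`.
#' @param ped a [pedigree()].
#' @return list of class `transfer_table`:
#'   \describe{
#'     \item{pairs}{the input rows with a `path_type` column
#'       (`direct`/`indirect`/`none`).}
#'     \item{subtotals}{one row per (descendant, path_type) with summed
#'       `n_ibd` and `total_size_mb` (path_type `none` excluded).}
#'   }
#' @export
aggregate_transfer <- function(records, ped) {
  stopifnot(all(c("ancestor", "descendant", "n_ibd", "total_size_mb")
                %in% names(records)))
  if (nrow(records) == 0) {
    return(structure(list(
      pairs = cbind(records, path_type = character(0)),
      subtotals = data.frame(descendant = character(0),
                             path_type = character(0),
                             n_ibd = integer(0),
                             total_size_mb = numeric(0))),
      class = "transfer_table"))
  }
  known <- ped$nodes$name
  pt <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    pt[i] <- if (records$ancestor[i] %in% known &&
                 records$descendant[i] %in% known) {
      classify_path(ped, records$ancestor[i], records$descendant[i])
    } else {
      "none"
    }
  }
  pairs <- cbind(records, path_type = pt, stringsAsFactors = FALSE)
  use <- pairs[pairs$path_type != "none", , drop = FALSE]
  if (nrow(use)) {
    key <- interaction(use$descendant, use$path_type, drop = TRUE)
    subtotals <- do.call(rbind, lapply(split(use, key), function(s) {
      data.frame(descendant = s$descendant[1], path_type = s$path_type[1],
                 n_ibd = sum(s$n_ibd), total_size_mb = sum(s$total_size_mb),
                 stringsAsFactors = FALSE)
    }))
    subtotals <- subtotals[order(subtotals$descendant, subtotals$path_type), ,
                           drop = FALSE]
    rownames(subtotals) <- NULL
  } else {
    subtotals <- data.frame(descendant = character(0),
                            path_type = character(0),
                            n_ibd = integer(0), total_size_mb = numeric(0))
  }
  structure(list(pairs = pairs, subtotals = subtotals),
            class = "transfer_table")
}

#' @export
print.transfer_table <- function(x, ...) {
  cat("transfer_table:", nrow(x$pairs), "ancestor/descendant pairs\n")
  print(x$subtotals)
  invisible(x)
}

#' Flatten a transfer table for TSV output
#'
#' Per-pair rows followed by subtotal rows (`ancestor = "subtotal"`).
#'
#' @param x a `transfer_table` from [aggregate_transfer()].
#' @return a single data.frame.
#' @export
as.data.frame.transfer_table <- function(x, ...) {
  sub <- x$subtotals
  if (nrow(sub)) {
    sub <- data.frame(ancestor = "subtotal", descendant = sub$descendant,
                      n_ibd = sub$n_ibd, total_size_mb = sub$total_size_mb,
                      path_type = sub$path_type, stringsAsFactors = FALSE)
  } else {
    sub <- NULL
  }
  pairs <- x$pairs[, c("ancestor", "descendant", "n_ibd",
                       "total_size_mb", "path_type")]
  out <- rbind(pairs, sub)
  rownames(out) <- NULL
  out
}
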