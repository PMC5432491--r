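#' IBD detector parameters
#'
#' Thresholds for the deterministic concordance-run detector.  Because the
#' cultivars are fully homozygous inbreds, identity by descent manifests
#' directly as long runs of concordant genotype calls; no haplotype
#' frequency model is needed.
#'
#' @param min_markers minimum compared (non-missing-in-both) markers a
#'   segment must contain.
#' @param min_length_mb minimum physical span in Mb
#'   (`(end_bp - start_bp)/1e6`).
#' @param max_mismatch_fraction a run may absorb a discordant marker only
#'   while its running mismatch fraction stays at or below this value
#'   (tolerates genotyping error).
#' @param max_missing_gap_markers a run is broken when more than this many
#'   consecutive markers are missing in either line.
#' @return list of class `detector_params`.
#' @export
detector_params <- function(min_markers = 20L, min_length_mb = 1.0,
                            max_mismatch_fraction = 0.02,
                            max_missing_gap_markers = 50L) {
  stopifnot(min_markers >= 0, min_length_mb >= 0,
            max_mismatch_fraction >= 0, max_mismatch_fraction < 0.5,
            max_missing_gap_markers >= 0)
  structure(list(min_markers = as.integer(min_markers),
                 min_length_mb = as.numeric(min_length_mb),
                 max_mismatch_fraction = as.numeric(max_mismatch_fraction),
                 max_missing_gap_markers = as.integer(max_missing_gap_markers)),
            class = "detector_params")
}

#' Detect IBD segments between two homozygous lines
#'
#' Scans each chromosome for maximal runs of concordant calls between two
#' lines.  Missing calls (in either line) neither extend nor break a run
#' unless more than `max_missing_gap_markers` occur consecutively; a
#' discordant call is absorbed only while the running mismatch fraction
#' stays within `max_mismatch_fraction` (ties between ending one run and
#' starting the next are broken by extending the left run greedily).
#' Run boundaries are always concordant markers.  Runs shorter than
#' `min_markers` compared markers or `min_length_mb` are discarded.
#'
#' Segment length in Mb is `end_bp - start_bp` (not `+ 1`), the
#' conventional reporting of physical spans.
#'
#' @param calls integer samples x markers matrix (0/1/NA), columns in map
#'   order.
#' @param map a [marker_map()].
#' @param a,b line names (rows of `calls`).
#' @param params a [detector_params()].
#' @return segment data.frame from [ibd_segments()], sorted by
#'   (chrom, start_bp).
#' @export
pairwise_ibd <- function(calls, map, a, b, params = detector_params()) {
  if (!a %in% rownames(calls)) stop("unknown line name: ", a)
  if (!b %in% rownames(calls)) stop("unknown line name: ", b)
  validate_marker_map(map)
  stopifnot(ncol(calls) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    x <- calls[a, idx]
    y <- calls[b, idx]
    comp <- which(!is.na(x) & !is.na(y))
    if (!length(comp)) {
      message("pairwise_ibd: chromosome ", ch, " all-missing for pair ",
              a, "/", b, "; skipped")
      next
    }
    eq <- x[comp] == y[comp]
    runs <- concordance_runs(comp, eq, params)
    if (nrow(runs)) {
      runs$start_bp <- map$pos[idx[runs$start_k]]
      runs$end_bp <- map$pos[idx[runs$end_k]]
      runs$chrom <- ch
      out[[length(out) + 1L]] <- runs
    }
  }
  if (!length(out)) {
    return(ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0)))
  }
  df <- do.call(rbind, out)
  keep <- df$n_markers >= params$min_markers &
    (df$end_bp - df$start_bp) / 1e6 >= params$min_length_mb
  df <- df[keep, , drop = FALSE]
  ibd_segments(a, b, df$chrom, df$start_bp, df$end_bp,
               df$n_markers, df$n_mismatch)
}

# Core greedy scan over the comparable markers of one chromosome.
# `comp`: indices (within the chromosome) of markers called in both lines;
# `eq`: concordance at those markers.  Returns runs in comp coordinates
# (start_k/end_k index into the chromosome's marker vector), with
# trailing absorbed mismatches trimmed so boundaries are concordant.
concordance_runs <- function(comp, eq, params) {
  f <- params$max_mismatch_fraction
  gap_max <- params$max_missing_gap_markers
  runs <- list()
  run_pos <- integer(0)   # comp positions in current run
  run_eq <- logical(0)

  close_run <- function() {
    if (!length(run_pos)) return()
    while (length(run_eq) && !run_eq[length(run_eq)]) {
      run_eq <- run_eq[-length(run_eq)]
      run_pos <- run_pos[-length(run_pos)]
    }
    if (length(run_pos)) {
      runs[[length(runs) + 1L]] <<- data.frame(
        start_k = run_pos[1], end_k = run_pos[length(run_pos)],
        n_markers = length(run_pos), n_mismatch = sum(!run_eq))
    }
  }

  for (i in seq_along(comp)) {
    if (length(run_pos)) {
      gap <- comp[i] - run_pos[length(run_pos)] - 1L
      if (gap > gap_max) {
        close_run()
        run_pos <- integer(0); run_eq <- logical(0)
      }
    }
    if (eq[i]) {
      run_pos <- c(run_pos, comp[i])
      run_eq <- c(run_eq, TRUE)
    } else if (length(run_pos)) {
      n_mis <- sum(!run_eq)
      if ((n_mis + 1) / (length(run_eq) + 1) <= f) {
        run_pos <- c(run_pos, comp[i])
        run_eq <- c(run_eq, FALSE)
      } else {
        close_run()
        run_pos <- integer(0); run_eq <- logical(0)
      }
    }
  }
  close_run()
  if (!length(runs)) {
    return(data.frame(start_k = integer(0), end_k = integer(0),
                      n_markers = integer(0), n_mismatch = integer(0)))
  }
  do.call(rbind, runs)
}

#' Detect IBD for many pairs of lines
#'
#' @param calls,map,params as in [pairwise_ibd()].
#' @param pairs data.frame with columns `a`, `b` (or a 2-column matrix).
#' @return concatenated segment table, sorted by
#'   (sample_a, sample_b, chrom, start_bp).
#' @export
all_pairs_ibd <- function(calls, map, pairs, params = detector_params()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) {
    return(ibd_segments(character(0), character(0), character(0),
                        integer(0), integer(0)))
  }
  names(pairs)[1:2] <- c("a", "b")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    pairwise_ibd(calls, map, pairs$a[i], pairs$b[i], params)
  })
  df <- do.call(rbind, res)
  df <- df[order(df$sample_a, df$sample_b, df$chrom, df$start_bp), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-pair, per-subgenome IBD summary
#'
#' Counts segments and sums their lengths for each line pair, split by
#' subgenome (chromosome-name prefix A/C), plus a pooled-over-pairs
#' total.  Both accountings are reported because pooled totals over many
#' pairs can exceed the physical subgenome length.
#'
#' @param segments a segment table.
#' @return list with `per_pair` (one row per pair: `count_A`,
#'   `length_A_mb`, `count_C`, `length_C_mb`, `count_total`,
#'   `length_total_mb`) and `pooled` (single-row totals over all pairs).
#' @export
ibd_summary <- function(segments) {
  if (nrow(segments) == 0) {
    per <- data.frame(sample_a = character(0), sample_b = character(0),
                      count_A = integer(0), length_A_mb = numeric(0),
                      count_C = integer(0), length_C_mb = numeric(0),
                      count_total = integer(0), length_total_mb = numeric(0))
    pooled <- data.frame(count_A = 0L, length_A_mb = 0, count_C = 0L,
                         length_C_mb = 0, count_total = 0L,
                         length_total_mb = 0)
    return(list(per_pair = per, pooled = pooled))
  }
  sg <- subgenome(segments$chrom)
  key <- paste(segments$sample_a, segments$sample_b, sep = "\r")
  per <- do.call(rbind, lapply(split(seq_len(nrow(segments)), key),
                               function(ii) {
    s <- segments[ii, , drop = FALSE]
    g <- sg[ii]
    data.frame(sample_a = s$sample_a[1], sample_b = s$sample_b[1],
               count_A = sum(g == "A"),
               length_A_mb = sum(s$length_mb[g == "A"]),
               count_C = sum(g == "C"),
               length_C_mb = sum(s$length_mb[g == "C"]),
               count_total = nrow(s),
               length_total_mb = sum(s$length_mb),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  pooled <- data.frame(count_A = sum(per$count_A),
                       length_A_mb = sum(per$length_A_mb),
                       count_C = sum(per$count_C),
                       length_C_mb = sum(per$length_C_mb),
                       count_total = sum(per$count_total),
                       length_total_mb = sum(per$length_total_mb))
  list(per_pair = per, pooled = pooled)
}
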