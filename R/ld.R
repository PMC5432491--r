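#' Pairwise linkage disequilibrium (r-squared) between markers
#'
#' For homozygous inbred lines the haplotypes are directly observed, so
#' for two markers with alternate-allele frequencies pA and pB and joint
#' frequency pAB (all over lines non-missing at both markers),
#' `r2 = (pAB - pA pB)^2 / (pA (1-pA) pB (1-pB))`.  Pairs are restricted
#' to the same chromosome within `max_distance_bp`; pairs with fewer
#' than two shared calls, a monomorphic member, or a zero denominator
#' are skipped.  Optionally pairs are restricted to those co-occurring
#' in a sliding window of `window_markers` markers advancing by
#' `window_step` (half a window by default), the windowed accounting
#' used by LD-decay software.
#'
#' @param calls integer samples x markers matrix (0/1/NA).
#' @param map a [marker_map()] aligned to the columns.
#' @param panel line names (default all).
#' @param max_distance_bp maximum pair separation (default 10 Mb).
#' @param window_markers,window_step optional windowed-pair rule; `NULL`
#'   (default) takes all within-distance pairs.
#' @return data.frame: `marker_i`, `marker_j`, `chrom`, `distance_bp`,
#'   `r2`.
#' @export
pairwise_r2 <- function(calls, map, panel = rownames(calls),
                        max_distance_bp = 10e6,
                        window_markers = NULL, window_step = NULL) {
  validate_marker_map(map)
  stopifnot(ncol(calls) == nrow(map))
  sub <- calls[panel, , drop = FALSE]
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pair_ok <- pair_mask(length(idx), window_markers, window_step)
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      jj <- which(pair_ok[[ii]])
      if (!length(jj)) next
      j_all <- idx[jj]
      j_all <- j_all[map$pos[j_all] - map$pos[i] <= max_distance_bp]
      if (!length(j_all)) next
      r2 <- vapply(j_all, function(j) r2_one(sub[, i], sub[, j]), numeric(1))
      keep <- !is.na(r2)
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        marker_i = map$marker_id[i],
        marker_j = map$marker_id[j_all[keep]],
        chrom = ch,
        distance_bp = map$pos[j_all[keep]] - map$pos[i],
        r2 = r2[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(marker_i = character(0), marker_j = character(0),
                      chrom = character(0), distance_bp = integer(0),
                      r2 = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# which later markers (by within-chromosome index) form a pair with
# marker ii; either all, or those sharing a sliding window
pair_mask <- function(m, window_markers, window_step) {
  if (is.null(window_markers)) {
    return(lapply(seq_len(m), function(ii) {
      v <- rep(FALSE, m); if (ii < m) v[(ii + 1):m] <- TRUE; v
    }))
  }
  if (is.null(window_step)) window_step <- max(1L, window_markers %/% 2L)
  masks <- lapply(seq_len(m), function(ii) rep(FALSE, m))
  starts <- unique(c(seq.int(1L, max(1L, m - window_markers + 1L),
                             by = window_step),
                     max(1L, m - window_markers + 1L)))
  for (s in starts) {
    w <- s:min(m, s + window_markers - 1L)
    for (a in seq_along(w)) {
      ii <- w[a]
      if (a < length(w)) masks[[ii]][w[(a + 1):length(w)]] <- TRUE
    }
  }
  masks
}

r2_one <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  pa <- mean(x); pb <- mean(y)
  den <- pa * (1 - pa) * pb * (1 - pb)
  if (den == 0) return(NA_real_)
  pab <- mean(x == 1 & y == 1)
  (pab - pa * pb)^2 / den
}

#' Fit the LD decay curve and estimate the decay distance
#'
#' Least-squares fit of the one-parameter hyperbolic decay
#' `r2(d) = 1 / (1 + beta d)` (d in Mb), which satisfies the anchor
#' `r2(0) = 1` by construction.  The decay distance is where the fitted
#' curve crosses `r2 = threshold`: `d = (1/threshold - 1) / beta`
#' (4/beta at the conventional threshold 0.2).  The single parameter is
#' found by golden-section search on log10(beta), which is robust for a
#' smooth one-dimensional residual surface.
#'
#' @param pairs data.frame from [pairwise_r2()] (needs `distance_bp`,
#'   `r2`), with at least 10 pairs spanning a range of distances.
#' @param threshold r2 level defining the decay distance (default 0.2).
#' @return object of class `ld_decay`: list with `beta` (1/Mb),
#'   `decay_distance_mb` (`Inf` when the fitted curve never falls below
#'   the threshold), `rss`, `n_pairs`, `mean_r2`, `threshold`.
#' @export
fit_decay <- function(pairs, threshold = 0.2) {
  stopifnot(is.data.frame(pairs), all(c("distance_bp", "r2") %in% names(pairs)))
  d <- pairs$distance_bp / 1e6
  r2 <- pairs$r2
  ok <- !is.na(d) & !is.na(r2)
  d <- d[ok]; r2 <- r2[ok]
  if (length(d) < 10) stop("fit_decay: need at least 10 LD pairs")
  if (length(unique(d)) < 2) stop("fit_decay: degenerate distances")
  rss <- function(log10b) sum((r2 - 1 / (1 + 10^log10b * d))^2)
  opt <- stats::optimize(rss, interval = c(-8, 6))
  beta <- 10^opt$minimum
  dec <- if (beta < 1e-7) Inf else (1 / threshold - 1) / beta
  structure(list(beta = beta, decay_distance_mb = dec,
                 rss = opt$objective, n_pairs = length(d),
                 mean_r2 = mean(r2), threshold = threshold),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay fit: r2(d) = 1 / (1 + beta d)\n")
  cat(sprintf("  beta        = %.4g per Mb (n = %d pairs, rss = %.4g)\n",
              x$beta, x$n_pairs, x$rss))
  cat(sprintf("  mean r2     = %.3f\n", x$mean_r2))
  if (is.finite(x$decay_distance_mb)) {
    cat(sprintf("  decay to r2 = %.2f at %.3f Mb\n",
                x$threshold, x$decay_distance_mb))
  } else {
    cat(sprintf("  fitted curve never falls below r2 = %.2f\n", x$threshold))
  }
  invisible(x)
}

#' @export
coef.ld_decay <- function(object, ...) {
  c(beta = object$beta, decay_distance_mb = object$decay_distance_mb)
}

#' Predicted r2 at given distances
#' @param object an `ld_decay` fit.
#' @param distance_mb numeric distances in Mb.
#' @param ... unused.
#' @return predicted r2 values.
#' @export
predict.ld_decay <- function(object, distance_mb, ...) {
  1 / (1 + object$beta * distance_mb)
}

#' Call favorable gene clusters within the LD decay distance
#'
#' Genes on a chromosome are grouped by single linkage: two genes join a
#' cluster when the gap between their intervals (start of the next minus
#' end of the previous) is at most `gap_mb`.  Genes within the LD decay
#' distance tend to be transferred together as an intact haplotype
#' block, so the default gap is the fitted decay distance.  Clusters are
#' annotated with the union of member traits and transfer pedigrees;
#' single-member groups are flagged as singletons, clusters with more
#' than one trait as multi-trait.
#'
#' @param genes data.frame as from [read_features()] (`feature_id`,
#'   `chrom`, `start`, `end`, `trait`); an optional `pedigree` column
#'   carries transfer provenance.
#' @param gap_mb clustering gap in Mb; must be positive.
#' @return data.frame, one row per cluster: `cluster_id`, `chrom`,
#'   `start`, `end`, `n_genes`, `gene_ids`, `traits`, `pedigrees`,
#'   `multi_trait`, `singleton`.
#' @export
call_clusters <- function(genes, gap_mb = 0.7) {
  if (gap_mb <= 0) stop("gap_mb must be positive")
  if (nrow(genes) == 0) {
    return(data.frame(cluster_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_genes = integer(0), gene_ids = character(0),
                      traits = character(0), pedigrees = character(0),
                      multi_trait = logical(0), singleton = logical(0)))
  }
  gap_bp <- gap_mb * 1e6
  out <- list()
  cid <- 0L
  for (ch in sort(unique(genes$chrom))) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    run_end <- g$end[1]
    grp <- integer(nrow(g)); grp[1] <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] - run_end <= gap_bp) {
        grp[i] <- grp[i - 1]
      } else {
        grp[i] <- grp[i - 1] + 1L
      }
      run_end <- max(run_end, g$end[i])
      if (grp[i] != grp[i - 1]) run_end <- g$end[i]
    }
    for (k in unique(grp)) {
      m <- g[grp == k, , drop = FALSE]
      cid <- cid + 1L
      peds <- if ("pedigree" %in% names(m)) {
        paste(sort(unique(stats::na.omit(m$pedigree))), collapse = ",")
      } else ""
      traits <- sort(unique(stats::na.omit(m$trait)))
      out[[cid]] <- data.frame(
        cluster_id = cid, chrom = ch,
        start = min(m$start), end = max(m$end),
        n_genes = nrow(m),
        gene_ids = paste(m$feature_id, collapse = ","),
        traits = paste(traits, collapse = ","),
        pedigrees = peds,
        multi_trait = length(traits) > 1,
        singleton = nrow(m) == 1,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
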