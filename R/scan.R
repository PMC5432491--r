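#' Per-site allele frequency and segregation status
#'
#' @param calls integer samples x markers matrix (0/1/NA).
#' @param panel line names to restrict to (default all rows).
#' @return data.frame per marker: `q` (alternate-allele frequency over
#'   non-missing calls), `n_called`, `segregating` (0 < q < 1), `usable`
#'   (at least two non-missing calls; `q` is `NA` otherwise).
#' @export
site_stats <- function(calls, panel = rownames(calls)) {
  sub <- calls[panel, , drop = FALSE]
  n_called <- colSums(!is.na(sub))
  q <- colMeans(sub, na.rm = TRUE)
  usable <- n_called >= 2
  q[!usable] <- NA_real_
  data.frame(marker_id = colnames(calls),
             q = as.numeric(q),
             n_called = as.integer(n_called),
             segregating = !is.na(q) & q > 0 & q < 1,
             usable = usable,
             stringsAsFactors = FALSE)
}

#' Tajima's D constants for a sample of n sequences
#'
#' The standard coefficients: `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for
#' i in 1..n-1, `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.  Homozygous inbred lines each contribute one
#' sequence.
#'
#' @param n number of sequences (lines); must be >= 2.
#' @return named list of the constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D for one window of calls
#'
#' `S` counts segregating sites (over non-missing calls), `pi` is the
#' mean over all line pairs of their per-window discordant-site counts
#' (sites called in both lines of the pair), and
#' `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`.  `D` is `NA` when fewer
#' than three lines are available, when `S = 0`, or when the variance
#' term vanishes; the `reason` element says why.
#'
#' @param window_calls integer lines x loci matrix (0/1/NA).
#' @return list `S`, `pi`, `D`, `n`, `reason` (`NA` when D is defined).
#' @export
tajima_d <- function(window_calls) {
  n <- nrow(window_calls)
  q <- colMeans(window_calls, na.rm = TRUE)
  ncall <- colSums(!is.na(window_calls))
  S <- sum(ncall >= 2 & !is.nan(q) & q > 0 & q < 1)
  # mean pairwise discordance, computed from pair comparisons
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) {
    a <- window_calls[p[1], ]
    b <- window_calls[p[2], ]
    sum(a != b, na.rm = TRUE)
  })
  pi <- mean(diffs)
  if (n < 3) {
    return(list(S = S, pi = pi, D = NA_real_, n = n, reason = "n < 3"))
  }
  if (S == 0) {
    return(list(S = S, pi = pi, D = NA_real_, n = n, reason = "S = 0"))
  }
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (v <= 0) {
    return(list(S = S, pi = pi, D = NA_real_, n = n,
                reason = "zero variance"))
  }
  list(S = S, pi = pi, D = (pi - S / k$a1) / sqrt(v), n = n, reason = NA)
}

#' Nei's gene diversity over loci
#'
#' For a biallelic locus with allele frequency q,
#' `Hs = 1 - q^2 - (1-q)^2` (equivalently `2q(1-q)`); the statistic is
#' the mean over loci.
#'
#' @param q per-locus allele frequencies in `[0, 1]`.
#' @return list `Hs` (mean) and `per_locus`.
#' @export
gene_diversity <- function(q) {
  if (!length(q)) stop("gene_diversity: empty frequency vector")
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE))
  per <- 1 - q^2 - (1 - q)^2
  list(Hs = mean(per, na.rm = TRUE), per_locus = per)
}

#' Polymorphism information content over biallelic loci
#'
#' Botstein's PIC for a biallelic locus with frequencies p = 1-q and q:
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, bounded by 0.375; the statistic
#' is the mean over loci.
#'
#' @param q per-locus allele frequencies in `[0, 1]`.
#' @return list `PIC` (mean) and `per_locus`.
#' @export
pic <- function(q) {
  if (!length(q)) stop("pic: empty frequency vector")
  stopifnot(all(q >= 0 & q <= 1, na.rm = TRUE))
  p <- 1 - q
  per <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  list(PIC = mean(per, na.rm = TRUE), per_locus = per)
}

#' Sliding-window selection scan
#'
#' Slides a window of `window` consecutive usable loci (at least two
#' non-missing calls in the panel; monomorphic loci are retained) along
#' each chromosome, advancing `step` loci per step, and computes per
#' window the segregating-site count S, mean pairwise difference pi,
#' Tajima's D, mean gene diversity Hs, and mean PIC.  Each window's value
#' is assigned to the marker at its midpoint (the 8th locus of a
#' 15-locus window).  Chromosomes are scanned independently; those with
#' fewer usable loci than `window` are skipped with a message.
#'
#' @param calls integer samples x markers matrix (0/1/NA).
#' @param map a [marker_map()] aligned to the columns of `calls`.
#' @param panel line names forming the diversity panel.
#' @param window window size in usable loci.
#' @param step step in loci.
#' @return data.frame, one row per window: `chrom`, `window_index`,
#'   `mid_marker`, `mid_bp`, `n`, `S`, `pi`, `D`, `Hs`, `PIC`.
#' @export
sliding_scan <- function(calls, map, panel, window = 15L, step = 1L) {
  validate_marker_map(map)
  stopifnot(ncol(calls) == nrow(map), window >= 2, step >= 1)
  missing_panel <- setdiff(panel, rownames(calls))
  if (length(missing_panel)) {
    stop("panel line(s) not genotyped: ", paste(missing_panel, collapse = ", "))
  }
  sub <- calls[panel, , drop = FALSE]
  ss <- site_stats(calls, panel)
  out <- list()
  mid_off <- floor((window + 1) / 2) - 1L   # 8th locus of 15
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    usable <- idx[ss$usable[idx]]
    if (length(usable) < window) {
      message("sliding_scan: chromosome ", ch, " has ", length(usable),
              " usable loci (< ", window, "); skipped")
      next
    }
    starts <- seq.int(1L, length(usable) - window + 1L, by = step)
    rows <- lapply(seq_along(starts), function(w) {
      loci <- usable[starts[w]:(starts[w] + window - 1L)]
      td <- tajima_d(sub[, loci, drop = FALSE])
      qs <- ss$q[loci]
      mid <- loci[mid_off + 1L]
      data.frame(chrom = ch, window_index = w,
                 mid_marker = map$marker_id[mid], mid_bp = map$pos[mid],
                 n = length(panel), S = td$S, pi = td$pi, D = td$D,
                 Hs = gene_diversity(qs)$Hs, PIC = pic(qs)$PIC,
                 stringsAsFactors = FALSE)
    })
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), window_index = integer(0),
                      mid_marker = character(0), mid_bp = integer(0),
                      n = integer(0), S = integer(0), pi = numeric(0),
                      D = numeric(0), Hs = numeric(0), PIC = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify loci into selection-timing quadrants
#'
#' Crosses the sign of Tajima's D with gene diversity against a 0.3
#' threshold to time artificial selection.  Under the default
#' `"main_text"` convention: D < 0 with Hs < 0.3 indicates selection in
#' the earlier breeding cycles (`early_breeding`); D < 0 with Hs > 0.3 a
#' later breeding round (`late_breeding`); D > 0 with Hs < 0.3 selection
#' that predates the documented pedigree (`pre_pedigree`); D > 0 with
#' Hs > 0.3 no strong evidence of selection (`no_selection`).  The
#' `"figure_legend"` convention swaps the early/late assignment of the
#' two D < 0 quadrants.  Boundary values (D = 0 or Hs = 0.3 exactly) are
#' reported as `no_selection` with `boundary = TRUE`.  Undefined D gives
#' `NA` (call suppressed).
#'
#' @param D,Hs numeric vectors (recycled to common length).
#' @param convention `"main_text"` (default) or `"figure_legend"`.
#' @return data.frame with `quadrant` (character, `NA` when D undefined)
#'   and `boundary` (logical).
#' @export
classify_selection <- function(D, Hs,
                               convention = c("main_text", "figure_legend")) {
  convention <- match.arg(convention)
  len <- max(length(D), length(Hs))
  D <- rep_len(D, len)
  Hs <- rep_len(Hs, len)
  stopifnot(all(Hs >= 0 & Hs <= 1, na.rm = TRUE))
  quadrant <- rep(NA_character_, len)
  boundary <- rep(FALSE, len)
  ok <- !is.na(D) & !is.na(Hs)
  bnd <- ok & (D == 0 | Hs == 0.3)
  quadrant[bnd] <- "no_selection"
  boundary[bnd] <- TRUE
  core <- ok & !bnd
  low_hs <- Hs < 0.3
  neg_low  <- if (convention == "main_text") "early_breeding" else "late_breeding"
  neg_high <- if (convention == "main_text") "late_breeding" else "early_breeding"
  quadrant[core & D < 0 & low_hs]  <- neg_low
  quadrant[core & D < 0 & !low_hs] <- neg_high
  quadrant[core & D > 0 & low_hs]  <- "pre_pedigree"
  quadrant[core & D > 0 & !low_hs] <- "no_selection"
  data.frame(quadrant = quadrant, boundary = boundary,
             stringsAsFactors = FALSE)
}

#' Histogram of Tajima's D over windows
#'
#' Fraction of defined-D windows in the classes `[-2,-1)`, `[-1,0)`,
#' `[0,1)` and `[1,2]`; values outside `[-2,2]` are excluded from the
#' fractions and counted separately.
#'
#' @param D numeric vector of window D values (or a [sliding_scan()]
#'   data.frame, whose `D` column is used).
#' @return list `fractions` (named numeric), `n_defined`,
#'   `n_out_of_range`.
#' @export
d_histogram <- function(D) {
  if (is.data.frame(D)) D <- D$D
  D <- D[!is.na(D)]
  if (!length(D)) stop("d_histogram: no defined D values")
  bins <- c("[-2,-1)" = sum(D >= -2 & D < -1),
            "[-1,0)"  = sum(D >= -1 & D < 0),
            "[0,1)"   = sum(D >= 0 & D < 1),
            "[1,2]"   = sum(D >= 1 & D <= 2))
  out_of_range <- length(D) - sum(bins)
  list(fractions = bins / length(D),
       n_defined = length(D),
       n_out_of_range = as.integer(out_of_range))
}
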