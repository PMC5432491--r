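# Independent brute-force oracles used to cross-check the package
# implementations.  These deliberately re-derive each quantity from its
# definition with explicit loops.

# Tajima's D from explicit pair enumeration and constant definitions.
oracle_tajima <- function(w) {
  n <- nrow(w)
  S <- 0L
  for (j in seq_len(ncol(w))) {
    v <- w[, j]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && length(unique(v)) > 1) S <- S + 1L
  }
  diffs <- c()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    d <- 0L
    for (j in seq_len(ncol(w))) {
      x <- w[a, j]; y <- w[b, j]
      if (!is.na(x) && !is.na(y) && x != y) d <- d + 1L
    }
    diffs <- c(diffs, d)
  }
  pi <- mean(diffs)
  if (n < 3 || S == 0) return(list(S = S, pi = pi, D = NA_real_))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(list(S = S, pi = pi, D = NA_real_))
  list(S = S, pi = pi, D = (pi - S / a1) / sqrt(v))
}

# Enumerate-all-runs IBD oracle for one chromosome.  From each candidate
# start it walks the prefix-valid run out as far as the rules allow
# (running mismatch fraction, missing-marker gap), emits the run trimmed
# to concordant boundaries, and restarts after the failure point.
oracle_ibd_chrom <- function(x, y, pos, params) {
  f <- params$max_mismatch_fraction
  gap_max <- params$max_missing_gap_markers
  comp <- which(!is.na(x) & !is.na(y))
  eq <- x[comp] == y[comp]
  runs <- list()
  cursor <- 1L
  while (cursor <= length(comp)) {
    s <- cursor
    while (s <= length(comp) && !eq[s]) s <- s + 1L
    if (s > length(comp)) break
    nm <- 0L; tot <- 0L; last_good <- s
    fail <- NA_integer_; fail_gap <- FALSE
    j <- s
    while (j <= length(comp)) {
      if (j > s && comp[j] - comp[j - 1] - 1L > gap_max) {
        fail <- j; fail_gap <- TRUE; break
      }
      if (eq[j]) {
        tot <- tot + 1L; last_good <- j
      } else if ((nm + 1) / (tot + 1) <= f) {
        nm <- nm + 1L; tot <- tot + 1L
      } else {
        fail <- j; break
      }
      j <- j + 1L
    }
    span <- comp[s:last_good]
    runs[[length(runs) + 1L]] <- data.frame(
      start_bp = pos[span[1]], end_bp = pos[span[length(span)]],
      n_markers = length(span),
      n_mismatch = sum(!eq[s:last_good]))
    if (is.na(fail)) break
    cursor <- if (fail_gap) fail else fail + 1L
  }
  if (!length(runs)) {
    return(data.frame(start_bp = integer(0), end_bp = integer(0),
                      n_markers = integer(0), n_mismatch = integer(0)))
  }
  df <- do.call(rbind, runs)
  keep <- df$n_markers >= params$min_markers &
    (df$end_bp - df$start_bp) / 1e6 >= params$min_length_mb
  df[keep, , drop = FALSE]
}

# All-pairs interval overlap by double loop.
oracle_overlap <- function(qtls, segments) {
  out <- list()
  for (i in seq_len(nrow(qtls))) for (j in seq_len(nrow(segments))) {
    if (qtls$chrom[i] != segments$chrom[j]) next
    s <- max(qtls$start[i], segments$start_bp[j])
    e <- min(qtls$end[i], segments$end_bp[j])
    if (s <= e) {
      out[[length(out) + 1L]] <- data.frame(
        qtl_id = qtls$feature_id[i], chrom = qtls$chrom[i],
        ov_start = s, ov_end = e,
        pair = paste(segments$sample_a[j], segments$sample_b[j], sep = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(qtl_id = character(0), chrom = character(0),
                      ov_start = integer(0), ov_end = integer(0),
                      pair = character(0)))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$ov_start, df$qtl_id, df$pair), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# O(n^2) single-linkage clustering of intervals by union-find.
oracle_single_linkage <- function(genes, gap_mb) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || genes$chrom[i] != genes$chrom[j]) next
    gap <- max(genes$start[i], genes$start[j]) -
      min(genes$end[i], genes$end[j])
    if (gap <= gap_mb * 1e6) parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(genes$feature_id, comp)
}

# deterministic small marker map: m markers per chromosome, evenly spaced
make_test_map <- function(chroms = c("A01", "C01"), m = 50,
                          spacing_bp = 100000L) {
  df <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(marker_id = sprintf("%s_%03d", ch, 1:m), chrom = ch,
               pos = spacing_bp * (1:m), stringsAsFactors = FALSE)
  }))
  marker_map(df$marker_id, df$chrom, df$pos)
}

rand_calls <- function(samples, map, seed, q = 0.5, missing = 0) {
  set.seed(seed)
  m <- nrow(map)
  calls <- matrix(stats::rbinom(length(samples) * m, 1L, q),
                  nrow = length(samples),
                  dimnames = list(samples, map$marker_id))
  if (missing > 0) calls[stats::runif(length(calls)) < missing] <- NA_integer_
  storage.mode(calls) <- "integer"
  calls
}

# Breeding-program pedigree for selection-footprint studies: two cross
# cycles ending in four sibling DH lines, so the measured panel
# (L1 + D1..D4) sits entirely downstream of the selection events.
sel_study_pedigree <- function() {
  pedigree(parent = c("F1", "F2", "F3", "F4",
                      "L1", "L2", "L1", "L2", "L1", "L2", "L1", "L2"),
           offspring = c("L1", "L1", "L2", "L2",
                         "D1", "D1", "D2", "D2", "D3", "D3", "D4", "D4"),
           cycle = c(1L, 1L, 1L, 1L, rep(2L, 8)))
}

sel_study_panel <- function() c("L1", "D1", "D2", "D3", "D4")

# panels of the built-in two-pedigree breeding history
tn_panels <- function() {
  list(Tapidor = c("Bienvenu", "Bronowski", "Liho", "Regent", "Tapidor"),
       Ningyou7 = c("Chengduai", "Chuanyou2", "Ningyou1", "Ningyou7",
                    "Shengliyoucai"))
}
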