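test_that("identical lines give one segment per chromosome spanning all markers", {
  map <- make_test_map(chroms = c("A01", "C01"), m = 40, spacing_bp = 50000L)
  calls <- rand_calls(c("a", "b"), map, seed = 1)
  calls["b", ] <- calls["a", ]
  segs <- pairwise_ibd(calls, map, "a", "b",
                       detector_params(min_markers = 5, min_length_mb = 0.1))
  expect_equal(nrow(segs), 2)
  for (ch in c("A01", "C01")) {
    s <- segs[segs$chrom == ch, ]
    expect_equal(s$start_bp, min(map$pos[map$chrom == ch]))
    expect_equal(s$end_bp, max(map$pos[map$chrom == ch]))
    expect_equal(s$n_markers, 40L)
  }
})

test_that("fully discordant lines give no segments and unknown lines error", {
  map <- make_test_map(chroms = "A01", m = 30, spacing_bp = 50000L)
  calls <- matrix(c(rep(0L, 30), rep(1L, 30)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), map$marker_id))
  segs <- pairwise_ibd(calls, map, "a", "b", detector_params(1, 0, 0.02, 50))
  expect_equal(nrow(segs), 0)
  expect_error(pairwise_ibd(calls, map, "a", "zz"), "unknown line")
})

test_that("an all-missing chromosome is skipped with a message, not an error", {
  map <- make_test_map(chroms = c("A01", "C01"), m = 20, spacing_bp = 50000L)
  calls <- rand_calls(c("a", "b"), map, seed = 2)
  calls["b", ] <- calls["a", ]
  calls["b", map$chrom == "C01"] <- NA_integer_
  expect_message(
    segs <- pairwise_ibd(calls, map, "a", "b",
                         detector_params(5, 0.1, 0.02, 50)),
    "all-missing")
  expect_equal(unique(segs$chrom), "A01")
})

test_that("the detector matches the enumerate-all-runs oracle on random instances", {
  par_sets <- list(detector_params(5, 0.1, 0.02, 3),
                   detector_params(8, 0.2, 0.10, 5),
                   detector_params(3, 0, 0, 2))
  for (seed in 1:30) {
    set.seed(seed)
    m <- sample(50:200, 1)
    map <- make_test_map(chroms = "A01", m = m, spacing_bp = 40000L)
    # correlated pair: long shared stretches + noise + missingness
    a <- rbinom(m, 1L, 0.5)
    b <- a
    flip <- runif(m) < 0.08
    b[flip] <- 1L - b[flip]
    calls <- rbind(a = a, b = b)
    calls[cbind(sample(1:2, m, TRUE), 1:m)][runif(m) < 0.1] <- NA
    storage.mode(calls) <- "integer"
    colnames(calls) <- map$marker_id
    pars <- par_sets[[seed %% length(par_sets) + 1]]
    got <- pairwise_ibd(calls, map, "a", "b", pars)
    want <- oracle_ibd_chrom(calls["a", ], calls["b", ], map$pos, pars)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      expect_equal(got$start_bp, want$start_bp, info = paste("seed", seed))
      expect_equal(got$end_bp, want$end_bp, info = paste("seed", seed))
      expect_equal(got$n_markers, want$n_markers, info = paste("seed", seed))
      expect_equal(got$n_mismatch, want$n_mismatch, info = paste("seed", seed))
    }
  }
})

test_that("reported segments are not extendable when mismatches are disallowed", {
  # with zero mismatch tolerance the segments are exactly the maximal
  # concordant runs: one marker further in either direction must hit a
  # mismatch, a gap break, or the chromosome end
  for (seed in 1:10) {
    map <- make_test_map(chroms = "A01", m = 120, spacing_bp = 40000L)
    calls <- rand_calls(c("a", "b"), map, seed = seed, missing = 0.05)
    pars <- detector_params(2, 0, 0, 50)
    segs <- pairwise_ibd(calls, map, "a", "b", pars)
    comp <- which(!is.na(calls["a", ]) & !is.na(calls["b", ]))
    eq <- calls["a", comp] == calls["b", comp]
    for (i in seq_len(nrow(segs))) {
      ks <- which(map$pos[comp] == segs$start_bp[i])
      ke <- which(map$pos[comp] == segs$end_bp[i])
      if (ks > 1) expect_false(eq[ks - 1])
      if (ke < length(comp)) expect_false(eq[ke + 1])
    }
  }
})

test_that("raising the length threshold never increases count or total length", {
  map <- make_test_map(chroms = c("A01", "C01"), m = 150, spacing_bp = 30000L)
  calls <- rand_calls(c("a", "b"), map, seed = 33)
  calls["b", 1:100] <- calls["a", 1:100]
  prev_n <- Inf
  prev_len <- Inf
  for (L in c(0, 0.5, 1, 2, 4)) {
    segs <- pairwise_ibd(calls, map, "a", "b",
                         detector_params(2, L, 0.02, 50))
    expect_lte(nrow(segs), prev_n)
    expect_lte(sum(segs$length_mb), prev_len + 1e-12)
    prev_n <- nrow(segs)
    prev_len <- sum(segs$length_mb)
  }
})

test_that("pair order does not change detected segments", {
  map <- make_test_map(chroms = "A01", m = 80, spacing_bp = 50000L)
  calls <- rand_calls(c("a", "b"), map, seed = 6)
  calls["b", 10:60] <- calls["a", 10:60]
  pars <- detector_params(5, 0.1, 0.02, 50)
  ab <- pairwise_ibd(calls, map, "a", "b", pars)
  ba <- pairwise_ibd(calls, map, "b", "a", pars)
  cols <- c("chrom", "start_bp", "end_bp", "n_markers", "n_mismatch")
  expect_equal(ab[, cols], ba[, cols])
})

test_that("all_pairs_ibd concatenates deterministically and handles empty input", {
  map <- make_test_map(chroms = "A01", m = 60, spacing_bp = 50000L)
  calls <- rand_calls(c("a", "b", "c"), map, seed = 7)
  calls["b", ] <- calls["a", ]
  pairs <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
  tab <- all_pairs_ibd(calls, map, pairs, detector_params(5, 0.1, 0.02, 50))
  expect_true(all(paste(tab$sample_a, tab$sample_b) %in%
                    paste(pairs$a, pairs$b)))
  expect_equal(nrow(all_pairs_ibd(calls, map, pairs[0, ])), 0)
})

test_that("the per-subgenome summary is additive and matches a BED recount", {
  segs <- ibd_segments(sample_a = c("a", "a", "a"),
                       sample_b = c("b", "b", "b"),
                       chrom = c("A03", "A03", "C02"),
                       start_bp = c(1000000L, 9000000L, 2000000L),
                       end_bp = c(3500000L, 10000000L, 8000000L),
                       n_markers = c(30L, 15L, 70L))
  s <- ibd_summary(segs)
  expect_equal(s$per_pair$count_A, 2L)
  expect_equal(s$per_pair$length_A_mb, 2.5 + 1.0)
  expect_equal(s$per_pair$count_C, 1L)
  expect_equal(s$per_pair$length_C_mb, 6.0)
  expect_equal(s$per_pair$count_total,
               s$per_pair$count_A + s$per_pair$count_C)
  expect_equal(s$per_pair$length_total_mb,
               s$per_pair$length_A_mb + s$per_pair$length_C_mb)
  # recount after a BED round trip
  path <- tempfile(fileext = ".bed")
  write_segments_bed(segs, path)
  back <- read_segments_bed(path)
  s2 <- ibd_summary(back)
  expect_equal(s2$per_pair, s$per_pair)
  expect_equal(s$pooled$count_total, 3L)
  # one 2.5 Mb segment on A03 alone
  one <- ibd_segments("a", "b", "A03", 1000000L, 3500000L, 10L)
  s3 <- ibd_summary(one)
  expect_equal(s3$per_pair$count_A, 1L)
  expect_equal(s3$per_pair$length_A_mb, 2.5)
  expect_equal(s3$per_pair$count_C, 0L)
})
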