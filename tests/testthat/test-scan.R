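test_that("per-site frequencies and segregation flags are counted over non-missing calls", {
  map <- make_test_map(chroms = "A01", m = 3, spacing_bp = 1000L)
  calls <- matrix(c(0L, 0L, 0L, 0L, 0L,
                    0L, 1L, 1L, 0L, 1L,
                    0L, 1L, 1L, NA, 1L),
                  ncol = 3, dimnames = list(paste0("s", 1:5), map$marker_id))
  ss <- site_stats(calls)
  expect_equal(ss$q, c(0, 0.6, 0.75))
  expect_equal(ss$segregating, c(FALSE, TRUE, TRUE))
  expect_equal(ss$n_called, c(5L, 5L, 4L))
  # fewer than two calls makes a site unusable
  calls[2:5, 1] <- NA
  ss2 <- site_stats(calls)
  expect_false(ss2$usable[1])
  expect_true(is.na(ss2$q[1]))
})

test_that("a monomorphic window has S = 0, pi = 0 and undefined D", {
  w <- matrix(0L, nrow = 5, ncol = 15)
  td <- tajima_d(w)
  expect_equal(td$S, 0L)
  expect_equal(td$pi, 0)
  expect_true(is.na(td$D))
  expect_equal(td$reason, "S = 0")
  expect_true(is.na(tajima_d(matrix(c(0L, 1L), 2, 15))$D))
})

test_that("Tajima's D matches the brute-force pair-enumeration oracle to 1e-12", {
  set.seed(2024)
  for (rep in 1:120) {
    n <- sample(3:8, 1)
    w <- matrix(rbinom(n * 15, 1L, runif(1, 0.2, 0.8)), nrow = n)
    if (rep %% 4 == 0) w[sample(length(w), 5)] <- NA_integer_
    got <- tajima_d(w)
    want <- oracle_tajima(w)
    expect_equal(got$S, want$S)
    expect_equal(got$pi, want$pi, tolerance = 1e-12)
    if (is.na(want$D)) {
      expect_true(is.na(got$D))
    } else {
      expect_equal(got$D, want$D, tolerance = 1e-12)
    }
  }
})

test_that("pi under line duplication equals the pair-enumeration oracle", {
  # duplicating every line adds zero-difference self pairs, so the mean
  # over all pairs shrinks by the factor 2(n-1)/(2n-1); the oracle and
  # the implementation must agree on that value
  set.seed(7)
  w <- matrix(rbinom(5 * 15, 1L, 0.5), nrow = 5)
  w2 <- w[rep(1:5, each = 2), ]
  got <- tajima_d(w2)
  want <- oracle_tajima(w2)
  expect_equal(got$pi, want$pi, tolerance = 1e-12)
  n <- 5
  expect_equal(got$pi, tajima_d(w)$pi * (2 * (n - 1)) / (2 * n - 1),
               tolerance = 1e-12)
})

test_that("sliding windows advance one locus at a time within chromosomes", {
  map <- make_test_map(chroms = c("A01", "C01"), m = 100, spacing_bp = 10000L)
  calls <- rand_calls(paste0("s", 1:5), map, seed = 3)
  sc <- sliding_scan(calls, map, paste0("s", 1:5), window = 15, step = 1)
  # m - window + 1 windows per chromosome
  expect_equal(sum(sc$chrom == "A01"), 86)
  expect_equal(sum(sc$chrom == "C01"), 86)
  # midpoint is the 8th locus of the window
  first <- sc[sc$chrom == "A01" & sc$window_index == 1, ]
  expect_equal(first$mid_marker, map$marker_id[8])
  # no cross-chromosome windows: every window's loci live on one chromosome
  expect_true(all(sc$mid_bp[sc$chrom == "A01"] <=
                    max(map$pos[map$chrom == "A01"])))
  # a short chromosome is skipped with a message
  map2 <- make_test_map(chroms = c("A01", "C01"), m = 10, spacing_bp = 10000L)
  calls2 <- rand_calls(paste0("s", 1:5), map2, seed = 4)
  msgs <- capture_messages(sc2 <- sliding_scan(calls2, map2, paste0("s", 1:5)))
  expect_length(msgs, 2)
  expect_match(msgs, "skipped", all = TRUE)
  expect_equal(nrow(sc2), 0)
})

test_that("gene diversity follows Nei's biallelic formula", {
  expect_equal(gene_diversity(0.5)$Hs, 0.5)
  expect_equal(gene_diversity(0)$Hs, 0)
  expect_equal(gene_diversity(1)$Hs, 0)
  g <- gene_diversity(c(0.2, 0.5, 1.0))
  expect_equal(g$per_locus, c(0.32, 0.5, 0))
  expect_equal(g$Hs, mean(c(0.32, 0.5, 0)))
  # algebraic identity: 1 - q^2 - (1-q)^2 = 2q(1-q)
  q <- seq(0, 1, by = 0.01)
  expect_equal(gene_diversity(q)$per_locus, 2 * q * (1 - q))
  expect_error(gene_diversity(numeric(0)), "empty")
})

test_that("PIC follows the biallelic Botstein formula", {
  expect_equal(pic(0.5)$PIC, 0.375)
  expect_equal(pic(0)$PIC, 0)
  expect_equal(pic(0.2)$PIC, 1 - (0.64 + 0.04) - 2 * 0.04 * 0.64)
  q <- c(0.1, 0.3, 0.5)
  p <- 1 - q
  expect_equal(pic(q)$per_locus, 1 - (p^2 + q^2) - 2 * p^2 * q^2)
})

test_that("the selection-timing quadrants enumerate correctly under both conventions", {
  main <- classify_selection(c(-0.5, -0.5, 0.5, 0.5), c(0.2, 0.4, 0.2, 0.4))
  expect_equal(main$quadrant, c("early_breeding", "late_breeding",
                                "pre_pedigree", "no_selection"))
  fig <- classify_selection(c(-0.5, -0.5, 0.5, 0.5), c(0.2, 0.4, 0.2, 0.4),
                            convention = "figure_legend")
  expect_equal(fig$quadrant, c("late_breeding", "early_breeding",
                               "pre_pedigree", "no_selection"))
  # boundaries go to no_selection with the flag set
  b <- classify_selection(c(0, -1), c(0.3, 0.3))
  expect_equal(b$quadrant, c("no_selection", "no_selection"))
  expect_true(all(b$boundary))
  # undefined D suppresses the call
  u <- classify_selection(NA_real_, 0.2)
  expect_true(is.na(u$quadrant))
})

test_that("the D histogram bins window values and recounts exactly", {
  h <- d_histogram(rep(0.5, 10))
  expect_equal(unname(h$fractions["[0,1)"]), 1)
  expect_error(d_histogram(NA_real_), "no defined")
  set.seed(5)
  D <- c(runif(50, -2.5, 2.5), NA)
  h2 <- d_histogram(D)
  d <- D[!is.na(D)]
  expect_equal(unname(h2$fractions),
               c(sum(d >= -2 & d < -1), sum(d >= -1 & d < 0),
                 sum(d >= 0 & d < 1), sum(d >= 1 & d <= 2)) / length(d))
  expect_equal(h2$n_out_of_range, sum(d < -2 | d > 2))
  expect_equal(sum(h2$fractions) + h2$n_out_of_range / h2$n_defined, 1)
})

test_that("directional selection fixes the target locus and depresses window Hs", {
  # panel of post-selection descendant lines: the favored founder's
  # haplotype copy is forced through every cross, so the target locus is
  # monomorphic in the panel (Hs exactly 0) and windows over it show
  # reduced diversity relative to the genome
  ped <- sel_study_pedigree()
  tgt <- data.frame(chrom = "A01", pos = 10e6, founder = "F1",
                    stringsAsFactors = FALSE)
  panel <- sel_study_panel()
  hits <- 0L
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                      selection_targets = tgt, seed = 1000 + seed)
    sim <- simulate_pedigree(ped, cfg)
    on_chrom <- which(sim$map$chrom == "A01")
    ti <- on_chrom[which.min(abs(sim$map$pos[on_chrom] - 10e6))]
    q <- site_stats(sim$calls, panel)$q[ti]
    expect_identical(gene_diversity(q)$per_locus, 0)
    sc <- sliding_scan(sim$calls, sim$map, panel)
    over <- sc$chrom == "A01" & abs(sc$mid_bp - 10e6) < 1e6
    if (any(over) && mean(sc$Hs[over]) < mean(sc$Hs)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
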