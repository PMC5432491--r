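make_two_founder_state <- function(config, seed = 1) {
  set.seed(seed)
  sim <- simulate_founders(config, c("P1", "P2"))
  nmark <- nrow(sim$map)
  list(calls = sim$calls,
       founder_origin = matrix(rep(c("P1", "P2"), each = nmark), 2,
                               byrow = TRUE,
                               dimnames = list(c("P1", "P2"),
                                               sim$map$marker_id)),
       donor = matrix(NA_character_, 2, nmark,
                      dimnames = list(c("P1", "P2"), sim$map$marker_id)),
       map = sim$map)
}

test_that("the simulator is reproducible and clean when error and missingness are off", {
  ped <- tapidor_ningyou_pedigree()
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 120, seed = 5)
  s1 <- simulate_pedigree(ped, cfg)
  s2 <- simulate_pedigree(ped, cfg)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$founder_origin, s2$founder_origin)
  # only the diploid-A cultivar's C subgenome is missing
  ccols <- subgenome(s1$map$chrom) == "C"
  expect_true(all(is.na(s1$calls["Chengduai", ccols])))
  others <- setdiff(rownames(s1$calls), "Chengduai")
  expect_false(anyNA(s1$calls[others, ]))
  expect_false(anyNA(s1$calls["Chengduai", !ccols]))
})

test_that("founder discordance matches the binomial expectation at fixed MAF 0.5", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 1000,
                    founder_maf_range = c(0.5, 0.5), seed = 9)
  sim <- simulate_founders(cfg, c("F1", "F2"))
  disc <- mean(sim$calls["F1", ] != sim$calls["F2", ])
  # expected discordance 2q(1-q) = 0.5; binomial se over 2000 markers ~ 0.011
  expect_lt(abs(disc - 0.5), 0.05)
})

test_that("without recombination an offspring chromosome is one whole parental chromosome", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 80,
                    cM_per_Mb = 0, seed = 2)
  st <- make_two_founder_state(cfg)
  off <- simulate_cross("P1", "P2", st, cfg)
  for (ch in unique(st$map$chrom)) {
    idx <- st$map$chrom == ch
    expect_length(unique(off$donor[idx]), 1)
  }
})

test_that("crossover counts follow the Poisson expectation for a 1-Morgan chromosome", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 400,
                    chromosome_length_bp = 50e6, cM_per_Mb = 2, seed = 4)
  st <- make_two_founder_state(cfg)
  set.seed(99)
  switches <- replicate(600, {
    off <- simulate_cross("P1", "P2", st, cfg)
    sum(off$donor[-1] != off$donor[-length(off$donor)])
  })
  # 50 Mb * 2 cM/Mb = 1 Morgan; visible switches slightly undercount
  # crossovers outside the marker span or cancelling within a gap
  expect_lt(abs(mean(switches) - 1.0), 0.15)
})

test_that("every offspring allele equals its ancestry-track founder's allele", {
  ped <- tapidor_ningyou_pedigree()
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150, seed = 8)
  sim <- simulate_pedigree(ped, cfg)
  for (line in c("Regent", "Tapidor", "Chuanyou2", "Ningyou7")) {
    fo <- sim$founder_origin[line, ]
    expected <- sim$true_calls[cbind(match(fo, rownames(sim$true_calls)),
                                     seq_along(fo))]
    expect_identical(unname(sim$true_calls[line, ]), expected)
  }
})

test_that("directional selection fixes the favored founder allele in all descendants", {
  ped <- tapidor_ningyou_pedigree()
  tgt <- data.frame(chrom = "A01", pos = 10e6, founder = "Shengliyoucai",
                    stringsAsFactors = FALSE)
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                    selection_targets = tgt, seed = 13)
  for (seed in 13:17) {
    cfg$seed <- seed
    sim <- simulate_pedigree(ped, cfg)
    on_chrom <- which(sim$map$chrom == "A01")
    ti <- on_chrom[which.min(abs(sim$map$pos[on_chrom] - 10e6))]
    expect_equal(unname(sim$founder_origin["Chuanyou2", ti]), "Shengliyoucai")
    expect_equal(unname(sim$founder_origin["Ningyou7", ti]), "Shengliyoucai")
  }
  # target off the map is a hard error
  bad <- sim_config(n_chromosomes = 2, markers_per_chromosome = 150,
                    selection_targets = data.frame(
                      chrom = "A09", pos = 1e6, founder = "Liho"),
                    seed = 1)
  expect_error(simulate_pedigree(ped, bad), "chromosome not in map")
})

test_that("lineage truth segments tile each offspring chromosome at crossover sites", {
  ped <- tapidor_ningyou_pedigree()
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 200, seed = 21)
  sim <- simulate_pedigree(ped, cfg)
  # a child's two parents partition its genome
  for (child in c("Regent", "Chuanyou2", "Tapidor", "Ningyou7")) {
    par <- sim$ped$edges$parent[sim$ped$edges$offspring == child]
    covered <- rep(0L, ncol(sim$calls))
    for (p in par) {
      segs <- true_ibd_segments(sim, p, child, mode = "lineage")
      for (i in seq_len(nrow(segs))) {
        sel <- sim$map$chrom == segs$chrom[i] &
          sim$map$pos >= segs$start_bp[i] & sim$map$pos <= segs$end_bp[i]
        covered[sel] <- covered[sel] + 1L
      }
    }
    expect_true(all(covered == 1L))
    # breakpoints coincide with donor switches, counted per chromosome
    for (p in par) {
      segs <- true_ibd_segments(sim, p, child, mode = "lineage")
      n_runs <- sum(vapply(unique(sim$map$chrom), function(ch) {
        donor_run <- sim$donor[child, sim$map$chrom == ch] == p
        sum(diff(c(FALSE, donor_run)) == 1)
      }, numeric(1)))
      expect_equal(nrow(segs), n_runs)
    }
  }
  # unrelated founders share no founder allele copies
  expect_equal(nrow(true_ibd_segments(sim, "Liho", "Ningyou1",
                                      mode = "shared_founder")), 0)
})

test_that("parent to offspring with no crossovers yields one whole-chromosome truth segment", {
  ped <- pedigree(parent = c("P1", "P2"), offspring = c("K", "K"))
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 60,
                    cM_per_Mb = 0, seed = 3)
  sim <- simulate_pedigree(ped, cfg)
  donor <- unique(sim$donor["K", ])
  segs <- true_ibd_segments(sim, donor, "K", mode = "lineage")
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_markers, 60L)
  expect_equal(segs$start_bp, min(sim$map$pos))
  expect_equal(segs$end_bp, max(sim$map$pos))
})
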