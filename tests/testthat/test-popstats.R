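test_that("allele_frequencies counts non-missing haplotypes only", {
  a <- matrix(c(0L, 0L, 0L, 0L,      # site 1: all ref
                0L, 1L, 1L, NA),     # site 2: {0,1,1,NA}
              nrow = 4)
  hm <- make_hm(a)
  pm <- make_popmap(hm, "P1")
  fr <- allele_frequencies(hm, pm, "P1")
  expect_equal(fr$p[, "P1"], c(0, 2 / 3))
  expect_equal(fr$n[, "P1"], c(4, 3))
  expect_error(allele_frequencies(hm, pm, c("P1", "nope")), "nope")
})

test_that("window pi matches the mean-pairwise-difference oracle to 1e-12", {
  # worked example: one SNP {0,0,1,1}, n = 4, 5000 bp window
  a1 <- matrix(c(0L, 0L, 1L, 1L), 4, 1)
  hm1 <- make_hm(a1, pos = 2500L)
  pm1 <- make_popmap(hm1, "P1")
  w1 <- one_window(hm1, 0, 5000)
  expect_equal(window_pi(hm1, w1, "P1", pm1), (2 * 2 * 2 / (4 * 3)) / 5000)
  expect_equal(window_pi(hm1, w1, "P1", pm1),
               pi_pairwise_oracle(a1, 5000), tolerance = 1e-12)
  # doubling window length halves pi
  w2 <- one_window(hm1, 0, 10000)
  expect_equal(window_pi(hm1, w2, "P1", pm1),
               window_pi(hm1, w1, "P1", pm1) / 2)
  # monomorphic window
  hm0 <- make_hm(matrix(0L, 4, 3), pos = c(10L, 20L, 30L))
  expect_equal(window_pi(hm0, one_window(hm0, 0, 1000), "P1",
                         make_popmap(hm0, "P1")), 0)
  # property: random complete fixtures, several shapes and seeds
  set.seed(101)
  for (rep in 1:20) {
    nh <- sample(c(4, 6, 10), 1); ns <- sample(5:40, 1)
    a <- matrix(rbinom(nh * ns, 1, runif(1, 0.1, 0.9)), nh, ns)
    hm <- make_hm(a, pos = sort(sample.int(4999, ns)))
    pm <- make_popmap(hm, "P1")
    expect_equal(window_pi(hm, one_window(hm, 0, 5000), "P1", pm),
                 pi_pairwise_oracle(a, 5000), tolerance = 1e-12)
  }
})

test_that("Hudson F_ST: worked value, symmetry, clamping, degenerate cases", {
  fr <- make_freqs(cbind(A = 0.2, B = 0.8), 10)
  got <- window_fst_hudson(fr, "A", "B")
  expect_equal(got$raw, 0.324444444 / 0.68, tolerance = 1e-6)
  expect_equal(got$raw, 0.47712, tolerance = 1e-5)
  expect_identical(window_fst_hudson(fr, "B", "A")$raw, got$raw)

  # fixed difference is maximal differentiation
  fx <- make_freqs(cbind(A = 1, B = 0), 8)
  expect_equal(window_fst_hudson(fx, "A", "B")$raw, 1)
  expect_lt(window_fst_hudson(fx, "A", "B")$clamped, 1)

  # identical frequencies: raw <= 0, clamped 0
  eq <- make_freqs(cbind(A = c(0.3, 0.5), B = c(0.3, 0.5)), 10)
  g <- window_fst_hudson(eq, "A", "B")
  expect_lte(g$raw, 0)
  expect_identical(g$clamped, 0)

  # no usable site: undefined, flagged, not zero
  none <- make_freqs(cbind(A = 0.5, B = 0.5), 1)
  expect_false(window_fst_hudson(none, "A", "B")$defined)

  # per-pair identity-probability oracle: Fst = 1 - Hw/Hb, ratio-of-averages,
  # at true frequencies (large n so corrections vanish)
  set.seed(11)
  p <- cbind(A = runif(200), B = runif(200))
  fr2 <- make_freqs(p, 1e9)
  hb <- sum(p[, 1] * (1 - p[, 2]) + p[, 2] * (1 - p[, 1]))
  hw <- sum(p[, 1] * (1 - p[, 1]) + p[, 2] * (1 - p[, 2]))
  expect_equal(window_fst_hudson(fr2, "A", "B")$raw, 1 - hw / hb,
               tolerance = 1e-6)
})

test_that("PBS: worked value, identities, error outside [0,1)", {
  expect_identical(pbs(0, 0, 0), 0)
  expect_equal(pbs(0.5, 0.5, 0), 0.693147, tolerance = 1e-6)
  expect_equal(pbs(0.5, 0.5, 0), (-log(0.5) - log(0.5)) / 2)
  # equal F on all branches: PBS = -ln(1-f)/2
  for (f in c(0.1, 0.3, 0.7))
    expect_equal(pbs(f, f, f), -log(1 - f) / 2)
  # additivity: PBS_A + PBS_B = T_AB for any triplet
  set.seed(3)
  for (i in 1:25) {
    f <- runif(3, 0, 0.95)
    expect_equal(pbs(f[1], f[2], f[3]) + pbs(f[1], f[3], f[2]),
                 -log(1 - f[1]), tolerance = 1e-12)
  }
  expect_error(pbs(1, 0.5, 0.2), "clamp")
})

test_that("windowed_stats agrees with the per-window operations", {
  set.seed(21)
  cfg <- sim_config(seed = 5, n_autosomes = 2, n_x = 0,
                    windows_per_autosome = 6, snps_per_window = 25,
                    n_selected = 0)
  sim <- simulate_dataset(cfg)
  sl <- setNames(cfg$scaffolds$length, cfg$scaffolds$scaffold)
  cw <- build_windows(sim$hm, "coordinate", 5000, sl)
  ws <- windowed_stats(sim$hm, cw, sim$popmap, populations = "WAF1",
                       pairs = list(c("WAF1", "EAF1")),
                       triplets = list(c("INT1", "WAF1", "EAF1")))
  fr <- allele_frequencies(sim$hm, sim$popmap, c("WAF1", "EAF1", "INT1"))
  for (k in c(1, 4, 9)) {
    expect_equal(ws$pi_WAF1[k],
                 window_pi(sim$hm, cw[k, ], "WAF1", sim$popmap))
    expect_equal(ws$fst_WAF1_EAF1[k],
                 window_fst_hudson(fr, "WAF1", "EAF1", cw[k, ])$clamped)
    expect_equal(ws$pbs_INT1.WAF1.EAF1[k],
                 pbs(window_fst_hudson(fr, "INT1", "WAF1", cw[k, ])$clamped,
                     window_fst_hudson(fr, "INT1", "EAF1", cw[k, ])$clamped,
                     window_fst_hudson(fr, "WAF1", "EAF1", cw[k, ])$clamped))
  }
})

test_that("joint_sfs polarizes on the fixed outgroup allele and counts exclusions", {
  # 2 pops x 2 haplotypes (1 diploid each) + outgroup of 1 diploid
  # sites: derived counts (0,0), (1,1), (2,0); site 4 has polymorphic outgroup
  a <- rbind(c(0L, 1L, 1L, 0L),   # p1 hap1
             c(0L, 0L, 1L, 0L),   # p1 hap2
             c(0L, 1L, 0L, 0L),   # p2 hap1
             c(0L, 0L, 0L, 0L),   # p2 hap2
             c(0L, 0L, 0L, 0L),   # outgroup hap1
             c(0L, 0L, 0L, 1L))   # outgroup hap2 (site 4 polymorphic)
  hm <- make_hm(a)
  pm <- data.frame(sample = hm$samples,
                   population = c("p1", "p2", "og"), sex = "unknown")
  sfs <- joint_sfs(hm, pm, c("p1", "p2"), "og")
  expect_identical(dim(sfs$counts), c(3L, 3L))
  expect_identical(sfs$counts["0", "0"], 1L)
  expect_identical(sfs$counts["1", "1"], 1L)
  expect_identical(sfs$counts["2", "0"], 1L)
  expect_identical(sfs$excluded, 1L)
  expect_identical(sum(sfs$counts) + sfs$excluded, n_sites(hm))

  # outgroup fixed derived flips polarity
  b <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L))
  hmb <- make_hm(b)
  pmb <- data.frame(sample = hmb$samples, population = c("p1", "og"),
                    sex = "unknown")
  sfsb <- joint_sfs(hmb, pmb, "p1", "og")
  # ancestral = the outgroup-fixed ALT allele: site 1 -> 0 derived in p1,
  # site 2 (p1 all REF) -> 2 derived
  expect_identical(as.vector(sfsb$counts[as.character(0:2)]),
                   c(1L, 0L, 1L))
  expect_error(joint_sfs(hmb, pmb, "p1", "p1"), "disjoint")

  # write_sfs round-trips the flattened line
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sfs(sfs, path)
  lines <- readLines(path)
  flat <- as.numeric(strsplit(lines[length(lines)], " ")[[1]])
  expect_equal(sum(flat), sum(sfs$counts))
})
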