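small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_autosomes = 2, n_x = 1,
             windows_per_autosome = 8, windows_per_x = 4,
             snps_per_window = 20, n_selected = 2, ...)
}

test_that("simulate_dataset is deterministic and round-trips through the VCF", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(small_cfg(7), dir = d1)
  s2 <- simulate_dataset(small_cfg(7), dir = d2)
  expect_identical(readLines(s1$files$vcf), readLines(s2$files$vcf))
  expect_identical(s1$truth, s2$truth)
  hm <- read_vcf(s1$files$vcf)
  expect_identical(unname(hm$alleles), unname(s1$hm$alleles))
  expect_identical(hm$pos, s1$hm$pos)
  expect_identical(hm$scaffold, s1$hm$scaffold)
  # popmap and lengths round-trip
  pm <- read_popmap(s1$files$popmap)
  expect_identical(pm$sample, s1$popmap$sample)
  sl <- read_scaffold_lengths(s1$files$scaffold_lengths)
  expect_identical(unname(sl[s1$scaffolds$scaffold]),
                   as.numeric(s1$scaffolds$length))
  # truth covers every window, ancestry defined, planted flags within plan
  expect_identical(nrow(s1$truth), 2L * 8L + 4L)
  expect_true(all(s1$truth$ancestry %in% c("west", "east")))
  expect_identical(sum(s1$truth$selected), 2L)
  expect_true(all(s1$truth$class[s1$truth$selected] == "autosome"))
  # different seeds differ
  expect_false(identical(simulate_dataset(small_cfg(8))$hm$alleles,
                         s1$hm$alleles))
})

test_that("no drift and no selection means no structure", {
  cfg <- sim_config(seed = 3, n_autosomes = 2, n_x = 0,
                    windows_per_autosome = 50, snps_per_window = 20,
                    F_split = 0, F_pop = 0, F_intro = 0, n_selected = 0)
  sim <- simulate_dataset(cfg)
  fr <- allele_frequencies(sim$hm, sim$popmap, c("WAF1", "EAF1", "INT1"))
  sl <- setNames(cfg$scaffolds$length, cfg$scaffolds$scaffold)
  cw <- build_windows(sim$hm, "coordinate", 5000, sl)
  fst <- vapply(seq_len(nrow(cw)), function(k)
    window_fst_hudson(fr, "WAF1", "EAF1", cw[k, ])$clamped, 0)
  expect_lt(median(fst), 0.01)
})

test_that("truth-west fraction tracks alpha and modes behave", {
  cfg <- sim_config(seed = 11, n_autosomes = 4, n_x = 0,
                    windows_per_autosome = 500, snps_per_window = 2,
                    alpha = 0.7, n_selected = 0)
  tr <- simulate_dataset(cfg)$truth
  expect_lt(abs(mean(tr$ancestry == "west") - 0.7), 0.03)

  ind <- sim_config(seed = 11, n_autosomes = 1, n_x = 0,
                    windows_per_autosome = 30, snps_per_window = 2,
                    alpha = 0.5, admixture_mode = "independent",
                    n_selected = 0)
  tri <- simulate_dataset(ind)$truth
  expect_true(all(c("ancestry_INT1", "ancestry_INT2", "ancestry_INT3")
                  %in% names(tri)))
  none <- sim_config(seed = 11, n_autosomes = 1, n_x = 0,
                     windows_per_autosome = 30, snps_per_window = 2,
                     admixture_mode = "none", n_selected = 0)
  expect_true(all(simulate_dataset(none)$truth$ancestry == "west"))
})

test_that("expected heterozygosity shrinks monotonically with drift (10 seeds)", {
  het <- function(F) {
    vals <- vapply(1:10, function(seed) {
      cfg <- sim_config(seed = seed, n_autosomes = 1, n_x = 0,
                        windows_per_autosome = 40, snps_per_window = 10,
                        F_split = F, F_pop = 0, F_intro = 0, n_selected = 0)
      sim <- simulate_dataset(cfg)
      fr <- allele_frequencies(sim$hm, sim$popmap, "WAF1")
      p <- fr$p[, 1]
      mean(2 * p * (1 - p))
    }, 0)
    mean(vals)
  }
  h <- c(het(0.05), het(0.2), het(0.4))
  expect_true(all(diff(h) < 0))
})

test_that("X windows are more differentiated than autosomal windows (10 seeds)", {
  wins <- function(sim, cls) {
    sl <- setNames(sim$scaffolds$length, sim$scaffolds$scaffold)
    cw <- build_windows(sim$hm, "coordinate", 5000, sl)
    cw$class <- sim$scaffolds$class[match(cw$scaffold, sim$scaffolds$scaffold)]
    cw[cw$class == cls, ]
  }
  med <- matrix(NA_real_, 10, 2)
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, n_autosomes = 2, n_x = 2,
                      windows_per_autosome = 25, windows_per_x = 25,
                      snps_per_window = 20, n_selected = 0)
    sim <- simulate_dataset(cfg)
    fr <- allele_frequencies(sim$hm, sim$popmap, c("WAF1", "EAF1"))
    f <- function(cw) vapply(seq_len(nrow(cw)), function(k)
      window_fst_hudson(fr, "WAF1", "EAF1", cw[k, ])$clamped, 0)
    med[seed, ] <- c(median(f(wins(sim, "autosome"))),
                     median(f(wins(sim, "X"))))
  }
  expect_gt(mean(med[, 2] > med[, 1]), 0.8)
  expect_gt(mean(med[, 2]), mean(med[, 1]))
})

test_that("depth table: sigma 0 is exact, config without X yields no X calls", {
  cfg0 <- small_cfg(depth_sigma = 0)
  dep <- simulate_depth_table(cfg0)
  wide <- matrix(dep$mean_depth, nrow = nrow(cfg0$scaffolds))
  # with sigma = 0 every male's raw X depth is exactly half their autosomal depth
  xrow <- which(cfg0$scaffolds$class == "X")[1]
  arow <- which(cfg0$scaffolds$class == "autosome")[1]
  sex <- rep(c("male", "female"),
             length.out = sum(cfg0$populations$n_diploid))
  expect_equal(wide[xrow, sex == "male"] / wide[arow, sex == "male"],
               rep(0.5, sum(sex == "male")))
  expect_equal(wide[xrow, sex == "female"] / wide[arow, sex == "female"],
               rep(1, sum(sex == "female")))

  noX <- sim_config(seed = 2, n_autosomes = 3, n_x = 0,
                    windows_per_autosome = 20, n_selected = 0)
  depX <- simulate_depth_table(noX)
  prof <- normalize_depths(depX, setNames(noX$scaffolds$length,
                                          noX$scaffolds$scaffold))
  pm <- data.frame(sample = unique(depX$sample), population = "P",
                   sex = rep(c("male", "female"),
                             length.out = length(unique(depX$sample))))
  expect_false(any(assign_scaffolds(prof, pm)$table$class == "X"))
})
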