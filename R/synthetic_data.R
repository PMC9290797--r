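# Synthetic-data generator.
#
# Generative caricature of the inferred invasion history: two differentiated
# African source lineages (west, east) diverge from a common ancestor, local
# populations drift within each lineage, and three introduced populations
# descend from a single admixed source predating colonization — each genomic
# window draws its ancestry from the west lineage with probability alpha
# (one draw shared by all introduced populations in "shared" mode), then
# drifts through the colonization bottleneck. Drift is the Balding-Nichols
# Beta construction: descendant frequency ~ Beta with mean p and variance
# F p (1 - p), which gives closed-form expectations for parameter-recovery
# tests. X-linked scaffolds drift harder via F_X = 1 - (1 - F)^(4/3),
# mirroring the 3/4 effective-size ratio of X to autosomes.

#' Simulation configuration
#'
#' Defaults describe a desk-scale genome: 10 autosomal scaffolds of 200
#' 5 kb windows (2,000 autosomal windows) plus 2 X scaffolds of 100 windows,
#' 40 SNPs per window; an outgroup, two west-lineage, two east-lineage and
#' three introduced populations; lineage split drift F_split = 0.15 (matching
#' the 0.14-0.19 genome-wide differentiation scale of the study system),
#' within-lineage drift F_pop = 0.05, colonization drift F_intro = 0.1;
#' shared admixture with alpha = 0.7 (predominantly west ancestry); 20
#' planted selected windows with derived-frequency shift delta = 0.6.
#'
#' @param seed integer seed (all outputs deterministic given it).
#' @param n_autosomes,n_x numbers of autosomal / X scaffolds carrying SNPs.
#' @param windows_per_autosome,windows_per_x 5 kb windows per scaffold.
#' @param snps_per_window SNPs per window.
#' @param window_bp window span in bp (default 5000).
#' @param n_repeat_scaffolds,n_small_scaffolds extra SNP-free scaffolds for
#'   depth-based classification tests (repeat-like inflated depth; small =
#'   autosomal but under 100 kb).
#' @param small_len length of small scaffolds (default 50000).
#' @param populations data.frame with columns \code{name}, \code{role}
#'   (\code{outgroup}/\code{west}/\code{east}/\code{introduced}),
#'   \code{n_diploid}.
#' @param F_split,F_pop,F_intro drift parameters in [0, 1).
#' @param alpha probability a window's introduced ancestry is west.
#' @param admixture_mode \code{"shared"} (one ancestry draw per window for
#'   all introduced populations), \code{"independent"} (per population), or
#'   \code{"none"} (pure west descent, alpha forced to 1).
#' @param x_inflation_exponent exponent g in F_X = 1 - (1-F)^g (default 4/3).
#' @param n_selected,delta planted-selection plan: autosomal windows given a
#'   derived shift p <- p + delta (1 - p) in every introduced population.
#' @param anc_range range of the uniform ancestral-frequency law.
#' @param outgroup_derived_prob probability the outgroup is fixed derived.
#' @param depth_mean,depth_sigma raw depth baseline (reads/site) and Gaussian
#'   noise sd on the normalized scale; \code{repeat_factor} the depth
#'   inflation of repeat scaffolds.
#' @param repeat_factor see above (default 1.8).
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 10L, n_x = 2L,
                       windows_per_autosome = 200L, windows_per_x = 100L,
                       snps_per_window = 40L, window_bp = 5000L,
                       n_repeat_scaffolds = 0L, n_small_scaffolds = 0L,
                       small_len = 50000L,
                       populations = NULL,
                       F_split = 0.15, F_pop = 0.05, F_intro = 0.10,
                       alpha = 0.7,
                       admixture_mode = c("shared", "independent", "none"),
                       x_inflation_exponent = 4 / 3,
                       n_selected = 20L, delta = 0.6,
                       anc_range = c(0.05, 0.95),
                       outgroup_derived_prob = 0.05,
                       depth_mean = 30, depth_sigma = 0.05,
                       repeat_factor = 1.8) {
  admixture_mode <- match.arg(admixture_mode)
  if (is.null(populations))
    populations <- data.frame(
      name = c("OUT", "WAF1", "WAF2", "EAF1", "EAF2", "INT1", "INT2", "INT3"),
      role = c("outgroup", "west", "west", "east", "east",
               "introduced", "introduced", "introduced"),
      n_diploid = c(6L, 6L, 6L, 6L, 6L, 8L, 8L, 8L),
      stringsAsFactors = FALSE)
  for (F in c(F_split, F_pop, F_intro))
    if (F < 0 || F >= 1) stop("drift parameters must lie in [0, 1)")
  if (alpha < 0 || alpha > 1 || delta < 0 || delta > 1)
    stop("alpha and delta must lie in [0, 1]")
  if (admixture_mode == "none") alpha <- 1
  needed <- c("outgroup", "west", "east", "introduced")
  if (!all(needed %in% populations$role))
    stop("populations must include roles: ", paste(needed, collapse = ", "))
  if (n_selected > n_autosomes * windows_per_autosome)
    stop("more planted windows than autosomal windows")
  scaffolds <- rbind(
    if (n_autosomes) data.frame(
      scaffold = sprintf("chrA%02d", seq_len(n_autosomes)),
      length = windows_per_autosome * window_bp, class = "autosome",
      n_windows = windows_per_autosome, stringsAsFactors = FALSE),
    if (n_x) data.frame(
      scaffold = sprintf("chrX%02d", seq_len(n_x)),
      length = windows_per_x * window_bp, class = "X",
      n_windows = windows_per_x, stringsAsFactors = FALSE),
    if (n_repeat_scaffolds) data.frame(
      scaffold = sprintf("rep%02d", seq_len(n_repeat_scaffolds)),
      length = 200000L, class = "repeat", n_windows = 0L,
      stringsAsFactors = FALSE),
    if (n_small_scaffolds) data.frame(
      scaffold = sprintf("small%02d", seq_len(n_small_scaffolds)),
      length = small_len, class = "autosome", n_windows = 0L,
      stringsAsFactors = FALSE))
  structure(list(
    seed = as.integer(seed), scaffolds = scaffolds,
    snps_per_window = as.integer(snps_per_window),
    window_bp = as.integer(window_bp), populations = populations,
    F_split = F_split, F_pop = F_pop, F_intro = F_intro, alpha = alpha,
    admixture_mode = admixture_mode,
    x_inflation_exponent = x_inflation_exponent,
    n_selected = as.integer(n_selected), delta = delta,
    anc_range = anc_range, outgroup_derived_prob = outgroup_derived_prob,
    depth_mean = depth_mean, depth_sigma = depth_sigma,
    repeat_factor = repeat_factor), class = "sim_config")
}

# Balding-Nichols draw: Beta(mean p, var F p(1-p)); F = 0 (or fixed p) is a
# point mass at p. Vectorized over sites with per-site F.
bn_draw <- function(p, F) {
  out <- p
  idx <- which(F > 0 & p > 0 & p < 1)
  if (length(idx)) {
    r <- (1 - F[idx]) / F[idx]
    out[idx] <- stats::rbeta(length(idx), p[idx] * r, (1 - p[idx]) * r)
  }
  out
}

x_inflate <- function(F, g) 1 - (1 - F)^g

#' Simulate a dataset under the admixture-then-colonization model
#'
#' Deterministic given \code{config$seed}. Per SNP: ancestral frequency from
#' the configured uniform law; west/east lineage frequencies by
#' Balding-Nichols drift (F_split) from the ancestor; population frequencies
#' by further drift (F_pop) within their lineage. Each introduced window
#' takes its source frequencies from the west lineage with probability alpha
#' (one shared draw per window in shared mode, independent draws per
#' population otherwise), then drifts with F_intro. Planted windows shift the
#' derived frequency p <- p + delta (1-p) at every SNP in every introduced
#' population. Haplotypes are independent Bernoulli draws at the population
#' frequency; the outgroup is fixed ancestral except fixed derived with the
#' configured probability. X-linked scaffolds apply the X inflation to all F
#' parameters.
#'
#' @param config a \code{\link{sim_config}}.
#' @param dir optional output directory; writes \code{sim.vcf},
#'   \code{popmap.tsv}, \code{scaffold_lengths.tsv}, \code{truth.tsv},
#'   \code{depth.tsv} and \code{sim_config.txt} (config echo + seed).
#' @return A \code{sim_dataset}: list with \code{hm} (\code{\link{hapmat}}),
#'   \code{popmap}, \code{truth} (per window: scaffold, start, end, class,
#'   ancestry, selected), \code{scaffolds}, \code{pop_freq} (site x
#'   population true frequencies), \code{config}, and \code{files} when
#'   \code{dir} was given.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sc <- config$scaffolds[config$scaffolds$n_windows > 0, , drop = FALSE]
  spw <- config$snps_per_window
  nwin_per <- sc$n_windows
  W <- sum(nwin_per)                       # total windows
  S <- W * spw                             # total SNPs
  win_scaffold <- rep(sc$scaffold, nwin_per)
  win_class <- rep(sc$class, nwin_per)
  win_index_in_scaf <- unlist(lapply(nwin_per, seq_len))
  win_start <- (win_index_in_scaf - 1L) * config$window_bp
  win_of_site <- rep(seq_len(W), each = spw)

  # positions: spw distinct sorted offsets within each window
  pos <- unlist(lapply(seq_len(W), function(w)
    win_start[w] + sort(sample.int(config$window_bp, spw))))
  scaffold <- rep(win_scaffold, each = spw)

  is_x <- win_class[win_of_site] == "X"
  g <- config$x_inflation_exponent
  Fsp <- ifelse(is_x, x_inflate(config$F_split, g), config$F_split)
  Fpo <- ifelse(is_x, x_inflate(config$F_pop, g), config$F_pop)
  Fin <- ifelse(is_x, x_inflate(config$F_intro, g), config$F_intro)

  panc <- stats::runif(S, config$anc_range[1], config$anc_range[2])
  west_lin <- bn_draw(panc, Fsp)
  east_lin <- bn_draw(panc, Fsp)

  pops <- config$populations
  pop_freq <- matrix(NA_real_, S, nrow(pops),
                     dimnames = list(NULL, pops$name))
  intro_names <- pops$name[pops$role == "introduced"]
  shared <- config$admixture_mode != "independent"
  anc_west_shared <- stats::runif(W) < config$alpha
  truth_anc <- matrix(NA, W, length(intro_names),
                      dimnames = list(NULL, intro_names))
  sel_win <- sort(sample(which(win_class == "autosome"),
                         config$n_selected))
  sel_site <- win_of_site %in% sel_win

  for (k in seq_len(nrow(pops))) {
    role <- pops$role[k]
    if (role == "outgroup") {
      pop_freq[, k] <- as.numeric(stats::runif(S) < config$outgroup_derived_prob)
    } else if (role == "west") {
      pop_freq[, k] <- bn_draw(west_lin, Fpo)
    } else if (role == "east") {
      pop_freq[, k] <- bn_draw(east_lin, Fpo)
    } else {
      anc_west <- if (shared) anc_west_shared else stats::runif(W) < config$alpha
      truth_anc[, pops$name[k] == intro_names] <- anc_west
      src <- ifelse(anc_west[win_of_site], west_lin, east_lin)
      p <- bn_draw(src, Fin)
      p[sel_site] <- p[sel_site] + config$delta * (1 - p[sel_site])
      pop_freq[, k] <- p
    }
  }

  nhap <- 2L * pops$n_diploid
  alleles <- matrix(NA_integer_, sum(nhap), S)
  samples <- character(0)
  row0 <- 0L
  for (k in seq_len(nrow(pops))) {
    samples <- c(samples, sprintf("%s_%02d", pops$name[k],
                                  seq_len(pops$n_diploid[k])))
    h <- nhap[k]
    draws <- matrix(stats::rbinom(h * S, 1L, rep(pop_freq[, k], each = h)),
                    nrow = h)
    alleles[row0 + seq_len(h), ] <- draws
    row0 <- row0 + h
  }
  # sample.int offsets are already 1-based within the window, so window w's
  # SNPs sit at 1-based positions (win_start, win_start + window_bp]
  hm <- hapmat(scaffold, pos, alleles, samples)

  sexes <- unlist(lapply(pops$n_diploid, function(n)
    rep(c("male", "female"), length.out = n)))
  popmap <- data.frame(sample = samples,
                       population = rep(pops$name, pops$n_diploid),
                       sex = sexes, stringsAsFactors = FALSE)

  truth <- data.frame(scaffold = win_scaffold, start = win_start,
                      end = win_start + config$window_bp,
                      class = win_class,
                      selected = seq_len(W) %in% sel_win,
                      stringsAsFactors = FALSE)
  if (shared) {
    truth$ancestry <- ifelse(anc_west_shared, "west", "east")
  } else for (nm in intro_names)
    truth[[paste0("ancestry_", nm)]] <- ifelse(truth_anc[, nm], "west", "east")

  out <- structure(list(hm = hm, popmap = popmap, truth = truth,
                        scaffolds = config$scaffolds, pop_freq = pop_freq,
                        config = config),
                   class = "sim_dataset")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f <- list(vcf = file.path(dir, "sim.vcf"),
              popmap = file.path(dir, "popmap.tsv"),
              scaffold_lengths = file.path(dir, "scaffold_lengths.tsv"),
              truth = file.path(dir, "truth.tsv"),
              depth = file.path(dir, "depth.tsv"),
              config = file.path(dir, "sim_config.txt"))
    write_vcf(hm, f$vcf)
    utils::write.table(popmap, f$popmap, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(config$scaffolds[, c("scaffold", "length")],
                       f$scaffold_lengths, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_window_table(truth, f$truth)
    utils::write.table(simulate_depth_table(config), f$depth, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(config_echo(config), f$config)
    out$files <- f
  }
  out
}

# flat key: value echo of a sim_config (scaffold/population plans summarized)
config_echo <- function(config) {
  flat <- config[!(names(config) %in% c("scaffolds", "populations"))]
  c(sprintf("%s: %s", names(flat),
            vapply(flat, function(v) paste(format(v), collapse = ","), "")),
    sprintf("scaffolds: %d (%s)", nrow(config$scaffolds),
            paste(sprintf("%s=%d", config$scaffolds$scaffold,
                          config$scaffolds$length), collapse = " ")),
    sprintf("populations: %s",
            paste(sprintf("%s[%s,n=%d]", config$populations$name,
                          config$populations$role,
                          config$populations$n_diploid), collapse = " ")))
}

#' Simulate a raw per-sample per-scaffold depth table
#'
#' Autosomal scaffolds: per-sample depth = baseline x Normal(1, sigma).
#' X scaffolds: males at 0.5x, females (and unknown) at 1x. Repeat-class
#' scaffolds at \code{repeat_factor}x in everyone. Truncated at 0.
#' Deterministic given \code{config$seed} (offset so it does not reuse the
#' genotype stream).
#'
#' @param config a \code{\link{sim_config}}.
#' @return Long data.frame: \code{scaffold}, \code{sample},
#'   \code{mean_depth}.
#' @export
simulate_depth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 777L)
  pops <- config$populations
  samples <- sprintf("%s_%02d", rep(pops$name, pops$n_diploid),
                     unlist(lapply(pops$n_diploid, seq_len)))
  sexes <- unlist(lapply(pops$n_diploid, function(n)
    rep(c("male", "female"), length.out = n)))
  baseline <- config$depth_mean * stats::runif(length(samples), 0.8, 1.2)
  sc <- config$scaffolds
  grid <- expand.grid(si = seq_len(nrow(sc)), pi = seq_along(samples))
  fac <- ifelse(sc$class[grid$si] == "repeat", config$repeat_factor,
         ifelse(sc$class[grid$si] == "X" & sexes[grid$pi] == "male", 0.5, 1))
  depth <- baseline[grid$pi] *
    pmax(stats::rnorm(nrow(grid), mean = fac, sd = config$depth_sigma), 0)
  data.frame(scaffold = sc$scaffold[grid$si], sample = samples[grid$pi],
             mean_depth = depth, stringsAsFactors = FALSE)
}
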