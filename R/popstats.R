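# Windowed diversity and differentiation statistics.
#
# F_ST uses the Hudson estimator in ratio-of-averages form (sum the per-site
# numerators and denominators over the window, then divide): per site,
#   N_s = (pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)
#   D_s = pA(1-pB) + pB(1-pA)
# with sample allele frequencies p and non-missing haplotype counts n. The
# finite-sample correction terms make E[N_s] equal the squared difference of
# the true frequencies at any n.

#' Per-site allele frequencies by population
#'
#' @param hm a \code{\link{hapmat}}.
#' @param popmap popmap data.frame (\code{sample}, \code{population}).
#' @param populations character vector of population labels to tabulate.
#' @return A \code{freqtab}: list with \code{p} and \code{n} (site x
#'   population matrices of alternate-allele frequency and non-missing
#'   haplotype count; \code{p} is NA where \code{n = 0}), plus
#'   \code{scaffold}, \code{pos} and \code{populations}.
#' @export
allele_frequencies <- function(hm, popmap, populations) {
  stopifnot(length(populations) > 0)
  S <- n_sites(hm)
  p <- n <- matrix(NA_real_, S, length(populations),
                   dimnames = list(NULL, populations))
  for (k in seq_along(populations)) {
    pop <- populations[k]
    smp <- popmap$sample[popmap$population == pop]
    smp <- intersect(smp, hm$samples)
    if (!length(smp)) stop("population with zero samples in hapmat: ", pop)
    rows <- match(sample_haplotypes(hm, smp), rownames(hm$alleles))
    a <- hm$alleles[rows, , drop = FALSE]
    nk <- colSums(!is.na(a))
    alt <- colSums(a == 1L, na.rm = TRUE)
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, alt / nk, NA_real_)
  }
  structure(list(p = p, n = n, populations = populations,
                 scaffold = hm$scaffold, pos = hm$pos),
            class = "freqtab")
}

# per-site pi contributions 2*c0*c1/(n*(n-1)); 0 where n < 2
pi_site_terms <- function(freqs, pop) {
  p <- freqs$p[, pop]; n <- freqs$n[, pop]
  c1 <- p * n; c0 <- n - c1
  ifelse(n >= 2, 2 * c0 * c1 / (n * (n - 1)), 0)
}

#' Nucleotide diversity of one coordinate window
#'
#' pi = sum over SNPs of 2 c0 c1 / (n (n-1)), divided by the full window
#' length in bp (non-SNP sites are assumed monomorphic, the convention of
#' windowed-pi tools). Sites with fewer than two called haplotypes are
#' skipped.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param window one row of a coordinate-mode window table.
#' @param pop population label.
#' @param popmap popmap data.frame.
#' @return Per-site pi (unitless).
#' @export
window_pi <- function(hm, window, pop, popmap) {
  if (window$mode != "coordinate") stop("window_pi needs a coordinate-mode window")
  len <- window$end - window$start
  if (len <= 0) stop("window length must be positive")
  freqs <- allele_frequencies(hm, popmap, pop)
  idx <- window_site_idx(window)
  sum(pi_site_terms(freqs, pop)[idx]) / len
}

window_site_idx <- function(window) {
  if (is.na(window$snp_first)) integer() else window$snp_first:window$snp_last
}

# Hudson per-site terms; usable = n >= 2 in both pops
fst_site_terms <- function(freqs, popA, popB) {
  pA <- freqs$p[, popA]; pB <- freqs$p[, popB]
  nA <- freqs$n[, popA]; nB <- freqs$n[, popB]
  usable <- !is.na(pA) & !is.na(pB) & nA >= 2 & nB >= 2
  N <- (pA - pB)^2 - pA * (1 - pA) / (nA - 1) - pB * (1 - pB) / (nB - 1)
  D <- pA * (1 - pB) + pB * (1 - pA)
  N[!usable] <- NA_real_; D[!usable] <- NA_real_
  list(N = N, D = D, usable = usable)
}

clamp_fst <- function(x) pmin(pmax(x, 0), 1 - 1e-9)

#' Hudson F_ST for one window (ratio of averages)
#'
#' @param freqs a \code{freqtab} from \code{\link{allele_frequencies}}.
#' @param popA,popB population labels (symmetric).
#' @param window optional window row; omitted = all sites (genome-wide).
#' @return List with \code{raw} (may be negative; NA with \code{defined =
#'   FALSE} when no usable site), \code{clamped} (into [0, 1-1e-9]),
#'   \code{n_sites}, \code{defined}.
#' @export
window_fst_hudson <- function(freqs, popA, popB, window = NULL) {
  t <- fst_site_terms(freqs, popA, popB)
  idx <- if (is.null(window)) seq_along(t$usable) else window_site_idx(window)
  use <- idx[t$usable[idx]]
  if (!length(use))
    return(list(raw = NA_real_, clamped = NA_real_, n_sites = 0L, defined = FALSE))
  raw <- sum(t$N[use]) / sum(t$D[use])
  list(raw = raw, clamped = clamp_fst(raw), n_sites = length(use), defined = TRUE)
}

#' Genome-wide Hudson F_ST
#' @inheritParams window_fst_hudson
#' @return Clamped genome-wide F_ST (scalar).
#' @export
hudson_fst <- function(freqs, popA, popB)
  window_fst_hudson(freqs, popA, popB)$clamped

#' Population branch statistic
#'
#' PBS for focal population A against references B and C:
#' \code{T_xy = -log(1 - F_ST,xy)}; \code{PBS_A = (T_AB + T_AC - T_BC) / 2}.
#' May be negative. Inputs must already be clamped into [0, 1).
#'
#' @param fst_ab,fst_ac,fst_bc clamped pairwise F_ST values (vectorized).
#' @return PBS of population A (same length as inputs).
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc) {
  v <- c(fst_ab, fst_ac, fst_bc)
  if (any(v[!is.na(v)] >= 1 | v[!is.na(v)] < 0))
    stop("pbs inputs must lie in [0, 1); clamp F_ST upstream")
  (-log(1 - fst_ab) - log(1 - fst_ac) + log(1 - fst_bc)) / 2
}

#' Per-window pi, pairwise Hudson F_ST and PBS
#'
#' Vectorized scan over a window table: per-site statistic terms are computed
#' once and summed by window.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param windows window table from \code{\link{build_windows}}.
#' @param popmap popmap data.frame.
#' @param populations populations for pi columns (default: none).
#' @param pairs list of length-2 character vectors for F_ST columns.
#' @param triplets list of length-3 character vectors \code{c(focal, ref1,
#'   ref2)} for PBS columns; the needed pairs are added automatically.
#' @return The window table plus columns \code{pi_<pop>},
#'   \code{fst_<A>_<B>} (clamped), \code{fst_raw_<A>_<B>},
#'   \code{nsites_<A>_<B>} and \code{pbs_<focal>.<ref1>.<ref2>}.
#' @export
windowed_stats <- function(hm, windows, popmap, populations = character(),
                           pairs = list(), triplets = list()) {
  for (tr in triplets) {
    stopifnot(length(tr) == 3L)
    for (pr in list(tr[1:2], tr[c(1, 3)], tr[2:3]))
      if (!any(vapply(pairs, function(q) setequal(q, pr), TRUE)))
        pairs <- c(pairs, list(pr))
  }
  allpops <- unique(c(populations,
                      unlist(pairs, use.names = FALSE)))
  freqs <- allele_frequencies(hm, popmap, allpops)
  nw <- nrow(windows)
  wlen <- windows$end - windows$start
  win_of_site <- rep(NA_integer_, n_sites(hm))   # site -> window id
  for (w in seq_len(nw))
    if (!is.na(windows$snp_first[w]))
      win_of_site[windows$snp_first[w]:windows$snp_last[w]] <- w
  sum_by_window <- function(v) {  # NA-safe per-window sums of site terms
    out <- numeric(nw)
    ok <- !is.na(win_of_site) & !is.na(v)
    if (any(ok)) {
      s <- rowsum(v[ok], win_of_site[ok])
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  res <- windows
  for (pop in populations)
    res[[paste0("pi_", pop)]] <- sum_by_window(pi_site_terms(freqs, pop)) / wlen
  fname <- function(a, b) paste0(a, "_", b)
  for (pr in pairs) {
    t <- fst_site_terms(freqs, pr[1], pr[2])
    ns <- sum_by_window(as.numeric(t$usable))
    raw <- ifelse(ns > 0, sum_by_window(t$N) / sum_by_window(t$D), NA_real_)
    res[[paste0("fst_", fname(pr[1], pr[2]))]] <- clamp_fst(raw)
    res[[paste0("fst_raw_", fname(pr[1], pr[2]))]] <- raw
    res[[paste0("nsites_", fname(pr[1], pr[2]))]] <- as.integer(ns)
  }
  getf <- function(a, b) {
    cn <- paste0("fst_", fname(a, b))
    if (is.null(res[[cn]])) cn <- paste0("fst_", fname(b, a))
    res[[cn]]
  }
  for (tr in triplets)
    res[[paste0("pbs_", paste(tr, collapse = "."))]] <-
      pbs(getf(tr[1], tr[2]), getf(tr[1], tr[3]), getf(tr[2], tr[3]))
  res
}

#' Joint site-frequency spectrum with outgroup polarization
#'
#' A site enters the spectrum iff the outgroup population is fixed at that
#' site (its allele defines the ancestral state) and every focal population
#' is fully called; all other sites are counted as excluded. Entries are
#' counts of sites at each derived-allele-count coordinate.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param popmap popmap data.frame.
#' @param populations ordered focal populations (spectrum dimensions).
#' @param outgroup outgroup population label (disjoint from
#'   \code{populations}).
#' @return A \code{joint_sfs}: list with \code{counts} (array, dimension k =
#'   haplotype count of population k plus one, index = derived count),
#'   \code{populations}, \code{n_hap}, \code{excluded}, \code{n_input}.
#' @export
joint_sfs <- function(hm, popmap, populations, outgroup) {
  if (outgroup %in% populations)
    stop("outgroup must be disjoint from focal populations")
  freqs <- allele_frequencies(hm, popmap, c(populations, outgroup))
  S <- n_sites(hm)
  n_og <- freqs$n[, outgroup]; p_og <- freqs$p[, outgroup]
  if (all(n_og == 0)) stop("outgroup has zero called haplotypes at all sites")
  og_fixed <- n_og > 0 & (p_og == 0 | p_og == 1)
  nhap <- unname(vapply(populations, function(pop)
    2L * sum(popmap$population == pop & popmap$sample %in% hm$samples), 1L))
  full <- rep(TRUE, S)
  for (k in seq_along(populations))
    full <- full & freqs$n[, populations[k]] == nhap[k]
  use <- which(og_fixed & full)
  counts <- array(0L, dim = nhap + 1L,
                  dimnames = lapply(nhap, function(n) as.character(0:n)))
  if (length(use)) {
    anc_is_alt <- p_og[use] == 1        # outgroup fixed for ALT: ALT = ancestral
    dmat <- sapply(seq_along(populations), function(k) {
      alt <- round(freqs$p[use, populations[k]] * nhap[k])
      ifelse(anc_is_alt, nhap[k] - alt, alt)
    })
    dmat <- matrix(dmat, ncol = length(populations))
    idx <- dmat %*% cumprod(c(1, utils::head(nhap + 1L, -1))) + 1
    tab <- tabulate(idx, nbins = prod(nhap + 1L))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, populations = populations,
                 n_hap = stats::setNames(nhap, populations),
                 excluded = S - length(use), n_input = S),
            class = "joint_sfs")
}

#' Write a joint SFS as TSV
#'
#' Two sections: a long table (one row per non-zero coordinate, derived
#' counts per population then the site count) and a single flattened line in
#' row-major (C) order, last listed population varying fastest — the layout
#' multidimensional-SFS consumers expect. Header comment lines document the
#' dimension order.
#'
#' @param sfs a \code{joint_sfs}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    paste0("# joint SFS; dimensions (slowest to fastest): ",
           paste(sprintf("%s[%d]", sfs$populations, sfs$n_hap + 1L),
                 collapse = " x ")),
    paste0("# excluded_sites=", sfs$excluded, " input_sites=", sfs$n_input),
    paste(c(paste0("d_", sfs$populations), "count"), collapse = "\t")), con)
  arr <- sfs$counts
  nz <- which(arr != 0, arr.ind = TRUE)
  if (length(nz)) {
    ord <- do.call(order, as.data.frame(nz))
    nz <- nz[ord, , drop = FALSE]
    writeLines(paste(apply(nz - 1L, 1L, paste, collapse = "\t"),
                     arr[nz], sep = "\t"), con)
  }
  flat <- as.vector(aperm(arr, rev(seq_along(dim(arr)))))
  writeLines(c("# flattened (row-major):", paste(flat, collapse = " ")), con)
  invisible(path)
}
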