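# Shared fixtures and independent oracles, built in code at test time.

# --- toy VCF --------------------------------------------------------------
# two samples, three biallelic records:
#   s1: 0|1, 1|1, 0|0     s2: 0|0, 0|1, .|.
toy_vcf_lines <- function(extra_records = character()) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "scafA\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t0|0",
    "scafA\t200\t.\tC\tG\t.\tPASS\t.\tGT\t1|1\t0|1",
    "scafA\t300\t.\tT\tA\t.\tPASS\t.\tGT\t0|0\t.|.",
    extra_records)
}

write_toy_vcf <- function(path, lines = toy_vcf_lines()) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# expected allele matrix for the toy VCF (haplotypes x sites)
toy_alleles <- function() {
  matrix(c(0L, 1L, 0L,    # s1_1
           1L, 1L, 0L,    # s1_2
           0L, 0L, NA,    # s2_1
           0L, 1L, NA),   # s2_2
         nrow = 4L, byrow = TRUE,
         dimnames = list(c("s1_1", "s1_2", "s2_1", "s2_2"), NULL))
}

# hapmat straight from an allele matrix (one scaffold, unit-spaced positions)
make_hm <- function(alleles, scaffold = "s1", pos = NULL) {
  ns <- nrow(alleles) / 2
  if (is.null(pos)) pos <- seq_len(ncol(alleles)) * 10L
  hapmat(rep(scaffold, ncol(alleles)), pos, alleles,
         samples = paste0("smp", seq_len(ns)))
}

make_popmap <- function(hm, populations) {
  data.frame(sample = hm$samples,
             population = rep_len(populations, length(hm$samples)),
             sex = "unknown", stringsAsFactors = FALSE)
}

one_window <- function(hm, start = 0, end = NULL) {
  if (is.null(end)) end <- max(hm$pos)
  data.frame(scaffold = hm$scaffold[1], start = start, end = end,
             snp_first = 1L, snp_last = n_sites(hm),
             n_snps = n_sites(hm), mode = "coordinate", partial = FALSE,
             class = "autosome", stringsAsFactors = FALSE)
}

# --- oracles --------------------------------------------------------------

# pi oracle: mean pairwise Hamming difference over all haplotype pairs of the
# population, divided by window length (complete-data fixtures only)
pi_pairwise_oracle <- function(alleles, window_len) {
  n <- nrow(alleles)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(alleles[i, ] != alleles[j, ])
  tot / choose(n, 2) / window_len
}

# quartet oracle: four-point condition on a 4x4 path-distance matrix with
# rows/cols ordered (o, w, e, i)
quartet_fourpoint_oracle <- function(d) {
  s <- c(d["o", "e"] + d["w", "i"],
         d["o", "w"] + d["e", "i"],
         d["o", "i"] + d["w", "e"])
  if (abs(sort(s)[1] - sort(s)[2]) < 1e-9) "unresolved" else which.min(s)
}

# random additive quartet: pick a topology, assign random branch lengths,
# return the path-distance matrix (taxa o, w, e, i) and the true topology
random_additive_quartet <- function() {
  topo <- sample(1:3, 1)
  pend <- stats::runif(4, 0.1, 2)   # o, w, e, i
  internal <- stats::runif(1, 0.05, 1)
  d <- matrix(0, 4, 4, dimnames = list(c("o", "w", "e", "i"),
                                       c("o", "w", "e", "i")))
  pair <- switch(topo, c("w", "i"), c("e", "i"), c("w", "e"))
  other <- setdiff(c("o", "w", "e", "i"), pair)
  names(pend) <- c("o", "w", "e", "i")
  for (a in c("o", "w", "e", "i")) for (b in c("o", "w", "e", "i")) {
    if (a == b) next
    same_side <- (all(c(a, b) %in% pair)) || (all(c(a, b) %in% other))
    d[a, b] <- pend[a] + pend[b] + if (same_side) 0 else internal
  }
  list(d = d, topo = topo)
}

# exact hypergeometric upper tail P(X >= x), X ~ Hypergeom(N, K, n)
hyper_tail <- function(x, N, K, n)
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)

# minimal freqtab for statistics that only need p and n
make_freqs <- function(p, n, scaffold = NULL) {
  p <- as.matrix(p); n <- matrix(n, nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(p = p, n = n, populations = colnames(p),
                 scaffold = if (is.null(scaffold)) rep("s1", nrow(p)) else scaffold,
                 pos = seq_len(nrow(p))), class = "freqtab")
}
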