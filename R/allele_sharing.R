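# Four-population f4 tests with block-jackknife standard errors.
#
# f4(A,B;C,D) = mean over SNPs of (pA - pB)(pC - pD). Under a strict tree
# ((A,B),(C,D)) its expectation is zero; an excess of allele sharing between
# B and C drives it negative, between B and D positive.

#' Per-site f4 products and their mean
#'
#' Sites are used only where all four populations have at least two called
#' haplotypes; others are skipped.
#'
#' @param freqs a \code{freqtab} from \code{\link{allele_frequencies}}.
#' @param A,B,C,D population labels, quartet ((A,B),(C,D)).
#' @return List with \code{products} (per used site), \code{site_idx}
#'   (indices of used sites), \code{f4} (the mean) and \code{n_sites}.
#' @export
f4_statistic <- function(freqs, A, B, C, D) {
  pops <- c(A, B, C, D)
  miss <- setdiff(pops, colnames(freqs$p))
  if (length(miss)) stop("population(s) not in frequency table: ",
                         paste(miss, collapse = ", "))
  ok <- rowSums(freqs$n[, pops, drop = FALSE] >= 2) == 4L &
    !rowSums(is.na(freqs$p[, pops, drop = FALSE]))
  if (!any(ok)) stop("zero usable sites for f4(", A, ",", B, ";", C, ",", D, ")")
  idx <- which(ok)
  prod <- (freqs$p[idx, A] - freqs$p[idx, B]) *
    (freqs$p[idx, C] - freqs$p[idx, D])
  list(products = unname(prod), site_idx = idx,
       f4 = mean(prod), n_sites = length(idx))
}

#' Block-jackknife standard error and Z-score for a per-site mean
#'
#' Consecutive sites are grouped into blocks of \code{block_size} SNPs (the
#' grouping used to absorb linkage between adjacent SNPs); a trailing block
#' is kept if it holds at least \code{block_size / 10} sites, otherwise it is
#' merged into the previous block. Delete-one-block estimates
#' \eqn{\theta_{-j}} give \eqn{SE^2 = ((m-1)/m) \sum_j (\theta_{-j} -
#' \bar\theta_{-})^2}; Z is the full-data mean over SE.
#'
#' @param values per-site statistic values (in genomic order).
#' @param block_size SNPs per block (default 500).
#' @param block_id optional precomputed block assignment (overrides
#'   \code{block_size}); use to keep blocks from spanning scaffolds.
#' @return List with \code{estimate}, \code{se}, \code{z} (NA with
#'   \code{z_defined = FALSE} when SE is 0), \code{n_blocks}, \code{n_sites}.
#' @export
block_jackknife <- function(values, block_size = 500L, block_id = NULL) {
  n <- length(values)
  if (is.null(block_id)) {
    block_id <- (seq_len(n) - 1L) %/% block_size + 1L
    m <- max(block_id)
    if (m > 1L && sum(block_id == m) < block_size / 10)
      block_id[block_id == m] <- m - 1L
  }
  ids <- unique(block_id)
  m <- length(ids)
  if (m < 2L) stop("block jackknife needs at least 2 blocks")
  tot <- sum(values)
  bs <- vapply(ids, function(b) sum(values[block_id == b]), 0)
  bn <- vapply(ids, function(b) sum(block_id == b), 0L)
  theta <- (tot - bs) / (n - bn)      # delete-one-block means
  se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
  est <- tot / n
  list(estimate = est, se = se,
       z = if (se > 0) est / se else NA_real_,
       z_defined = se > 0, n_blocks = m, n_sites = n)
}

#' f4 test with block-jackknife Z-score
#'
#' @inheritParams f4_statistic
#' @param block_size SNPs per jackknife block (default 500).
#' @param split_scaffolds if \code{TRUE} (default), blocks never span
#'   scaffold boundaries.
#' @return One-row data.frame: A, B, C, D, f4, se, z, n_sites, n_blocks.
#' @export
f4_test <- function(freqs, A, B, C, D, block_size = 500L,
                    split_scaffolds = TRUE) {
  st <- f4_statistic(freqs, A, B, C, D)
  block_id <- NULL
  if (split_scaffolds && !is.null(freqs$scaffold)) {
    sc <- freqs$scaffold[st$site_idx]
    block_id <- integer(length(sc)); nb <- 0L
    for (s in unique(sc)) {
      i <- which(sc == s)
      b <- (seq_along(i) - 1L) %/% block_size + 1L
      mb <- max(b)
      if (mb > 1L && sum(b == mb) < block_size / 10) b[b == mb] <- mb - 1L
      block_id[i] <- b + nb
      nb <- nb + max(b)
    }
  }
  jk <- block_jackknife(st$products, block_size = block_size,
                        block_id = block_id)
  data.frame(A = A, B = B, C = C, D = D, f4 = st$f4, se = jk$se, z = jk$z,
             n_sites = st$n_sites, n_blocks = jk$n_blocks,
             stringsAsFactors = FALSE)
}
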