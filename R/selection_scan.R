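# Percentile outlier scan, overlap categories and the randomization null.

#' Call top-percentile outlier windows per chromosome class
#'
#' A window is an outlier iff its value is >= the nearest-rank upper
#' (1 - quantile) quantile within its chromosome class, i.e. the top 1\% by
#' default; ties at the threshold are all included, so the flagged set is the
#' top ceiling(0.01 x class size) windows plus threshold ties. Autosomal and
#' X windows are processed separately. Classes with fewer than 10 windows are
#' skipped with a warning (no outliers called).
#'
#' @param values per-window statistic (e.g. PBS); NA never flagged.
#' @param classes chromosome class per window (e.g. \code{"autosome"},
#'   \code{"X"}).
#' @param quantile outlier quantile (default 0.99).
#' @return Logical outlier flags, with attribute \code{thresholds} (named
#'   per-class cutoffs).
#' @export
call_outliers <- function(values, classes, quantile = 0.99) {
  stopifnot(length(values) == length(classes), quantile > 0, quantile < 1)
  flags <- rep(FALSE, length(values))
  thr <- c()
  for (cl in unique(classes)) {
    idx <- which(classes == cl & !is.na(values))
    if (length(idx) < 10L) {
      warning("class '", cl, "' has fewer than 10 windows; skipped")
      next
    }
    k <- max(1L, ceiling((1 - quantile) * length(idx) - 1e-9))
    cut <- sort(values[idx], decreasing = TRUE)[k]   # nearest-rank
    flags[idx] <- values[idx] >= cut
    if (all(values[idx] == cut))
      warning("all values tied in class '", cl, "'; every window flagged")
    thr[cl] <- cut
  }
  attr(flags, "thresholds") <- thr
  flags
}

norm_groups <- function(comparison_groups) {
  g <- unlist(comparison_groups)
  bad <- setdiff(unique(g), c("between_range", "within_native", "within_introduced"))
  if (length(bad)) stop("unknown comparison label(s): ", paste(bad, collapse = ", "))
  g
}

#' Overlap categories of outlier windows across comparisons
#'
#' Comparisons are grouped as between-range (introduced vs the two native
#' lineages), within-native or within-introduced. Categories per window:
#' \describe{
#'   \item{shared_two}{outlier in at least two between-range comparisons.}
#'   \item{shared_three}{outlier in at least three (i.e. all three in the
#'     standard design) between-range comparisons.}
#'   \item{plus_native}{between-range outlier that is also an outlier in at
#'     least one within-native comparison.}
#'   \item{plus_introduced}{between-range outlier also flagged in at least
#'     one within-introduced comparison.}
#'   \item{unique}{outlier in exactly one between-range comparison.}
#' }
#'
#' @param flags logical matrix, windows x comparisons, with comparison names
#'   as column names.
#' @param comparison_groups named character vector mapping each comparison to
#'   \code{"between_range"}, \code{"within_native"} or
#'   \code{"within_introduced"}.
#' @return List with \code{table} (per-window logical category columns) and
#'   \code{counts} (windows per category).
#' @export
overlap_categories <- function(flags, comparison_groups) {
  flags <- as.matrix(flags)
  g <- norm_groups(comparison_groups)
  if (is.null(colnames(flags)) || !all(colnames(flags) %in% names(g)))
    stop("every flag column needs an entry in comparison_groups")
  g <- g[colnames(flags)]
  between <- which(g == "between_range")
  if (length(between) < 2L) stop("need at least 2 between-range comparisons")
  br <- rowSums(flags[, between, drop = FALSE])
  nat <- rowSums(flags[, g == "within_native", drop = FALSE])
  intr <- rowSums(flags[, g == "within_introduced", drop = FALSE])
  tab <- data.frame(
    shared_two = br >= 2L,
    shared_three = br >= 3L,
    plus_native = br >= 1L & nat >= 1L,
    plus_introduced = br >= 1L & intr >= 1L,
    unique = br == 1L)
  list(table = tab, counts = vapply(tab, sum, 0L))
}

#' Randomization null for outlier-window overlap
#'
#' Each replicate draws, per comparison, a uniform without-replacement sample
#' of windows of the observed outlier count, then recomputes the overlap
#' statistics; the empirical p is the fraction of replicates with a null
#' statistic at least as large as observed (reported raw, which can be 0, and
#' with the (count + 1) / (reps + 1) correction). Run once per chromosome
#' class with that class's window count.
#'
#' @param n_windows number of windows in the class.
#' @param outlier_counts named integer vector, outliers per comparison.
#' @param comparison_groups named map as in \code{\link{overlap_categories}}.
#' @param observed named observed counts for a subset of
#'   \code{shared_two, shared_three, plus_native, plus_introduced}.
#' @param reps replicates (default 100000).
#' @param seed integer seed.
#' @return A \code{randomization_result}: observed counts, \code{reps},
#'   \code{seed}, per-statistic null \code{mean} and \code{max}, \code{p_raw}
#'   and \code{p_corrected}.
#' @export
overlap_randomization <- function(n_windows, outlier_counts,
                                  comparison_groups, observed,
                                  reps = 100000L, seed = 1L) {
  stopifnot(reps >= 1, all(outlier_counts <= n_windows))
  g <- norm_groups(comparison_groups)[names(outlier_counts)]
  if (anyNA(g)) stop("every outlier count needs an entry in comparison_groups")
  between <- names(outlier_counts)[g == "between_range"]
  native <- names(outlier_counts)[g == "within_native"]
  intro <- names(outlier_counts)[g == "within_introduced"]
  stats <- names(observed)
  bad <- setdiff(stats, c("shared_two", "shared_three", "plus_native",
                          "plus_introduced"))
  if (length(bad)) stop("unknown statistic(s): ", paste(bad, collapse = ", "))
  kb <- sort(outlier_counts[between], decreasing = TRUE)
  bound <- c(shared_two = if (length(kb) >= 2) unname(kb[2]) else 0,
             shared_three = if (length(kb) >= 3) unname(kb[3]) else 0,
             plus_native = min(sum(kb), sum(outlier_counts[native])),
             plus_introduced = min(sum(kb), sum(outlier_counts[intro])))
  if (any(unlist(observed) > bound[stats]))
    stop("observed overlap exceeds the maximum possible given outlier counts")
  set.seed(as.integer(seed))
  k <- outlier_counts
  null <- matrix(0L, nrow = reps, ncol = length(stats),
                 dimnames = list(NULL, stats))
  need_b <- any(stats %in% c("shared_two", "shared_three", "plus_native",
                             "plus_introduced"))
  for (r in seq_len(reps)) {
    draws <- lapply(k, function(kk) sample.int(n_windows, kk))
    if (need_b) {
      x <- sort(unlist(draws[between], use.names = FALSE))
      rl <- rle(x)$lengths
      if ("shared_two" %in% stats) null[r, "shared_two"] <- sum(rl >= 2L)
      if ("shared_three" %in% stats) null[r, "shared_three"] <- sum(rl >= 3L)
      if ("plus_native" %in% stats && length(native))
        null[r, "plus_native"] <-
          sum(unique(unlist(draws[native], use.names = FALSE)) %in% x)
      if ("plus_introduced" %in% stats && length(intro))
        null[r, "plus_introduced"] <-
          sum(unique(unlist(draws[intro], use.names = FALSE)) %in% x)
    }
  }
  cnt <- vapply(stats, function(s) sum(null[, s] >= observed[[s]]), 0)
  structure(list(
    observed = unlist(observed), reps = reps, seed = seed,
    null_mean = colMeans(null), null_max = apply(null, 2L, max),
    p_raw = cnt / reps, p_corrected = (cnt + 1) / (reps + 1)),
    class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("overlap randomization: %d replicates (seed %d)\n", x$reps, x$seed))
  for (s in names(x$observed))
    cat(sprintf("  %-16s observed %3d  null mean %.3f  max %d  p %.5g (corrected %.5g)\n",
                s, x$observed[s], x$null_mean[s], x$null_max[s],
                x$p_raw[s], x$p_corrected[s]))
  invisible(x)
}

#' Chi-squared test of ancestry composition at outlier windows
#'
#' Compares the topology-class composition (topo1/topo2/topo3/ambiguous) of
#' outlier windows against expectations from the genomic background:
#' Pearson's statistic sum (O - E)^2 / E with E = background proportion x
#' outlier total, df = 3.
#'
#' @param outlier_categories character vector of per-outlier-window classes,
#'   or named counts over the four categories.
#' @param background_categories same, for the genomic background.
#' @return List with \code{statistic}, \code{df}, \code{p_value},
#'   \code{observed}, \code{expected}.
#' @export
ancestry_enrichment <- function(outlier_categories, background_categories) {
  lev <- c("topo1", "topo2", "topo3", "ambiguous")
  as_counts <- function(x) {
    if (is.numeric(x)) {
      out <- stats::setNames(rep(0, 4L), lev)
      out[names(x)] <- x
      out
    } else table(factor(x, levels = lev))
  }
  O <- as.numeric(as_counts(outlier_categories))
  B <- as.numeric(as_counts(background_categories))
  if (sum(O) == 0) stop("zero outlier windows")
  if (sum(B) == 0) stop("zero background windows")
  E <- B / sum(B) * sum(O)
  if (any(E < 1)) warning("expected count below 1 in at least one category")
  stat <- sum(ifelse(E == 0 & O == 0, 0, (O - E)^2 / E))
  list(statistic = stat, df = 3L,
       p_value = stats::pchisq(stat, df = 3L, lower.tail = FALSE),
       observed = stats::setNames(O, lev), expected = stats::setNames(E, lev))
}
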