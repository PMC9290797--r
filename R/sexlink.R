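# Sex-linked scaffold assignment from normalized read depth.
#
# Hemizygous males sequence the X at ~half the depth of females, the Y at
# ~half depth vs ~zero in females, and collapsed repeats at inflated depth in
# everyone; thresholds on normalized depth separate these classes.

#' Classification thresholds for scaffold assignment
#'
#' Cutoffs are on normalized depth (scaffold depth over the sample's
#' genome-wide mean). The vote fractions generalize the original absolute
#' counts (at least 4 of 5 males, 3 of 4 females, 7 of 9 samples) to any
#' cohort via ceiling(fraction x available samples); at the original sample
#' sizes they reproduce those counts exactly
#' (ceil(0.8*5)=4, ceil(0.75*4)=3, ceil(7/9*9)=7). The all-sample fraction
#' must be the exact ratio 7/9: any rounded-up decimal (e.g. 0.78) would
#' demand 8 of 9 votes. A tiny tolerance inside the ceiling guards against
#' floating-point noise in fraction x n.
#'
#' @param x_cut X threshold: males below, females above (default 0.85).
#' @param y_cut Y threshold: males above, females below (default 0.25).
#' @param repeat_cut repeat threshold, any sex (default 1.5).
#' @param min_len minimum scaffold length in bp for assignment (default 1e5).
#' @param male_frac,female_frac,all_frac required vote fractions
#'   (defaults 0.8, 0.75, 0.78).
#' @return A named list of parameters.
#' @export
sexlink_params <- function(x_cut = 0.85, y_cut = 0.25, repeat_cut = 1.5,
                           min_len = 1e5, male_frac = 0.8,
                           female_frac = 0.75, all_frac = 7 / 9) {
  list(x_cut = x_cut, y_cut = y_cut, repeat_cut = repeat_cut,
       min_len = min_len, male_frac = male_frac, female_frac = female_frac,
       all_frac = all_frac)
}

#' Normalize per-scaffold read depth by genome-wide sample means
#'
#' Divides each sample's per-scaffold mean depth by that sample's
#' length-weighted genome-wide mean depth, so a typical autosomal scaffold
#' sits near 1 regardless of sequencing effort.
#'
#' @param depths long data.frame with columns \code{scaffold}, \code{sample},
#'   \code{mean_depth} (reads per site), or a path to such a TSV (no header
#'   needed if columns are in that order).
#' @param scaffold_lengths named vector of scaffold lengths (bp), or a path.
#' @return A \code{depth_profile}: list with \code{norm} (scaffold x sample
#'   matrix of normalized depths), \code{sample_means} (raw genome-wide mean
#'   per sample) and \code{lengths}.
#' @export
normalize_depths <- function(depths, scaffold_lengths) {
  if (is.character(depths) && length(depths) == 1L)
    depths <- utils::read.table(depths, sep = "\t", header = FALSE,
                                col.names = c("scaffold", "sample", "mean_depth"),
                                stringsAsFactors = FALSE)
  if (is.character(scaffold_lengths) && length(scaffold_lengths) == 1L)
    scaffold_lengths <- read_scaffold_lengths(scaffold_lengths)
  stopifnot(all(c("scaffold", "sample", "mean_depth") %in% names(depths)))
  scafs <- unique(depths$scaffold)
  if (any(is.na(scaffold_lengths[scafs])))
    stop("missing scaffold length for: ",
         paste(setdiff(scafs, names(scaffold_lengths)), collapse = ", "))
  samples <- unique(depths$sample)
  raw <- matrix(NA_real_, length(scafs), length(samples),
                dimnames = list(scafs, samples))
  raw[cbind(match(depths$scaffold, scafs), match(depths$sample, samples))] <-
    depths$mean_depth
  if (anyNA(raw)) stop("depth table is not complete (scaffold x sample)")
  if (any(raw < 0)) stop("negative depth values")
  len <- as.numeric(scaffold_lengths[scafs])
  sm <- as.numeric(crossprod(len, raw)) / sum(len)  # length-weighted mean/sample
  if (any(sm == 0))
    stop("sample(s) with zero total depth: ",
         paste(samples[sm == 0], collapse = ", "))
  structure(list(norm = sweep(raw, 2L, sm, `/`),
                 sample_means = stats::setNames(sm, samples),
                 lengths = stats::setNames(len, scafs)),
            class = "depth_profile")
}

#' Assign scaffolds to X / autosome / Y / repeat classes
#'
#' Rules, applied in fixed precedence order (first match wins):
#' \enumerate{
#'   \item \code{unassigned_small}: length < \code{min_len}.
#'   \item \code{repeat}: normalized depth > \code{repeat_cut} in at least
#'     \code{ceil(all_frac x n_samples)} samples (sex-independent; inflated
#'     depth invalidates the sex signal, so this outranks X/Y).
#'   \item \code{X}: depth < \code{x_cut} in at least
#'     \code{ceil(male_frac x n_males)} males AND > \code{x_cut} in at least
#'     \code{ceil(female_frac x n_females)} females.
#'   \item \code{Y}: depth > \code{y_cut} in the required male fraction AND
#'     < \code{y_cut} in the required female fraction.
#'   \item \code{autosome} otherwise.
#' }
#' Unknown-sex samples vote only in the repeat rule.
#'
#' @param profile a \code{depth_profile} from \code{\link{normalize_depths}}.
#' @param popmap popmap data.frame (needs \code{sample} and \code{sex}).
#' @param params thresholds from \code{\link{sexlink_params}}.
#' @return A \code{scaffold_assignment}: list with \code{table} (data.frame
#'   scaffold, class, length, and per-rule vote counts) and \code{params}
#'   (thresholds recorded verbatim).
#' @export
assign_scaffolds <- function(profile, popmap, params = sexlink_params()) {
  stopifnot(inherits(profile, "depth_profile"))
  sex <- popmap$sex[match(colnames(profile$norm), popmap$sample)]
  sex[is.na(sex)] <- "unknown"
  males <- which(sex == "male"); females <- which(sex == "female")
  if (!length(males) || !length(females))
    stop("need at least one male and one female of known sex")
  ceil_votes <- function(frac, n) max(1L, ceiling(frac * n - 1e-9))
  need_m <- ceil_votes(params$male_frac, length(males))
  need_f <- ceil_votes(params$female_frac, length(females))
  need_all <- ceil_votes(params$all_frac, ncol(profile$norm))
  nm <- profile$norm
  x_m <- rowSums(nm[, males, drop = FALSE] < params$x_cut)
  x_f <- rowSums(nm[, females, drop = FALSE] > params$x_cut)
  y_m <- rowSums(nm[, males, drop = FALSE] > params$y_cut)
  y_f <- rowSums(nm[, females, drop = FALSE] < params$y_cut)
  rep_all <- rowSums(nm > params$repeat_cut)
  cls <- ifelse(profile$lengths < params$min_len, "unassigned_small",
         ifelse(rep_all >= need_all, "repeat",
         ifelse(x_m >= need_m & x_f >= need_f, "X",
         ifelse(y_m >= need_m & y_f >= need_f, "Y", "autosome"))))
  structure(list(
    table = data.frame(scaffold = rownames(nm), class = unname(cls),
                       length = unname(profile$lengths),
                       x_votes_male = unname(x_m), x_votes_female = unname(x_f),
                       y_votes_male = unname(y_m), y_votes_female = unname(y_f),
                       repeat_votes = unname(rep_all),
                       stringsAsFactors = FALSE),
    params = params,
    votes_needed = c(male = need_m, female = need_f, all = need_all)),
    class = "scaffold_assignment")
}

#' Write a scaffold assignment table
#' @param assignment a \code{scaffold_assignment}.
#' @param path output TSV path; thresholds are recorded in '#' header lines.
#' @return \code{path}, invisibly.
#' @export
write_scaffold_assignment <- function(assignment, path) {
  con <- file(path, "wt"); on.exit(close(con))
  p <- assignment$params
  writeLines(sprintf("# %s=%s", names(p), unlist(p)), con)
  utils::write.table(assignment$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
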