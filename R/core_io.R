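# Genotype, popmap and window I/O.
#
# Internal coordinates are 0-based half-open everywhere; VCF positions
# (1-based) are converted on read and back on write. All written tables are
# 0-based half-open (BED-compatible).

#' Phased haplotype matrix
#'
#' Container for phased biallelic genotypes: one row per haplotype (two per
#' diploid sample), one column per SNP. Allele values are 0 (reference /
#' ancestral), 1 (alternate / derived) or \code{NA} (missing). Sites are
#' ordered by scaffold (order of first appearance) and strictly increasing
#' position within scaffold.
#'
#' @param scaffold character vector, scaffold id per site.
#' @param pos integer vector, 1-based base-pair position per site.
#' @param alleles integer matrix, haplotypes x sites, values in \{0, 1, NA\}.
#' @param samples character vector of sample ids; haplotype row \code{2i-1}
#'   and \code{2i} belong to \code{samples[i]}.
#' @param unphased optional logical matrix (same shape as \code{alleles});
#'   \code{TRUE} marks alleles whose phase was not given in the input.
#'   Frequency-based statistics ignore it; haplotype-based ones refuse it
#'   unless phase was randomized (see \code{\link{read_vcf}}).
#' @return An object of class \code{hapmat}.
#' @export
hapmat <- function(scaffold, pos, alleles, samples, unphased = NULL) {
  scaffold <- as.character(scaffold)
  pos <- as.integer(pos)
  if (!is.matrix(alleles)) alleles <- matrix(as.integer(alleles), nrow = 2L * length(samples))
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != length(pos) || length(scaffold) != length(pos))
    stop("hapmat: scaffold, pos and alleles columns must agree in length")
  if (nrow(alleles) != 2L * length(samples))
    stop("hapmat: need exactly two haplotype rows per diploid sample")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && any(bad != 0L & bad != 1L))
    stop("hapmat: allele values must be 0, 1 or NA")
  if (length(pos)) {
    for (sc in unique(scaffold)) {
      p <- pos[scaffold == sc]
      if (any(diff(p) <= 0L))
        stop("hapmat: positions not strictly increasing on scaffold ", sc)
    }
  }
  rownames(alleles) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  structure(
    list(scaffold = scaffold, pos = pos, alleles = alleles,
         samples = as.character(samples), unphased = unphased),
    class = "hapmat")
}

#' @export
print.hapmat <- function(x, ...) {
  cat(sprintf("hapmat: %d sites on %d scaffold(s), %d samples (%d haplotypes)\n",
              length(x$pos), length(unique(x$scaffold)),
              length(x$samples), nrow(x$alleles)))
  if (!is.null(x$unphased) && any(x$unphased, na.rm = TRUE))
    cat(sprintf("  %d unphased heterozygous calls flagged\n",
                sum(x$unphased, na.rm = TRUE) / 2L))
  invisible(x)
}

#' @export
dim.hapmat <- function(x) dim(x$alleles)

#' Number of sites in a hapmat
#' @param hm a \code{\link{hapmat}}.
#' @return Integer site count.
#' @export
n_sites <- function(hm) length(hm$pos)

#' Haplotype ids of a hapmat
#' @param hm a \code{\link{hapmat}}.
#' @return Character vector of haplotype row names.
#' @export
haplotype_ids <- function(hm) rownames(hm$alleles)

#' Haplotype ids belonging to a set of samples
#' @param hm a \code{\link{hapmat}}.
#' @param samples character vector of sample ids.
#' @return Character vector of haplotype ids (two per sample).
#' @export
sample_haplotypes <- function(hm, samples) {
  miss <- setdiff(samples, hm$samples)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  paste0(rep(samples, each = 2L), c("_1", "_2"))
}

# subset sites, keeping order
hm_subset_sites <- function(hm, idx) {
  hapmat(hm$scaffold[idx], hm$pos[idx],
         hm$alleles[, idx, drop = FALSE], hm$samples,
         unphased = if (is.null(hm$unphased)) NULL else hm$unphased[, idx, drop = FALSE])
}

#' Read a VCF into a haplotype matrix
#'
#' Minimal VCF v4.x reader for biallelic SNP records with a GT field
#' (plain or gzip). Phased genotypes (\code{0|1}) yield two haplotype rows per
#' diploid sample. Unphased heterozygotes (\code{0/1}) are stored in file
#' order and flagged in the \code{unphased} slot; pass a
#' \code{random_phase_seed} to assign phase at random instead (frequency
#' statistics are phase-free, trees are not). Multiallelic records are skipped
#' and counted (attribute \code{n_multiallelic}).
#'
#' @param path VCF file (\code{.vcf} or \code{.vcf.gz}).
#' @param region optional scaffold id; restrict to records on that scaffold.
#'   An absent region yields an empty matrix, not an error.
#' @param random_phase_seed optional integer; if given, unphased heterozygotes
#'   are randomly phased under this seed and not flagged.
#' @return A \code{\link{hapmat}}.
#' @export
read_vcf <- function(path, region = NULL, random_phase_seed = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) stop("malformed VCF (no #CHROM header line): ", path)
  hfields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(hfields) < 10L || hfields[9L] != "FORMAT")
    stop("malformed VCF: header has no FORMAT/sample columns")
  samples <- hfields[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  lineno <- hdr + seq_along(body)

  n_multi <- 0L
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(hfields)))
      stop("malformed VCF record at line ",
           lineno[which(nf != length(hfields))[1L]], ": wrong field count")
    m <- matrix(unlist(parts, use.names = FALSE), ncol = length(hfields), byrow = TRUE)
    keep <- rep(TRUE, nrow(m))
    multi <- grepl(",", m[, 5L], fixed = TRUE)
    n_multi <- sum(multi)
    keep[multi] <- FALSE
    if (!is.null(region)) keep <- keep & m[, 1L] == region
    m <- m[keep, , drop = FALSE]
    lineno <- lineno[keep]
  } else {
    m <- matrix(character(), ncol = length(hfields))
  }

  ns <- length(samples)
  S <- nrow(m)
  alleles <- matrix(NA_integer_, nrow = 2L * ns, ncol = S)
  unphased <- matrix(FALSE, nrow = 2L * ns, ncol = S)
  if (S) {
    gt_first <- vapply(strsplit(m[, 9L], ":", fixed = TRUE), `[`, "", 1L)
    if (any(gt_first != "GT"))
      stop("malformed VCF record at line ",
           lineno[which(gt_first != "GT")[1L]], ": GT must be first FORMAT key")
    gt <- matrix(sub(":.*$", "", m[, -(1:9), drop = FALSE]), nrow = S)  # S x ns
    a1 <- substr(gt, 1L, 1L); sep <- substr(gt, 2L, 2L); a2 <- substr(gt, 3L, 3L)
    ok <- (a1 %in% c("0", "1", ".")) & (a2 %in% c("0", "1", ".")) & (sep %in% c("|", "/"))
    if (any(!ok)) {
      bad <- which(!ok)[1L]
      bi <- (bad - 1L) %% S + 1L; bj <- (bad - 1L) %/% S + 1L
      stop("malformed genotype '", gt[bi, bj], "' at line ",
           lineno[bi], " (sample ", samples[bj], ")")
    }
    v1 <- suppressWarnings(as.integer(a1))   # "." -> NA
    v2 <- suppressWarnings(as.integer(a2))
    het_un <- sep == "/" & !is.na(v1) & !is.na(v2) & v1 != v2
    if (any(het_un) && !is.null(random_phase_seed)) {
      set.seed(as.integer(random_phase_seed))
      flip <- matrix(FALSE, nrow = S, ncol = ns)
      flip[het_un] <- stats::runif(sum(het_un)) < 0.5
      tmp <- v1[flip]; v1[flip] <- v2[flip]; v2[flip] <- tmp
      het_un[] <- FALSE
    }
    # rows 2i-1 / 2i of alleles are sample i; v1/v2 are S x ns
    alleles[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(v1, nrow = S))
    alleles[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(v2, nrow = S))
    unphased[seq(1L, 2L * ns, by = 2L), ] <- t(matrix(het_un, nrow = S))
    unphased[seq(2L, 2L * ns, by = 2L), ] <- t(matrix(het_un, nrow = S))
  }
  hm <- hapmat(if (S) m[, 1L] else character(),
               if (S) as.integer(m[, 2L]) else integer(),
               alleles, samples,
               unphased = if (any(unphased)) unphased else NULL)
  attr(hm, "n_multiallelic") <- n_multi
  if (n_multi) message(n_multi, " multiallelic record(s) skipped")
  hm
}

#' Write a haplotype matrix as phased VCF v4.2
#'
#' @param hm a \code{\link{hapmat}}.
#' @param path output path (\code{.gz} suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(hm, path) {
  ns <- length(hm$samples)
  S <- n_sites(hm)
  tok <- matrix("", nrow = S, ncol = ns)
  if (S) {
    i1 <- seq(1L, 2L * ns, by = 2L)
    a1 <- t(hm$alleles[i1, , drop = FALSE]); a2 <- t(hm$alleles[i1 + 1L, , drop = FALSE])
    c1 <- ifelse(is.na(a1), ".", as.character(a1))
    c2 <- ifelse(is.na(a2), ".", as.character(a2))
    tok <- matrix(paste0(c1, "|", c2), nrow = S)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=zapscan-simulate",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", hm$samples), collapse = "\t"))
  body <- if (S) {
    gtcols <- do.call(paste, c(split(tok, col(tok)), list(sep = "\t")))
    paste(hm$scaffold, hm$pos, ".", "A", "T", ".", "PASS", ".", "GT", gtcols,
          sep = "\t")
  } else character()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Hard-filter sites on call rate and minor-allele count
#'
#' Retains sites where the fraction of non-missing haplotype calls is at
#' least \code{max_missing_frac} (the vcftools \code{--max-missing} boundary
#' semantics) and the minor-allele count among non-missing calls is at least
#' \code{min_mac}. Site order is preserved; the operation is idempotent.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param max_missing_frac minimum called fraction in [0, 1] (default 0.5).
#' @param min_mac minimum minor-allele count (default 2).
#' @return Filtered \code{\link{hapmat}} (possibly with zero sites).
#' @export
filter_variants <- function(hm, max_missing_frac = 0.5, min_mac = 2L) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1, min_mac >= 0)
  if (!n_sites(hm)) return(hm)
  called <- colSums(!is.na(hm$alleles))
  alt <- colSums(hm$alleles == 1L, na.rm = TRUE)
  mac <- pmin(alt, called - alt)
  keep <- (called / nrow(hm$alleles)) >= max_missing_frac & mac >= min_mac
  hm_subset_sites(hm, which(keep))
}

#' Read a population map
#'
#' Tab-separated, two or three columns: sample, population, optional sex
#' (\code{male}/\code{female}; missing third column or empty token means
#' \code{unknown}).
#'
#' @param path popmap TSV.
#' @return \code{data.frame} with columns \code{sample}, \code{population},
#'   \code{sex}.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE,
                          col.names = c("sample", "population", "sex")[1:3],
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("popmap needs at least 2 columns")
  if (ncol(df) == 2L) df$sex <- "unknown"
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  if (anyDuplicated(df$sample))
    stop("duplicate sample(s) in popmap: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  bad <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad)) stop("unknown sex token(s): ", paste(bad, collapse = ", "))
  if (any(!nzchar(df$population))) stop("empty population label in popmap")
  df
}

#' Read a scaffold-lengths table (scaffold<TAB>length)
#' @param path two-column TSV, no header.
#' @return Named integer vector of lengths.
#' @export
read_scaffold_lengths <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"))
  stats::setNames(as.numeric(df[[2L]]), df[[1L]])
}

#' Build non-overlapping analysis windows
#'
#' Two modes. \code{"snp_count"} emits \code{floor(n_snps / size)} full
#' windows of exactly \code{size} SNPs per scaffold, dropping the trailing
#' remainder (fixed-SNP window convention). \code{"coordinate"} tiles
#' \code{[0, scaffold_length)} in \code{size}-bp bins, keeping a final partial
#' window flagged \code{partial = TRUE}. Every SNP belongs to at most one
#' window.
#'
#' @param hm a \code{\link{hapmat}}.
#' @param mode \code{"coordinate"} or \code{"snp_count"}.
#' @param size window size: base pairs (coordinate) or SNPs (snp_count).
#' @param scaffold_lengths named vector of scaffold lengths in bp; required
#'   for coordinate mode and must cover the last SNP of each scaffold.
#' @return \code{data.frame} of windows: \code{scaffold}, \code{start},
#'   \code{end} (0-based half-open bp), \code{snp_first}, \code{snp_last}
#'   (1-based indices into \code{hm} sites, NA when the window holds no SNP),
#'   \code{n_snps}, \code{mode}, \code{partial}, \code{class} (filled by
#'   \code{\link{annotate_window_class}}, initially \code{"unassigned"}).
#' @export
build_windows <- function(hm, mode = c("coordinate", "snp_count"), size,
                          scaffold_lengths = NULL) {
  mode <- match.arg(mode)
  stopifnot(size > 0)
  scafs <- unique(hm$scaffold)
  out <- vector("list", length(scafs))
  for (k in seq_along(scafs)) {
    sc <- scafs[k]
    idx <- which(hm$scaffold == sc)
    pos <- hm$pos[idx]
    if (mode == "snp_count") {
      nw <- length(idx) %/% size
      if (!nw) { out[[k]] <- NULL; next }
      first <- (seq_len(nw) - 1L) * size + 1L
      last <- first + size - 1L
      out[[k]] <- data.frame(
        scaffold = sc,
        start = pos[first] - 1L, end = pos[last],
        snp_first = idx[first], snp_last = idx[last],
        n_snps = as.integer(size), mode = "snp_count", partial = FALSE,
        class = "unassigned", stringsAsFactors = FALSE)
    } else {
      if (is.null(scaffold_lengths) || is.na(scaffold_lengths[sc]))
        stop("coordinate mode needs a scaffold length for ", sc)
      L <- as.numeric(scaffold_lengths[sc])
      if (length(pos) && L < max(pos))
        stop("scaffold length for ", sc, " smaller than last SNP position")
      starts <- seq(0, L - 1, by = size)
      ends <- pmin(starts + size, L)
      # site i (1-based pos) falls in [start, end) on the 0-based axis
      wi <- findInterval(pos - 1L, starts)
      sf <- sl <- rep(NA_integer_, length(starts))
      cnt <- tabulate(wi, nbins = length(starts))
      has <- cnt > 0L
      sf[has] <- idx[match(which(has), wi)]
      sl[has] <- sf[has] + cnt[has] - 1L
      out[[k]] <- data.frame(
        scaffold = sc, start = starts, end = ends,
        snp_first = sf, snp_last = sl, n_snps = cnt,
        mode = "coordinate", partial = ends - starts < size,
        class = "unassigned", stringsAsFactors = FALSE)
    }
  }
  out <- Filter(Negate(is.null), out)
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), snp_first = integer(),
                      snp_last = integer(), n_snps = integer(),
                      mode = character(), partial = logical(),
                      class = character(), stringsAsFactors = FALSE)
  res
}

#' Attach chromosome classes to a window table
#' @param windows a window table from \code{\link{build_windows}}.
#' @param assignment a \code{\link{assign_scaffolds}} result (or a data.frame
#'   with columns \code{scaffold}, \code{class}).
#' @return The window table with \code{class} filled (\code{"unassigned"}
#'   where the scaffold was not classified).
#' @export
annotate_window_class <- function(windows, assignment) {
  if (inherits(assignment, "scaffold_assignment")) assignment <- assignment$table
  cl <- assignment$class[match(windows$scaffold, assignment$scaffold)]
  windows$class <- ifelse(is.na(cl), "unassigned", cl)
  windows
}

#' Write / read a per-window statistic table
#'
#' Tab-separated with a single header line; \code{scaffold}, \code{start},
#' \code{end} are forced to be the first three columns (0-based half-open).
#' Floats are rendered with 15 significant digits so the table round-trips
#' losslessly to within 1e-9.
#'
#' @param rows data.frame sharing one schema; must contain scaffold/start/end.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_window_table <- function(rows, path) {
  need <- c("scaffold", "start", "end")
  if (!all(need %in% names(rows)))
    stop("window table needs columns: ", paste(need, collapse = ", "))
  rows <- rows[, c(need, setdiff(names(rows), need)), drop = FALSE]
  isnum <- vapply(rows, is.double, TRUE)
  for (j in which(isnum)) rows[[j]] <- sprintf("%.15g", rows[[j]])
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
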