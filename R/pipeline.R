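# End-to-end orchestration: one config file, deterministic seeding,
# per-stage manifest.

#' Stage-local seed derived from the global seed
#'
#' Stable string hash of the stage name mixed with the global seed, so
#' enabling or disabling one stage never shifts another stage's random
#' draws. Always below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000003 * 2053 + h) %% 2147483647)
}

#' Read a pipeline configuration
#'
#' JSON (preferred) or a flat \code{key: value} file for scalar-only
#' configs. See \code{\link{default_pipeline_config}} for the schema.
#'
#' @param path config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  first <- trimws(txt[nzchar(trimws(txt))][1])
  if (startsWith(first, "{"))
    return(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE))
  kv <- txt[grepl(":", txt, fixed = TRUE) & !startsWith(trimws(txt), "#")]
  keys <- trimws(sub(":.*$", "", kv))
  vals <- trimws(sub("^[^:]*:", "", kv))
  num <- suppressWarnings(as.numeric(vals))
  stats::setNames(lapply(seq_along(vals), function(i)
    if (!is.na(num[i])) num[i] else vals[i]), keys)
}

#' Default pipeline configuration for the bundled simulator
#'
#' Full-stage config using the default \code{\link{sim_config}} populations:
#' between-range PBS comparisons compare each introduced population to one
#' west and one east native population; within-introduced comparisons compare
#' each introduced population to the other two; the two within-native
#' comparisons compare one population of each African lineage to the two
#' populations of the opposite lineage. Topology groups use the outgroup,
#' the first west and east populations and every introduced population as a
#' focal lineage in turn; f4 quartets hold the outgroup as A.
#'
#' @param seed global seed.
#' @param simulate named list of \code{\link{sim_config}} overrides.
#' @param reps overlap-randomization replicates (default 1000 for smoke runs;
#'   the study-scale value is 100000).
#' @param n_subtrees quartets per topology window (default 600).
#' @return Config list accepted by \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function(seed = 1L, simulate = list(),
                                    reps = 1000L, n_subtrees = 600L) {
  list(
    seed = seed,
    simulate = simulate,
    filter = list(max_missing = 0.5, min_mac = 2),
    windows = list(coordinate_bp = 5000, snp_count = 500),
    groups = list(outgroup = "OUT", west = "WAF1", east = "EAF1",
                  focal = c("INT1", "INT2", "INT3")),
    comparisons = list(
      INT1_native = list(triplet = c("INT1", "WAF1", "EAF1"), group = "between_range"),
      INT2_native = list(triplet = c("INT2", "WAF1", "EAF1"), group = "between_range"),
      INT3_native = list(triplet = c("INT3", "WAF1", "EAF1"), group = "between_range"),
      INT1_intro = list(triplet = c("INT1", "INT2", "INT3"), group = "within_introduced"),
      INT2_intro = list(triplet = c("INT2", "INT1", "INT3"), group = "within_introduced"),
      INT3_intro = list(triplet = c("INT3", "INT1", "INT2"), group = "within_introduced"),
      WAF1_native = list(triplet = c("WAF1", "EAF1", "EAF2"), group = "within_native"),
      EAF1_native = list(triplet = c("EAF1", "WAF1", "WAF2"), group = "within_native")),
    f4 = list(quartets = list(c("OUT", "INT1", "WAF1", "EAF1"),
                              c("OUT", "INT2", "WAF1", "EAF1"),
                              c("OUT", "INT3", "WAF1", "EAF1")),
              block_size = 500),
    topoweights = list(n_subtrees = n_subtrees),
    scan = list(quantile = 0.99, reps = reps))
}

need_key <- function(config, key, stage) {
  if (is.null(config[[key]]))
    stop("config is missing required key '", key, "' (needed by stage ",
         stage, ")")
  config[[key]]
}

#' Run the full analysis pipeline
#'
#' Stage order: filter, sexlink, windows, popstats, topoweights, f4, scan.
#' Inputs come either from a \code{simulate} block (the bundled generator) or
#' from an \code{inputs} block naming a VCF, popmap, scaffold-lengths and
#' depth table. Identical config + seed reproduce identical statistic
#' tables; stage seeds are derived with \code{\link{stage_seed}}.
#'
#' @param config config list or path (see
#'   \code{\link{default_pipeline_config}}).
#' @param out_dir optional output directory; all stage tables plus
#'   \code{manifest.json} are written there.
#' @param seed overrides \code{config$seed}.
#' @param stages subset of stages to run (default: all).
#' @return List of stage results plus \code{manifest}, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, stages = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  all_stages <- c("filter", "sexlink", "windows", "popstats", "topoweights",
                  "f4", "scan")
  if (is.null(stages)) stages <- config$stages
  if (is.null(stages)) stages <- all_stages
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("config is missing required key 'seed'")
  seed <- as.integer(seed)
  # validate config up front, before any computation
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config is missing required key 'simulate' or 'inputs'")
  if ("topoweights" %in% stages) need_key(config, "groups", "topoweights")
  if ("scan" %in% stages) need_key(config, "comparisons", "scan")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  manifest <- list(package = "zapscan",
                   version = as.character(utils::packageVersion("zapscan")),
                   seed = seed, config = config, stages = list())
  res <- list()
  emit <- function(stage, name, obj, writer, t0) {
    path <- NULL
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, name)
      writer(obj, path)
    }
    rows <- if (is.data.frame(obj)) nrow(obj) else NA_integer_
    manifest$stages[[stage]] <<- c(
      manifest$stages[[stage]],
      list(list(output = name, path = path, rows = rows,
                elapsed_s = round(as.numeric(Sys.time()) - t0, 3))))
    invisible(obj)
  }
  tsv_writer <- function(obj, path)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- stage_seed(seed, "simulate")
    sim <- simulate_dataset(do.call(sim_config, sim_args))
    hm <- sim$hm
    popmap <- sim$popmap
    scaffold_lengths <- stats::setNames(sim$scaffolds$length,
                                        sim$scaffolds$scaffold)
    depth <- simulate_depth_table(sim$config)
    res$sim <- sim
  } else {
    inp <- config$inputs
    for (k in c("vcf", "popmap", "scaffold_lengths"))
      if (is.null(inp[[k]]))
        stop("config is missing required key 'inputs$", k, "'")
    hm <- read_vcf(inp$vcf,
                   random_phase_seed = if (isTRUE(inp$force_random_phase))
                     stage_seed(seed, "phase") else NULL)
    popmap <- read_popmap(inp$popmap)
    scaffold_lengths <- read_scaffold_lengths(inp$scaffold_lengths)
    depth <- if (!is.null(inp$depth))
      utils::read.table(inp$depth, sep = "\t",
                        col.names = c("scaffold", "sample", "mean_depth"),
                        stringsAsFactors = FALSE)
  }

  # ---- filter -------------------------------------------------------------
  if ("filter" %in% stages) {
    t0 <- as.numeric(Sys.time())
    fl <- config$filter
    hm <- filter_variants(hm,
                          max_missing_frac = if (is.null(fl$max_missing)) 0.5 else fl$max_missing,
                          min_mac = if (is.null(fl$min_mac)) 2L else fl$min_mac)
    res$n_sites_filtered <- n_sites(hm)
    emit("filter", "filtered_sites.txt",
         data.frame(n_sites = n_sites(hm)), tsv_writer, t0)
  }

  # ---- sexlink ------------------------------------------------------------
  assignment <- NULL
  if ("sexlink" %in% stages && !is.null(depth)) {
    t0 <- as.numeric(Sys.time())
    prof <- normalize_depths(depth, scaffold_lengths)
    assignment <- assign_scaffolds(prof, popmap)
    res$assignment <- assignment
    emit("sexlink", "scaffold_classes.tsv", assignment$table, tsv_writer, t0)
  }

  # ---- windows ------------------------------------------------------------
  wconf <- config$windows
  if (is.null(wconf)) wconf <- list(coordinate_bp = 5000, snp_count = 500)
  t0 <- as.numeric(Sys.time())
  coord_win <- build_windows(hm, "coordinate", wconf$coordinate_bp,
                             scaffold_lengths)
  snp_win <- build_windows(hm, "snp_count", wconf$snp_count)
  if (!is.null(assignment)) {
    coord_win <- annotate_window_class(coord_win, assignment)
    snp_win <- annotate_window_class(snp_win, assignment)
  }
  res$coord_windows <- coord_win
  res$snp_windows <- snp_win
  if ("windows" %in% stages)
    emit("windows", "windows_coordinate.tsv", coord_win, function(o, p)
      write_window_table(o, p), t0)

  populations <- unique(popmap$population)

  # ---- popstats -----------------------------------------------------------
  if ("popstats" %in% stages) {
    t0 <- as.numeric(Sys.time())
    triplets <- lapply(config$comparisons, `[[`, "triplet")
    ws <- windowed_stats(hm, coord_win, popmap,
                         populations = populations, triplets = triplets)
    # name PBS columns after their comparison
    for (nm in names(triplets)) {
      old <- paste0("pbs_", paste(triplets[[nm]], collapse = "."))
      names(ws)[names(ws) == old] <- paste0("pbs_", nm)
    }
    res$window_stats <- ws
    emit("popstats", "window_stats.tsv", ws, function(o, p)
      write_window_table(o, p), t0)
  }

  # ---- topoweights --------------------------------------------------------
  if ("topoweights" %in% stages) {
    t0 <- as.numeric(Sys.time())
    gconf <- config$groups
    pop_haps <- function(pops) {
      smp <- popmap$sample[popmap$population %in% pops]
      sample_haplotypes(hm, smp)
    }
    tw_all <- list()
    for (focal in gconf$focal) {
      groups <- topo_groups(pop_haps(gconf$outgroup), pop_haps(gconf$west),
                            pop_haps(gconf$east), pop_haps(focal))
      n_sub <- if (is.null(config$topoweights$n_subtrees)) 600L
               else config$topoweights$n_subtrees
      tw <- topoweights_scan(hm, snp_win, groups, n_subtrees = n_sub,
                             seed = stage_seed(seed, paste0("topoweights_", focal)))
      tw_all[[focal]] <- tw
      emit("topoweights", paste0("topoweights_", focal, ".tsv"), tw,
           function(o, p) write_window_table(o, p), t0)
    }
    res$topoweights <- tw_all
    if (length(tw_all) >= 2L) {
      prs <- utils::combn(names(tw_all), 2L, simplify = FALSE)
      cors <- do.call(rbind, lapply(prs, function(pr) {
        ac <- ancestry_correlation(tw_all[[pr[1]]]$score, tw_all[[pr[2]]]$score)
        data.frame(popA = pr[1], popB = pr[2], rho = ac$rho,
                   p_value = ac$p_value, n = ac$n, stringsAsFactors = FALSE)
      }))
      res$ancestry_correlations <- cors
      emit("topoweights", "ancestry_correlations.tsv", cors, tsv_writer, t0)
    }
  }

  # ---- f4 -----------------------------------------------------------------
  if ("f4" %in% stages && !is.null(config$f4)) {
    t0 <- as.numeric(Sys.time())
    freqs <- allele_frequencies(hm, popmap, populations)
    bs <- if (is.null(config$f4$block_size)) 500L else config$f4$block_size
    f4tab <- do.call(rbind, lapply(config$f4$quartets, function(q)
      f4_test(freqs, q[1], q[2], q[3], q[4], block_size = bs)))
    res$f4 <- f4tab
    emit("f4", "f4_tests.tsv", f4tab, tsv_writer, t0)
  }

  # ---- scan ---------------------------------------------------------------
  if ("scan" %in% stages) {
    t0 <- as.numeric(Sys.time())
    if (is.null(res$window_stats))
      stop("scan stage needs popstats results (enable the popstats stage)")
    sconf <- config$scan
    q <- if (is.null(sconf$quantile)) 0.99 else sconf$quantile
    reps <- if (is.null(sconf$reps)) 100000L else as.integer(sconf$reps)
    ws <- res$window_stats
    comp_groups <- vapply(config$comparisons, `[[`, "", "group")
    flags <- sapply(names(config$comparisons), function(nm)
      call_outliers(ws[[paste0("pbs_", nm)]], ws$class, quantile = q))
    res$outlier_flags <- flags
    out_tab <- cbind(ws[, c("scaffold", "start", "end", "class")],
                     as.data.frame(flags))
    rand <- list(); cats_by_class <- list()
    for (cl in intersect(c("autosome", "X"), unique(ws$class))) {
      sel <- ws$class == cl
      if (sum(sel) < 10L) next
      oc <- overlap_categories(flags[sel, , drop = FALSE], comp_groups)
      cats_by_class[[cl]] <- oc
      obs <- as.list(oc$counts[c("shared_two", "shared_three", "plus_native",
                                 "plus_introduced")])
      obs <- obs[vapply(names(obs), function(s)
        !(s %in% c("plus_native", "plus_introduced")) ||
          any(comp_groups == sub("plus_", "within_", s)), TRUE)]
      rand[[cl]] <- overlap_randomization(
        n_windows = sum(sel),
        outlier_counts = colSums(flags[sel, , drop = FALSE]),
        comparison_groups = comp_groups, observed = obs, reps = reps,
        seed = stage_seed(seed, paste0("scan_", cl)))
    }
    res$overlap <- cats_by_class
    res$randomization <- rand
    emit("scan", "outlier_windows.tsv", out_tab, function(o, p)
      write_window_table(o, p), t0)
    if (!is.null(out_dir))
      jsonlite::write_json(
        lapply(rand, unclass), file.path(out_dir, "randomization.json"),
        auto_unbox = TRUE, digits = NA)
    # ancestry composition at shared outliers vs background, per focal pop
    if (!is.null(res$topoweights)) {
      enr <- list()
      for (nm in names(config$comparisons)) {
        if (comp_groups[nm] != "between_range") next
        focal <- config$comparisons[[nm]]$triplet[1]
        tw <- res$topoweights[[focal]]
        if (is.null(tw)) next
        cls <- map_window_class(ws, tw)
        out_idx <- which(flags[, nm] & !is.na(cls))
        if (!length(out_idx)) next
        enr[[nm]] <- suppressWarnings(
          ancestry_enrichment(cls[out_idx], cls[!is.na(cls)]))
      }
      res$ancestry_enrichment <- enr
    }
  }

  manifest$n_stages <- length(manifest$stages)
  res$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  invisible(res)
}

# topology class of the snp-window overlapping each coordinate window's
# midpoint (NA where none)
map_window_class <- function(coord_tab, topo_tab) {
  cls <- rep(NA_character_, nrow(coord_tab))
  mid <- (coord_tab$start + coord_tab$end) / 2
  for (sc in unique(coord_tab$scaffold)) {
    ci <- which(coord_tab$scaffold == sc)
    ti <- which(topo_tab$scaffold == sc)
    if (!length(ti)) next
    hit <- findInterval(mid[ci], topo_tab$start[ti])
    ok <- hit >= 1 & hit <= length(ti)
    ok[ok] <- mid[ci][ok] < topo_tab$end[ti][hit[ok]]
    cls[ci[ok]] <- topo_tab$class[ti[hit[ok]]]
  }
  cls
}
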