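# End-to-end orchestration: configuration, the window-statistics scan,
# and the full scan -> segmentation -> inference chain.

#' Build and validate a run configuration
#'
#' Inputs may be file paths (VCF, sample TSV, scaffold-length TSV, BED of
#' named loci) or the corresponding in-memory objects. Validation collects
#' every problem before failing so a bad config reports all issues at
#' once.
#'
#' @param vcf Path to a VCF, or a `variant_matrix`.
#' @param samples Path to a sample TSV, or a sample-table data frame.
#' @param lengths Path to a scaffold-length TSV, or a data frame
#'   (`name`, `length`).
#' @param loci_bed Optional path to a BED of named loci (or a tibble), used
#'   by the exclusion permutation test.
#' @param width Window width bp (default 5000).
#' @param pct_hi,pct_lo Percentile thresholds (defaults 95 and 75).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param n_perm Permutations for the exclusion test (default 1000).
#' @param seed Integer seed for all resampling.
#' @param pairs Optional list of population pairs (default: all).
#' @param d_taxa Optional four-taxon ordering (p1, p2, p3) for
#'   Patterson's D (outgroup implied by sample roles).
#' @param min_mac LD minor-allele-count filter (default 2).
#' @param out_dir Optional output directory.
#' @return A validated `divscan_config` list.
#' @export
scan_config <- function(vcf, samples, lengths, loci_bed = NULL,
                        width = 5000, pct_hi = 95, pct_lo = 75,
                        n_boot = 10000, n_perm = 1000, seed = 1,
                        pairs = NULL, d_taxa = NULL, min_mac = 2,
                        out_dir = NULL) {
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(is_scalar_number(width) && width > 0, "width must be a positive number")
  chk(is_scalar_number(pct_hi) && pct_hi > 0 && pct_hi < 100,
      "pct_hi must be in (0, 100)")
  chk(is_scalar_number(pct_lo) && pct_lo > 0 && pct_lo < 100,
      "pct_lo must be in (0, 100)")
  chk(is_scalar_number(n_boot) && n_boot >= 1, "n_boot must be >= 1")
  chk(is_scalar_number(n_perm) && n_perm >= 1, "n_perm must be >= 1")
  chk(is_scalar_number(seed), "seed must be a number")
  for (nm in c("vcf", "samples", "lengths", "loci_bed")) {
    val <- get(nm)
    if (is.character(val)) chk(file.exists(val),
                               paste0(nm, " file does not exist: ", val))
  }
  if (length(problems) > 0) {
    fatal(paste0("invalid configuration:\n", paste0("- ", problems, collapse = "\n")),
          class = "divscan_config_error")
  }
  structure(list(vcf = vcf, samples = samples, lengths = lengths,
                 loci_bed = loci_bed, width = width, pct_hi = pct_hi,
                 pct_lo = pct_lo, n_boot = n_boot, n_perm = n_perm,
                 seed = seed, pairs = pairs, d_taxa = d_taxa,
                 min_mac = min_mac, out_dir = out_dir),
            class = "divscan_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fatal(paste0("stage '", name, "' failed: ", conditionMessage(e)),
          class = "divscan_stage_error")
  })
}

load_config_inputs <- function(config) {
  sample_table <- stage("load_samples",
    if (is.character(config$samples)) read_sample_table(config$samples)
    else validate_sample_table(config$samples))
  vm <- stage("load_variants",
    if (is.character(config$vcf)) load_variants(config$vcf, sample_table)
    else config$vcf)
  lengths <- stage("load_lengths",
    if (is.character(config$lengths)) read_scaffold_lengths(config$lengths)
    else tibble::as_tibble(config$lengths))
  loci <- if (is.null(config$loci_bed)) NULL
          else stage("load_loci_bed",
                     if (is.character(config$loci_bed)) read_bed(config$loci_bed)
                     else tibble::as_tibble(config$loci_bed))
  list(vm = vm, sample_table = sample_table, lengths = lengths, loci = loci)
}

#' Run the window-statistics scan
#'
#' Loads inputs, tiles windows, and computes the full per-window
#' statistics table. Deterministic given the inputs. With `out_dir` set,
#' writes `window_stats.tsv` and a `run_report.json` with the load report
#' and provenance.
#'
#' @param config A `divscan_config` from [scan_config()].
#' @return The window statistics tibble (invisible attributes: `vm`,
#'   `windows` accessible via the returned list when `full = TRUE` in
#'   [run_full()]).
#' @export
run_scan <- function(config) {
  inp <- load_config_inputs(config)
  windows <- stage("make_windows", make_windows(inp$lengths, width = config$width))
  stats <- stage("window_stats",
                 window_stats(inp$vm, windows, sample_table = inp$sample_table,
                              pairs = config$pairs, d_taxa = config$d_taxa,
                              min_mac = config$min_mac))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_window_stats(stats, file.path(config$out_dir, "window_stats.tsv"))
    write_run_report(config, inp$vm$report,
                     file.path(config$out_dir, "run_report.json"))
  }
  stats
}

write_run_report <- function(config, load_report, path, extra = list()) {
  cfg <- unclass(config)
  cfg$vcf <- if (is.character(cfg$vcf)) cfg$vcf else "<in-memory>"
  cfg$samples <- if (is.character(cfg$samples)) cfg$samples else "<in-memory>"
  cfg$lengths <- if (is.character(cfg$lengths)) cfg$lengths else "<in-memory>"
  cfg$loci_bed <- if (is.null(cfg$loci_bed)) NULL
                  else if (is.character(cfg$loci_bed)) cfg$loci_bed else "<in-memory>"
  report <- c(list(config = cfg, config_hash = rlang::hash(cfg),
                   load_report = load_report,
                   package_version = as.character(utils::packageVersion("divscan"))),
              extra)
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Run the full scan -> segmentation -> inference pipeline
#'
#' Chains the window scan, per-pair empirical thresholds and window
#' linking, the union of divergent regions across pairs, bootstrap
#' divergent-vs-background comparisons for every windowed statistic (with
#' BH adjustment), and, when a loci BED is configured, the permutation
#' test excluding those loci. With `out_dir` set, writes per-pair region
#' BEDs, the comparison TSV and a summary JSON.
#'
#' @param config A `divscan_config`.
#' @return A list of class `divscan_run`: `stats`, `thresholds` (per
#'   pair), `regions` (per pair), `union`, `comparisons` (tibble),
#'   `permutation`, `summary`.
#' @export
run_full <- function(config) {
  inp <- load_config_inputs(config)
  windows <- stage("make_windows", make_windows(inp$lengths, width = config$width))
  stats <- stage("window_stats",
                 window_stats(inp$vm, windows, sample_table = inp$sample_table,
                              pairs = config$pairs, d_taxa = config$d_taxa,
                              min_mac = config$min_mac))
  fst_cols <- grep("^fst_", names(stats), value = TRUE)
  thresholds <- list(); regions <- list()
  for (fc in fst_cols) {
    pair <- sub("^fst_", "", fc)
    th <- stage("thresholds",
                tryCatch(empirical_thresholds(stats[[fc]], config$pct_hi, config$pct_lo),
                         warning = function(w) {
                           suppressWarnings(empirical_thresholds(stats[[fc]],
                                                                 config$pct_hi,
                                                                 config$pct_lo))
                         }))
    thresholds[[pair]] <- th
    regions[[pair]] <- stage("link_windows", link_windows(stats, th, fst_col = fc))
  }
  un <- stage("region_union", region_union(regions, windows = windows))
  member <- windows$window_id %in% attr(un, "member_window_ids")

  stat_cols <- setdiff(names(stats),
                       c("window_id", "scaffold", "start", "end", "length",
                         "short", "n_snps", fst_cols,
                         grep("^n_snps_", names(stats), value = TRUE),
                         grep("^(abba|baba)_", names(stats), value = TRUE)))
  comparisons <- NULL
  if (any(member) && any(!member)) {
    comparisons <- purrr::map_dfr(stat_cols, function(sc) {
      x <- stats[[sc]]
      if (sc == "patterson_d") x <- abs(x)
      xin <- x[member]; xout <- x[!member]
      if (all(is.na(xin)) || all(is.na(xout))) return(NULL)
      bootstrap_compare(xin, xout, n_boot = config$n_boot,
                        seed = config$seed, statistic = sc)
    })
    if (!is.null(comparisons) && nrow(comparisons) > 0) {
      comparisons$p_adj <- adjust_pvalues(comparisons$p_raw)
    }
  }

  permutation <- NULL
  if (!is.null(inp$loci) && any(member) &&
      "patterson_d" %in% names(stats)) {
    stats_abs <- stats
    stats_abs$abs_patterson_d <- abs(stats$patterson_d)
    permutation <- tryCatch(
      permutation_excluding(stats_abs, member, exclude = inp$loci,
                            statistic = "abs_patterson_d",
                            n_perm = config$n_perm, seed = config$seed),
      error = function(e) list(error = conditionMessage(e)))
  }

  summary <- list(
    per_pair = lapply(regions, summarize_regions),
    union = list(count = nrow(un),
                 n_windows = attr(un, "n_windows_total"),
                 cumulative_bp = attr(un, "bp_total"),
                 genome_fraction = attr(un, "genome_fraction")),
    thresholds = lapply(thresholds, function(th)
      list(pct_hi = th$pct_hi, t_hi = th$t_hi,
           pct_lo = th$pct_lo, t_lo = th$t_lo))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_window_stats(stats, file.path(config$out_dir, "window_stats.tsv"))
    for (pair in names(regions)) {
      write_regions_bed(regions[[pair]],
                        file.path(config$out_dir, paste0("regions_", pair, ".bed")))
    }
    if (!is.null(comparisons)) {
      readr::write_tsv(comparisons, file.path(config$out_dir, "comparisons.tsv"))
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    write_run_report(config, inp$vm$report,
                     file.path(config$out_dir, "run_report.json"))
  }
  structure(list(stats = stats, thresholds = thresholds, regions = regions,
                 union = un, comparisons = comparisons,
                 permutation = permutation, summary = summary),
            class = "divscan_run")
}

#' @export
print.divscan_run <- function(x, ...) {
  cat("<divscan run>\n")
  for (pair in names(x$regions)) {
    s <- summarize_regions(x$regions[[pair]])
    cat(sprintf("  %s: %d region(s), %s bp (t_hi = %.3g, t_lo = %.3g)\n",
                pair, s$count, format(s$cumulative_bp, big.mark = ","),
                x$thresholds[[pair]]$t_hi, x$thresholds[[pair]]$t_lo))
  }
  cat(sprintf("  union: %d region(s), %s bp (%.1f%% of genome)\n",
              x$summary$union$count,
              format(x$summary$union$cumulative_bp, big.mark = ","),
              100 * x$summary$union$genome_fraction))
  invisible(x)
}
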