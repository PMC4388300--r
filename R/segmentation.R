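# Divergence-island segmentation: empirical percentile thresholds and the
# two-tier linking rule that joins runs of elevated-F_ST windows.

#' Empirical F_ST significance thresholds
#'
#' Percentile thresholds computed from the genome-wide distribution of
#' defined window F_ST values for one comparison (linear interpolation on
#' the sorted values). The realized values `t_hi` and `t_lo` are carried
#' in the result and recorded in output metadata downstream.
#'
#' @param fst Numeric vector of window F_ST values (NA allowed).
#' @param pct_hi High percentile defining highly divergent windows
#'   (default 95).
#' @param pct_lo Low percentile used by the linking rule (default 75).
#' @return A list of class `divscan_thresholds`: `pct_hi`, `pct_lo`,
#'   `t_hi`, `t_lo`, `n_defined`.
#' @export
empirical_thresholds <- function(fst, pct_hi = 95, pct_lo = 75) {
  stopifnot(pct_hi > 0, pct_hi < 100, pct_lo > 0, pct_lo < 100, pct_lo <= pct_hi)
  x <- fst[!is.na(fst)]
  if (length(x) == 0) {
    fatal("no defined F_ST values: cannot compute empirical thresholds",
          class = "divscan_data_error")
  }
  if (length(x) < 100) {
    warn(sprintf("only %d defined F_ST values; empirical percentiles will be noisy",
                 length(x)))
  }
  q <- stats::quantile(x, probs = c(pct_hi, pct_lo) / 100, names = FALSE, type = 7)
  structure(list(pct_hi = pct_hi, pct_lo = pct_lo,
                 t_hi = q[1], t_lo = q[2], n_defined = length(x)),
            class = "divscan_thresholds")
}

#' @export
print.divscan_thresholds <- function(x, ...) {
  cat(sprintf("<thresholds> %gth pct: F_ST >= %.4g | %gth pct: F_ST >= %.4g (from %d windows)\n",
              x$pct_hi, x$t_hi, x$pct_lo, x$t_lo, x$n_defined))
  invisible(x)
}

#' Link elevated-F_ST windows into divergent regions
#'
#' Windows with F_ST at or above `t_hi` are highly divergent. For each
#' pair of consecutive (though not necessarily adjacent) highly divergent
#' windows on the same scaffold, all enclosed windows are classified
#' divergent if and only if none of their F_ST values falls below `t_lo`;
#' windows with undefined F_ST never link (they count as below `t_lo`).
#' Divergent regions are maximal runs of consecutive divergent windows.
#'
#' @param stats A window tibble with columns `window_id`, `scaffold`,
#'   `start`, `end`, `length` and the F_ST column named by `fst_col`.
#' @param thresholds A `divscan_thresholds` object (or a list with `t_hi`,
#'   `t_lo`).
#' @param fst_col Name of the F_ST column (default `"fst"`).
#' @return A tibble of regions: `region_id`, `scaffold`, `start`, `end`,
#'   `n_windows`, `size_bp`, `mean_fst`, `window_ids` (list column), with
#'   attribute `"divergent"` (logical per input window) and
#'   `"thresholds"`.
#' @export
link_windows <- function(stats, thresholds, fst_col = "fst") {
  stats <- dplyr::arrange(tibble::as_tibble(stats), .data$scaffold, .data$start)
  fst <- stats[[fst_col]]
  if (is.null(fst)) fatal(paste0("no column '", fst_col, "' in stats"),
                          class = "divscan_config_error")
  divergent <- classify_divergent(stats$scaffold, fst, thresholds$t_hi, thresholds$t_lo)
  regions <- runs_to_regions(stats, divergent, fst)
  attr(regions, "divergent") <- divergent
  attr(regions, "thresholds") <- thresholds
  regions
}

# the linking rule on parallel vectors; returns logical "divergent" flags
classify_divergent <- function(scaffold, fst, t_hi, t_lo) {
  hi <- !is.na(fst) & fst >= t_hi
  ge_lo <- !is.na(fst) & fst >= t_lo
  divergent <- hi
  hi_idx <- which(hi)
  if (length(hi_idx) >= 2) {
    for (k in seq_len(length(hi_idx) - 1)) {
      i <- hi_idx[k]; j <- hi_idx[k + 1]
      if (scaffold[i] != scaffold[j] || j == i + 1) next
      between <- (i + 1):(j - 1)
      if (all(ge_lo[between])) divergent[between] <- TRUE
    }
  }
  divergent
}

# collapse maximal runs of divergent windows (per scaffold) into regions
runs_to_regions <- function(stats, divergent, fst) {
  if (!any(divergent)) {
    return(tibble::tibble(region_id = integer(), scaffold = character(),
                          start = integer(), end = integer(),
                          n_windows = integer(), size_bp = integer(),
                          mean_fst = numeric(), window_ids = list()))
  }
  new_run <- divergent & (!dplyr::lag(divergent, default = FALSE) |
                            stats$scaffold != dplyr::lag(stats$scaffold,
                                                         default = "\x01"))
  run_id <- cumsum(new_run)
  run_id[!divergent] <- NA
  idx <- which(divergent)
  grp <- run_id[idx]
  tibble::tibble(
    region_id = as.integer(sort(unique(grp))),
    scaffold = as.character(tapply(stats$scaffold[idx], grp, function(s) s[1])),
    start = as.integer(tapply(stats$start[idx], grp, min)),
    end = as.integer(tapply(stats$end[idx], grp, max)),
    n_windows = as.integer(tapply(idx, grp, length)),
    size_bp = as.integer(tapply(stats$length[idx], grp, sum)),
    mean_fst = as.numeric(tapply(fst[idx], grp, mean)),
    window_ids = unname(tapply(stats$window_id[idx], grp, function(w) as.integer(w),
                               simplify = FALSE))
  )
}

#' Summarize a set of divergent regions
#'
#' @param regions A region tibble from [link_windows()].
#' @return A list: `count`, `cumulative_bp`, `mean_bp` (0s when empty).
#' @export
summarize_regions <- function(regions) {
  n <- nrow(regions)
  cum <- if (n > 0) sum(regions$size_bp) else 0
  list(count = n, cumulative_bp = cum, mean_bp = if (n > 0) cum / n else 0)
}

#' Union of divergent-region sets at window resolution
#'
#' Takes the union by window membership across any number of region sets
#' built on the same window index; overlapping or adjacent member windows
#' merge into maximal runs.
#'
#' @param ... Region tibbles from [link_windows()] (or a single list of
#'   them).
#' @param windows The shared window tibble underlying all sets.
#' @return A region tibble (same shape as [link_windows()] output, without
#'   `mean_fst`), with attributes `n_windows_total`, `bp_total`,
#'   `genome_fraction`.
#' @export
region_union <- function(..., windows) {
  sets <- list(...)
  if (length(sets) == 1 && !is.data.frame(sets[[1]])) sets <- sets[[1]]
  member <- rep(FALSE, nrow(windows))
  for (rg in sets) {
    ids <- unlist(rg$window_ids)
    bad <- setdiff(ids, windows$window_id)
    if (length(bad) > 0) {
      fatal("region set refers to window ids absent from the window index",
            class = "divscan_data_error")
    }
    member[match(ids, windows$window_id)] <- TRUE
  }
  stats <- dplyr::arrange(windows, .data$scaffold, .data$start)
  member <- member[match(stats$window_id, windows$window_id)]
  out <- runs_to_regions(stats, member, rep(NA_real_, nrow(stats)))
  out$mean_fst <- NULL
  attr(out, "member_window_ids") <- stats$window_id[member]
  attr(out, "n_windows_total") <- sum(member)
  attr(out, "bp_total") <- sum(stats$length[member])
  attr(out, "genome_fraction") <- sum(stats$length[member]) / sum(stats$length)
  out
}

#' Base-pair overlap between two region sets
#'
#' Computed at window resolution on a shared window index. Conservation
#' holds exactly: `|A| + |B| = 2 |A and B| + |A xor B|`.
#'
#' @param set_a,set_b Region tibbles from [link_windows()].
#' @param windows The shared window tibble.
#' @return A list: `shared_bp`, `only_a_bp`, `only_b_bp`.
#' @export
region_overlap <- function(set_a, set_b, windows) {
  mem <- function(rg) windows$window_id %in% unlist(rg$window_ids)
  a <- mem(set_a); b <- mem(set_b)
  L <- windows$length
  list(shared_bp = sum(L[a & b]),
       only_a_bp = sum(L[a & !b]),
       only_b_bp = sum(L[b & !a]))
}
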