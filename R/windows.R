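#' Tile scaffolds into fixed-width genome windows
#'
#' Each scaffold is divided into consecutive, non-overlapping windows of
#' `width` bp (default 5 kbp). The final window of a scaffold may be
#' shorter and is flagged `short`; statistics computed on it use its
#' actual length as denominator. Coordinates are 0-based half-open.
#'
#' @param scaffold_lengths A data frame with columns `name` and `length`
#'   (see [read_scaffold_lengths()]).
#' @param width Window width in bp (default 5000).
#' @return A tibble with columns `window_id`, `scaffold`, `start`, `end`,
#'   `length`, `short`, ordered by (scaffold, start).
#' @export
#' @examples
#' make_windows(data.frame(name = "scf1", length = 12345), width = 5000)
make_windows <- function(scaffold_lengths, width = 5000) {
  if (!is_scalar_number(width) || width <= 0) {
    fatal("window width must be a positive number", class = "divscan_config_error")
  }
  sl <- tibble::as_tibble(scaffold_lengths)
  if (any(sl$length <= 0)) fatal("scaffold lengths must be positive",
                                 class = "divscan_config_error")
  sl <- dplyr::arrange(sl, .data$name)
  win <- purrr::map2_dfr(sl$name, sl$length, function(nm, L) {
    starts <- seq(0L, L - 1L, by = width)
    tibble::tibble(scaffold = nm, start = as.integer(starts),
                   end = as.integer(pmin(starts + width, L)))
  })
  win |>
    dplyr::mutate(window_id = dplyr::row_number(),
                  length = .data$end - .data$start,
                  short = .data$length < width) |>
    dplyr::select("window_id", "scaffold", "start", "end", "length", "short")
}

#' Assign variant sites to genome windows
#'
#' Maps each 1-based VCF position to the 0-based half-open window that
#' contains it: position p belongs to the window with start <= p - 1 < end.
#'
#' @param vm A `variant_matrix` (see [load_variants()]).
#' @param windows A window tibble from [make_windows()].
#' @return An integer vector of window ids, one per site in `vm`.
#' @export
assign_sites <- function(vm, windows) {
  sites <- vm$sites
  missing_scafs <- setdiff(unique(sites$scaffold), unique(windows$scaffold))
  if (length(missing_scafs) > 0) {
    fatal(paste0("scaffold(s) absent from window index: ",
                 paste(missing_scafs, collapse = ", ")),
          class = "divscan_data_error")
  }
  out <- integer(nrow(sites))
  for (scaf in unique(sites$scaffold)) {
    w <- windows[windows$scaffold == scaf, ]
    idx <- which(sites$scaffold == scaf)
    pos0 <- sites$position[idx] - 1L  # to 0-based
    too_far <- pos0 >= max(w$end) | pos0 < 0
    if (any(too_far)) {
      fatal(sprintf("site at %s:%d lies beyond scaffold length %d",
                    scaf, sites$position[idx[which(too_far)[1]]], max(w$end)),
            class = "divscan_data_error")
    }
    # windows tile the scaffold contiguously, so interval lookup is a
    # findInterval on the sorted start coordinates
    k <- findInterval(pos0, w$start)
    out[idx] <- w$window_id[k]
  }
  out
}
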