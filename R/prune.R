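#' LD-pruning parameters
#'
#' Windowed pairwise pruning in the style of PLINK's `--indep-pairwise`.
#'
#' @param window_size Window width in markers (>= 2).
#' @param step Window slide in markers (1 <= step <= window_size).
#' @param r2_threshold Squared genotype correlation above which one marker of
#'   a pair is removed.
#' @return A list of class `prune_params`.
#' @export
prune_params <- function(window_size = 50L, step = 5L, r2_threshold = 0.5) {
  stopifnot(window_size >= 2, step >= 1, step <= window_size,
            r2_threshold > 0, r2_threshold <= 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step), r2_threshold = r2_threshold),
            class = "prune_params")
}

#' Greedy windowed LD pruning
#'
#' Within each window of `window_size` currently retained markers, while any
#' retained pair has squared genotype correlation above the threshold, the
#' lower-MAF marker of the pair is removed (ties remove the later marker);
#' the window then slides by `step`. Markers are processed per chromosome in
#' map order. Monomorphic markers have undefined correlation and are never
#' removed on account of it.
#'
#' @param gt A [genotype_table()].
#' @param map A [marker_map()] giving chromosome and order for `gt`'s
#'   markers.
#' @param params A [prune_params()].
#' @return Character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(gt, map, params = prune_params()) {
  idx <- match(gt$marker_ids, map$marker_id)
  if (anyNA(idx)) stop("genotype table contains markers absent from map")
  mp <- map[idx, , drop = FALSE]
  retained_all <- character(0)
  for (ch in unique(mp$chrom)) {
    sel <- which(mp$chrom == ch)
    calls <- gt$calls[sel, , drop = FALSE]
    ids <- gt$marker_ids[sel]
    keep <- prune_chromosome(calls, params)
    retained_all <- c(retained_all, ids[keep])
  }
  retained_all
}

prune_chromosome <- function(calls, params) {
  n <- nrow(calls)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  maf <- apply(calls, 1, function(g) {
    f <- mean(g, na.rm = TRUE) / 2
    if (is.nan(f)) 0 else min(f, 1 - f)
  })
  starts <- seq(1L, n, by = params$step)
  for (s in starts) {
    e <- min(s + params$window_size - 1L, n)
    win <- s:e
    repeat {
      live <- win[keep[win]]
      if (length(live) < 2) break
      removed <- FALSE
      for (ai in seq_len(length(live) - 1)) {
        for (bi in seq((ai + 1), length(live))) {
          a <- live[ai]; b <- live[bi]
          r <- suppressWarnings(stats::cor(calls[a, ], calls[b, ],
                                           use = "pairwise.complete.obs"))
          if (is.na(r)) next  # monomorphic or no overlap
          if (r * r > params$r2_threshold) {
            drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else b
            keep[drop] <- FALSE
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!removed) break
    }
    if (e == n) break
  }
  keep
}
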