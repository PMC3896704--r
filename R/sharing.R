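#' Multipoint all-affected IBD sharing
#'
#' Computes, at every marker, the posterior probability that all affected
#' family members carry at least one founder allele identical by descent,
#' using a Lander-Green hidden Markov model over inheritance vectors. The
#' hidden state has one bit per meiosis; between adjacent markers each bit
#' flips independently with the Haldane recombination fraction for the map
#' gap. Emissions sum founder-allele assignments weighted by the marker's
#' panel allele frequency. Forward-backward posteriors are normalized per
#' marker.
#'
#' Markers on the X chromosome use an X-specific inheritance-vector space
#' (maternal meioses only; males hemizygous with genotypes coded 0/2).
#' A marker at which every genotype is missing yields the prior sharing.
#'
#' @param ped A valid [pedigree()] with at least one genotyped affected
#'   member.
#' @param gt A [genotype_table()]; samples not in the pedigree are ignored,
#'   pedigree members absent from the table are treated as untyped.
#' @param map A [marker_map()] covering `gt`'s markers (LD-pruned, ordered).
#' @param max_meioses Capacity cap on inheritance-vector bits (memory grows
#'   as 2^m).
#' @param error_rate Optional per-genotype error rate mixed into emissions
#'   (0 disables; small values add robustness to genotyping error).
#' @return A data frame of class `sharing_profile` with columns `family_id`,
#'   `chrom`, `marker_id`, `position_bp`, `sharing`.
#' @export
compute_sharing <- function(ped, gt, map, max_meioses = 16L, error_rate = 0) {
  if (!is_valid_pedigree(ped))
    stop("pedigree is not structurally valid")
  aff <- affected_ids(ped)
  typed <- intersect(intersect(gt$sample_ids, ped$members$person_id),
                     ped$members$person_id[ped$members$genotyped])
  if (!length(intersect(aff, typed)))
    stop("at least one affected member must be genotyped")
  idx <- match(gt$marker_ids, map$marker_id)
  if (anyNA(idx)) stop("genotype table contains markers absent from map")
  mp <- map[idx, , drop = FALSE]

  out <- list()
  for (ch in unique(mp$chrom)) {
    sel <- which(mp$chrom == ch)
    sub_map <- mp[sel, , drop = FALSE]
    chrom_type <- if (is_x_chrom(ch)) "x" else "autosome"
    desc <- build_descent(ped, chrom_type, max_meioses = max_meioses)
    share <- sharing_indicator(desc, aff)

    use <- intersect(desc$members, typed)
    geno <- t(gt$calls[sel, use, drop = FALSE])  # n x M
    if (chrom_type == "x") {
      sex <- stats::setNames(ped$members$sex, ped$members$person_id)[use]
      badhet <- sweep(geno == 1L, 1, sex == "male", `&`)
      if (any(badhet, na.rm = TRUE)) geno[which(badhet)] <- NA_integer_
    }
    geno[is.na(geno)] <- -1L
    storage.mode(geno) <- "integer"

    d <- diff(sub_map$position_cM) / 100
    theta <- haldane_theta(d)

    if (desc$n_meioses == 0L) {
      sh <- rep(as.numeric(share[1]), nrow(sub_map))
    } else {
      A1 <- desc$A1[, use, drop = FALSE]
      A2 <- desc$A2[, use, drop = FALSE]
      sh <- .lander_green_fb(A1, A2, geno, sub_map$panel_af,
                             as.numeric(theta), share,
                             desc$n_slots, error_rate,
                             as.integer(desc$founder_masks))
    }
    out[[ch]] <- data.frame(family_id = ped$family_id, chrom = ch,
                            marker_id = sub_map$marker_id,
                            position_bp = sub_map$position_bp,
                            sharing = as.numeric(sh),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sharing_profile", "data.frame")
  res
}

#' Segment-calling parameters
#'
#' @param window_markers Sliding-window width in markers.
#' @param sharing_threshold Sharing must strictly exceed this value at every
#'   marker of a qualifying window (ties at the threshold do not qualify).
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(window_markers = 10L, sharing_threshold = 0.5) {
  stopifnot(window_markers >= 1, sharing_threshold >= 0, sharing_threshold < 1)
  structure(list(window_markers = as.integer(window_markers),
                 sharing_threshold = sharing_threshold),
            class = "segment_params")
}

#' Call IBD segments from a sharing profile
#'
#' A marker is IBD-flagged iff it lies in some window of
#' `window_markers` consecutive markers whose sharing strictly exceeds the
#' threshold at every marker. Maximal runs of flagged markers become
#' segments whose endpoints are the first and last flagged markers'
#' physical positions (1-based inclusive). Chromosomes with fewer markers
#' than the window width require all their markers to exceed the threshold.
#'
#' @param profile A `sharing_profile` from [compute_sharing()].
#' @param params A [segment_params()].
#' @return Data frame of segments: `family_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_markers`, `mean_sharing`; non-overlapping and sorted
#'   within chromosome.
#' @export
call_segments <- function(profile, params = segment_params()) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    flag <- flag_ibd_markers(p$sharing, params$window_markers,
                             params$sharing_threshold)
    if (!any(flag)) next
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      out[[length(out) + 1]] <- data.frame(
        family_id = p$family_id[1], chrom = ch,
        start_bp = p$position_bp[i], end_bp = p$position_bp[j],
        n_markers = j - i + 1L,
        mean_sharing = mean(p$sharing[i:j]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_markers = integer(0), mean_sharing = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(chrom_order(res$chrom), res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

flag_ibd_markers <- function(sharing, window, threshold) {
  n <- length(sharing)
  above <- sharing > threshold
  if (n < window) return(rep(all(above), n))
  # window starting at s qualifies iff all of above[s..s+window-1]
  cs <- cumsum(c(0, above))
  qual <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) == window
  flag <- rep(FALSE, n)
  for (s in which(qual)) flag[s:(s + window - 1L)] <- TRUE
  flag
}

#' Genome-wide IBD segments for one family
#'
#' Composes LD pruning, multipoint sharing and segment calling per
#' chromosome. Autosomes are always analyzed; the X chromosome only when
#' the pedigree is compatible with X-linked inheritance.
#'
#' @param ped A valid [pedigree()].
#' @param gt Array [genotype_table()] (genotyped members).
#' @param map A [marker_map()].
#' @param prune A [prune_params()].
#' @param seg A [segment_params()].
#' @param max_meioses,error_rate Passed to [compute_sharing()].
#' @param prune_gt Optional reference-cohort [genotype_table()] on which LD
#'   is measured for pruning (the study design prunes against a reference
#'   panel); defaults to the family genotypes themselves.
#' @return List with `segments` (data frame) and `profile`
#'   (`sharing_profile` over retained markers).
#' @export
segments_genomewide <- function(ped, gt, map, prune = prune_params(),
                                seg = segment_params(), max_meioses = 16L,
                                error_rate = 0.01, prune_gt = NULL) {
  if (!length(gt$marker_ids))
    return(list(segments = call_segments(
      structure(data.frame(family_id = character(0), chrom = character(0),
                           marker_id = character(0), position_bp = integer(0),
                           sharing = numeric(0)),
                class = c("sharing_profile", "data.frame")), seg),
      profile = NULL))
  use_x <- length(affected_ids(ped)) >= 2 && xlinked_compatible(ped)
  idx <- match(gt$marker_ids, map$marker_id)
  mp <- map[idx, , drop = FALSE]
  keep_chrom <- !is_x_chrom(mp$chrom) | use_x
  gt2 <- subset_genotypes(gt, markers = gt$marker_ids[keep_chrom])

  prune_source <- if (is.null(prune_gt)) gt2 else
    subset_genotypes(prune_gt,
                     markers = intersect(prune_gt$marker_ids, gt2$marker_ids))
  retained <- ld_prune(prune_source, map, prune)
  gt3 <- subset_genotypes(gt2, markers = intersect(gt2$marker_ids, retained))

  # wipe genotypes implicated in Mendelian inconsistencies (single-call
  # genotyping errors would otherwise zero the sharing posterior locally
  # and split segments)
  viol <- mendelian_check(ped, gt3)
  if (nrow(viol)) {
    mi <- match(viol$marker_id, gt3$marker_ids)
    gt3$calls[cbind(mi, match(viol$child_id, gt3$sample_ids))] <- NA_integer_
    pj <- match(viol$parent_id, gt3$sample_ids)
    ok <- !is.na(pj)
    gt3$calls[cbind(mi[ok], pj[ok])] <- NA_integer_
  }
  profile <- compute_sharing(ped, gt3, map, max_meioses = max_meioses,
                             error_rate = error_rate)
  list(segments = call_segments(profile, seg), profile = profile)
}
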