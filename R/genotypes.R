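#' Construct a genotype table
#'
#' Unphased biallelic genotypes coded as alternate-allele counts
#' (0, 1, 2, `NA`), markers in rows and samples in columns. Male X-chromosome
#' calls use the diploid hemizygous convention (0 or 2). Tables produced by
#' the gene-dropping simulator additionally carry phased founder-allele
#' information in `phase` (paternal/maternal allele matrices) and `descent`
#' (founder allele slot labels), used for truth bookkeeping.
#'
#' @param marker_ids Character vector of marker ids (row order).
#' @param sample_ids Character vector of sample ids (column order).
#' @param calls Integer matrix `length(marker_ids)` x `length(sample_ids)`.
#' @param phase Optional list with matrices `pat` and `mat` of 0/1 alleles.
#' @param descent Optional list with integer matrices `pat` and `mat` of
#'   founder allele slot indices.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(marker_ids, sample_ids, calls,
                           phase = NULL, descent = NULL) {
  calls <- as.matrix(calls)
  if (nrow(calls) != length(marker_ids) || ncol(calls) != length(sample_ids))
    stop("calls must be length(marker_ids) x length(sample_ids)")
  storage.mode(calls) <- "integer"
  ok <- is.na(calls) | calls %in% 0:2
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(marker_ids, sample_ids)
  structure(list(marker_ids = as.character(marker_ids),
                 sample_ids = as.character(sample_ids),
                 calls = calls, phase = phase, descent = descent),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d markers x %d samples%s\n",
              length(x$marker_ids), length(x$sample_ids),
              if (!is.null(x$phase)) " (phased)" else ""))
  invisible(x)
}

#' Subset a genotype table
#'
#' @param gt A [genotype_table()].
#' @param markers,samples Character vectors (or indices) to keep; `NULL`
#'   keeps all.
#' @return A [genotype_table()].
#' @export
subset_genotypes <- function(gt, markers = NULL, samples = NULL) {
  mi <- if (is.null(markers)) seq_along(gt$marker_ids) else
    match(markers, gt$marker_ids)
  si <- if (is.null(samples)) seq_along(gt$sample_ids) else
    match(samples, gt$sample_ids)
  if (anyNA(mi)) stop("unknown marker ids")
  if (anyNA(si)) stop("unknown sample ids")
  ph <- if (!is.null(gt$phase))
    list(pat = gt$phase$pat[mi, si, drop = FALSE],
         mat = gt$phase$mat[mi, si, drop = FALSE])
  de <- if (!is.null(gt$descent))
    list(pat = gt$descent$pat[mi, si, drop = FALSE],
         mat = gt$descent$mat[mi, si, drop = FALSE])
  genotype_table(gt$marker_ids[mi], gt$sample_ids[si],
                 gt$calls[mi, si, drop = FALSE], phase = ph, descent = de)
}

#' Construct a marker map
#'
#' @param df Data frame with columns `marker_id`, `chrom`, `position_bp`,
#'   `position_cM`, `ref_allele`, `alt_allele`, `panel_af`. Positions must be
#'   strictly increasing (in both bp and cM) within each chromosome.
#' @return The validated data frame with class `marker_map`.
#' @export
marker_map <- function(df) {
  req <- c("marker_id", "chrom", "position_bp", "position_cM",
           "ref_allele", "alt_allele", "panel_af")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("map is missing columns: ", paste(miss, collapse = ", "))
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$position_bp, strictly = TRUE) ||
        is.unsorted(sub$position_cM, strictly = TRUE))
      stop("markers on chromosome ", ch,
           " must be strictly increasing in bp and cM")
  }
  if (any(df$panel_af < 0 | df$panel_af > 1))
    stop("panel_af must lie in [0, 1]")
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

is_x_chrom <- function(chrom) toupper(sub("^chr", "", chrom)) == "X"

#' Haldane map function
#'
#' Converts genetic distance to a recombination fraction assuming no
#' interference: theta = (1 - exp(-2 d)) / 2 with `d` in Morgans.
#'
#' @param d_morgans Numeric vector of distances in Morgans.
#' @return Recombination fractions in `[0, 0.5)`.
#' @export
haldane_theta <- function(d_morgans) (1 - exp(-2 * d_morgans)) / 2
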