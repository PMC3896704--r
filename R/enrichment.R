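#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` genes without replacement from a universe of
#' `N` genes of which `K` are candidates; the observed count is included in
#' the tail. Terms are computed in log space (`lchoose`) and combined with a
#' log-sum-exp for numerical stability.
#'
#' @param k Observed overlap.
#' @param K Candidate genes in the universe.
#' @param n Genes drawn (genes with surviving variants).
#' @param N Universe size.
#' @return Probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K < 0 || n < 0 || K > N || n > N)
    stop("require 0 <= K, n <= N")
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (k < lo || k > hi)
    stop("k must lie in [max(0, n+K-N), min(K, n)]")
  j <- k:hi
  lt <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(lt)
  p <- exp(mx + log(sum(exp(lt - mx))))
  min(p, 1)
}

#' Candidate-gene enrichment among genes with surviving variants
#'
#' Counts how many genes with surviving variants fall in a candidate list,
#' relative to the gene universe captured by the exome design, and tests the
#' overlap with an upper-tail hypergeometric probability. Symbols are
#' compared case-insensitively after whitespace stripping; candidates are
#' intersected with the universe before counting.
#'
#' @param hit_genes Genes with surviving variants (must lie in the universe).
#' @param candidate_genes Candidate gene list.
#' @param universe All genes captured.
#' @return A list of class `enrichment_result` with fields `universe_n` (N),
#'   `candidate_k` (K), `hit_n` (n), `overlap` (k), `fold`
#'   ((k/K)/(n/N)), and `p_value`.
#' @export
enrichment <- function(hit_genes, candidate_genes, universe) {
  universe <- unique(normalize_symbols(universe))
  if (!length(universe)) stop("universe is empty")
  hit_genes <- unique(normalize_symbols(hit_genes))
  candidate_genes <- unique(normalize_symbols(candidate_genes))
  extra <- setdiff(hit_genes, universe)
  if (length(extra))
    stop("hit genes absent from universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  cand <- intersect(candidate_genes, universe)
  if (!length(cand))
    stop("no candidate genes overlap the universe (K = 0)")
  N <- length(universe)
  K <- length(cand)
  n <- length(hit_genes)
  k <- length(intersect(hit_genes, cand))
  fold <- if (n == 0) NA_real_ else (k / K) / (n / N)
  structure(list(universe_n = N, candidate_k = K, hit_n = n, overlap = k,
                 fold = fold, p_value = hypergeometric_tail(k, K, n, N)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d/%d candidate genes hit vs %d/%d overall (fold %.3f, P = %.3g)\n",
    x$overlap, x$candidate_k, x$hit_n, x$universe_n, x$fold, x$p_value))
  invisible(x)
}

#' Permutation null for the enrichment test
#'
#' Draws random hit-gene sets of the observed size uniformly from the
#' universe and reports the empirical upper-tail probability
#' `(1 + #{overlap >= observed}) / (n_perm + 1)`. Serves as a
#' model-validation check on the hypergeometric tail.
#'
#' @param hit_genes Observed hit genes.
#' @param candidate_genes Candidate list.
#' @param universe Gene universe.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Empirical p-value.
#' @export
permutation_null <- function(hit_genes, candidate_genes, universe,
                             n_perm = 10000L, seed = NULL) {
  stopifnot(n_perm >= 1)
  universe <- unique(normalize_symbols(universe))
  hit_genes <- unique(normalize_symbols(hit_genes))
  cand <- intersect(unique(normalize_symbols(candidate_genes)), universe)
  n <- length(hit_genes)
  obs <- length(intersect(hit_genes, cand))
  in_cand <- universe %in% cand
  with_seed(seed, {
    hits <- vapply(seq_len(n_perm), function(i)
      sum(in_cand[sample.int(length(universe), n)]), integer(1))
    (1 + sum(hits >= obs)) / (n_perm + 1)
  })
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Cross-platform genotype concordance
#'
#' Compares genotype calls between two platforms (e.g. exome sequencing and
#' array genotyping) over shared samples and shared sites matched by
#' chromosome, position and alleles after strand/allele harmonization:
#' swapped ref/alt flips the genotype (g -> 2 - g), strand-complemented
#' alleles are matched through their complements, and sites that cannot be
#' harmonized are excluded. The denominator counts only sites called on both
#' platforms.
#'
#' @param a,b Lists with elements `calls` (matrix sites x samples, column
#'   names sample ids) and `sites` (data frame `chrom`, `pos`, `ref`, `alt`
#'   aligned to rows). A [genotype_table()] plus a site frame also works via
#'   [gt_with_sites()].
#' @return A list of class `concordance_report`: `per_sample` (data frame
#'   `sample`, `n_compared`, `concordance`), `overall_mean`,
#'   `n_sites_compared`.
#' @export
genotype_concordance <- function(a, b) {
  samples <- intersect(colnames(a$calls), colnames(b$calls))
  if (!length(samples)) stop("no shared samples")
  key_a <- paste(a$sites$chrom, a$sites$pos)
  key_b <- paste(b$sites$chrom, b$sites$pos)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  ra <- a$sites$ref[ia]; aa <- a$sites$alt[ia]
  rb <- b$sites$ref[ib]; ab <- b$sites$alt[ib]
  direct <- (ra == rb & aa == ab) | (ra == comp_base(rb) & aa == comp_base(ab))
  swapped <- (ra == ab & aa == rb) | (ra == comp_base(ab) & aa == comp_base(rb))
  usable <- direct | swapped
  if (!any(usable)) stop("no shared harmonizable sites")
  ia <- ia[usable]; ib <- ib[usable]
  flip <- swapped[usable] & !direct[usable]

  ga <- a$calls[ia, samples, drop = FALSE]
  gb <- b$calls[ib, samples, drop = FALSE]
  gb[flip, ] <- 2L - gb[flip, , drop = FALSE]

  per <- lapply(samples, function(s) {
    ok <- !is.na(ga[, s]) & !is.na(gb[, s])
    data.frame(sample = s, n_compared = sum(ok),
               concordance = if (any(ok)) mean(ga[ok, s] == gb[ok, s])
               else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(per_sample = per,
                 overall_mean = mean(per$concordance, na.rm = TRUE),
                 n_sites_compared = length(ia)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: mean %.4f over %d samples (%d shared sites)\n",
              x$overall_mean, nrow(x$per_sample), x$n_sites_compared))
  invisible(x)
}

#' Pair a genotype table with site metadata for concordance
#'
#' @param gt A [genotype_table()].
#' @param map A [marker_map()] covering its markers.
#' @return A list with `calls` and `sites` as consumed by
#'   [genotype_concordance()].
#' @export
gt_with_sites <- function(gt, map) {
  idx <- match(gt$marker_ids, map$marker_id)
  if (anyNA(idx)) stop("markers absent from map")
  list(calls = gt$calls,
       sites = data.frame(chrom = map$chrom[idx], pos = map$position_bp[idx],
                          ref = map$ref_allele[idx], alt = map$alt_allele[idx],
                          stringsAsFactors = FALSE))
}

#' Per-sample call-rate QC
#'
#' A sample passes iff its fraction of non-missing calls is at least
#' `min_rate` (inclusive threshold).
#'
#' @param gt A [genotype_table()].
#' @param min_rate Minimum call rate, default 0.98.
#' @return Data frame `sample`, `call_rate`, `pass`.
#' @export
call_rate_qc <- function(gt, min_rate = 0.98) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  cr <- colMeans(!is.na(gt$calls))
  data.frame(sample = gt$sample_ids, call_rate = unname(cr),
             pass = unname(cr >= min_rate), stringsAsFactors = FALSE)
}
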