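#' Pipeline run configuration
#'
#' Bundles the stage parameters, the data source (a simulation configuration
#' or paths to PED/MAP/VCF inputs), the candidate gene list, the output
#' directory, and the root seed. All randomness in a run flows from the root
#' seed through deterministically derived per-stage seeds.
#'
#' @param out_dir Output directory (created if missing).
#' @param sim A [sim_config()] to generate the inputs, or `NULL` when
#'   reading from files.
#' @param ped_path,map_path,marker_info_path,vcf_paths Input paths used when
#'   `sim` is `NULL`: a (possibly multi-family) PED file, the MAP/marker-info
#'   sidecar, and one VCF per family (named by family id).
#' @param candidate_genes Character vector of candidate gene symbols, or a
#'   path to a one-symbol-per-line file, or `NULL` to skip enrichment.
#' @param prune A [prune_params()].
#' @param seg A [segment_params()].
#' @param filter A [filter_config()].
#' @param max_meioses Inheritance-vector capacity cap.
#' @param seed Root seed (recorded in the manifest).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), ped_path = NULL,
                       map_path = NULL, marker_info_path = NULL,
                       vcf_paths = NULL, candidate_genes = NULL,
                       prune = prune_params(), seg = segment_params(),
                       filter = filter_config(), max_meioses = 16L,
                       seed = 1L) {
  if (is.null(sim)) {
    for (p in c(ped_path, marker_info_path, unlist(vcf_paths)))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(out_dir = out_dir, sim = sim, ped_path = ped_path,
                 map_path = map_path, marker_info_path = marker_info_path,
                 vcf_paths = vcf_paths, candidate_genes = candidate_genes,
                 prune = prune, seg = seg, filter = filter,
                 max_meioses = max_meioses, seed = seed),
            class = "run_config")
}

load_study_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    return(simulate_study(sim))
  }
  map <- read_marker_info(config$marker_info_path)
  fam_lines <- readLines(config$ped_path)
  fam_ids <- unique(vapply(strsplit(fam_lines, "[ \t]+"), `[`, character(1), 1))
  fams <- list()
  for (fid in fam_ids) {
    pd <- read_ped(config$ped_path, map = map, family_id = fid)
    vcf <- config$vcf_paths[[fid]]
    if (is.null(vcf)) stop("no VCF path for family ", fid)
    fams[[fid]] <- list(ped = pd$pedigree, array_gt = pd$genotypes,
                        exome = read_vcf(vcf),
                        truth = data.frame())
  }
  list(map = map, families = fams, config = NULL)
}

#' Run the full study-shaped workflow
#'
#' Per family: LD pruning, multipoint all-affected IBD sharing, segment
#' calling, and the variant filter cascade; then cross-family gene
#' summaries, candidate-gene enrichment (when a candidate list is given),
#' and call-rate QC. Writes segments (BED + TSV), sharing profiles,
#' candidate variants, gene summaries, enrichment JSON, QC TSV and a run
#' manifest with seed and per-stage record counts. Outputs are
#' deterministic: re-running with the same configuration and seed
#' reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a list; also written as JSON).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- load_study_inputs(config)

  cand <- config$candidate_genes
  if (is.character(cand) && length(cand) == 1 && file.exists(cand))
    cand <- read_gene_list(cand)

  all_segments <- list()
  all_profiles <- list()
  all_candidates <- list()
  all_qc <- list()
  stage_counts <- list()
  truth_recovered <- list()

  for (fid in names(study$families)) {
    fam <- study$families[[fid]]
    genotyped <- fam$ped$members$person_id[fam$ped$members$genotyped]
    agt <- subset_genotypes(fam$array_gt,
                            samples = intersect(fam$array_gt$sample_ids,
                                                genotyped))
    res <- segments_genomewide(fam$ped, agt, study$map,
                               prune = config$prune, seg = config$seg,
                               max_meioses = config$max_meioses,
                               prune_gt = study$panel_gt)
    all_segments[[fid]] <- res$segments
    all_profiles[[fid]] <- res$profile
    cands <- run_family_cascade(fam$exome, fam$ped, res$segments,
                                config$filter)
    stage_counts[[fid]] <- as.list(attr(cands, "stage_counts"))
    all_candidates[[fid]] <- cands
    all_qc[[fid]] <- cbind(family_id = fid, call_rate_qc(agt))
    if (!is.null(fam$truth) && nrow(fam$truth)) {
      hit <- any(cands$chrom == fam$truth$chrom[1] &
                   cands$pos == fam$truth$pos[1])
      truth_recovered[[fid]] <- data.frame(
        family_id = fid, chrom = fam$truth$chrom[1], pos = fam$truth$pos[1],
        gene = fam$truth$gene[1], model = fam$truth$model[1],
        recovered = hit, stringsAsFactors = FALSE)
    }
  }

  rbind_all <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  }
  segments <- rbind_all(all_segments)
  candidates <- rbind_all(all_candidates)
  profiles <- rbind_all(all_profiles)
  qc <- rbind_all(all_qc)
  gene_summary <- summarize_genes(candidates)

  out <- function(f) file.path(config$out_dir, f)
  write_segments_bed(segments, out("segments.bed"))
  write_segments_tsv(segments, out("segments.tsv"))
  utils::write.table(profiles, out("sharing.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(candidates, out("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gene_summary, out("gene_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(qc, out("qc_call_rate.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  enr <- NULL
  if (!is.null(cand)) {
    universe <- unique(unlist(lapply(study$families,
                                     function(f) f$exome$variants$gene)))
    hit_genes <- unique(candidates$gene)
    enr <- tryCatch(enrichment(hit_genes, cand, universe),
                    error = function(e) {
                      message("enrichment skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(enr))
      jsonlite::write_json(unclass(enr), out("enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  truth_df <- if (length(truth_recovered))
    do.call(rbind, c(truth_recovered, list(make.row.names = FALSE))) else NULL
  if (!is.null(truth_df))
    utils::write.table(truth_df, out("truth_recovery.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "kindredscan",
    version = as.character(utils::packageVersion("kindredscan")),
    seed = config$seed,
    n_families = length(study$families),
    stage_counts = stage_counts,
    n_segments = nrow(segments),
    n_candidates = nrow(candidates),
    n_genes = nrow(gene_summary),
    n_multi_family_genes = sum(gene_summary$multi_family),
    causal_recall = if (!is.null(truth_df)) mean(truth_df$recovered) else NULL,
    enrichment = if (!is.null(enr)) unclass(enr) else NULL)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
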