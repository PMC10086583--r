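#' Pipeline configuration
#'
#' Bundles inputs and parameters for [run_pipeline()]. Cut-off mode
#' `"infer"` runs the full procedure (two-component mixture on HRR-CIN,
#' then ROC/Youden of the HRD score against the inferred HRR-CIN
#' status, then the LOH cut-off from the HRD status); `"fixed"` applies
#' published thresholds instead (HRD score >= 32, LOH >= 10), for
#' cross-cohort application.
#'
#' @param segments_path ASCN segment TSV (see [read_ascn_segments()]).
#' @param genome build name or cytoband file for [load_genome_build()].
#' @param expression_path optional expression matrix for signature
#'   scoring.
#' @param maf_path optional MAF for the alteration matrix.
#' @param out_dir output directory (created).
#' @param cutoff_mode `"infer"` or `"fixed"`.
#' @param hrd_cutoff,loh_cutoff fixed thresholds (used when
#'   `cutoff_mode = "fixed"`).
#' @param scar_params,cin_params parameter objects.
#' @param n_boot bootstrap replicates for the HRR-CIN cut-off CI
#'   (0 disables).
#' @param seed integer seed.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(segments_path, genome = "hg38",
                            expression_path = NULL, maf_path = NULL,
                            out_dir = "hrdscape_out",
                            cutoff_mode = c("infer", "fixed"),
                            hrd_cutoff = 32, loh_cutoff = 10,
                            scar_params = hrdscape::scar_params(),
                            cin_params = hrdscape::cin_params(),
                            n_boot = 200L, seed = 1L) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (cutoff_mode == "fixed" && (hrd_cutoff <= 0 || loh_cutoff <= 0))
    stop("fixed cutoffs must be positive")
  for (p in c(segments_path, expression_path, maf_path))
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  structure(list(segments_path = segments_path, genome = genome,
                 expression_path = expression_path, maf_path = maf_path,
                 out_dir = out_dir, cutoff_mode = cutoff_mode,
                 hrd_cutoff = hrd_cutoff, loh_cutoff = loh_cutoff,
                 scar_params = scar_params, cin_params = cin_params,
                 n_boot = n_boot, seed = seed),
            class = "PipelineConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the HRD profiling pipeline
#'
#' Segments -> scar scores (LOH/LST/TAI/HRD) + CIN features + HRR-CIN
#' -> cut-off inference (or fixed thresholds) -> HRD classification ->
#' optional signature scores and alteration table -> TSV/JSON report.
#' Outputs: `per_sample.tsv`, `cutoffs.json`, `per_cytoband.tsv`,
#' optional `alterations.tsv`, and `manifest.json` (package version,
#' seed, parameters). Any stage failure aborts with a stage-tagged
#' message and removes partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) { unlink(written); stop(e) }

  tryCatch({
    genome <- stage("genome", load_genome_build(config$genome))
    catalog <- stage("genome", hrr_gene_catalog(genome))
    segments <- stage("read_segments", read_ascn_segments(config$segments_path))
    scars <- stage("scar_scores",
                   score_cohort(segments, genome, config$scar_params))
    cin <- stage("cin_features",
                 cin_profile(segments, genome, catalog, config$cin_params))
    per_sample <- merge(scars, cin$per_sample, by = "sample")

    cutoffs <- stage("cutoff_inference", {
      if (config$cutoff_mode == "infer") {
        fit <- fit_two_component_mixture(per_sample$hrr_cin, seed = config$seed)
        if (config$n_boot > 0) {
          ci <- bootstrap_cutoff_ci(per_sample$hrr_cin, n_boot = config$n_boot,
                                    seed = config$seed)
        } else ci <- c(low = NA_real_, high = NA_real_)
        hrr_status <- classify_by_cutoff(per_sample$hrr_cin, fit$cutoff)
        roc_hrd <- roc_youden(hrr_status == "high", per_sample$hrd)
        hrd_cut <- roc_hrd$optimal_cutpoint
        hrd_status <- classify_by_cutoff(per_sample$hrd, hrd_cut)
        roc_loh <- roc_youden(hrd_status == "high", per_sample$loh)
        list(mode = "infer",
             hrr_cin_cutoff = fit$cutoff, hrr_cin_ci = unname(ci),
             mixture = list(means = fit$means, sds = fit$sds,
                            weights = fit$weights, converged = fit$converged),
             hrd_cutoff = hrd_cut, hrd_auc = roc_hrd$auc,
             loh_cutoff = roc_loh$optimal_cutpoint, loh_auc = roc_loh$auc)
      } else {
        list(mode = "fixed", hrd_cutoff = config$hrd_cutoff,
             loh_cutoff = config$loh_cutoff)
      }
    })
    per_sample$hrd_status <- classify_by_cutoff(per_sample$hrd, cutoffs$hrd_cutoff)
    if (!is.null(cutoffs$hrr_cin_cutoff))
      per_sample$hrr_cin_status <-
        classify_by_cutoff(per_sample$hrr_cin, cutoffs$hrr_cin_cutoff)

    if (!is.null(config$expression_path)) {
      expr <- stage("signature", read_expression_matrix(config$expression_path))
      sc <- stage("signature", signature_score(expr))
      per_sample$signature_score <- sc[per_sample$sample]
    }

    alt <- NULL
    if (!is.null(config$maf_path)) {
      variants <- stage("alterations", read_maf_minimal(config$maf_path))
      alt <- stage("alterations",
                   build_alteration_matrix(variants, NULL, catalog$symbol,
                                           unique(per_sample$sample)))
    }

    ps_path <- file.path(config$out_dir, "per_sample.tsv")
    utils::write.table(per_sample, ps_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, ps_path)
    cj_path <- file.path(config$out_dir, "cutoffs.json")
    jsonlite::write_json(cutoffs, cj_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, cj_path)
    cb_path <- file.path(config$out_dir, "per_cytoband.tsv")
    utils::write.table(cin$per_cytoband, cb_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, cb_path)
    if (!is.null(alt)) {
      al_path <- file.path(config$out_dir, "alterations.tsv")
      write_alteration_matrix(alt, al_path)
      written <- c(written, al_path)
    }
    manifest <- list(
      package = "hrdscape",
      version = as.character(utils::packageVersion("hrdscape")),
      genome = genome$name, seed = config$seed,
      cutoff_mode = config$cutoff_mode,
      scar_params = unclass(config$scar_params),
      cin_params = unclass(config$cin_params),
      inputs = list(segments = config$segments_path,
                    expression = config$expression_path,
                    maf = config$maf_path))
    mf_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mf_path)

    invisible(list(per_sample = per_sample, cutoffs = cutoffs,
                   per_cytoband = cin$per_cytoband, alterations = alt,
                   manifest = manifest, files = written))
  }, error = on_fail)
}
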