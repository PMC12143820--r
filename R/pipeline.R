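#' Run the full two-condition super-enhancer analysis
#'
#' Orchestrates the whole pipeline: (optionally) simulate a landscape, call
#' super-enhancers per condition, build consensus SE regions, test them for
#' differential signal, screen the expression table, and integrate
#' differential SEs with concordant expression changes. Every stage uses the
#' exported functions; identical inputs and seeds give identical outputs.
#'
#' Inputs are either a [simulation_config()] (`sim_config`, in which case
#' peaks, annotation and expression are generated) or explicit `peaks_a`,
#' `peaks_b`, `annotation` and a `de_table` (data.frame with `gene_id`,
#' `fold_change`, `p_value` and optionally `direction`).
#'
#' @param peaks_a,peaks_b peak data.frames (condition A = reference,
#'   condition B = treatment).
#' @param annotation a [genome_annotation()].
#' @param de_table differential-expression table keyed by `gene_id`.
#' @param sim_config a [simulation_config()]; overrides the four inputs
#'   above.
#' @param outdir output directory; `NULL` runs in memory only.
#' @param se_params a [se_call_params()].
#' @param int_params an [integration_params()].
#' @param fc_threshold,p_threshold differential-SE call gates (log2 fold
#'   change strictly above `fc_threshold`, raw p strictly below
#'   `p_threshold`; defaults 1 and 0.05).
#' @param rna_fc_threshold,rna_p_threshold differential-expression call
#'   gates on the simulated tables (linear fold change, defaults 2 and
#'   0.05); ignored when `de_table` is supplied.
#' @param overwrite allow overwriting an existing run manifest.
#' @param verbose log the resolved parameter set and stage progress to
#'   stderr (default TRUE).
#' @return list of class `se_run`: `se_a`, `se_b` (per-condition `se_call`
#'   objects), `diff_ses` (consensus SE regions with `log2fc`, `p_value`,
#'   `call`), `de_table`, `associations` (from [integrate_se_genes()]),
#'   `summary` (from [summarize_integration()]), `truth` (when simulated)
#'   and `files` (the manifest, when `outdir` was given).
#' @export
run_pipeline <- function(peaks_a = NULL, peaks_b = NULL, annotation = NULL,
                         de_table = NULL, sim_config = NULL, outdir = NULL,
                         se_params = se_call_params(),
                         int_params = integration_params(),
                         fc_threshold = 1, p_threshold = 0.05,
                         rna_fc_threshold = 2, rna_p_threshold = 0.05,
                         overwrite = FALSE, verbose = TRUE) {
  log_msg <- function(...) if (verbose) message("[sercall] ", ...)
  truth <- NULL
  if (!is.null(sim_config)) {
    stopifnot(inherits(sim_config, "simulation_config"))
    log_msg("simulating landscape (seed ", sim_config$seed, ")")
    sim <- simulate_landscape(sim_config)
    expr <- simulate_expression(sim$annotation, sim$truth, sim_config)
    peaks_a <- sim$peaks_a; peaks_b <- sim$peaks_b
    annotation <- sim$annotation; truth <- sim$truth
    de_table <- de_analysis(expr$fpkm_a, expr$fpkm_b,
                            rownames(expr$fpkm_a),
                            fc_threshold = rna_fc_threshold,
                            p_threshold = rna_p_threshold)
  }
  if (is.null(peaks_a) || is.null(peaks_b) || is.null(annotation) ||
      is.null(de_table))
    stop("need peaks_a, peaks_b, annotation and de_table (or sim_config)")
  log_msg("parameters: tss_radius=", se_params$tss_exclusion_radius,
          " stitch_gap=", se_params$stitch_gap,
          " fc_threshold=", fc_threshold, " p_threshold=", p_threshold,
          " se_fc_min=", int_params$se_fc_min,
          " rna_fc_min=", int_params$rna_fc_min,
          " gene_window=", int_params$gene_window,
          " require_concordance=", int_params$require_concordance)

  log_msg("calling super-enhancers, condition A (", nrow(peaks_a), " peaks)")
  se_a <- call_superenhancers(peaks_a, annotation, se_params)
  log_msg("calling super-enhancers, condition B (", nrow(peaks_b), " peaks)")
  se_b <- call_superenhancers(peaks_b, annotation, se_params)

  sup_a <- se_a$enhancers[se_a$enhancers$is_super, , drop = FALSE]
  sup_b <- se_b$enhancers[se_b$enhancers$is_super, , drop = FALSE]
  as_peaks <- function(e, tag) {
    if (nrow(e) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character(),
                        stringsAsFactors = FALSE))
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               name = paste0(tag, e$se_id), stringsAsFactors = FALSE)
  }
  regions <- build_consensus_regions(as_peaks(sup_a, "A:"),
                                     as_peaks(sup_b, "B:"))
  log_msg(nrow(regions), " consensus SE regions")

  sum_over <- function(peaks, regions) {
    vapply(seq_len(nrow(regions)), function(i) {
      hit <- peaks$chrom == regions$chrom[i] &
        peaks$start < regions$end[i] & peaks$end > regions$start[i]
      sum(peaks$signal[hit])
    }, numeric(1))
  }
  diff_ses <- if (nrow(regions) > 0L) {
    count_a <- sum_over(peaks_a, regions)
    count_b <- sum_over(peaks_b, regions)
    lib_a <- sum(peaks_a$signal); lib_b <- sum(peaks_b$signal)
    dt <- differential_signal_test(count_a, count_b, lib_a, lib_b)
    data.frame(se_id = regions$region_id, chrom = regions$chrom,
               start = regions$start, end = regions$end,
               count_a = count_a, count_b = count_b,
               signal = pmax(count_a, count_b),
               log2fc = dt$log2fc, p_value = dt$p_value,
               call = as.character(classify_regions(dt$log2fc, dt$p_value,
                                                    fc_threshold, p_threshold)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(se_id = character(), chrom = character(), start = numeric(),
               end = numeric(), count_a = numeric(), count_b = numeric(),
               signal = numeric(), log2fc = numeric(), p_value = numeric(),
               call = character(), stringsAsFactors = FALSE)
  }
  log_msg(sum(diff_ses$call == "up"), " SE regions up, ",
          sum(diff_ses$call == "down"), " down")

  associations <- integrate_se_genes(diff_ses, annotation, de_table,
                                     int_params)
  summary <- summarize_integration(associations)
  log_msg(summary$n_total, " concordant SE-gene associations (",
          summary$n_up, " up, ", summary$n_down, " down)")

  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(outdir, "run_manifest.tsv")
    if (file.exists(manifest_path) && !overwrite)
      stop("run manifest already exists in ", outdir,
           " (use overwrite = TRUE)")
    emitted <- character()
    put <- function(name) { emitted <<- c(emitted, name); file.path(outdir, name) }
    write_se_call(se_a, put("enhancers_a.bed"), put("curve_a.tsv"))
    write_se_call(se_b, put("enhancers_b.bed"), put("curve_b.tsv"))
    write_table(diff_ses, put("differential_ses.tsv"))
    write_table(de_table, put("de_table.tsv"))
    write_table(associations, put("associations.tsv"))
    files <- data.frame(file = emitted,
                        md5 = unname(tools::md5sum(file.path(outdir, emitted))),
                        stringsAsFactors = FALSE)
    write_table(files, manifest_path)
    log_msg("wrote ", length(emitted), " files to ", outdir)
  }

  structure(list(se_a = se_a, se_b = se_b, diff_ses = diff_ses,
                 de_table = de_table, associations = associations,
                 summary = summary, truth = truth, files = files),
            class = "se_run")
}

#' @export
print.se_run <- function(x, ...) {
  cat("se_run:\n  condition A:", sum(x$se_a$enhancers$is_super),
      "SEs of", nrow(x$se_a$enhancers), "enhancers\n  condition B:",
      sum(x$se_b$enhancers$is_super), "SEs of", nrow(x$se_b$enhancers),
      "enhancers\n  differential SE regions:",
      sum(x$diff_ses$call != "ns"), "of", nrow(x$diff_ses),
      "\n  concordant SE-gene associations:", x$summary$n_total,
      "(", x$summary$n_up, "up,", x$summary$n_down, "down )\n")
  invisible(x)
}

pipeline_config_keys <- c(
  "seed", "n_chrom", "chrom_length", "n_genes", "n_background_peaks",
  "n_typical_enhancers", "n_super_clusters", "peaks_per_cluster",
  "intra_cluster_gap", "background_meanlog", "background_sdlog",
  "se_signal_multiplier", "n_differential_ses", "differential_effect",
  "tss_proximal_fraction", "condition_noise_sdlog", "expr_meanlog",
  "expr_sdlog", "dispersion", "n_replicates", "concordant_fraction",
  "tss_exclusion_radius", "stitch_gap", "min_points_for_cutoff",
  "se_fc_min", "rna_fc_min", "gene_window", "require_concordance",
  "fc_threshold", "p_threshold", "rna_fc_threshold", "rna_p_threshold",
  "peaks_a", "peaks_b", "gtf", "de_table", "outdir", "overwrite")

#' Load and validate a pipeline configuration file
#'
#' YAML file mapping stage parameters to values; any key outside the known
#' set is an error naming the key, so typos never silently fall back to
#' defaults.
#'
#' @param path path to a YAML config file.
#' @return Named list of validated keys.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), pipeline_config_keys)
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  cfg
}
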