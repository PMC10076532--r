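# Pipeline orchestration: simulate / extract / analyze / demo, each writing a
# reproducible output bundle (effective config + seed archived alongside the
# results). A thin Rscript front-end in inst/scripts/metconn.R exposes these
# as command-line subcommands.

.archive_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Simulate a cohort pair and write it to disk
#'
#' Delegates to [generate_cohorts()] and writes `cohort.tsv` (both groups
#' stacked), `ground_truth.json`, and the effective `config.json` needed to
#' reproduce the run.
#'
#' @param out_dir Output directory.
#' @param spec A [simulation_spec()]; the default simulates 40 patients vs 41
#'   controls with no planted effect.
#' @param seed Overrides `spec$seed` when not `NULL`.
#' @return The combined `cohort_table`, invisibly; files under `out_dir`.
#' @export
run_simulate <- function(out_dir, spec = simulation_spec(), seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) spec$seed <- seed
  sim <- generate_cohorts(spec)
  cohort <- as_cohort_table(rbind(sim$cohort_a, sim$cohort_b))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_table(cohort, file.path(out_dir, "cohort.tsv"))
  jsonlite::write_json(
    lapply(sim$ground_truth, function(x) if (is.matrix(x)) round(x, 10) else x),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  .archive_config(list(
    command = "simulate", seed = spec$seed, n_a = spec$n_a, n_b = spec$n_b,
    uptake_mean = spec$uptake_mean, uptake_sd = spec$uptake_sd,
    noise_sd = spec$noise_sd,
    planted_edges = spec$planted_edges,
    base_correlation = round(spec$base_correlation, 10)
  ), out_dir)
  invisible(cohort)
}

#' Extract a cohort table from a manifest of image files
#'
#' Processes each manifest row (file, subject id, group) through the
#' preprocessing chain and writes `cohort.tsv` plus a per-subject QC log
#' (`extract_qc.tsv`: status, brain mean, VOI voxel counts). Per-subject
#' failures are reported in the QC log without aborting the batch.
#'
#' @param manifest Data frame (or CSV path) with columns `file`,
#'   `subject_id`, `group`.
#' @param out_dir Output directory.
#' @param atlas A `voi_atlas` (default packaged atlas).
#' @param radius_mm Sphere radius for the VOI masks.
#' @param smooth_fwhm Smoothing FWHM in mm (0 = off).
#' @param normalize Normalize by brain mean (default TRUE).
#' @return The `cohort_table` of successfully processed subjects, invisibly.
#' @export
run_extract <- function(manifest, out_dir, atlas = load_default_atlas(),
                        radius_mm = 6, smooth_fwhm = 0, normalize = TRUE) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("file", "subject_id", "group")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  masks <- NULL
  rows <- list()
  qc <- list()
  for (k in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[k]
    res <- tryCatch({
      vol <- read_brain_volume(manifest$file[k], subject_id = sid,
                               group = manifest$group[k])
      if (is.null(masks)) {
        masks <- build_sphere_masks(atlas, vol$affine, dim(vol$data),
                                    radius_mm)
      }
      if (smooth_fwhm > 0) vol <- gaussian_smooth(vol, smooth_fwhm)
      bm <- NA_real_
      if (normalize) {
        vol <- normalize_by_brain_mean(vol)
        bm <- attr(vol, "brain_mean")
      }
      list(uptake = extract_voi_means(vol, masks), brain_mean = bm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc[[k]] <- data.frame(subject_id = sid, status = "failed",
                            brain_mean = NA_real_,
                            message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- c(
        list(subject_id = sid, group = manifest$group[k]),
        as.list(res$uptake))
      qc[[k]] <- data.frame(subject_id = sid, status = "ok",
                            brain_mean = res$brain_mean, message = "")
    }
  }
  qc <- do.call(rbind, qc)
  utils::write.table(qc, file.path(out_dir, "extract_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(masks)) {
    counts <- data.frame(voi = names(masks$indices),
                         n_voxels = vapply(masks$indices, length, integer(1)))
    utils::write.table(counts, file.path(out_dir, "voi_voxel_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!length(rows)) stop("no subject processed successfully", call. = FALSE)
  cohort <- as_cohort_table(do.call(rbind, lapply(rows, as.data.frame)))
  write_cohort_table(cohort, file.path(out_dir, "cohort.tsv"))
  .archive_config(list(command = "extract", radius_mm = radius_mm,
                       smooth_fwhm = smooth_fwhm, normalize = normalize,
                       n_subjects = nrow(manifest),
                       n_failed = sum(qc$status == "failed")), out_dir)
  invisible(cohort)
}

#' Run the full group-comparison analysis on a cohort table
#'
#' The analysis stage: per-group correlation networks (R/Z/W), per-group
#' graph-metric reports, the edgewise Fisher-z permutation test, the four
#' metric permutation tests, and (when `age`/`sex` columns are present)
#' demographic comparisons. With `out_dir` set, all results plus the
#' effective config and seed are written so the run is reproducible
#' byte-for-byte.
#'
#' @param cohort A `cohort_table` (or TSV path) containing exactly two
#'   groups; the first group label encountered is treated as group a
#'   (conventionally patients).
#' @param out_dir Optional output directory.
#' @param n_permutations Permutations for all tests (default 1000 for
#'   interactive use; pass 10000 for full-fidelity runs).
#' @param seed Integer seed driving all randomness in the run.
#' @param sidedness,fdr_q,weight_mode Passed to the permutation tests.
#' @param metrics Which metric tests to run (default all four).
#' @return An `analysis_bundle` list: `networks`, `metrics`, `edgewise`,
#'   `metric_tests`, `demographics`, `config`.
#' @export
run_analyze <- function(cohort, out_dir = NULL, n_permutations = 1000,
                        seed = 1L,
                        sidedness = c("two_sided", "less", "greater"),
                        fdr_q = 0.05,
                        weight_mode = c("positive", "absolute"),
                        metrics = c("global_efficiency",
                                    "characteristic_path_length",
                                    "nodal_efficiency", "degree_centrality")) {
  sidedness <- match.arg(sidedness)
  weight_mode <- match.arg(weight_mode)
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  cohort <- as_cohort_table(cohort)
  groups <- unique(cohort$group)
  if (length(groups) != 2L) {
    stop("cohort must contain exactly two groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  parts <- split_cohort(cohort)
  cohort_a <- as_cohort_table(parts[[1L]])
  cohort_b <- as_cohort_table(parts[[2L]])

  networks <- list(
    a = intersubject_correlation(cohort_a, weight_mode),
    b = intersubject_correlation(cohort_b, weight_mode)
  )
  metric_reports <- lapply(networks, graph_metrics)

  edgewise <- edgewise_permutation_test(
    cohort_a, cohort_b, n_permutations = n_permutations, seed = seed,
    sidedness = sidedness, fdr_q = fdr_q)
  metric_tests <- lapply(stats::setNames(metrics, metrics), function(m) {
    metric_permutation_test(
      cohort_a, cohort_b, metric = m, n_permutations = n_permutations,
      seed = seed, sidedness = sidedness, fdr_q = fdr_q,
      weight_mode = weight_mode)
  })

  demographics <- NULL
  if ("age" %in% names(cohort)) {
    a <- cohort$age[cohort$group == groups[1L]]
    b <- cohort$age[cohort$group == groups[2L]]
    demographics$age <- two_sample_t_from_summary(
      mean(a), stats::sd(a), length(a), mean(b), stats::sd(b), length(b))
  }
  if ("sex" %in% names(cohort)) {
    demographics$sex <- chi_square_2x2(table(cohort$group, cohort$sex))
  }

  config <- list(command = "analyze", seed = seed,
                 n_permutations = n_permutations, sidedness = sidedness,
                 fdr_q = fdr_q, weight_mode = weight_mode,
                 group_a = groups[1L], group_b = groups[2L],
                 n_a = nrow(cohort_a), n_b = nrow(cohort_b),
                 n_vois = length(attr(cohort, "voi_names")))
  bundle <- structure(
    list(networks = networks, metrics = metric_reports, edgewise = edgewise,
         metric_tests = metric_tests, demographics = demographics,
         config = config),
    class = "analysis_bundle"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_group_network(networks$a, out_dir)
    write_group_network(networks$b, out_dir)
    write_graph_metrics(metric_reports$a, out_dir,
                        paste0("metrics_", networks$a$group))
    write_graph_metrics(metric_reports$b, out_dir,
                        paste0("metrics_", networks$b$group))
    write_permutation_result(edgewise, out_dir, "edgewise")
    for (m in names(metric_tests)) {
      write_permutation_result(metric_tests[[m]], out_dir, paste0("metric_", m))
    }
    sig <- edgewise$table[edgewise$table$significant, , drop = FALSE]
    summary <- list(
      config = config,
      significant_edges = sig$edge,
      n_significant_edges = nrow(sig),
      demographics = demographics,
      global_metrics = lapply(metric_reports, function(r)
        r[c("global_efficiency", "characteristic_path_length")])
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    .archive_config(config, out_dir)
  }
  bundle
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<analysis_bundle> %s (n=%d) vs %s (n=%d), %d VOIs\n",
              cfg$group_a, cfg$n_a, cfg$group_b, cfg$n_b, cfg$n_vois))
  print(x$edgewise)
  for (m in names(x$metric_tests)) {
    t <- x$metric_tests[[m]]$table
    cat(sprintf("  %s: %d/%d significant (min p %.4g)\n", m,
                sum(t$significant), nrow(t), min(t$p)))
  }
  invisible(x)
}

#' End-to-end demonstration run
#'
#' Simulates a cohort pair with one planted decreased edge (HIP.R - PCG.L,
#' correlation lowered by 0.35 in the patient group) and analyzes it,
#' writing both bundles under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for the whole run.
#' @param n_permutations Permutations for the analysis stage.
#' @return The `analysis_bundle`, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, n_permutations = 1000) {
  spec <- simulation_spec(
    planted_edges = data.frame(voi_i = "HIP.R", voi_j = "PCG.L",
                               delta_r = -0.35),
    seed = seed)
  cohort <- run_simulate(file.path(out_dir, "simulate"), spec)
  invisible(run_analyze(cohort, file.path(out_dir, "analyze"),
                        n_permutations = n_permutations, seed = seed))
}

#' Command-line entry point
#'
#' Dispatches `simulate`, `extract`, `analyze`, `demo` subcommands; used by
#' the `inst/scripts/metconn.R` front-end as
#' `Rscript metconn.R <subcommand> --out DIR [--config FILE] [--seed N] ...`.
#' The config file is JSON with fields matching the corresponding `run_*`
#' arguments.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
metconn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: metconn <simulate|extract|analyze|demo> --out DIR",
    "[--config FILE.json] [--seed N] [--cohort FILE.tsv]",
    "[--manifest FILE.csv] [--permutations N]")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opt <- list(seed = 1L, permutations = 1000L)
  rest <- args[-1L]
  while (length(rest)) {
    key <- sub("^--", "", rest[[1L]])
    if (length(rest) < 2L) stop("missing value for --", key, call. = FALSE)
    opt[[key]] <- rest[[2L]]
    rest <- rest[-(1:2)]
  }
  if (is.null(opt$out)) stop(usage, call. = FALSE)
  seed <- as.integer(opt$seed)
  nperm <- as.integer(opt$permutations)
  cfg <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else list()

  switch(cmd,
    simulate = {
      spec <- do.call(simulation_spec, c(
        cfg[intersect(names(cfg),
                      c("n_a", "n_b", "uptake_mean", "uptake_sd",
                        "noise_sd"))],
        list(planted_edges = cfg$planted_edges, seed = seed)))
      run_simulate(opt$out, spec)
    },
    extract = {
      if (is.null(opt$manifest)) stop("extract needs --manifest", call. = FALSE)
      do.call(run_extract, c(list(manifest = opt$manifest, out_dir = opt$out),
                             cfg[intersect(names(cfg),
                                           c("radius_mm", "smooth_fwhm",
                                             "normalize"))]))
    },
    analyze = {
      if (is.null(opt$cohort)) stop("analyze needs --cohort", call. = FALSE)
      do.call(run_analyze, c(
        list(cohort = opt$cohort, out_dir = opt$out,
             n_permutations = nperm, seed = seed),
        cfg[intersect(names(cfg), c("sidedness", "fdr_q", "weight_mode"))]))
    },
    demo = run_demo(opt$out, seed = seed, n_permutations = nperm),
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  )
  invisible(0L)
}
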