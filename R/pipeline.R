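#' Run the full analysis pipeline
#'
#' Chains all stages on a directory of micrographs: per-image neighborhood
#' analysis (`results.csv`), the random-distribution simulation null on the
#' first image's geometry (`sim.csv`), patient-level summaries and paired
#' Wilcoxon tests per width (`stats.csv`), QQ-plot data against the null
#' (`qq.csv`), and a reproducibility manifest (`manifest.json`).  A rerun
#' with the same config is byte-identical.
#'
#' The `config` is a named list (or path to a JSON file) with fields:
#' * `input_dir` — directory containing `<id>.tif`/`<id>.png` images,
#'   matching `<id>.roi.json` ROI files and a `mapping.csv`
#'   (image_id, patient_id); alternatively `fixtures` — a list of
#'   arguments to [make_cohort()] to generate the inputs first.
#' * `output_dir` — where the CSVs are written.
#' * `scale` (default 1.5), `widths_um` (default 10..50 by 10),
#'   `alpha` (default 0.01), `rng_seed` (default 1),
#'   `segmentation` — optional arguments to [segmentation_params()],
#'   `simulation` — optional arguments to [simulation_config()].
#'
#' @param config named list or JSON path.
#' @return invisibly, a list with the four tables and the manifest.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) pv_io_error("config '%s' not found", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config$output_dir))
    pv_validation_error("config$output_dir is required")
  scale <- config$scale %||% 1.5
  widths <- config$widths_um %||% c(10, 20, 30, 40, 50)
  alpha <- config$alpha %||% 0.01
  rng_seed <- as.integer(config$rng_seed %||% 1L)
  params <- do.call(segmentation_params, as.list(config$segmentation))
  sim_args <- as.list(config$simulation)
  if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- rng_seed
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  set.seed(rng_seed)
  if (!is.null(config$fixtures)) {
    fx_args <- as.list(config$fixtures)
    fx_args$spec <- do.call(fixture_spec, as.list(fx_args$spec))
    fx_args$dir <- fx_args$dir %||% file.path(out_dir, "fixtures")
    cohort <- do.call(make_cohort, fx_args)
    input_dir <- cohort$dir
  } else if (!is.null(config$input_dir)) {
    input_dir <- config$input_dir
  } else {
    pv_validation_error("config needs either input_dir or fixtures")
  }

  mapping_path <- file.path(input_dir, "mapping.csv")
  if (!file.exists(mapping_path))
    pv_io_error("mapping file '%s' not found", mapping_path)
  mapping <- read.csv(mapping_path, stringsAsFactors = FALSE,
                      colClasses = "character")

  message("[analyze] ", nrow(mapping), " image(s) from ", input_dir)
  results <- do.call(rbind, lapply(seq_len(nrow(mapping)), function(i) {
    id <- mapping$image_id[i]
    img_path <- file.path(input_dir, paste0(id, ".tif"))
    if (!file.exists(img_path)) img_path <- file.path(input_dir, paste0(id, ".png"))
    image <- read_color_image(img_path, scale)
    roi <- read_roi(file.path(input_dir, paste0(id, ".roi.json")))
    analyze_image(image, roi, widths, params,
                  image_id = id, patient_id = mapping$patient_id[i])
  }))
  write_results_table(results, file.path(out_dir, "results.csv"))

  message("[simulate] null model on geometry of ", mapping$image_id[1])
  first <- read_color_image(
    file.path(input_dir, paste0(mapping$image_id[1],
                                if (file.exists(file.path(input_dir,
                                      paste0(mapping$image_id[1], ".tif"))))
                                  ".tif" else ".png")), scale)
  first_roi <- read_roi(file.path(input_dir,
                                  paste0(mapping$image_id[1], ".roi.json")))
  a_t <- segment_total(first, first_roi)
  a_b <- clean_blue_mask(segment_relative_color(first, "blue", params, a_t),
                         params, a_t)
  a_r1 <- clean_red_mask(segment_relative_color(first, "red", params, a_t),
                         params, a_t)
  if (is.null(sim_args$target_cell_area_px) && any(a_r1))
    sim_args$target_cell_area_px <- estimate_cell_area(a_r1)
  sim_cfg <- do.call(simulation_config, sim_args)
  study <- run_simulation_study(a_t, a_b, widths, sim_cfg, scale)
  write_simulation_table(study, file.path(out_dir, "sim.csv"))

  message("[stats] per-patient summaries and paired Wilcoxon tests")
  summaries <- summarize_patients(results, mapping)
  stats_tab <- test_all_widths(summaries, alpha)
  write.csv(stats_tab, file.path(out_dir, "stats.csv"), row.names = FALSE)
  qq <- do.call(rbind, lapply(widths, function(w)
    cbind(width_um = w, qq_plot_data(summaries, study, w))))
  write.csv(qq, file.path(out_dir, "qq.csv"), row.names = FALSE)

  manifest <- list(
    config = config, rng_seed = rng_seed, widths_um = widths, scale = scale,
    alpha = alpha,
    segmentation = unclass(params), simulation = unclass(sim_cfg),
    n_images = nrow(mapping),
    package_version = as.character(utils::packageVersion("perivasc")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, simulation = study,
                 summaries = summaries, stats = stats_tab, qq = qq,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- command-line interface ------------------------------------------------

#' Command-line entry point
#'
#' Subcommand interface mirroring the pipeline stages.  Invoke from a
#' shell as e.g.
#' `Rscript -e 'perivasc::perivasc_cli()' analyze --image x.tif --roi x.roi.json --out results.csv`.
#'
#' Subcommands:
#' * `fixtures --out DIR [--patients N] [--samples N] [--effect F] [--seed S]`
#' * `analyze --image FILE --roi FILE --out FILE [--scale S] [--widths 10,20,...] [--id ID] [--dump-masks DIR]`
#' * `simulate --total-mask FILE --structure-mask FILE --out FILE [--seeds 100,200,...] [--reps N] [--cell-area N] [--rng-seed S] [--widths ...] [--scale S]`
#' * `stats --results FILE --mapping FILE --out FILE [--null FILE] [--alpha A]`
#' * `run-all --config FILE`
#'
#' @param args character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly: 0 success, 2 validation error, 3 I/O
#'   error.  When run non-interactively the process exits with that
#'   status.
#' @export
perivasc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      pv_validation_error("usage: perivasc <fixtures|analyze|simulate|stats|run-all> [options]")
    cmd <- args[1]
    opts <- parse_cli_options(args[-1])
    switch(cmd,
      fixtures = cli_fixtures(opts),
      analyze = cli_analyze(opts),
      simulate = cli_simulate(opts),
      stats = cli_stats(opts),
      `run-all` = {
        run_full_analysis(cli_require(opts, "config"))
        0L
      },
      pv_validation_error("unknown subcommand '%s'", cmd))
    0L
  },
  perivasc_io_error = function(e) { message("[error:io] ", conditionMessage(e)); 3L },
  perivasc_error = function(e) { message("[error:validation] ", conditionMessage(e)); 2L },
  error = function(e) { message("[error] ", conditionMessage(e)); 2L })
  if (!interactive() && !identical(Sys.getenv("PERIVASC_CLI_NO_EXIT"), "1"))
    quit(status = status, save = "no")
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      pv_validation_error("unexpected argument '%s'", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE; i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

cli_require <- function(opts, key) {
  if (is.null(opts[[key]]))
    pv_validation_error("missing required option --%s", gsub("_", "-", key))
  opts[[key]]
}

cli_num_vec <- function(x) as.numeric(strsplit(x, ",")[[1]])

cli_fixtures <- function(opts) {
  out <- cli_require(opts, "out")
  set.seed(as.integer(opts$seed %||% 1L))
  make_cohort(n_patients = as.integer(opts$patients %||% 4L),
              samples_per_patient = as.integer(opts$samples %||% 1L),
              spec = fixture_spec(),
              effect = as.numeric(opts$effect %||% 1),
              dir = out)
  message("[fixtures] wrote cohort to ", out)
  0L
}

cli_analyze <- function(opts) {
  image <- read_color_image(cli_require(opts, "image"),
                            as.numeric(opts$scale %||% 1.5))
  roi <- read_roi(cli_require(opts, "roi"))
  widths <- cli_num_vec(opts$widths %||% "10,20,30,40,50")
  res <- analyze_image(image, roi, widths,
                       image_id = opts$id %||% basename(cli_require(opts, "image")),
                       keep_masks = !is.null(opts$dump_masks))
  write_results_table(res, cli_require(opts, "out"))
  if (!is.null(opts$dump_masks)) {
    masks <- attr(res, "masks")
    if (!dir.exists(opts$dump_masks)) dir.create(opts$dump_masks, recursive = TRUE)
    for (nm in names(masks))
      write_mask_png(masks[[nm]], file.path(opts$dump_masks, paste0(nm, ".png")))
  }
  message("[analyze] wrote ", cli_require(opts, "out"))
  0L
}

cli_simulate <- function(opts) {
  a_t <- read_mask_png(cli_require(opts, "total_mask"))
  a_b <- read_mask_png(cli_require(opts, "structure_mask"))
  cfg <- simulation_config(
    seed_counts = as.integer(cli_num_vec(opts$seeds %||% "100,200,300,400,500")),
    replicates_per_count = as.integer(opts$reps %||% 100L),
    target_cell_area_px = as.integer(opts$cell_area %||% 25L),
    rng_seed = as.integer(opts$rng_seed %||% 1L))
  study <- run_simulation_study(a_t, a_b,
                                cli_num_vec(opts$widths %||% "10,20,30,40,50"),
                                cfg, as.numeric(opts$scale %||% 1.5))
  write_simulation_table(study, cli_require(opts, "out"))
  message("[simulate] wrote ", cli_require(opts, "out"))
  0L
}

cli_stats <- function(opts) {
  results <- read_results_table(cli_require(opts, "results"))
  mapping <- read.csv(cli_require(opts, "mapping"), stringsAsFactors = FALSE,
                      colClasses = "character")
  summaries <- summarize_patients(results, mapping)
  tab <- test_all_widths(summaries, as.numeric(opts$alpha %||% 0.01))
  write.csv(tab, cli_require(opts, "out"), row.names = FALSE)
  message("[stats] wrote ", cli_require(opts, "out"))
  0L
}
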