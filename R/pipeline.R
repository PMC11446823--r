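# Pipeline orchestration: the staged analysis chain
#   simulate -> grid -> features -> harmonize -> fit-kls -> fit-demo -> report
# with per-stage manifests (input hashes, config echo, seed, version) so a
# rerun with unchanged inputs is a no-op and corrupted intermediates are
# refused.  The hand-off contract between stages is a single tidy per-cell
# table to which every stage appends columns.

PIPELINE_STAGES <- c("simulate", "grid", "features", "harmonize",
                     "fit-kls", "fit-demo", "report")

#' Pipeline configuration
#'
#' @param out_dir output directory for all stage outputs and manifests.
#' @param seed master seed recorded in every manifest; overrides the scene
#'   config's seed.
#' @param scene an [scene_config()] describing the synthetic inputs.
#' @param gap_threshold_s drive-pass separation threshold (seconds).
#' @param buffers KLS buffer distances in meters.
#' @param bart_kls,bart_demo [bart_config()]s for the source model and the
#'   demographic models.
#' @param pollutants which pollutants to analyze.
#' @param top_k_vip number of top-VIP features given PDPs in the source
#'   model stage.
#' @return list of class `ld_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scene = scene_config(),
                            gap_threshold_s = 60, buffers = KLS_BUFFERS,
                            bart_kls = bart_config(), bart_demo = bart_config(),
                            pollutants = POLLUTANTS, top_k_vip = 8L) {
  scene$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), scene = scene,
                 gap_threshold_s = gap_threshold_s, buffers = buffers,
                 bart_kls = bart_kls, bart_demo = bart_demo,
                 pollutants = pollutants, top_k_vip = as.integer(top_k_vip)),
            class = "ld_pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  x$scene$source_strengths <- as.vector(x$scene$source_strengths)
  x$bart_kls <- unclass(x$bart_kls); x$bart_demo <- unclass(x$bart_demo)
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

manifest_path <- function(config, stage) {
  file.path(config$out_dir, paste0("manifest_", sub("-", "_", stage), ".json"))
}

read_manifest <- function(config, stage) {
  mp <- manifest_path(config, stage)
  if (!file.exists(mp)) return(NULL)
  jsonlite::read_json(mp, simplifyVector = TRUE)
}

write_manifest <- function(config, stage, inputs, outputs) {
  m <- list(stage = stage,
            seed = config$seed,
            config_hash = config_hash(config),
            inputs = as.list(tools::md5sum(inputs)),
            outputs = as.list(tools::md5sum(outputs)),
            package_version = as.character(utils::packageVersion("localdiff")),
            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(m, manifest_path(config, stage), auto_unbox = TRUE)
  invisible(m)
}

# verify that this stage's input files still match the hashes the upstream
# stage recorded for its outputs.
check_inputs_intact <- function(config, stage, inputs) {
  upstream <- PIPELINE_STAGES[match(stage, PIPELINE_STAGES) - 1L]
  man <- read_manifest(config, upstream)
  if (is.null(man)) {
    stop("stage `", stage, "` needs outputs of stage `", upstream,
         "`; run run_stage(\"", upstream, "\", config) first")
  }
  for (f in inputs) {
    rec <- man$outputs[[f]]
    if (!is.null(rec)) {
      cur <- unname(tools::md5sum(f))
      if (!identical(cur, rec)) {
        stop("intermediate file ", f, " does not match the hash recorded by ",
             "stage `", upstream, "` (corrupted or edited); rerun that stage")
      }
    }
  }
  invisible(TRUE)
}

stage_up_to_date <- function(config, stage, inputs) {
  man <- read_manifest(config, stage)
  if (is.null(man)) return(FALSE)
  if (!identical(man$config_hash, unname(config_hash(config)))) return(FALSE)
  recorded <- man$inputs
  if (length(recorded) != length(inputs)) return(FALSE)
  for (f in inputs) {
    if (!file.exists(f)) return(FALSE)
    if (!identical(unname(tools::md5sum(f)), recorded[[f]])) return(FALSE)
  }
  outs <- names(man$outputs)
  all(file.exists(outs))
}

#' Run one pipeline stage
#'
#' Each stage reads its prerequisites from the output directory, writes its
#' outputs plus a manifest (input hashes, configuration hash, seed,
#' package version), and skips work when its manifest shows inputs and
#' configuration unchanged.  A missing prerequisite is an error naming the
#' stage to run; a corrupted intermediate (hash mismatch against the
#' upstream manifest) is refused.
#'
#' @param stage one of `simulate`, `grid`, `features`, `harmonize`,
#'   `fit-kls`, `fit-demo`, `report`.
#' @param config a [pipeline_config()].
#' @param force rerun even when up to date.
#' @return invisibly, the stage's manifest (or `NULL` when skipped).
#' @export
run_stage <- function(stage, config, force = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)

  inputs <- switch(stage,
    "simulate" = character(0),
    "grid" = p(c("traces.csv", "grid.csv")),
    "features" = p(c("roads.geojson", "food_service.geojson",
                     "gas_stations.geojson", "industrial.geojson", "grid.csv")),
    "harmonize" = p(c("mm.csv", "block_groups.geojson", "grid.csv",
                      "kls.csv")),
    "fit-kls" = p("cells.csv"),
    "fit-demo" = p("cells.csv"),
    "report" = p(c("cells.csv", "fit_kls.csv", "fit_demo.csv"))
  )
  if (stage != "simulate") {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing) > 0) {
      need <- PIPELINE_STAGES[match(stage, PIPELINE_STAGES) - 1L]
      stop("stage `", stage, "` is missing prerequisite file(s) ",
           paste(basename(missing), collapse = ", "),
           "; run run_stage(\"", need, "\", config) first")
    }
    check_inputs_intact(config, stage, inputs)
  }
  if (!force && stage_up_to_date(config, stage, inputs)) {
    message("stage `", stage, "` is up to date; skipping (use force = TRUE to rerun)")
    return(invisible(NULL))
  }

  outputs <- switch(stage,
    "simulate" = stage_simulate(config, p),
    "grid" = stage_grid(config, p),
    "features" = stage_features(config, p),
    "harmonize" = stage_harmonize(config, p),
    "fit-kls" = stage_fit_kls(config, p),
    "fit-demo" = stage_fit_demo(config, p),
    "report" = stage_report(config, p)
  )
  invisible(write_manifest(config, stage, inputs, outputs))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config, force = FALSE) {
  for (s in PIPELINE_STAGES) run_stage(s, config, force = force)
  invisible(config$out_dir)
}

stage_simulate <- function(config, p) {
  scene <- generate_scene(config$scene)
  paths <- write_scene(scene, config$out_dir)
  traces <- simulate_drive_traces(scene)
  write_table(traces, p("traces.csv"))
  c(unname(paths), p("traces.csv"))
}

stage_grid <- function(config, p) {
  traces <- read_table(p("traces.csv"))
  grid <- read_table(p("grid.csv"))
  mm <- grid_concentration_field(traces, grid,
                                 gap_threshold_s = config$gap_threshold_s,
                                 pollutants = config$pollutants)
  write_table(mm, p("mm.csv"))
  p("mm.csv")
}

stage_features <- function(config, p) {
  layers <- read_scene_layers(config$out_dir)
  mat <- build_feature_matrix(layers, grid = layers$grid,
                              buffers = config$buffers)
  df <- cbind(tibble::tibble(cell_id = layers$grid$cell_id),
              tibble::as_tibble(as.data.frame(mat)))
  write_table(df, p("kls.csv"))
  zf <- attr(mat, "zero_fraction")
  write_table(tibble::tibble(feature = names(zf), zero_fraction = unname(zf)),
              p("kls_sparsity.csv"))
  p(c("kls.csv", "kls_sparsity.csv"))
}

stage_harmonize <- function(config, p) {
  grid <- read_table(p("grid.csv"))
  mm <- read_table(p("mm.csv"))
  kls <- read_table(p("kls.csv"))
  bg <- read_block_groups(p("block_groups.geojson"))

  cells <- grid[, c("cell_id", "x0", "y0", "size")]
  cells <- merge(cells, mm, by = "cell_id", all.x = TRUE)
  for (poll in config$pollutants) {
    cells[[paste0("lur_", poll)]] <-
      areal_resample(bg, paste0("lur_", poll), grid)
    ld <- compute_ld(cells[[paste0("mm_", poll)]],
                     cells[[paste0("lur_", poll)]])
    cells[[paste0("ld_", poll)]] <- as.numeric(ld)
  }
  pop <- allocate_population(bg, grid)
  cells <- merge(cells, pop, by = "cell_id")
  cells <- merge(cells, kls, by = "cell_id")
  cells <- cells[order(cells$cell_id), ]
  write_table(cells, p("cells.csv"))
  p("cells.csv")
}

# cells retained for modeling: monitored (MM present) with complete inputs
model_cells <- function(cells, poll) {
  ok <- !is.na(cells[[paste0("ld_", poll)]])
  cells[ok, , drop = FALSE]
}

stage_fit_kls <- function(config, p) {
  cells <- read_table(p("cells.csv"))
  kls_cols <- grep("^KLS_", names(cells), value = TRUE)
  summaries <- list(); vips <- list(); outs <- character(0)
  for (poll in config$pollutants) {
    dat <- model_cells(cells, poll)
    X <- as.matrix(dat[, kls_cols])
    y <- dat[[paste0("ld_", poll)]]
    cfg <- config$bart_kls
    cfg$seed <- config$seed + match(poll, POLLUTANTS)
    fit <- bart_fit(X, y, cfg)
    vip <- variable_inclusion_proportions(fit)
    vips[[poll]] <- tibble::tibble(pollutant = poll, feature = names(vip),
                                   vip = unname(vip))
    summaries[[poll]] <- tibble::tibble(
      pollutant = poll, n = length(y),
      pseudo_r2 = pseudo_r2(fit), nrmse = nrmse(fit),
      mean_ld_obs = mean(y),
      mean_ld_pred = mean(posterior_mean_fit(fit, X, y)))
    top <- top_vip(fit, config$top_k_vip)
    pdp_rows <- lapply(top$feature, function(f) {
      pd <- partial_dependence(fit, f)
      tibble::tibble(pollutant = poll, feature = f, value = pd$value,
                     quantile = pd$quantile, mean = pd$mean,
                     lower = pd$lower, upper = pd$upper)
    })
    write_table(do.call(rbind, pdp_rows), p(paste0("pdp_kls_", poll, ".csv")))
    outs <- c(outs, p(paste0("pdp_kls_", poll, ".csv")))
  }
  write_table(do.call(rbind, summaries), p("fit_kls.csv"))
  write_table(do.call(rbind, vips), p("vip.csv"))
  c(p(c("fit_kls.csv", "vip.csv")), outs)
}

stage_fit_demo <- function(config, p) {
  cells <- read_table(p("cells.csv"))
  kls_cols <- grep("^KLS_", names(cells), value = TRUE)
  summaries <- list(); outs <- character(0)
  for (poll in config$pollutants) {
    dat <- model_cells(cells, poll)
    dat <- dat[dat$pop > 0, , drop = FALSE]   # shares defined where pop > 0
    y <- dat[[paste0("ld_", poll)]]
    cfg <- config$bart_demo
    cfg$seed <- config$seed + 10L + match(poll, POLLUTANTS)
    ma <- fit_model_a(dat$pop, dat[, SHARE_COLS], y, cfg)
    cfg$seed <- cfg$seed + 10L
    mb <- fit_model_b(dat$pop, dat[, SHARE_COLS],
                      as.matrix(dat[, kls_cols]), y, cfg, model_a = ma)
    att <- attenuation_report(ma, mb)
    att$pollutant <- poll
    pdp_rows <- lapply(names(ma$pdps), function(f) {
      rbind(
        cbind(tibble::tibble(pollutant = poll, model = "A", feature = f),
              ma$pdps[[f]][, c("value", "quantile", "mean", "lower", "upper")]),
        cbind(tibble::tibble(pollutant = poll, model = "B", feature = f),
              mb$pdps[[f]][, c("value", "quantile", "mean", "lower", "upper")])
      )
    })
    write_table(do.call(rbind, pdp_rows), p(paste0("pdp_demo_", poll, ".csv")))
    write_table(att, p(paste0("attenuation_", poll, ".csv")))
    outs <- c(outs, p(paste0("pdp_demo_", poll, ".csv")),
              p(paste0("attenuation_", poll, ".csv")))

    gw <- population_weighted_quantiles(y, dat[, sub("share_", "pop_",
                                                     SHARE_COLS)])
    gw$pollutant <- poll
    write_table(gw, p(paste0("group_weighted_ld_", poll, ".csv")))
    outs <- c(outs, p(paste0("group_weighted_ld_", poll, ".csv")))

    summaries[[poll]] <- tibble::tibble(
      pollutant = poll, n = length(y),
      pseudo_r2_a = pseudo_r2(ma$fit), pseudo_r2_b = pseudo_r2(mb$fit),
      white_share_range_a = att$range_a[att$predictor == "share_white"],
      white_share_range_b = att$range_b[att$predictor == "share_white"],
      white_share_ratio = att$ratio[att$predictor == "share_white"])
  }
  write_table(do.call(rbind, summaries), p("fit_demo.csv"))
  c(p("fit_demo.csv"), outs)
}

stage_report <- function(config, p) {
  cells <- read_table(p("cells.csv"))
  ols <- list(); ldsum <- list()
  for (poll in config$pollutants) {
    mm <- cells[[paste0("mm_", poll)]]
    lur <- cells[[paste0("lur_", poll)]]
    ld <- cells[[paste0("ld_", poll)]]
    ols[[poll]] <- ols_compare(mm, lur, pollutant = poll)
    ldsum[[poll]] <- tibble::tibble(
      pollutant = poll, n = sum(!is.na(ld)),
      mean_ld = mean(ld, na.rm = TRUE),
      median_ld = stats::median(ld, na.rm = TRUE),
      q25 = stats::quantile(ld, 0.25, na.rm = TRUE, names = FALSE),
      q75 = stats::quantile(ld, 0.75, na.rm = TRUE, names = FALSE),
      mm_lur_mean_ratio = mean(mm, na.rm = TRUE) /
        mean(lur[!is.na(mm)], na.rm = TRUE))
  }
  write_table(do.call(rbind, ols), p("ols_comparison.csv"))
  write_table(do.call(rbind, ldsum), p("ld_summary.csv"))
  p(c("ols_comparison.csv", "ld_summary.csv"))
}
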