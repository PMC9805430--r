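# Pipeline orchestration: a validated YAML run configuration and the five
# stages (synth, prepare, train, reconstruct, evaluate), each reading the
# previous stage's artifacts from the run directory. All randomness funnels
# through the single config seed. A thin command-line dispatcher over these
# functions is installed at `system.file("cli", "oct-reveng.R")`.

run_config_defaults <- function() {
  list(
    seed = 1L,
    n_cases = 8L,
    phantom = list(volume_shape = c(64L, 64L, 16L), n_druse_clusters = 2L,
                   n_foci = 2L, n_sdd = 1L, druse_radius_range = c(5, 9),
                   focus_radius_range = c(2, 3), noise_sigma = 0.08,
                   transform_jitter = list(translate = 8, rotate = 3,
                                           projective = 5e-5),
                   conversion_margin = 2L),
    network = list(depth = 3L, base_channels = 4L, kernel_size = 3L,
                   in_shape = NULL, learning_rate = 1e-4, epochs = 30L,
                   batch_size = 2L),
    evaluation = list(k = 4L, bscans_per_case = 8L, threshold = 0.5,
                      otsu_classes = c(2L, 3L)),
    log_level = "info")
}

validate_config <- function(cfg, ref = run_config_defaults(), path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(ref)) {
      stop(sprintf("unknown configuration key '%s%s'", path, nm))
    }
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop(sprintf("'%s%s' must be a mapping", path, nm))
      validate_config(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
                      is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Load and validate a pipeline run configuration
#'
#' YAML configuration merged over the package defaults; unknown keys are
#' rejected by name. Every source of randomness in the pipeline derives from
#' the single `seed` entry (overridable per stage call).
#'
#' @param path YAML file, or NULL for the defaults.
#' @param overrides Named list merged last (e.g. from command-line flags).
#' @return Validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("missing configuration file %s", path))
    user <- yaml::read_yaml(path)
    validate_config(user)
    cfg <- merge_config(cfg, user)
  }
  if (length(overrides)) {
    validate_config(overrides)
    cfg <- merge_config(cfg, overrides)
  }
  structure(cfg, class = "run_config")
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

phantom_spec_from_config <- function(cfg, case_index) {
  ph <- cfg$phantom
  phantom_spec(volume_shape = unlist(ph$volume_shape),
               n_druse_clusters = ph$n_druse_clusters, n_foci = ph$n_foci,
               n_sdd = ph$n_sdd,
               druse_radius_range = unlist(ph$druse_radius_range),
               focus_radius_range = unlist(ph$focus_radius_range),
               noise_sigma = ph$noise_sigma,
               transform_jitter = ph$transform_jitter,
               conversion_margin = ph$conversion_margin,
               seed = as.integer(cfg$seed * 1000L + case_index))
}

#' Pipeline stage: synthesize phantom cases
#'
#' Writes `n_cases` seeded phantom case directories (`case_001`, ...) plus a
#' `manifest.json` listing cases, the effective seed and per-file checksums.
#'
#' @param config A [load_run_config()] result.
#' @param out_dir Output run directory.
#' @param force Overwrite an existing non-empty directory.
#' @return The manifest, invisibly.
#' @export
run_synth <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop(sprintf("output directory %s is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("case_%03d", seq_len(config$n_cases))
  for (i in seq_along(ids)) {
    case <- generate_phantom(phantom_spec_from_config(config, i))
    write_case(case, file.path(out_dir, ids[i]))
    log_msg(config, "synth: wrote %s", ids[i])
  }
  files <- sort(dir(out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- list(seed = config$seed, cases = as.list(ids),
                   checksums = as.list(stats::setNames(
                     unname(tools::md5sum(files)),
                     sub(paste0("^", out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

read_manifest <- function(run_dir) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("missing manifest file %s", mf))
  jsonlite::read_json(mf)
}

#' Pipeline stage: register and extrude labels
#'
#' For every case in the run directory, registers the follow-up GA annotation
#' into the baseline frame (writing `truth_enface.png`) and extrudes it into
#' the per-B-scan label stack (`truth_stack.tiff`, one page per B-scan).
#' Idempotent: re-running reproduces identical artifacts.
#'
#' @param config A [load_run_config()] result.
#' @param run_dir Directory produced by [run_synth()].
#' @return Invisibly, the list of case ids prepared.
#' @export
run_prepare <- function(config, run_dir) {
  manifest <- read_manifest(run_dir)
  for (id in unlist(manifest$cases)) {
    case <- read_case(file.path(run_dir, id))
    prep <- prepare_case(case, id)
    png::writePNG(prep$truth_enface, file.path(run_dir, id, "truth_enface.png"))
    pages <- lapply(seq_len(dim(prep$truth_stack)[3]),
                    function(d) prep$truth_stack[, , d])
    tiff::writeTIFF(pages, file.path(run_dir, id, "truth_stack.tiff"),
                    bits.per.sample = 8L, compression = "none")
    log_msg(config, "prepare: %s", id)
  }
  invisible(unlist(manifest$cases))
}

load_prepared <- function(run_dir, ids) {
  lapply(ids, function(id) {
    dirc <- file.path(run_dir, id)
    for (f in c("truth_enface.png", "truth_stack.tiff")) {
      if (!file.exists(file.path(dirc, f))) {
        stop(sprintf("case %s is missing prepared artifact %s (run prepare first)",
                     id, f))
      }
    }
    case <- read_case(dirc)
    pages <- tiff::readTIFF(file.path(dirc, "truth_stack.tiff"), all = TRUE)
    stack <- array(0, c(dim(pages[[1]]), length(pages)))
    for (d in seq_along(pages)) stack[, , d] <- pages[[d]]
    list(id = id, oct = case$oct, truth_stack = as_binary(stack) ,
         truth_enface = as_binary(read_gray_png(file.path(dirc, "truth_enface.png"))),
         case = case)
  })
}

net_config_from <- function(config, h, w, seed) {
  nw <- config$network
  in_shape <- if (is.null(nw$in_shape)) c(h, w) else unlist(nw$in_shape)
  unet_config(depth = nw$depth, base_channels = nw$base_channels,
              kernel_size = nw$kernel_size, in_shape = in_shape,
              learning_rate = nw$learning_rate, epochs = nw$epochs,
              batch_size = nw$batch_size, seed = as.integer(seed))
}

#' Pipeline stage: train a network on all prepared cases
#'
#' Trains one network on every prepared case's selected B-scans and writes a
#' checkpoint (`model.rds` + `model.json` sidecar + `model_history.csv`)
#' under `run_dir`.
#'
#' @param config A [load_run_config()] result.
#' @param run_dir Prepared run directory.
#' @return The training fit, invisibly.
#' @export
run_train <- function(config, run_dir) {
  ids <- unlist(read_manifest(run_dir)$cases)
  preps <- load_prepared(run_dir, ids)
  ds <- dim(preps[[1]]$oct)
  cfg <- net_config_from(config, ds[1], ds[2], config$seed)
  samples <- list()
  with_seed(config$seed, {
    for (p in preps) {
      for (di in select_bscans(p, config$evaluation$bscans_per_case)) {
        samples[[length(samples) + 1]] <-
          list(x = p$oct[, , di], y = p$truth_stack[, , di])
      }
    }
  })
  log_msg(config, "train: %d samples, %d epochs", length(samples), cfg$epochs)
  fit <- train_unet(build_unet(cfg), samples)
  save_unet(fit, file.path(run_dir, "model"))
  invisible(fit)
}

#' Pipeline stage: reconstruct salient features
#'
#' Loads the stage checkpoint and writes, per case, a multi-page TIFF of
#' input-space saliency maps for the B-scans crossing lesion footprints,
#' plus a CSV of per-lesion reconstruction energies.
#'
#' @param config A [load_run_config()] result.
#' @param run_dir Run directory holding `model.rds`.
#' @return Invisibly, the combined per-lesion energy data frame.
#' @export
run_reconstruct <- function(config, run_dir) {
  model <- load_unet(file.path(run_dir, "model"))
  ids <- unlist(read_manifest(run_dir)$cases)
  out <- list()
  for (id in ids) {
    case <- read_case(file.path(run_dir, id))
    any_fp <- Reduce(`+`, lapply(case$lesions, `[[`, "enface_footprint"))
    depths <- which(colSums(any_fp > 0) > 0)
    pages <- lapply(depths, function(d) {
      saliency_image(reconstruct_stack(model, case$oct[, , d]))
    })
    if (length(pages)) {
      tiff::writeTIFF(pages, file.path(run_dir, id, "saliency.tiff"),
                      bits.per.sample = 8L, compression = "none")
    }
    en <- reconstruction_contrast(model, case)
    en$case_id <- id
    out[[id]] <- en
    log_msg(config, "reconstruct: %s (%d B-scans)", id, length(depths))
  }
  df <- do.call(rbind, out)
  utils::write.csv(df, file.path(run_dir, "reconstruction_energy.csv"),
                   row.names = FALSE)
  invisible(df)
}

#' Pipeline stage: cross-validated evaluation
#'
#' Runs the seeded k-fold cross-validation over the prepared cases and writes
#' `metrics.csv` (per-fold rows plus a combined row), `per_case.csv` and the
#' fold assignment `folds.json`.
#'
#' @param config A [load_run_config()] result.
#' @param run_dir Prepared run directory.
#' @return The `cv_result`, invisibly.
#' @export
run_evaluate <- function(config, run_dir) {
  ids <- unlist(read_manifest(run_dir)$cases)
  preps <- load_prepared(run_dir, ids)
  ds <- dim(preps[[1]]$oct)
  cfg <- net_config_from(config, ds[1], ds[2], config$seed)
  cv <- crossvalidate(preps, k = config$evaluation$k, seed = config$seed,
                      net_cfg = cfg,
                      bscans_per_case = config$evaluation$bscans_per_case,
                      verbose = !identical(config$log_level, "quiet"))
  write_metrics_csv(cv, file.path(run_dir, "metrics.csv"))
  utils::write.csv(cv$per_case, file.path(run_dir, "per_case.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(cv$folds, function(f) list(fold = f$fold_id,
                                      cases = as.list(f$case_ids))),
    file.path(run_dir, "folds.json"), auto_unbox = TRUE)
  invisible(cv)
}
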