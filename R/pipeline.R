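#' Declarative pipeline configuration
#'
#' Builds (or reads from YAML) the configuration driving [run_pipeline()]:
#' simulator design, B-mode dynamic range, segmentation network and training
#' sizes, spectrum kinds, binary tasks and classifier settings, plus one
#' master seed from which every stage's seed is derived. Any field supplied
#' in `...` or in the YAML file overrides the default.
#'
#' @param file Optional YAML file with (partial) settings.
#' @param ... Named overrides, e.g. `seed = 7`,
#'   `sim = list(n_per_stage = 4)`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- list(
    seed = 1L,
    sim = list(mode = "balanced", n_per_stage = 2L, total = NULL,
               stage_effect = 1),
    acq = list(n_samples = 1247L, n_lines = 256L, fs = 12e6, fc = 3e6,
               pulse_bw = 0.6),
    bmode = list(dynamic_range_db = 40),
    seg = list(arch = "unet", input_shape = c(96L, 128L),
               encoder_widths = c(8L, 16L, 32L), epochs = 5L,
               batch_size = 2L, lr = 2e-4,
               ratios = c(0.6, 0.2, 0.2), use_truth_masks = FALSE),
    kinds = "phase",
    tasks = c("geF1", "geF2", "geF3", "geF4"),
    clf = list(conv_channels = c(4L, 8L, 16L, 32L),
               kernel_sizes = c(7L, 5L, 5L, 3L),
               pool_sizes = c(4L, 4L, 2L, 2L),
               fc_widths = c(64L, 32L, 16L, 2L),
               epochs = 5L, batch_size = 256L, lr = 2e-4,
               ratios = c(0.8, 0.1, 0.1)),
    gate = list(gate_len = 768L, gate_step = 20L))
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  if (!is.null(file)) cfg <- merge_in(cfg, yaml::read_yaml(file))
  cfg <- merge_in(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

# md5 of the canonical deparsed config (order-stable, excludes run options)
config_hash <- function(cfg) {
  core <- unclass(cfg)
  core <- core[order(names(core))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(core), tf)
  unname(tools::md5sum(tf))
}

# number of scan lines whose longest liver run admits the gate
eligible_lines <- function(mask, gate_len) {
  sum(apply(mask, 2, function(m) longest_run(m)[2] >= gate_len))
}

# total lateral width the sliding gate would produce for this mask
gated_width <- function(mask, gate_len, gate_step) {
  runs <- apply(mask, 2, function(m) longest_run(m)[2])
  sum(ifelse(runs >= gate_len, (runs - gate_len) %/% gate_step + 1L, 0L))
}

#' Run the end-to-end staging pipeline
#'
#' Executes simulate -> B-mode -> split/augment -> train segmentation ->
#' predict masks -> spectra -> ROI gating -> train classifier -> evaluate,
#' for every (task, spectrum kind) pair in the config. Artifacts (dataset,
#' trained models, reports) are written under `out_dir`, each stamped with
#' the config hash; with `resume = TRUE`, stages whose artifact exists with a
#' matching hash are loaded instead of recomputed. All randomness derives
#' from the config's master seed, so two runs of the same config produce
#' identical reports.
#'
#' If a predicted mask yields fewer gated segments than the lateral window
#' width (so no classifier frame could be assembled), ROI extraction for that
#' frame falls back to an all-ones mask (no ROI restriction); the report
#' counts such fallbacks.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse up-to-date artifacts.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `eval_report`: `seg` (named vector),
#'   `clf` (data frame: task, kind, n_test, n_aug, acc, sen, spe, auc),
#'   `n_mask_fallback`, `config_hash`, `artifacts`.
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, maker) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (resume && file.exists(path)) {
      obj <- readRDS(path)
      if (identical(attr(obj, "config_hash"), hash)) {
        log("[%s] reused", name)
        return(obj)
      }
    }
    obj <- tryCatch(maker(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    attr(obj, "config_hash") <- hash
    saveRDS(obj, path)
    log("[%s] done", name)
    obj
  }
  acq <- do.call(acquisition_spec, config$acq)

  frames <- stage("dataset", function() {
    if (identical(config$sim$mode, "paper"))
      simulate_dataset(total = config$sim$total, mode = "paper", acq = acq,
                       seed = config$seed,
                       stage_effect = config$sim$stage_effect)
    else
      simulate_dataset(n_per_stage = config$sim$n_per_stage, acq = acq,
                       seed = config$seed,
                       stage_effect = config$sim$stage_effect)
  })
  ids <- vapply(frames, `[[`, "", "frame_id")

  prep <- stage("bmode", function() {
    shp <- config$seg$input_shape
    imgs <- lapply(frames, function(f)
      pmin(pmax(resize_image(bmode(f, config$bmode$dynamic_range_db)$pixels,
                             shp), 0), 1))
    msks <- lapply(frames, function(f)
      (resize_image(f$truth_mask, shp) >= 0.5) * 1L)
    list(images = imgs, masks = msks)
  })

  spl <- stage("split", function()
    split_dataset(ids, config$seg$ratios, seed = config$seed + 1L))

  segnet <- stage("segnet", function() {
    tr <- match(spl$train, ids); va <- match(spl$val, ids)
    aug <- augment_images(prep$images[tr], prep$masks[tr],
                          seed = config$seed + 2L)
    vaug <- augment_images(prep$images[va], prep$masks[va],
                           seed = config$seed + 3L)
    cfg <- seg_config(arch = config$seg$arch,
                      input_shape = config$seg$input_shape,
                      encoder_widths = config$seg$encoder_widths,
                      batch_size = config$seg$batch_size,
                      epochs = config$seg$epochs, lr = config$seg$lr,
                      seed = config$seed + 4L)
    train_segnet(build_segnet(cfg), aug$images, aug$masks,
                 vaug$images, vaug$masks)
  })

  masks <- stage("masks", function() {
    pred <- lapply(prep$images, function(im) segment_bmode(segnet, im))
    sig <- lapply(pred, resize_mask_to_signal,
                  out_shape = c(acq$n_samples, acq$n_lines))
    te <- match(spl$test, ids)
    seg_report <- seg_metrics_set(lapply(pred[te], `[[`, "pixels"),
                                  prep$masks[te])
    list(network = pred, signal = sig, seg_report = seg_report)
  })

  clf_rows <- list()
  n_fallback <- 0L
  for (kind in config$kinds) {
    specs <- stage(paste0("spectra_", kind), function()
      lapply(frames, spectrum_frame, kind = kind))
    rois <- stage(paste0("roi_", kind), function()
      lapply(seq_along(frames), function(i) {
        mk <- if (isTRUE(config$seg$use_truth_masks))
          frames[[i]]$truth_mask else masks$signal[[i]]$pixels
        if (gated_width(mk, config$gate$gate_len, config$gate$gate_step) <
            acq$n_lines)
          mk <- matrix(1L, acq$n_samples, acq$n_lines)
        normalize_roi(apply_mask(specs[[i]], mk))
      }))
    if (!isTRUE(config$seg$use_truth_masks))
      n_fallback <- n_fallback + sum(vapply(seq_along(frames), function(i)
        gated_width(masks$signal[[i]]$pixels, config$gate$gate_len,
                    config$gate$gate_step) < acq$n_lines, logical(1)))
    for (ti in seq_along(config$tasks)) {
      task <- binary_task(config$tasks[ti])
      res <- stage(paste0("clf_", kind, "_", task$name), function() {
        ds <- balance_and_assemble(rois, task, ratios = config$clf$ratios,
                                   seed = config$seed + 10L + ti,
                                   gate_len = config$gate$gate_len,
                                   gate_step = config$gate$gate_step)
        ccfg <- clf_config(conv_channels = config$clf$conv_channels,
                           kernel_sizes = config$clf$kernel_sizes,
                           pool_sizes = config$clf$pool_sizes,
                           fc_widths = config$clf$fc_widths,
                           input_len = config$gate$gate_len,
                           batch_size = config$clf$batch_size,
                           epochs = config$clf$epochs, lr = config$clf$lr,
                           seed = config$seed + 100L + 10L * ti +
                             match(kind, config$kinds))
        net <- train_clf(build_clf(ccfg), ds$train,
                         if (length(ds$val) > 0) ds$val else NULL)
        preds <- lapply(ds$test, function(s) predict_frame(net, s))
        cm <- clf_metrics(preds)
        ra <- roc_auc(score_frames(net, ds$test),
                      vapply(ds$test, `[[`, integer(1), "label"))
        list(metrics = cm, auc = ra$auc, n_test = length(ds$test),
             n_aug = ds$n_aug)
      })
      clf_rows[[length(clf_rows) + 1L]] <- data.frame(
        task = task$name, kind = kind, n_test = res$n_test,
        n_aug = res$n_aug, acc = res$metrics$acc, sen = res$metrics$sen,
        spe = res$metrics$spe, auc = res$auc)
    }
  }
  clf_df <- do.call(rbind, clf_rows)
  report <- structure(list(seg = masks$seg_report, clf = clf_df,
                           n_mask_fallback = n_fallback,
                           config_hash = hash,
                           artifacts = list.files(out_dir)),
                      class = "eval_report")
  write.csv(clf_df, file.path(out_dir, "clf_report.csv"), row.names = FALSE)
  write.csv(data.frame(metric = names(masks$seg_report),
                       value = as.numeric(masks$seg_report)),
            file.path(out_dir, "seg_report.csv"), row.names = FALSE)
  jsonlite::write_json(list(seg = as.list(masks$seg_report),
                            clf = clf_df, n_mask_fallback = n_fallback,
                            config_hash = hash),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n segmentation (test, macro):\n")
  print(round(x$seg, 4))
  cat(" classification:\n")
  print(x$clf, row.names = FALSE)
  if (x$n_mask_fallback > 0)
    cat(sprintf(" mask fallbacks (no eligible line): %d\n", x$n_mask_fallback))
  invisible(x)
}

#' Write a B-mode image or mask as 8-bit PNG
#'
#' @param x A `bmode_image`, `liver_mask`, or numeric matrix in \[0,1\].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
save_png <- function(x, file) {
  px <- if (inherits(x, "bmode_image")) x$pixels
        else if (inherits(x, "liver_mask")) x$pixels
        else as.matrix(x)
  png::writePNG(pmin(pmax(px, 0), 1), file)
  invisible(file)
}
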