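#' Load and reduce a dataset to a spectra table
#'
#' Runs the image-processing front end over every tuber in a manifest: read
#' the raw ENVI cube, calibrate against the shared white/dark references, drop
#' the leading noisy bands, segment the slice, then either take the masked
#' mean spectrum (`mode = "mean"`) or unfold every masked pixel
#' (`mode = "pixel"`). Rows keep the manifest's order; pixel rows additionally
#' carry image coordinates for re-folding.
#'
#' @param manifest Manifest tibble or path to `manifest.csv`; paths inside it
#'   are resolved relative to the manifest's directory (`dir` when a tibble is
#'   passed).
#' @param mode `"mean"` or `"pixel"`.
#' @param dir Directory the manifest paths are relative to.
#' @param n_drop Leading bands to trim (default 30).
#' @param min_object_px,closing_radius Segmentation settings, see
#'   [segment_slice()].
#' @return A spectra table (see [unfold()]); attribute `shapes` holds each
#'   sample's image shape for map folding.
#' @export
extract_spectra <- function(manifest, mode = c("mean", "pixel"), dir = ".",
                            n_drop = 30, min_object_px = 50,
                            closing_radius = 2) {
  mode <- match.arg(mode)
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  refs <- reference_pair(
    read_envi(file.path(dir, manifest$path_white[1]))$data,
    read_envi(file.path(dir, manifest$path_dark[1]))$data
  )
  shapes <- list()
  parts <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cube <- read_envi(file.path(dir, manifest$path_raw[i]))
    cube$sample_id <- manifest$sample_id[i]
    cube$class_label <- manifest$class[i]
    refl <- trim_leading_bands(calibrate_reflectance(cube, refs), n_drop)
    mask <- segment_slice(refl, min_object_px = min_object_px,
                          closing_radius = closing_radius)
    shapes[[manifest$sample_id[i]]] <- dim(refl$data)[1:2]
    parts[[i]] <- if (mode == "mean") {
      mean_spectrum(refl, mask)
    } else {
      unfold(refl, mask)
    }
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "shapes") <- shapes
  out
}

#' Run a full classification experiment
#'
#' End-to-end reproduction of one experiment: load + calibrate + segment +
#' reduce ([extract_spectra()]), split into calibration/validation
#' ([split_dataset()]), fit the pre-processing chain on calibration data,
#' choose the latent-variable count ([select_n_lv()]), cross-validate, fit the
#' final model and validate externally; optionally run forward iPLS on the
#' pre-processed calibration matrix and refit on the selected bands; in pixel
#' mode, build one classification map per validation tuber.
#'
#' @param manifest Manifest tibble or path (see [extract_spectra()]).
#' @param mode `"mean"` (one mean spectrum per tuber, 75/25 split) or
#'   `"pixel"` (per-pixel spectra of a 3-tubers-per-cultivar subset, 2/1
#'   split).
#' @param chain Chain label (see [build_chain()]); default `"SM+SNV+MC"`.
#' @param dir Directory for relative manifest paths.
#' @param max_lv Largest latent-variable count scanned.
#' @param cv List with `n_splits` and `width` for [venetian_blinds()].
#' @param ipls `NULL`, or a list with `interval_size` (and optionally
#'   `rel_tol`, `max_lv`) enabling forward interval selection.
#' @param seed Integer seed (splitting).
#' @param out_dir If non-`NULL`, write metric CSVs, maps and a run log below
#'   it.
#' @param positive Positive class (default `"cooking"`).
#' @return A list of class `hsi_run`: `metrics` (per-class CV + external
#'   validation table), `n_lv`, `lv_curves`, `cv`, `external`
#'   (confusion tibbles), `model`, `chain`, `ipls`, `maps` (pixel mode),
#'   `split` (the split manifest), `data` sizes and the `config` used.
#' @export
run_experiment <- function(manifest, mode = c("mean", "pixel"),
                           chain = "SM+SNV+MC", dir = ".", max_lv = 10,
                           cv = list(n_splits = 10, width = 1), ipls = NULL,
                           seed = 1, out_dir = NULL, positive = "cooking") {
  mode <- match.arg(mode)
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  split_mode <- if (mode == "mean") "mean_spectra_75_25" else
    "pixelwise_2_1_per_cultivar"
  split_man <- split_dataset(manifest, split_mode, seed = seed)
  used <- split_man[split_man$split != "unused", ]
  data <- extract_spectra(used, mode = if (mode == "mean") "mean" else "pixel",
                          dir = dir)
  shapes <- attr(data, "shapes")
  sample_split <- stats::setNames(used$split, used$sample_id)
  data$split <- unname(sample_split[data$sample_id])
  cal <- data[data$split == "calibration", ]
  val <- data[data$split == "validation", ]

  res <- fit_stage(cal, val, chain, max_lv = max_lv, cv = cv, ipls = ipls,
                   positive = positive)
  res$split <- split_man
  res$mode <- mode
  res$config <- list(mode = mode, chain = chain, max_lv = max_lv, cv = cv,
                     ipls = ipls, seed = seed)

  if (mode == "pixel") {
    res$maps <- pixel_maps(val, res$val_pred, shapes, positive)
  }
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  class(res) <- "hsi_run"
  res
}

# modelling stage shared by run_experiment() and compare_chains()
fit_stage <- function(cal, val, chain_label, max_lv = 10,
                      cv = list(n_splits = 10, width = 1), ipls = NULL,
                      positive = "cooking") {
  ch <- build_chain(chain_label)
  plan <- venetian_blinds(nrow(cal), n_splits = cv$n_splits, width = cv$width)
  sel <- select_n_lv(cal, ch, max_lv = max_lv, plan = plan, positive = positive)
  cvres <- cross_validate(cal, ch, n_lv = sel$n_lv, plan = plan,
                          positive = positive)
  ft <- fit_transform_chain(ch, cal)
  model <- plsda_fit(ft$X, n_lv = sel$n_lv, class = cal$class,
                     positive = positive)
  Xval <- apply_chain(ft$chain, val)
  val_pred <- predict(model, Xval)
  ext <- confusion_stats(val$class, val_pred$.pred_class, positive)
  classes <- model$classes
  ext_pc <- per_class_stats(val$class, val_pred$.pred_class, classes)

  ipls_res <- NULL
  if (!is.null(ipls)) {
    ipls_res <- run_ipls_stage(ft, model, cal, val, plan, ipls, positive)
  }

  metrics <- metrics_table(chain_label, sel$n_lv,
                           model$explained_x_variance_pct,
                           cvres$per_class, ext_pc, classes)
  list(metrics = metrics, n_lv = sel$n_lv, lv_curves = sel$curves, cv = cvres,
       external = ext, external_per_class = ext_pc, model = model,
       chain = ft$chain, val_pred = val_pred, ipls = ipls_res,
       n_cal = nrow(cal), n_val = nrow(val))
}

run_ipls_stage <- function(ft, model, cal, val, plan, ipls, positive) {
  sel <- forward_ipls(ft$X, interval_size = ipls$interval_size, plan = plan,
                      class = cal$class,
                      rel_tol = ipls$rel_tol %||% 1e-3,
                      max_intervals = ipls$max_intervals %||% Inf,
                      max_lv = ipls$max_lv %||% 10, positive = positive)
  bands <- sel$selected_variables
  sub_model <- plsda_fit(ft$X[, bands, drop = FALSE], n_lv = sel$n_lv,
                         class = cal$class, positive = positive)
  Xval <- apply_chain(ft$chain, val)[, bands, drop = FALSE]
  pred <- predict(sub_model, Xval)
  list(selection = sel, model = sub_model,
       external = confusion_stats(val$class, pred$.pred_class, positive),
       n_variables = length(bands))
}

pixel_maps <- function(val, val_pred, shapes, positive) {
  ids <- unique(val$sample_id)
  maps <- lapply(ids, function(sid) {
    i <- val$sample_id == sid
    categorize(val_pred$.pred_class[i], val$class[which(i)[1]],
               cbind(val$row[i], val$col[i]), shapes[[sid]],
               positive = positive, sample_id = sid)
  })
  stats::setNames(maps, ids)
}

# per-class table mirroring the pipeline's comparison layout
metrics_table <- function(chain_label, n_lv, variance_pct, cv_pc, ext_pc,
                          classes) {
  short <- c("C", "FC")[match(cv_pc$class, classes)]
  tibble(
    preprocessing = chain_label, n_lv = n_lv, variance_pct = variance_pct,
    class = short,
    cv_sensitivity = cv_pc$sensitivity, cv_specificity = cv_pc$specificity,
    cv_error = cv_pc$class_error, cv_accuracy_pct = cv_pc$accuracy_pct,
    val_sensitivity = ext_pc$sensitivity, val_specificity = ext_pc$specificity,
    val_error = ext_pc$class_error, val_accuracy_pct = ext_pc$accuracy_pct
  )
}

#' @export
print.hsi_run <- function(x, ...) {
  cat(sprintf(
    "<hsi_run> %s mode, chain %s, %d LV | CV accuracy %.2f%%, external %.2f%%\n",
    x$mode %||% "?", x$config$chain, x$n_lv, x$cv$stats$accuracy_pct,
    x$external$accuracy_pct))
  invisible(x)
}

#' @export
tidy.hsi_run <- function(x, ...) x$metrics

#' @export
glance.hsi_run <- function(x, ...) {
  tibble(chain = x$config$chain, n_lv = x$n_lv,
         cv_accuracy_pct = x$cv$stats$accuracy_pct,
         cv_error = x$cv$stats$class_error,
         val_accuracy_pct = x$external$accuracy_pct,
         val_error = x$external$class_error,
         n_cal = x$n_cal, n_val = x$n_val)
}

write_run_outputs <- function(res, out_dir) {
  for (d in c("metrics", "maps", "logs")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
  }
  readr::write_csv(round_metrics(res$metrics),
                   file.path(out_dir, "metrics", "model_metrics.csv"))
  readr::write_csv(res$lv_curves, file.path(out_dir, "metrics", "lv_curves.csv"))
  if (!is.null(res$ipls)) {
    readr::write_csv(tidy(res$ipls$selection),
                     file.path(out_dir, "metrics", "ipls_selection.csv"))
  }
  if (!is.null(res$maps)) {
    for (sid in names(res$maps)) {
      render_map(res$maps[[sid]],
                 file.path(out_dir, "maps", paste0(sid, ".png")))
      writeLines(to_json_counts(res$maps[[sid]]),
                 file.path(out_dir, "maps", paste0(sid, "_counts.json")))
    }
  }
  log <- c(
    sprintf("tuberspec %s", as.character(utils::packageVersion("tuberspec"))),
    sprintf("seed: %s", res$config$seed),
    sprintf("mode: %s  chain: %s  n_lv: %d", res$mode, res$config$chain,
            res$n_lv),
    config_hash_line(res$config))
  writeLines(log, file.path(out_dir, "logs", "run.log"))
  invisible(out_dir)
}

config_hash_line <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- sum(utf8ToInt(txt) * seq_len(nchar(txt))) %% 2147483647
  sprintf("config hash: %d", h)
}

to_json_counts <- function(cimg) {
  sprintf('{"sample_id": "%s", "true_label": "%s", %s}',
          cimg$sample_id, cimg$true_label,
          paste(sprintf('"%s": %d', names(cimg$counts),
                        as.integer(cimg$counts)), collapse = ", "))
}

#' Round a metrics table for reporting
#'
#' Errors and sensitivity/specificity to 3 decimals, accuracies to 2
#' (round-half-even); raw values stay available in the unrounded table.
#'
#' @param metrics A metrics tibble from [run_experiment()]/[compare_chains()].
#' @return The rounded tibble.
#' @export
round_metrics <- function(metrics) {
  dplyr::mutate(
    metrics,
    dplyr::across(dplyr::ends_with(c("sensitivity", "specificity", "error")),
                  ~ round(.x, 3)),
    dplyr::across(dplyr::ends_with("accuracy_pct"), ~ round(.x, 2)),
    variance_pct = round(.data$variance_pct, 2)
  )
}

#' Compare pre-processing chains on one dataset
#'
#' Loads the dataset once, then runs the modelling stage for each chain and
#' stacks the per-class metric rows into one comparison table.
#'
#' @inheritParams run_experiment
#' @param chains Character vector of chain labels (default all ten benchmark
#'   chains, see [paper_chains()]).
#' @return A list of class `chain_comparison`: `table` (combined per-class
#'   metrics, with a `best` marker on the chain with highest external
#'   accuracy) and `runs` (per-chain [glance()] rows).
#' @export
compare_chains <- function(manifest, mode = c("mean", "pixel"),
                           chains = paper_chains(), dir = ".", max_lv = 10,
                           cv = list(n_splits = 10, width = 1), seed = 1,
                           positive = "cooking") {
  mode <- match.arg(mode)
  if (length(chains) < 1) {
    stop_ts("Provide at least one chain.", "tuberspec_parameter_error")
  }
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  }
  split_mode <- if (mode == "mean") "mean_spectra_75_25" else
    "pixelwise_2_1_per_cultivar"
  split_man <- split_dataset(manifest, split_mode, seed = seed)
  used <- split_man[split_man$split != "unused", ]
  data <- extract_spectra(used, mode = if (mode == "mean") "mean" else "pixel",
                          dir = dir)
  sample_split <- stats::setNames(used$split, used$sample_id)
  data$split <- unname(sample_split[data$sample_id])
  cal <- data[data$split == "calibration", ]
  val <- data[data$split == "validation", ]

  runs <- lapply(chains, function(chl) {
    fit_stage(cal, val, chl, max_lv = max_lv, cv = cv, positive = positive)
  })
  tab <- dplyr::bind_rows(lapply(runs, `[[`, "metrics"))
  ext_acc <- vapply(runs, function(r) r$external$accuracy_pct, numeric(1))
  tab$best <- tab$preprocessing == chains[which.max(ext_acc)]
  summaries <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tibble(chain = chains[i], n_lv = runs[[i]]$n_lv,
           cv_accuracy_pct = runs[[i]]$cv$stats$accuracy_pct,
           val_accuracy_pct = ext_acc[i])
  }))
  structure(list(table = tab, runs = summaries), class = "chain_comparison")
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat("<chain_comparison>\n")
  print(x$runs)
  invisible(x)
}

#' @export
tidy.chain_comparison <- function(x, ...) x$table

#' Read a pipeline run configuration
#'
#' YAML key-value file mirroring [run_experiment()]'s arguments: `manifest`,
#' `mode`, `chain`, `max_lv`, `cv: {n_splits, width}`,
#' `ipls: {interval_size, rel_tol}`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$manifest)) {
    stop_ts("Config must name a `manifest`.", "tuberspec_config_error")
  }
  cfg$mode <- cfg$mode %||% "mean"
  if (!cfg$mode %in% c("mean", "pixel")) {
    stop_ts("`mode` must be \"mean\" or \"pixel\".", "tuberspec_config_error")
  }
  cfg$chain <- cfg$chain %||% "SM+SNV+MC"
  build_chain(cfg$chain) # validates the label
  cfg$max_lv <- cfg$max_lv %||% 10
  cfg$cv <- utils::modifyList(list(n_splits = 10, width = 1),
                              cfg$cv %||% list())
  cfg$seed <- cfg$seed %||% 1
  cfg
}
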