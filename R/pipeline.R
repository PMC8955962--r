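# End-to-end orchestration: generate/read -> focal slice -> detect ->
# segment -> quantify -> evaluate/compare, with persisted intermediates
# and a reproducibility manifest.

#' Serialize a fitted model to JSON
#'
#' Plain-text weight storage so models survive text-only pipelines.
#'
#' @param model a `synapse_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "synapse_model"))
  ser_head <- function(h) list(W1 = as.vector(h$W1), d1 = dim(h$W1),
                               b1 = h$b1, W2 = as.vector(h$W2),
                               d2 = dim(h$W2), b2 = h$b2)
  doc <- list(kind = "synapse_model",
              detector = ser_head(model$detector),
              segmenter = ser_head(model$segmenter),
              loss = model$loss, full_scale = model$full_scale,
              n_train = model$n_train,
              config = unclass(model$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [write_model()]
#' @param path JSON path.
#' @return a `synapse_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$kind, "synapse_model"))
    sq_stop("%s is not a serialized synapse_model", path)
  de_head <- function(h) list(W1 = matrix(h$W1, h$d1[1L], h$d1[2L]),
                              b1 = as.numeric(h$b1),
                              W2 = matrix(h$W2, h$d2[1L], h$d2[2L]),
                              b2 = as.numeric(h$b2))
  cfg <- doc$config
  config <- train_config(learning_rate = cfg$learning_rate,
                         epochs = cfg$epochs, hidden = cfg$hidden,
                         batch = cfg$batch,
                         augmentations = as.character(cfg$augmentations),
                         margin = cfg$margin, scales = as.numeric(cfg$scales),
                         max_pixels_per_image = cfg$max_pixels_per_image,
                         seed = cfg$seed)
  structure(list(detector = de_head(doc$detector),
                 segmenter = de_head(doc$segmenter),
                 loss = as.data.frame(doc$loss),
                 config = config, full_scale = doc$full_scale,
                 n_train = doc$n_train),
            class = "synapse_model")
}

#' Pipeline configuration
#'
#' @param out_dir directory for all persisted artifacts.
#' @param n_images number of scenes to generate (ignored when
#'   `input_dir` is given).
#' @param params [scene_params()] for generation.
#' @param input_dir optional directory of existing stack TIFFs (named
#'   `*.tif`/`*.tiff`) instead of generation.
#' @param model `"oracle"` (threshold path), a fitted `synapse_model`,
#'   or a path to a [write_model()] JSON.
#' @param thresholds evaluation IoU thresholds.
#' @param cohort_b optional second [scene_params()]; when given, a
#'   second cohort of `n_images` scenes is generated and the two
#'   populations are compared channel-by-channel.
#' @param seed root seed; all stage randomness derives from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_images = 4L, params = scene_params(),
                            input_dir = NULL, model = "oracle",
                            thresholds = c(0.5, 0.7), cohort_b = NULL,
                            seed = 1L) {
  structure(list(out_dir = out_dir, n_images = as.integer(n_images),
                 params = params, input_dir = input_dir, model = model,
                 thresholds = thresholds, cohort_b = cohort_b,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Resolve the model argument to NULL (oracle) or a synapse_model.
resolve_model <- function(model) {
  if (is.null(model) || identical(model, "oracle")) return(NULL)
  if (inherits(model, "synapse_model")) return(model)
  if (is.character(model) && file.exists(model)) return(read_model(model))
  sq_stop("model must be 'oracle', a synapse_model, or a model JSON path")
}

# Process one scene through zselect -> detect -> segment -> quantify.
process_scene <- function(stack, model, image_id, margin = 8L) {
  fp <- select_focal_slice(stack)
  img <- stack_slice(stack, 1L, fp$z_index)
  boxes <- detect_cells(img, model)
  instances <- segment_instances(img, boxes, model = model, margin = margin)
  tfi <- per_cell_channel_table(stack, fp, instances, image_id = image_id)
  list(focal = fp, boxes = boxes, instances = instances, tfi = tfi)
}

run_cohort <- function(cfg, params, tag, out_dir, model) {
  scenes <- if (!is.null(cfg$input_dir) && tag == "a") {
    paths <- sort(list.files(cfg$input_dir, pattern = "\\.tiff?$",
                             full.names = TRUE))
    if (!length(paths)) sq_stop("no TIFF stacks in %s", cfg$input_dir)
    lapply(paths, function(p) list(stack = read_stack(p), gt = NULL))
  } else {
    generate_dataset(cfg$n_images, params,
                     seed = derive_seeds(cfg$seed, 1L, paste0("cohort_", tag)))
  }
  tfi_all <- list()
  evals <- list()
  for (i in seq_along(scenes)) {
    id <- sprintf("%s_%03d", tag, i)
    res <- process_scene(scenes[[i]]$stack, model, image_id = id)
    if (length(res$instances)) {
      write_annotations(lapply(res$instances, `[[`, "mask"),
                        file.path(out_dir, paste0(id, "_masks.json")),
                        image_id = id,
                        scores = vapply(res$instances, `[[`, 0, "score"))
    }
    tfi_all[[i]] <- res$tfi
    if (!is.null(scenes[[i]]$gt) && length(scenes[[i]]$gt$masks)) {
      ev <- evaluate_instances(res$instances, scenes[[i]]$gt$masks,
                               thresholds = cfg$thresholds)
      ev$image_id <- id
      evals[[length(evals) + 1L]] <- ev
    }
  }
  list(tfi = do.call(rbind, tfi_all), evals = evals)
}

#' Run the full pipeline
#'
#' Generates (or reads) stacks, selects the focal slice, detects and
#' segments every cell, quantifies per-cell channel intensities, and —
#' when ground truth or a second cohort is available — writes evaluation
#' and statistics reports. Every intermediate is persisted under
#' `out_dir`; a manifest records the configuration, its hash and the
#' seed, so a rerun with the same config reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @return list with `tfi` (cohort A records), `eval` (aggregated
#'   evaluation data.frame or `NULL`), `stats` (per-channel comparison
#'   or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- resolve_model(config$model)

  a <- run_cohort(config, config$params, "a", config$out_dir, model)
  write_tfi_table(a$tfi, file.path(config$out_dir, "tfi_a.csv"))

  eval_df <- NULL
  if (length(a$evals)) {
    eval_df <- do.call(rbind, a$evals)
    agg <- stats::aggregate(value ~ metric + threshold, eval_df, mean)
    jsonlite::write_json(list(per_image = eval_df, mean = agg),
                         file.path(config$out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    eval_df <- agg
  }

  stats_out <- NULL
  if (!is.null(config$cohort_b)) {
    b <- run_cohort(config, config$cohort_b, "b", config$out_dir, model)
    write_tfi_table(b$tfi, file.path(config$out_dir, "tfi_b.csv"))
    stats_out <- lapply(1:4, function(ch) {
      cmp <- compare_groups(a$tfi, b$tfi, ch)
      ds_a <- distribution_summaries(a$tfi$tfi[a$tfi$channel == ch])
      ds_b <- distribution_summaries(b$tfi$tfi[b$tfi$channel == ch])
      list(channel = ch,
           group_a = unclass(cmp$stats_a), group_b = unclass(cmp$stats_b),
           t = cmp$test$t, p = cmp$test$p, df = cmp$test$df,
           histogram_a = ds_a$histogram, histogram_b = ds_b$histogram,
           ecdf_a = ds_a$ecdf, ecdf_b = ds_b$ecdf)
    })
    jsonlite::write_json(stats_out, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  cfg_json <- jsonlite::toJSON(list(
    n_images = config$n_images, seed = config$seed,
    model = if (is.null(model)) "oracle" else "learned",
    params = unclass(config$params),
    cohort_b = if (is.null(config$cohort_b)) NULL else
      unclass(config$cohort_b),
    thresholds = config$thresholds), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   n_images = config$n_images,
                   outputs = sort(setdiff(list.files(config$out_dir),
                                          "manifest.json")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tfi = a$tfi, eval = eval_df, stats = stats_out,
                 manifest = manifest))
}
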