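#' Simulate one synthetic monolayer acquisition
#'
#' Generates a tessellation, its border channel, a tracer channel with
#' ground truth, and the junction annotation mask, all from one seed.
#'
#' @param field A [field_spec()]; its `rng_seed` drives the geometry.
#' @param render A [render_params()].
#' @param tracer A [tracer_params()].
#' @param annotation_radius_px Disk radius of the training mask.
#' @param relaxation_steps Lloyd relaxation steps for the tessellation.
#' @return List: `tess`, `border`, `tracer`, `truth`, `mask`, `field`.
#' @export
simulate_monolayer <- function(field = field_spec(),
                               render = render_params(),
                               tracer = tracer_params(),
                               annotation_radius_px = 3,
                               relaxation_steps = 2) {
  tess <- generate_tessellation(field, relaxation_steps)
  border <- render_border_channel(tess, render,
                                  rng_seed = field$rng_seed + 1L)
  tr <- render_tracer_channel(tess, tracer, rng_seed = field$rng_seed + 2L)
  mask <- make_annotation_mask(tess$vertices, annotation_radius_px, field)
  list(tess = tess, border = border, tracer = tr$image, truth = tr$truth,
       mask = mask, field = field)
}

#' Build a synthetic segmentation training set
#'
#' Simulates border-channel fields with their junction annotation masks,
#' tiles each into `tile_px` squares and (optionally) expands every tile
#' with the geometric augmentation recipe (rotations by 90/180/270 and
#' horizontal flip), yielding `list(image, mask)` pairs for
#' [train_segmenter()].
#'
#' @param n_fields Number of simulated fields.
#' @param field A [field_spec()] template (seed overridden per field).
#' @param render A [render_params()].
#' @param annotation_radius_px Junction disk radius of the masks.
#' @param tile_px Tile side; must divide into the field size.
#' @param augment Apply rotations + flip (8 variants per tile).
#' @param seed Base seed.
#' @return List with `pairs` and `fields` (the per-field `tess` objects,
#'   for ground-truth junction lookup).
#' @export
make_training_data <- function(n_fields = 8, field = field_spec(512, 512, 100),
                               render = render_params(),
                               annotation_radius_px = 3, tile_px = 256L,
                               augment = TRUE, seed = 1L) {
  pairs <- list(); fields <- list()
  for (i in seq_len(n_fields)) {
    f <- field
    f$rng_seed <- as.integer(seed * 100L + i)
    tess <- generate_tessellation(f)
    border <- render_border_channel(tess, render, rng_seed = f$rng_seed + 1L)
    mask <- make_annotation_mask(tess$vertices, annotation_radius_px, f)
    fields[[i]] <- tess
    spec <- augmentation_spec(tile_px,
                              rotations = if (augment) c(90, 180, 270)
                                          else numeric(),
                              horizontal_flip = augment,
                              rng_seed = seed * 100L + i)
    pairs <- c(pairs, augment_pair(border, mask, spec))
  }
  list(pairs = pairs, fields = fields)
}

#' Simulate and quantify a multi-condition study
#'
#' Emulates the experimental design used to contrast monolayer conditions:
#' `n_replicates` replicates (donors) per condition, `n_images` fields per
#' replicate, each field simulated from its condition's preset and
#' quantified with the chosen junction source. Seeds are derived
#' deterministically from `seed`.
#'
#' @param conditions Character vector of [condition_preset()] names.
#' @param n_replicates,n_images Replicates per condition and images per
#'   replicate.
#' @param field A [field_spec()] template (its seed is overridden).
#' @param render A [render_params()].
#' @param junction_source `"truth"` (generator ground truth),
#'   `"geometric"` (skeleton detector on the border channel) or a trained
#'   `tj_segmenter`.
#' @param threshold A [threshold_params()].
#' @param distance_threshold_px Association radius.
#' @param seed Base seed.
#' @return Data frame of per-image report rows with `condition`,
#'   `replicate`, `image`, the four metrics, raw counts, and the realised
#'   generator truth (`true_fraction_permeable`, `true_share`).
#' @export
simulate_condition_study <- function(conditions = condition_presets()$condition,
                                     n_replicates = 3, n_images = 9,
                                     field = field_spec(256, 256, 60),
                                     render = render_params(),
                                     junction_source = "truth",
                                     threshold = threshold_params(),
                                     distance_threshold_px = 2,
                                     seed = 1L) {
  rows <- list()
  counter <- 0L
  for (ci in seq_along(conditions)) {
    tp <- condition_preset(conditions[ci])
    for (r in seq_len(n_replicates)) {
      for (i in seq_len(n_images)) {
        counter <- counter + 1L
        f <- field
        f$rng_seed <- as.integer(seed * 1000L + counter * 10L)
        sim <- simulate_monolayer(f, render, tp)
        jn <- .resolve_junctions(junction_source, sim)
        q <- quantify_image(sim$tracer, jn, threshold,
                            distance_threshold_px)
        rows[[counter]] <- report_as_row(
          q$report, condition = conditions[ci], replicate = r, image = i,
          true_fraction_permeable =
            sim$truth$n_permeable / nrow(sim$truth$junctions),
          true_share = sim$truth$realised_share)
      }
    }
  }
  do.call(rbind, rows)
}

.resolve_junctions <- function(junction_source, sim) {
  if (inherits(junction_source, "tj_segmenter"))
    return(segment_junctions(junction_source, sim$border)$junctions)
  switch(junction_source,
    truth = sim$truth$junctions,
    geometric = geometric_detector(sim$border),
    stop("junction_source must be 'truth', 'geometric' or a tj_segmenter"))
}

#' Compare conditions on replicate means
#'
#' Applies [summarize_conditions()] and then pairwise pooled-variance t
#' tests on the replicate means of every metric, with percent changes
#' relative to the first-listed condition of each pair.
#'
#' @param reports Per-image report data frame
#'   ([simulate_condition_study()] or bound CSVs).
#' @param pairs List of length-2 character vectors of condition names;
#'   defaults to all pairs present.
#' @param metrics Metric columns to compare.
#' @return List: `summary` (condition x metric table) and `comparisons`
#'   (data frame: metric, condition pair, percent change, t, df, p, stars).
#' @export
compare_conditions <- function(reports, pairs = NULL, metrics = NULL) {
  summ <- summarize_conditions(reports, metrics)
  metrics <- unique(summ$metric)
  rep_means <- attr(summ, "replicate_means")
  conds <- unique(summ$condition)
  if (is.null(pairs))
    pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    for (m in metrics) {
      a <- rep_means[rep_means$condition == pr[1], m]
      b <- rep_means[rep_means$condition == pr[2], m]
      tt <- unpaired_t_test(a, b, metric = m)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, reference = pr[1], treated = pr[2],
        mean_reference = mean(a), mean_treated = mean(b),
        percent_change = percent_change(mean(a), mean(b)),
        t = tt$t, df = tt$df, p = tt$p, stars = tt$stars)
    }
  }
  list(summary = summ, comparisons = do.call(rbind, rows))
}

# content hash of an R object (serialised to a temp file, md5)
.param_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the end-to-end pipeline from a single configuration
#'
#' Stages (`simulate`, `segment`, `quantify`, `summarize`) execute in
#' order into `out_dir`. Each stage's outputs land in a directory keyed by
#' a content hash of its parameters (plus its upstream stage's key), so a
#' rerun with unchanged parameters reuses cached outputs and a change to,
#' say, the association distance recomputes only quantification onward. A
#' manifest (parameters, seeds, stage keys, outputs, package version)
#' sufficient to reproduce the run is written as JSON.
#'
#' @param config Nested list (or YAML path, see [read_run_config()]) with
#'   blocks `seed`, `field` (height_px, width_px, n_cells), `render`,
#'   `tracer` (`preset` name or [tracer_params()] fields), `segmentation`
#'   (`method`: "truth", "geometric" or "model"; `model_path`),
#'   `threshold`, `distance_threshold_px`, `n_images`, and optional stage
#'   toggles in `stages`.
#' @param out_dir Output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- .fill_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("tjperm")),
                   seed = cfg$seed, config = cfg, stages = list())

  sim_key <- .param_hash(cfg[c("seed", "field", "render", "tracer",
                               "n_images")])
  sim_dir <- file.path(out_dir, "stages", paste0("simulate-", sim_key))
  if (!file.exists(file.path(sim_dir, ".done"))) {
    dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(cfg$n_images)) {
      f <- do.call(field_spec, c(cfg$field,
                                 list(rng_seed = cfg$seed * 100L + i)))
      sim <- simulate_monolayer(f, do.call(render_params, cfg$render),
                                .tracer_from_config(cfg$tracer))
      save_image(sim$border, file.path(sim_dir, sprintf("border_%02d.tif", i)))
      save_image(sim$tracer, file.path(sim_dir, sprintf("tracer_%02d.tif", i)))
      write_junctions_csv(sim$truth$junctions,
                          file.path(sim_dir, sprintf("junctions_%02d.csv", i)))
      write_ground_truth_json(sim$truth,
                              file.path(sim_dir, sprintf("truth_%02d.json", i)))
    }
    file.create(file.path(sim_dir, ".done"))
  }
  manifest$stages$simulate <- list(key = sim_key, dir = sim_dir,
                                   cached = TRUE)

  seg_key <- .param_hash(list(sim_key, cfg$segmentation))
  seg_dir <- file.path(out_dir, "stages", paste0("segment-", seg_key))
  if (!file.exists(file.path(seg_dir, ".done"))) {
    dir.create(seg_dir, recursive = TRUE, showWarnings = FALSE)
    model <- if (identical(cfg$segmentation$method, "model"))
      load_segmenter(cfg$segmentation$model_path) else NULL
    for (i in seq_len(cfg$n_images)) {
      jn <- switch(cfg$segmentation$method,
        truth = read_junctions_csv(
          file.path(sim_dir, sprintf("junctions_%02d.csv", i))),
        geometric = geometric_detector(
          load_image(file.path(sim_dir, sprintf("border_%02d.tif", i)))),
        model = segment_junctions(model, load_image(
          file.path(sim_dir, sprintf("border_%02d.tif", i))))$junctions,
        stop("unknown segmentation method"))
      write_junctions_csv(jn,
        file.path(seg_dir, sprintf("detected_%02d.csv", i)))
    }
    file.create(file.path(seg_dir, ".done"))
  }
  manifest$stages$segment <- list(key = seg_key, dir = seg_dir)

  q_key <- .param_hash(list(seg_key, cfg$threshold,
                            cfg$distance_threshold_px))
  q_dir <- file.path(out_dir, "stages", paste0("quantify-", q_key))
  if (!file.exists(file.path(q_dir, ".done"))) {
    dir.create(q_dir, recursive = TRUE, showWarnings = FALSE)
    rows <- list()
    for (i in seq_len(cfg$n_images)) {
      tr <- load_image(file.path(sim_dir, sprintf("tracer_%02d.tif", i)))
      jn <- read_junctions_csv(
        file.path(seg_dir, sprintf("detected_%02d.csv", i)))
      q <- quantify_image(tr, jn, do.call(threshold_params, cfg$threshold),
                          cfg$distance_threshold_px)
      write_spots_csv(q$spots,
                      file.path(q_dir, sprintf("spots_%02d.csv", i)),
                      q$association$assignment)
      rows[[i]] <- report_as_row(q$report, image = i)
    }
    write.csv(do.call(rbind, rows), file.path(q_dir, "reports.csv"),
              row.names = FALSE)
    file.create(file.path(q_dir, ".done"))
  }
  manifest$stages$quantify <- list(key = q_key, dir = q_dir)

  reports <- read.csv(file.path(q_dir, "reports.csv"))
  means <- colMeans(reports[c("fraction_permeable", "total_accumulation",
                              "tj_fraction", "mean_per_permeable")],
                    na.rm = TRUE)
  manifest$stages$summarize <- list(means = as.list(means))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

.fill_config <- function(config) {
  cfg <- list(seed = 1L, field = list(height_px = 256, width_px = 256,
                                      n_cells = 60),
              render = list(), tracer = list(preset = "untreated"),
              segmentation = list(method = "truth"),
              threshold = list(), distance_threshold_px = 2, n_images = 3L)
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_images <- as.integer(cfg$n_images)
  cfg
}

.tracer_from_config <- function(tr) {
  if (!is.null(tr$preset)) condition_preset(tr$preset)
  else do.call(tracer_params, tr)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
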