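# One-config end-to-end pipeline: forge -> score -> scatter -> dataset ->
# train, with resumable stages and config snapshots next to every artifact.

#' Pipeline configuration
#'
#' A single nested list drives the whole pipeline; every entry has a
#' default. `read_pipeline_config()` overlays a YAML file on these
#' defaults.
#'
#' @param n_conformations Ensemble size.
#' @param seed Master seed for forging, splitting and training.
#' @param ranges Arguments for [ensemble_ranges()].
#' @param conditions Condition table; default the nine documented salts.
#' @param qgrid Arguments for [make_qgrid()].
#' @param r_bead Gaussian bead width (Angstrom).
#' @param fractions Train/validation/test fractions.
#' @param descriptors Descriptors to train.
#' @param variants Training variants to run, a subset of
#'   `c("noise_free", "noisy", "sparse", "dense", "random")`.
#' @param training Arguments for [training_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_conformations = 200,
                            seed = 1L,
                            ranges = list(),
                            conditions = default_conditions(),
                            qgrid = list(qmin = 0, qmax = 0.95, spacing = 0.005),
                            r_bead = 2.5,
                            fractions = c(0.68, 0.17, 0.15),
                            descriptors = .waxs_descriptors,
                            variants = c("noise_free", "noisy", "sparse",
                                         "dense", "random"),
                            training = list()) {
  structure(list(n_conformations = n_conformations, seed = as.integer(seed),
                 ranges = ranges, conditions = conditions, qgrid = qgrid,
                 r_bead = r_bead, fractions = fractions,
                 descriptors = descriptors, variants = variants,
                 training = training),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose entries override the defaults.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  cfg <- utils::modifyList(unclass(base), user)
  cfg$conditions <- as_tibble(as.data.frame(cfg$conditions))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full pipeline
#'
#' Forge a synthetic ensemble, score its descriptors, scatter it under all
#' conditions, assemble and split the labeled dataset, and train the
#' requested model variants for every descriptor. Each stage writes its
#' artifact into `out_dir` together with a config snapshot; rerunning with
#' the same configuration resumes from existing artifacts (the dataset is
#' regenerated deterministically from the seed if its file was deleted),
#' while a differing configuration in a non-empty directory is an error —
#' artifacts are never silently overwritten.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the ensemble manifest, descriptor table,
#'   dataset and the trained bundles (`models[[descriptor]][[variant]]`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a `pipeline_config`.")
  hash <- config_hash(config)
  hash_file <- file.path(out_dir, "config_hash.txt")
  if (dir.exists(out_dir) && file.exists(hash_file)) {
    old <- readLines(hash_file)[1]
    if (!identical(old, hash)) {
      abort(sprintf("Output directory '%s' holds artifacts from a different configuration; refusing to overwrite.", out_dir))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(hash, hash_file)
  cfg_out <- unclass(config)
  cfg_out$conditions <- as.data.frame(cfg_out$conditions)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[forge] %d conformations (seed %d)", config$n_conformations, config$seed)
  ranges <- do.call(ensemble_ranges, config$ranges)
  models <- sample_ensemble(config$n_conformations, ranges, seed = config$seed)
  manifest <- ensemble_manifest(models)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

  ds_file <- file.path(out_dir, "dataset.rds")
  if (file.exists(ds_file)) {
    say("[dataset] resuming from %s", ds_file)
    ds <- readRDS(ds_file)
    desc <- ds$labels[!duplicated(ds$labels$conformation_id), ]
  } else {
    say("[score+scatter] descriptors and Debye profiles under %d conditions",
        nrow(config$conditions))
    qgrid <- do.call(make_qgrid, config$qgrid)
    ds <- assemble_dataset(models, conditions = config$conditions,
                           qgrid = qgrid, r_bead = config$r_bead)
    ds <- split_by_conformation(ds, fractions = config$fractions,
                                seed = config$seed)
    saveRDS(ds, ds_file)
    desc <- ds$labels[!duplicated(ds$labels$conformation_id), ]
    utils::write.csv(desc, file.path(out_dir, "descriptors.csv"),
                     row.names = FALSE)
    write_dataset_csv(ds, file.path(out_dir, "dataset.csv"))
  }

  tcfg <- do.call(training_config, c(config$training,
                                     list(seed = config$seed)))
  all_variants <- list(
    noise_free = identity,
    noisy = function(d) add_noise(d, 0.05, seed = config$seed, rows = "train"),
    sparse = function(d) resample_qgrid(d, 100),
    dense = function(d) resample_qgrid(d, 400),
    random = function(d) randomize_labels(d, seed = config$seed)
  )
  bundles <- list()
  for (desc_name in config$descriptors) {
    bundles[[desc_name]] <- list()
    for (v in config$variants) {
      bdir <- file.path(out_dir, "models", desc_name, v)
      if (file.exists(file.path(bdir, "report.json"))) {
        say("[train] resuming %s/%s", desc_name, v)
        bundles[[desc_name]][[v]] <- load_model_bundle(bdir)
        next
      }
      say("[train] %s / %s", desc_name, v)
      m <- train_descriptor_model(all_variants[[v]](ds), desc_name, tcfg)
      save_model_bundle(m, bdir)
      bundles[[desc_name]][[v]] <- m
    }
  }

  summary <- purrr::map_dfr(bundles, function(per_desc) {
    purrr::imap_dfr(per_desc, function(m, v) {
      dplyr::mutate(glance(m), variant = v, .before = 1)
    })
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %s", out_dir)
  invisible(list(manifest = manifest, descriptors = desc, dataset = ds,
                 models = bundles, summary = summary))
}
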