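# End-to-end orchestration: simulate -> retrieve -> reconstruct ->
# (stitch) -> segment -> quantify -> compare, with per-stage seed fan-out,
# artefact writing and a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter blocks. `samples` is a list of phantom
#' parameter blocks (each a list understood by [phantom_params()], plus
#' optional `sample_id`, `stage`, `age_unit`, `age_value`); the same
#' geometry and processing settings are applied to every sample. The
#' single global `seed` fans out deterministically to per-stage seeds
#' (stage seed = seed * 97 + stage offset, mod 2^31), so stages are
#' individually reproducible without seed reuse.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory; created if missing.
#' @param samples List of per-sample phantom blocks.
#' @param geometry Parameter block for [ct_geometry()].
#' @param retrieval List: `delta_beta` (numeric, `"matched"` to use the
#'   cortex material ratio, or `"adaptive"`), `candidates` (for adaptive),
#'   `criterion`.
#' @param reconstruction List: `filter`, `apodization`.
#' @param segmentation List: `interval` (annotate every k-th slice),
#'   `num_trees`, `hb_method` (`"rule"` = intensity rule inside the
#'   classifier's medulla support, `"classifier"` = HB class of the
#'   forest), `q_hi`, `q_lo`, `min_component`.
#' @param quantification List: `n_slices` (NULL = all slices),
#'   `hb_in_medulla` convention flag.
#' @param materials A [material_table()].
#' @return A `pipeline_config` object (YAML-serialisable).
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = file.path(tempdir(), "pcctomo_run"),
                            samples = list(
                              list(sample_id = "foetal_demo", stage = "foetal",
                                   age_unit = "GW", age_value = 15,
                                   target_medulla_frac = 0.38,
                                   n_lobules = 1, interlobular_gap = 20),
                              list(sample_id = "postnatal_demo",
                                   stage = "postnatal", age_unit = "MPN",
                                   age_value = 5,
                                   target_medulla_frac = 0.22,
                                   n_lobules = 4, interlobular_gap = 0,
                                   target_hb_frac = 0.25)),
                            geometry = list(n_angles = 180),
                            retrieval = list(delta_beta = "matched"),
                            reconstruction = list(filter = "ram-lak",
                                                  apodization = "none"),
                            segmentation = list(interval = 10L,
                                                num_trees = 100L,
                                                hb_method = "rule",
                                                q_hi = 0.99, q_lo = 0.01,
                                                min_component = 50L),
                            quantification = list(n_slices = NULL,
                                                  hb_in_medulla = TRUE),
                            materials = material_table()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 samples = samples, geometry = geometry,
                 retrieval = retrieval, reconstruction = reconstruction,
                 segmentation = segmentation,
                 quantification = quantification, materials = materials),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly (the materials table is stored by columns).
#' @param config A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$materials <- list(energy_kev = attr(config$materials, "energy_kev"),
                      columns = as.list(config$materials))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  mt <- tibble::as_tibble(x$materials$columns)
  attr(mt, "energy_kev") <- x$materials$energy_kev
  x$materials <- mt
  do.call(pipeline_config, x)
}

run_stage <- function(name, verbose, expr) {
  if (verbose) message(sprintf("[pcctomo] stage %s ...", name))
  tryCatch(force(expr), error = function(e)
    abort(sprintf("pipeline stage `%s` failed: %s", name,
                  conditionMessage(e))))
}

#' Run the full pipeline on a configuration
#'
#' Executes, per sample: phantom generation, material assignment, projection
#' simulation, Paganin retrieval, filtered backprojection (with the
#' half-acquisition stitch when the geometry is a 360-degree scan),
#' sparse-annotation segmentation (ground-truth labels every k-th slice
#' stand in for the manual annotations), HB detection and quantification;
#' then compares medulla content between stages when both are present.
#' All artefacts (TIFF stacks, CSV records, JSON comparison) are written
#' under `config$out_dir` together with the fully resolved configuration
#' and a manifest of seeds and artefact checksums; identical config and
#' seed give bit-identical artefacts.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return The manifest, invisibly; `$records` holds the quantification
#'   tibble and `$comparison` the tidied group comparison (or NULL).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config"))
    abort("`config` must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
  geom <- do.call(ct_geometry, config$geometry)
  mt <- config$materials
  db_cfg <- config$retrieval$delta_beta %||% "matched"
  artefacts <- character(0)
  records <- list()

  for (i in seq_along(config$samples)) {
    blk <- config$samples[[i]]
    sid <- blk$sample_id %||% sprintf("sample%02d", i)
    meta <- blk[intersect(names(blk),
                          c("stage", "age_unit", "age_value"))]
    pp_args <- blk[intersect(names(blk), names(formals(phantom_params)))]
    pp_args$rng_seed <- stage_seed(config$seed, 10L + i)
    phantom <- run_stage(paste0("phantom:", sid), verbose,
                         generate_thymus_phantom(do.call(phantom_params,
                                                         pp_args)))
    ph_path <- file.path(config$out_dir, paste0(sid, "_labels.tif"))
    write_phantom(phantom, ph_path)

    rv <- run_stage(paste0("materials:", sid), verbose,
                    assign_materials(phantom, mt))
    pset <- run_stage(paste0("simulate:", sid), verbose,
                      acquire(rv, geom, seed = stage_seed(config$seed,
                                                          20L + i)))

    db <- if (identical(db_cfg, "matched") || identical(db_cfg, "adaptive")) {
      cortex_row <- mt[mt$name == "cortex", ]
      cortex_row$delta / cortex_row$beta
    } else as.numeric(db_cfg)
    if (identical(db_cfg, "adaptive")) {
      mid <- pset$data[ceiling(dim(pset$data)[1] / 2), , , drop = TRUE]
      sel <- run_stage(paste0("adaptive-db:", sid), verbose,
                       adaptive_delta_beta(
                         mid, config$retrieval$candidates %||%
                           (db * c(0.25, 1, 4)),
                         geom, criterion = "negativity"))
      db <- sel$delta_beta
    }
    tset <- run_stage(paste0("retrieve:", sid), verbose,
                      retrieve_projections(pset,
                                           retrieval_params(db, geom)))
    if (geom$angular_range == 360)
      tset <- run_stage(paste0("stitch:", sid), verbose,
                        halfacq_stitch(tset))
    recon <- run_stage(paste0("reconstruct:", sid), verbose,
                       reconstruct_volume(
                         tset,
                         filter = config$reconstruction$filter %||% "ram-lak",
                         apodization =
                           config$reconstruction$apodization %||% "none"))
    rc_path <- file.path(config$out_dir, paste0(sid, "_recon.tif"))
    write_tiff_stack(recon$voxels, rc_path, type = "float32")

    segcfg <- config$segmentation
    ann <- annotate_every_kth(phantom, interval = segcfg$interval %||% 10L)
    masks <- run_stage(paste0("segment:", sid), verbose,
                       propagate_annotations(
                         recon, ann,
                         num_trees = segcfg$num_trees %||% 100L,
                         seed = stage_seed(config$seed, 30L + i)))
    if (identical(segcfg$hb_method %||% "rule", "rule")) {
      support <- masks$medulla | masks$hb
      hb <- run_stage(paste0("segment-hb:", sid), verbose,
                      segment_hbs(recon, support,
                                  reference_mask = masks$medulla,
                                  q_hi = segcfg$q_hi %||% 0.99,
                                  q_lo = segcfg$q_lo %||% 0.01,
                                  min_component =
                                    segcfg$min_component %||% 50L))
      masks <- compartment_masks(cortex = masks$cortex & !hb,
                                 medulla = support & !hb, hb = hb)
    }
    mask_path <- file.path(config$out_dir, paste0(sid, "_masks.tif"))
    write_tiff_stack(
      array(masks$cortex * PHANTOM_LABELS[["cortex"]] +
              masks$medulla * PHANTOM_LABELS[["medulla"]] +
              masks$hb * PHANTOM_LABELS[["hb"]],
            dim = dim(masks$cortex)),
      mask_path, type = "uint8")

    qc <- config$quantification
    qmasks <- if (!is.null(qc$n_slices))
      select_central_slices(masks, qc$n_slices) else masks
    records[[i]] <- run_stage(paste0("quantify:", sid), verbose,
                              quantify_masks(
                                qmasks, sid,
                                stage = meta$stage %||% "foetal",
                                age_unit = meta$age_unit %||% NA_character_,
                                age_value = meta$age_value %||% NA_real_,
                                hb_in_medulla =
                                  isTRUE(qc$hb_in_medulla)))
    artefacts <- c(artefacts, ph_path, rc_path, mask_path)
  }

  records <- dplyr::bind_rows(records)
  csv_path <- file.path(config$out_dir, "quantification.csv")
  write_quant_csv(records, csv_path)
  artefacts <- c(artefacts, csv_path)

  comparison <- NULL
  if (length(unique(records$stage)) == 2L &&
      sum(!is.na(records$medulla_pct)) >= 2L) {
    cmp <- run_stage("compare", verbose,
                     compare_groups(records, "stage", "medulla_pct"))
    comparison <- tidy(cmp)
    jsonlite::write_json(comparison,
                         file.path(config$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    artefacts <- c(artefacts,
                   file.path(config$out_dir, "comparison.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pcctomo")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = list(phantom = stage_seed(config$seed, 11L),
                       noise = stage_seed(config$seed, 21L),
                       segmentation = stage_seed(config$seed, 31L)),
    artefacts = as.list(setNames(unname(tools::md5sum(artefacts)),
                                 basename(artefacts))),
    records = records,
    comparison = comparison)
  jsonlite::write_json(
    manifest[c("package_version", "r_version", "seed", "stage_seeds",
               "artefacts")],
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
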