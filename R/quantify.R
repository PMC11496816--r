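# Normalised compartment-content measures: volumetric medulla content over
# cortex+medulla, HB content over the medulla, the 2D histology analogue,
# and the flow-cytometry analogue; plus the fixed-budget central-slice
# selection used to compare samples of different sizes on equal footing.

#' Select the central n slices of a volume
#'
#' Returns slices `[floor((N - n)/2), floor((N - n)/2) + n)` (0-based,
#' half-open; ties in the centring broken towards the lower start index).
#' `N = n` is the identity.
#'
#' @param x A 3D array, `recon_volume`, `phantom_volume` or
#'   `compartment_masks`.
#' @param n Number of slices to keep (default 300, the per-sample budget
#'   used for all quantitative comparisons).
#' @return Object of the same class restricted to the selected slices.
#' @export
select_central_slices <- function(x, n = 300L) {
  N <- if (inherits(x, "compartment_masks")) dim(x$cortex)[1]
  else if (inherits(x, "recon_volume")) dim(x$voxels)[1]
  else if (inherits(x, "phantom_volume")) dim(x$labels)[1]
  else dim(x)[1]
  if (N < n)
    abort(sprintf(
      "volume has %d slices < n = %d: lower `n` to quantify this sample",
      N, n))
  start <- floor((N - n) / 2)            # 0-based
  idx <- seq(start + 1L, start + n)      # 1-based
  if (inherits(x, "compartment_masks")) {
    compartment_masks(cortex = x$cortex[idx, , , drop = FALSE],
                      medulla = x$medulla[idx, , , drop = FALSE],
                      hb = x$hb[idx, , , drop = FALSE],
                      labels = if (!is.null(x$labels))
                        x$labels[idx, , , drop = FALSE],
                      slice_range = c(start + 1L, start + n))
  } else if (inherits(x, "recon_volume")) {
    recon_volume(x$voxels[idx, , , drop = FALSE], x$voxel_pitch,
                 provenance = c(x$provenance,
                                list(central_slices = c(start + 1L, start + n))))
  } else if (inherits(x, "phantom_volume")) {
    x$labels <- x$labels[idx, , , drop = FALSE]
    x$label_counts <- label_counts(x$labels)
    x
  } else {
    x[idx, , , drop = FALSE]
  }
}

#' Volumetric medulla content (%)
#'
#' `100 * V_medulla / (V_medulla + V_cortex)`: the volumetric percentage of
#' the medulla over the core thymic tissue (cortex and medulla combined).
#' By default HB voxels are excluded from both terms; with
#' `hb_in_medulla = TRUE` they count as medulla in numerator and
#' denominator (the HB-inclusive convention; both are reported in logs
#' because the choice is a declared convention, not a measurement).
#'
#' @param masks A [compartment_masks()].
#' @param hb_in_medulla Count HB voxels as medulla.
#' @return Percentage in \[0, 100\].
#' @export
medulla_content <- function(masks, hb_in_medulla = FALSE) {
  v_med <- sum(masks$medulla) + if (hb_in_medulla) sum(masks$hb) else 0
  v_cor <- sum(masks$cortex)
  if (v_med + v_cor == 0)
    abort("empty masks: cortex + medulla volume is zero")
  100 * v_med / (v_med + v_cor)
}

#' Volumetric Hassall's-body content (%)
#'
#' `100 * V_HB / (V_medulla + V_HB)`: the volumetric percentage of the HBs
#' over the (HB-inclusive) medulla.
#'
#' @param masks A [compartment_masks()].
#' @return Percentage in \[0, 100\].
#' @export
hb_content <- function(masks) {
  v_med <- sum(masks$medulla); v_hb <- sum(masks$hb)
  if (v_med + v_hb == 0) abort("empty medulla: cannot normalise HB volume")
  100 * v_hb / (v_med + v_hb)
}

#' Histology-based relative medulla area (%)
#'
#' The 2D analogue of [medulla_content()] on a single section:
#' `100 * A_medulla / (A_medulla + A_cortex)`.
#'
#' @param medulla,cortex Logical 2D masks of identical shape.
#' @return Percentage in \[0, 100\].
#' @export
histology_area_content <- function(medulla, cortex) {
  if (!identical(dim(medulla), dim(cortex)))
    abort("masks must share one shape")
  a_med <- sum(medulla); a_cor <- sum(cortex)
  if (a_med + a_cor == 0) abort("empty masks: cortex + medulla area is zero")
  100 * a_med / (a_med + a_cor)
}

#' FACS-based medulla content (%)
#'
#' Medullary epithelial cell content relative to total epithelial cells:
#' `100 * med / (med + cort)` from exported medullary (EpCAM+ CD205-) and
#' cortical (CD205+ EpCAM low) percentages. Invariant under common
#' rescaling of both inputs.
#'
#' @param medullary_pct,cortical_pct Non-negative cell percentages (or
#'   counts) with a positive sum.
#' @return Percentage in \[0, 100\].
#' @export
facs_medulla_content <- function(medullary_pct, cortical_pct) {
  if (any(medullary_pct < 0) || any(cortical_pct < 0))
    abort("inputs must be non-negative")
  s <- medullary_pct + cortical_pct
  if (any(s <= 0)) abort("medullary + cortical input must be positive")
  100 * medullary_pct / s
}

#' Quantify one sample's masks into a record
#'
#' @param masks A [compartment_masks()].
#' @param sample_id Sample identifier.
#' @param stage `"foetal"` or `"postnatal"`.
#' @param age_unit,age_value Age metadata (e.g. `"GW"`, 15; `"MPN"`, 3;
#'   `"CS"`, 23). Consistency with the stage is enforced: CS/GW are foetal
#'   units, MPN/days postnatal.
#' @param source Measurement source tag.
#' @param hb_in_medulla Convention flag passed to [medulla_content()].
#' @return A one-row tibble: sample_id, stage, age_unit, age_value,
#'   medulla_pct, hb_pct (NA when no HB mask voxels exist and none were
#'   sought), n_slices, source.
#' @export
quantify_masks <- function(masks, sample_id, stage = c("foetal", "postnatal"),
                           age_unit = NA_character_, age_value = NA_real_,
                           source = c("pcct", "histology", "facs"),
                           hb_in_medulla = FALSE) {
  stage <- match.arg(stage)
  source <- match.arg(source)
  if (!is.na(age_unit)) {
    foetal_units <- c("CS", "GW"); postnatal_units <- c("MPN", "days")
    if (stage == "foetal" && age_unit %in% postnatal_units ||
        stage == "postnatal" && age_unit %in% foetal_units)
      abort(sprintf("age unit %s inconsistent with stage %s", age_unit, stage))
  }
  tibble::tibble(
    sample_id = as.character(sample_id), stage = stage,
    age_unit = age_unit, age_value = age_value,
    medulla_pct = medulla_content(masks, hb_in_medulla = hb_in_medulla),
    hb_pct = hb_content(masks),
    n_slices = dim(masks$cortex)[1],
    source = source)
}

#' Read / write quantification records as CSV
#'
#' The schema is one record per row with columns sample_id, stage,
#' age_unit, age_value, medulla_pct, hb_pct, n_slices, source. A named
#' `col_map` allows ingesting externally produced per-sample tables whose
#' columns are named differently (values of `col_map` are the external
#' names, names are the schema names).
#'
#' @param records Tibble of quantification records.
#' @param path CSV path.
#' @param col_map Optional named character vector mapping schema columns to
#'   the file's column names.
#' @return `write_quant_csv()` returns `path` invisibly; `read_quant_csv()`
#'   a tibble in schema order.
#' @export
write_quant_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path, col_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (schema_name in names(col_map)) {
      ext <- col_map[[schema_name]]
      if (!ext %in% names(df))
        abort(sprintf("mapped column `%s` absent from %s", ext, path))
      df[[schema_name]] <- df[[ext]]
    }
  }
  want <- c("sample_id", "stage", "age_unit", "age_value", "medulla_pct",
            "hb_pct", "n_slices", "source")
  missing <- setdiff(c("sample_id", "stage", "medulla_pct"), names(df))
  if (length(missing))
    abort(sprintf("quantification CSV lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  for (w in setdiff(want, names(df))) df[[w]] <- NA
  out <- tibble::as_tibble(df[want])
  bad <- with(out, !is.na(medulla_pct) & (medulla_pct < 0 | medulla_pct > 100))
  if (any(bad)) abort("medulla_pct outside [0, 100]")
  out
}
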