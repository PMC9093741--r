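#' Radial intensity profile around a soma center
#'
#' Mean intensity over concentric annuli of one pixel width, normalized to the
#' profile maximum (so the output peaks at 1). Used to quantify NeuN staining
#' around candidate somata.
#'
#' @param image Numeric matrix.
#' @param center Length-2 vector `(row, col)` of the soma center, pixels.
#' @param r_max_um Maximal radius in um.
#' @param px_size_um Pixel size in um.
#' @return Tibble with `radius_um` (annulus outer edge) and `intensity`
#'   (normalized to max 1).
#' @export
radial_profile <- function(image, center, r_max_um, px_size_um = 1) {
  stopifnot(is.matrix(image), length(center) == 2, r_max_um > 0)
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image)) {
    rlang::abort("center falls outside the image")
  }
  r_max_px <- r_max_um / px_size_um
  rows <- max(1, floor(center[1] - r_max_px)):min(nrow(image),
                                                  ceiling(center[1] + r_max_px))
  cols <- max(1, floor(center[2] - r_max_px)):min(ncol(image),
                                                  ceiling(center[2] + r_max_px))
  g <- expand.grid(row = rows, col = cols)
  r <- sqrt((g$row - center[1])^2 + (g$col - center[2])^2)
  keep <- r <= r_max_px
  ann <- floor(r[keep]) + 1L
  vals <- image[(g$col[keep] - 1) * nrow(image) + g$row[keep]]
  prof <- tapply(vals, ann, mean)
  out <- tibble::tibble(
    radius_um = as.numeric(names(prof)) * px_size_um,
    intensity = as.numeric(prof)
  )
  if (max(out$intensity) <= 0) {
    rlang::abort("all-zero image: radial profile cannot be normalized")
  }
  out$intensity <- out$intensity / max(out$intensity)
  out
}

#' Classify a soma as neuron or non-neuron from its NeuN profile
#'
#' A cell is a neuron if its normalized NeuN radial intensity exceeds 20 %
#' anywhere within a 2 um radius (strict inequality at the boundary).
#'
#' @param profile Tibble from [radial_profile()] of the NeuN channel,
#'   covering at least 2 um.
#' @param r_um Radius within which the criterion applies.
#' @param threshold Normalized-intensity threshold.
#' @return `"neuron"` or `"non-neuron"`.
#' @export
classify_by_neun <- function(profile, r_um = 2, threshold = 0.20) {
  if (max(profile$radius_um) < r_um) {
    rlang::abort("profile must cover at least the classification radius")
  }
  inner <- profile$intensity[profile$radius_um <= r_um]
  if (any(inner > threshold)) "neuron" else "non-neuron"
}

#' Classify somata as neurons or non-neurons by area
#'
#' IO neurons and non-neurons (mostly astrocytes) separate on soma area: the
#' 5th percentile of neuron areas and the 95th percentile of non-neuron areas
#' straddle 100 um^2, so a strict `area > 100 um^2` rule labels neurons.
#'
#' @param somata Data frame with an `area_um2` column (e.g. from
#'   [simulate_anatomy()]).
#' @param threshold_um2 Area threshold.
#' @return The input as a tibble with a `label` column added.
#' @export
classify_by_area <- function(somata, threshold_um2 = 100) {
  stopifnot("area_um2" %in% names(somata))
  dplyr::mutate(tibble::as_tibble(somata),
                label = ifelse(.data$area_um2 > threshold_um2,
                               "neuron", "non-neuron"))
}

#' Reference-normalized expression
#'
#' Per-soma test-transgene intensity (EGFP) divided by the co-expressed
#' reference-transgene intensity (tdTomato), removing local transfection-level
#' variation.
#'
#' @param test_mean,reference_mean Per-soma mean channel intensities.
#' @return Numeric ratios.
#' @export
normalized_expression <- function(test_mean, reference_mean) {
  if (any(reference_mean <= 0)) {
    rlang::abort("reference intensities must be positive")
  }
  test_mean / reference_mean
}

#' Structural specificity of labeling relative to a region
#'
#' Each channel is thresholded at `mean + z * SD` of its whole-image
#' histogram (Z = 3 by default); supra-threshold pixels count as labeled.
#' Inside and outside the region mask separately, the spatial-extent ratio is
#' labeled-area(test) / labeled-area(ref) and the intensity ratio the
#' analogous ratio of mean supra-threshold intensities. Compartments with no
#' supra-threshold reference pixels yield `NA` (undefined, not zero).
#'
#' @param test_image,ref_image Co-registered numeric matrices.
#' @param io_mask Logical matrix marking the region (e.g. the IO contour).
#' @param z Z-score threshold.
#' @return One-row tibble: `inside_extent_ratio`, `outside_extent_ratio`,
#'   `inside_intensity_ratio`, `outside_intensity_ratio`.
#' @export
structure_specificity <- function(test_image, ref_image, io_mask, z = 3) {
  stopifnot(all(dim(test_image) == dim(ref_image)),
            all(dim(test_image) == dim(io_mask)))
  lab_t <- test_image > mean(test_image) + z * stats::sd(test_image)
  lab_r <- ref_image > mean(ref_image) + z * stats::sd(ref_image)
  comp <- function(region) {
    nt <- sum(lab_t & region); nr <- sum(lab_r & region)
    ext <- if (nr == 0) NA_real_ else nt / nr
    int <- if (nr == 0 || nt == 0) NA_real_ else {
      mean(test_image[lab_t & region]) / mean(ref_image[lab_r & region])
    }
    c(ext, int)
  }
  ins <- comp(io_mask); outs <- comp(!io_mask)
  tibble::tibble(inside_extent_ratio = ins[1], outside_extent_ratio = outs[1],
                 inside_intensity_ratio = ins[2],
                 outside_intensity_ratio = outs[2])
}

#' Nearest-neighbour distances between soma centers
#'
#' Per-cell shortest Euclidean distance to any other center.
#'
#' @param centroids Two-column matrix or data frame of coordinates (um).
#' @return Numeric vector, one distance per centroid.
#' @export
nn_distances <- function(centroids) {
  x <- as.matrix(as.data.frame(centroids))
  if (nrow(x) < 2) rlang::abort("at least 2 centroids are required")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Cell-type preference of a construct
#'
#' Labeled-neuron and labeled-astrocyte counts of a test construct are each
#' normalized by the counts obtained with the control virus; the preference is
#' the percent excess of the neuron enrichment over the astrocyte enrichment
#' (positive = neuron-preferring):
#' `((test_n/ref_n) / (test_a/ref_a) - 1) * 100`.
#'
#' @param test_counts,ref_counts Named vectors or lists with elements
#'   `neuron` and `astro`.
#' @return Percent preference.
#' @export
cell_type_preference <- function(test_counts, ref_counts) {
  tn <- test_counts[["neuron"]]; ta <- test_counts[["astro"]]
  rn <- ref_counts[["neuron"]]; ra <- ref_counts[["astro"]]
  if (rn <= 0 || ra <= 0 || ta <= 0) {
    rlang::abort("reference and test astrocyte counts must be positive")
  }
  ((tn / rn) / (ta / ra) - 1) * 100
}
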