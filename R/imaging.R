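#' Scanner resolution to physical pixel size
#'
#' @param dpi scanner resolution in dots per inch; positive.
#' @return pixel edge length in micrometres (`25400 / dpi`); 2400 dpi gives
#'   10.58 um (commonly reported as 10.6 um).
#' @export
#' @examples
#' pixel_size_from_dpi(2400)
pixel_size_from_dpi <- function(dpi) {
  if (!is.numeric(dpi) || any(!is.finite(dpi) | dpi <= 0))
    stop("'dpi' must be positive", call. = FALSE)
  25400 / dpi
}

#' Net-tow sampling geometry
#'
#' Describes how a zooplankton net sample relates to the water column:
#' a net of `net_diameter_m` pulled vertically through `tow_depth_m` of
#' water, concentrated into `madeup_volume_ml` of filtered seawater, of
#' which `subsample_volume_ml` is imaged. Defaults correspond to an Apstein
#' net of 17 cm diameter towed from 17 m depth, made up to 500 mL, with a
#' 20 mL (4 %) subsample scanned.
#'
#' @param net_diameter_m net mouth diameter in metres.
#' @param tow_depth_m vertical tow length in metres.
#' @param madeup_volume_ml volume the concentrated sample is made up to, mL.
#' @param subsample_volume_ml imaged subsample volume, mL; at most
#'   `madeup_volume_ml`.
#' @return object of class `"sampling_geometry"`.
#' @seealso [tow_volume()], [effective_subsample_volume()]
#' @export
sampling_geometry <- function(net_diameter_m = 0.17, tow_depth_m = 17,
                              madeup_volume_ml = 500,
                              subsample_volume_ml = 20) {
  vals <- c(net_diameter_m, tow_depth_m, madeup_volume_ml, subsample_volume_ml)
  if (any(!is.finite(vals) | vals <= 0))
    stop("all geometry fields must be positive", call. = FALSE)
  if (subsample_volume_ml > madeup_volume_ml)
    stop("subsample volume cannot exceed made-up volume", call. = FALSE)
  structure(list(net_diameter_m = net_diameter_m, tow_depth_m = tow_depth_m,
                 madeup_volume_ml = madeup_volume_ml,
                 subsample_volume_ml = subsample_volume_ml),
            class = "sampling_geometry")
}

#' @export
print.sampling_geometry <- function(x, ...) {
  cat(sprintf(paste0("net tow: %.2f m mouth diameter x %.1f m depth ",
                     "(%.1f L), %g / %g mL imaged -> effective %.2f L\n"),
              x$net_diameter_m, x$tow_depth_m, tow_volume(x),
              x$subsample_volume_ml, x$madeup_volume_ml,
              effective_subsample_volume(x)))
  invisible(x)
}

#' Water volume sampled by a vertical net tow
#'
#' Cylinder swept by the net mouth: `pi * (d/2)^2 * depth`, in litres.
#'
#' @param geometry a [sampling_geometry()].
#' @return tow volume in litres.
#' @export
tow_volume <- function(geometry = sampling_geometry()) {
  stopifnot(inherits(geometry, "sampling_geometry"))
  pi * (geometry$net_diameter_m / 2)^2 * geometry$tow_depth_m * 1000
}

#' Effective water volume represented by the imaged subsample
#'
#' The scanned subsample is `subsample/madeup` of the whole net catch, so
#' it represents that fraction of the tow volume. With the default geometry
#' this is 4 % of ~385 L = 15.4 L.
#'
#' @inheritParams tow_volume
#' @return effective volume in litres.
#' @export
effective_subsample_volume <- function(geometry = sampling_geometry()) {
  stopifnot(inherits(geometry, "sampling_geometry"))
  tow_volume(geometry) * geometry$subsample_volume_ml / geometry$madeup_volume_ml
}

# ---------------------------------------------------------------------------
# segmentation

# internal: 8-connected component labelling of a logical matrix by
# run-length union-find. Returns an integer matrix of labels (0 =
# background). Row runs in adjacent image rows are merged when their column
# spans overlap or touch diagonally (+/- 1 column).
label_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  runs <- vector("list", nr)
  for (r in seq_len(nr)) {
    v <- bw[r, ]
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    runs[[r]] <- cbind(row = r, start = starts[fg], end = ends[fg])
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(matrix(0L, nr, nc))
  n <- nrow(runs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  row_of <- runs[, "row"]
  idx_by_row <- split(seq_len(n), row_of)
  for (r in as.integer(names(idx_by_row))) {
    above <- idx_by_row[[as.character(r - 1L)]]
    if (is.null(above)) next
    for (i in idx_by_row[[as.character(r)]]) {
      # 8-connectivity: spans within one column of each other touch
      touching <- above[runs[above, "start"] <= runs[i, "end"] + 1L &
                        runs[above, "end"] >= runs[i, "start"] - 1L]
      for (j in touching) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  out <- matrix(0L, nr, nc)
  for (i in seq_len(n))
    out[runs[i, "row"], runs[i, "start"]:runs[i, "end"]] <- labels[i]
  out
}

#' Segment a greyscale scan plate into objects
#'
#' Thresholds the image (objects are darker than the background, the usual
#' appearance of organisms on a transmissive flatbed scan), labels
#' 8-connected components, discards components below a minimum pixel area,
#' and flags components touching the image border.
#'
#' @param image a `scan_image` (see [render_scan_plate()], [read_scan()]) or
#'   a numeric matrix of grey levels 0-255.
#' @param grey_threshold grey level strictly below which a pixel is object.
#' @param min_area_px smallest retained component area in pixels. The
#'   default 64 px is approximately the pixel count of a 150 um disk at
#'   10.6 um/pixel, matching the minimum size of reliably classifiable
#'   organisms.
#' @return object of class `"scan_masks"`: a list with elements `masks`
#'   (list of two-column matrices of pixel (row, col) indices), `border`
#'   (logical, component touches the plate edge), `n_discarded_small`
#'   (components removed by the area filter) and `dpi` (carried over from
#'   the image, if any).
#' @export
segment_scan <- function(image, grey_threshold, min_area_px = 64L) {
  dpi <- attr(image, "dpi")
  img <- unclass(image)
  stopifnot(is.matrix(img), is.numeric(img))
  if (grey_threshold < 0 || grey_threshold > 255)
    stop("'grey_threshold' must lie in [0, 255]", call. = FALSE)
  bw <- img < grey_threshold
  if (all(bw))
    stop("every pixel is below the threshold: implausible plate ",
         "(no background visible)", call. = FALSE)
  lab <- label_components(bw)
  k <- max(lab)
  masks <- list(); border <- logical(0); n_small <- 0L
  if (k > 0L) {
    px <- which(lab > 0L, arr.ind = TRUE)
    by_lab <- split(seq_len(nrow(px)), lab[lab > 0L])
    keep <- vapply(by_lab, length, integer(1)) >= min_area_px
    n_small <- sum(!keep)
    by_lab <- by_lab[keep]
    masks <- lapply(by_lab, function(i) {
      m <- px[i, , drop = FALSE]
      colnames(m) <- c("row", "col")
      m
    })
    border <- vapply(masks, function(m) {
      any(m[, "row"] == 1L | m[, "row"] == nrow(img) |
          m[, "col"] == 1L | m[, "col"] == ncol(img))
    }, logical(1))
    names(masks) <- NULL
  }
  structure(list(masks = masks, border = unname(border),
                 n_discarded_small = n_small, dpi = dpi),
            class = "scan_masks")
}

#' Morphometry of one segmented object
#'
#' Computes size descriptors from a pixel mask: area (pixel count times
#' pixel area), area-equivalent ESD `2 * sqrt(area / pi)`, major and minor
#' axis lengths of the intensity-equivalent ellipse from second-order
#' central moments (with the 1/12-pixel variance of the square pixel
#' footprint added, so a single pixel has a finite axis), and biovolume of
#' the prolate spheroid spanned by the ellipse axes,
#' `(pi/6) * major * minor^2`, reported in cubic millimetres.
#'
#' @param mask two-column matrix of (row, col) pixel indices.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @return one-row data.frame with columns `area_px`, `esd_um`, `major_um`,
#'   `minor_um`, `orientation_rad`, `biovolume_mm3`.
#' @export
measure_object <- function(mask, pixel_size_um) {
  if (is.null(dim(mask)) || nrow(mask) == 0L)
    stop("empty mask", call. = FALSE)
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  n <- nrow(mask)
  area_um2 <- n * pixel_size_um^2
  esd <- 2 * sqrt(area_um2 / pi)
  r <- mask[, 1]; c <- mask[, 2]
  # second-order central moments; + 1/12 for the unit-square pixel footprint
  mrr <- sum((r - mean(r))^2) / n + 1 / 12
  mcc <- sum((c - mean(c))^2) / n + 1 / 12
  mrc <- sum((r - mean(r)) * (c - mean(c))) / n
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2
  l2 <- (mrr + mcc - common) / 2
  major <- 4 * sqrt(l1) * pixel_size_um
  minor <- 4 * sqrt(l2) * pixel_size_um
  theta <- 0.5 * atan2(2 * mrc, mcc - mrr)
  bv <- (pi / 6) * major * minor^2 / 1e9
  data.frame(area_px = n, esd_um = esd, major_um = major, minor_um = minor,
             orientation_rad = theta, biovolume_mm3 = bv)
}

#' Segment and measure a whole scan plate
#'
#' Convenience wrapper: [segment_scan()] followed by [measure_object()] on
#' each retained component.
#'
#' @inheritParams segment_scan
#' @param pixel_size_um physical pixel size; defaults to the dpi carried by
#'   the image.
#' @return imaged-object table: one row per object with an `id` column, the
#'   [measure_object()] features, a `border` flag and a `category` column
#'   initialised to `NA` (taxon labels are assigned externally).
#' @export
measure_scan <- function(image, grey_threshold, min_area_px = 64L,
                         pixel_size_um = NULL) {
  seg <- segment_scan(image, grey_threshold, min_area_px)
  if (is.null(pixel_size_um)) {
    if (is.null(seg$dpi))
      stop("image carries no dpi; supply 'pixel_size_um'", call. = FALSE)
    pixel_size_um <- pixel_size_from_dpi(seg$dpi)
  }
  if (!length(seg$masks)) {
    out <- measure_object(cbind(1L, 1L), pixel_size_um)[0, ]
    out <- cbind(id = integer(), out, border = logical(),
                 category = character())
    return(out)
  }
  feats <- do.call(rbind, lapply(seg$masks, measure_object,
                                 pixel_size_um = pixel_size_um))
  cbind(id = seq_len(nrow(feats)), feats, border = seg$border,
        category = NA_character_, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# object-table filters and classing

#' Remove objects below the minimum classifiable size
#'
#' Image classification needs a minimum number of pixels per object, which
#' translates into a minimum organism size (~150 um ESD at 2400 dpi).
#'
#' @param objects imaged-object table with an `esd_um` column.
#' @param min_esd_um minimum retained ESD in micrometres.
#' @return the filtered table; attribute `n_removed_small` counts removals.
#' @export
apply_min_size_filter <- function(objects, min_esd_um = 150) {
  check_particles(objects, require = "esd_um")
  keep <- objects$esd_um >= min_esd_um
  out <- objects[keep, , drop = FALSE]
  attr(out, "n_removed_small") <- sum(!keep)
  out
}

#' Remove imaging disturbances
#'
#' Objects classified as `"disturbance"` (touching objects, bubbles,
#' scanner artefacts) are subtracted before any abundance, biomass or
#' spectrum computation. Non-living but real material labelled
#' `"other_biomass"` is retained.
#'
#' @param objects imaged-object table with a `category` column (no `NA`s).
#' @return the filtered table; attribute `n_removed_disturbance` counts
#'   removals.
#' @export
remove_disturbances <- function(objects) {
  if (!"category" %in% names(objects))
    stop("'objects' lack a 'category' column", call. = FALSE)
  if (anyNA(objects$category))
    stop("unlabelled objects present; assign categories before filtering",
         call. = FALSE)
  keep <- objects$category != "disturbance"
  out <- objects[keep, , drop = FALSE]
  attr(out, "n_removed_disturbance") <- sum(!keep)
  out
}

#' Copepod body-size classes
#'
#' Copepods (life stages being indistinguishable on scan images) are grouped
#' by ESD into small (S, < 600 um, mostly copepodites), medium
#' (M, 600-1000 um) and large (L, > 1000 um) individuals. Boundaries are
#' half-open `[lower, upper)`: 600 um is M and 1000 um is L.
#'
#' @param esd numeric ESD in micrometres, all at or above `min_esd_um` (the
#'   classification minimum).
#' @param min_esd_um lower limit of classifiable sizes.
#' @return factor with levels `S`, `M`, `L`.
#' @export
#' @examples
#' assign_copepod_class(c(300, 600, 999, 1000, 1500))
assign_copepod_class <- function(esd, min_esd_um = 150) {
  if (length(esd) && (!is.numeric(esd) || any(!is.finite(esd))))
    stop("ESD must be numeric and finite", call. = FALSE)
  if (any(esd < min_esd_um))
    stop("ESD below the classification minimum of ", min_esd_um, " um",
         call. = FALSE)
  cut(esd, breaks = c(min_esd_um, 600, 1000, Inf), labels = c("S", "M", "L"),
      right = FALSE)
}

#' Scale imaged objects to in-situ particle records
#'
#' Each object in the scanned subsample represents `1 / effective_volume_l`
#' individuals per litre of mesocosm water.
#'
#' @param objects imaged-object table with at least `esd_um` and
#'   `biovolume_mm3` columns; `category` becomes the record's `group`.
#' @param effective_volume_l effective sampled volume in litres (see
#'   [effective_subsample_volume()]).
#' @param mesocosm,day identifiers stamped on the records when the object
#'   table does not carry them.
#' @param density_g_cm3 tissue density for the wet-weight conversion.
#' @return particle records (see [particle-records]).
#' @export
objects_to_particles <- function(objects, effective_volume_l,
                                 mesocosm = NA_character_, day = NA_integer_,
                                 density_g_cm3 = 1.060) {
  check_particles(objects, require = c("esd_um", "biovolume_mm3"))
  if (!is.finite(effective_volume_l) || effective_volume_l <= 0)
    stop("'effective_volume_l' must be positive", call. = FALSE)
  if (!nrow(objects)) return(empty_particles())
  data.frame(
    mesocosm = if ("mesocosm" %in% names(objects)) objects$mesocosm else mesocosm,
    day = if ("day" %in% names(objects)) objects$day else day,
    group = if ("category" %in% names(objects)) objects$category
            else if ("group" %in% names(objects)) objects$group
            else "unclassified",
    instrument = "imaging",
    esd_um = objects$esd_um,
    biovolume_mm3 = objects$biovolume_mm3,
    biomass_mg = biomass_from_biovolume(objects$biovolume_mm3, density_g_cm3),
    weight_l = 1 / effective_volume_l,
    stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# image and object-table IO

#' Read / write scan plates
#'
#' Scan plates are 8-bit greyscale PNG images; the physical resolution is
#' stored in a plain-text sidecar file `<path>.dpi.txt` so that images and
#' their scale travel together.
#'
#' @param path PNG file path.
#' @param image a `scan_image` (grey-level matrix 0-255 with a `dpi`
#'   attribute).
#' @return `read_scan()` returns a `scan_image`; `write_scan()` returns
#'   `path` invisibly.
#' @export
read_scan <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  img <- round(arr * 255)
  sidecar <- paste0(path, ".dpi.txt")
  dpi <- if (file.exists(sidecar)) as.numeric(readLines(sidecar)[1]) else NULL
  structure(img, dpi = dpi, class = c("scan_image", class(img)))
}

#' @rdname read_scan
#' @export
write_scan <- function(image, path) {
  img <- unclass(image)
  png::writePNG(img / 255, path)
  dpi <- attr(image, "dpi")
  if (!is.null(dpi)) writeLines(as.character(dpi), paste0(path, ".dpi.txt"))
  invisible(path)
}

#' Read / write imaged-object tables
#'
#' Tab-separated object tables in the style of scanner image-processing
#' toolchains, with at least the columns `id`, `area_px`, `esd_um`,
#' `major_um`, `minor_um`, `biovolume_mm3`, `category`; any extra feature
#' columns pass through untouched.
#'
#' @param path file path.
#' @param objects object table to write.
#' @return `read_objects()` returns the object data.frame; `write_objects()`
#'   returns `path` invisibly.
#' @export
read_objects <- function(path) {
  obj <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "area_px", "esd_um", "major_um", "minor_um",
            "biovolume_mm3", "category")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("object table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  obj
}

#' @rdname read_objects
#' @export
write_objects <- function(objects, path) {
  utils::write.table(objects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
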