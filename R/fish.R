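# FISH spatial quantification: per-channel intensity masks, 8-connected
# component filtering, intensity-weighted centroids, radius-based cell typing
# and distance statistics (nearest tumor cell, double-positive pairs).

#' Multi-channel FISH scene container
#'
#' @param channels named list of equally sized 2-D numeric rasters (rows = y,
#'   cols = x); conventionally includes `DAPI` (nuclei), one channel per
#'   marker probe, and `Tumor`.
#' @param pixel_size_um physical pixel size in micrometres per pixel (> 0).
#' @param channel_map named list mapping marker channel names to the marker
#'   gene they carry (channels absent from the map, e.g. DAPI/Tumor, are not
#'   treated as marker channels).
#' @return object of class `fish_scene`.
#' @export
fish_scene <- function(channels, pixel_size_um, channel_map) {
  if (!length(channels) || is.null(names(channels)))
    stopf("channels must be a non-empty named list of rasters")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stopf("every channel must be a 2-D matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("all channels must have the same shape")
  assert_scalar_num(pixel_size_um, "pixel_size_um", lo = 0, strict_lo = TRUE)
  if (!all(names(channel_map) %in% names(channels)))
    stopf("channel_map refers to channels absent from the scene")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 channel_map = channel_map), class = "fish_scene")
}

#' @export
print.fish_scene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("fish_scene: %d x %d px (%.3g um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Otsu's threshold on a 256-bin histogram of the raster's value range.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[2])         # constant image -> empty mask
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# 8-connected component labeling by frontier BFS on the foreground pixels.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  todo <- which(mask)
  cur <- 0L
  for (seed_px in todo) {
    if (lab[seed_px]) next
    cur <- cur + 1L
    frontier <- seed_px
    lab[seed_px] <- cur
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nbrs <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; c2 <- cc + dc
        ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nbrs <- c(nbrs, (c2[ok] - 1L) * nr + rr[ok])
      }
      nbrs <- unique(nbrs)
      nbrs <- nbrs[mask[nbrs] & lab[nbrs] == 0L]
      lab[nbrs] <- cur
      frontier <- nbrs
    }
  }
  lab
}

#' Segment a fluorescence channel into components
#'
#' Thresholds the raster into a binary mask, labels 8-connected components,
#' discards components smaller than `min_component_px`, and returns the
#' intensity-weighted centroid of each survivor.
#'
#' @param raster 2-D numeric matrix (rows = y, cols = x).
#' @param threshold intensity threshold (mask = raster > threshold); `NULL`
#'   uses Otsu's method on the channel histogram.
#' @param min_component_px components with fewer pixels are discarded.
#' @return data.frame `component_id`, `area_px`, `x`, `y` (pixel coordinates,
#'   intensity-weighted); the label matrix is attached as attribute
#'   `"labels"`. An empty mask yields a 0-row result, not an error.
#' @export
segment_channel <- function(raster, threshold = NULL, min_component_px = 5) {
  if (length(dim(raster)) != 2L) stopf("raster must be a 2-D matrix")
  if (is.null(threshold)) threshold <- otsu_threshold(raster)
  mask <- raster > threshold
  lab <- label_components_8(mask)
  empty <- data.frame(component_id = integer(0), area_px = integer(0),
                      x = numeric(0), y = numeric(0))
  n_comp <- max(lab)
  if (n_comp == 0L) {
    attr(empty, "labels") <- lab
    return(empty)
  }
  px <- which(lab > 0L)
  comp <- lab[px]
  r <- (px - 1L) %% nrow(raster) + 1L
  cc <- (px - 1L) %/% nrow(raster) + 1L
  w <- raster[px]
  area <- tabulate(comp, n_comp)
  wsum <- vapply(seq_len(n_comp), function(k) sum(w[comp == k]), numeric(1))
  cx <- vapply(seq_len(n_comp), function(k) sum((w * cc)[comp == k]), numeric(1)) / wsum
  cy <- vapply(seq_len(n_comp), function(k) sum((w * r)[comp == k]), numeric(1)) / wsum
  keep <- area >= min_component_px
  out <- data.frame(component_id = seq_len(n_comp), area_px = area,
                    x = cx, y = cy)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}

#' Default marker-class table
#'
#' Maps the probe panel (Clec4f, C1qa, Cxcl3, Cxcl10, Trem2, Spp1, Cd3, Klf2)
#' to lineages (macrophage / tcell), roles (lineage vs subtype marker) and
#' resolved cell-type labels. Macrophage markers use the 20 um typing
#' diameter, T-cell markers 10 um.
#'
#' @return data.frame with columns `marker`, `lineage`, `role`, `cell_type`.
#' @export
default_marker_classes <- function() {
  data.frame(
    marker = c("Clec4f", "C1qa", "Cxcl3", "Cxcl10", "Trem2", "Spp1", "Cd3", "Klf2"),
    lineage = c(rep("macrophage", 6), "tcell", "tcell"),
    role = c("lineage", "subtype", "subtype", "subtype", "subtype", "subtype",
             "lineage", "subtype"),
    cell_type = c("Mac", "C1QA+ Mac", "CXCL3+ Mac", "CXCL10+ Mac", "SAMac",
                  "SPP1+ Mac", "T", "Tc"),
    stringsAsFactors = FALSE)
}

#' Resolve nuclei into typed cell calls
#'
#' Every nucleus centroid is a candidate cell. A marker is assigned to a
#' nucleus when a spot centroid of that marker's channel lies within the
#' typing radius of the nucleus centroid — half the class diameter
#' (macrophage markers 20 um diameter -> 10 um radius; T-cell markers 10 um
#' -> 5 um radius), boundary inclusive. The resolved type is the cell type of
#' the nearest assigned subtype marker when one exists, otherwise of the
#' nearest assigned lineage marker; nuclei carrying both a lineage marker and
#' a subtype marker of the same lineage (e.g. Clec4f + Spp1) are flagged
#' double-positive. All assignments are retained for audit.
#'
#' @param scene a [fish_scene()] (provides pixel size and the channel map).
#' @param nuclei components of the DAPI channel ([segment_channel()] output).
#' @param spots named list: channel name -> [segment_channel()] output for
#'   that marker channel. Channels missing from the scene's channel map raise
#'   a configuration error.
#' @param mac_diameter_um,t_diameter_um typing diameters.
#' @param marker_classes marker class table, see [default_marker_classes()].
#' @return data.frame of class `cell_calls`: `call_id`, `nucleus_id`, `x`,
#'   `y` (px), `x_um`, `y_um`, `resolved_type`, `double_positive`, `markers`
#'   (comma-joined). The long assignment table (`nucleus_id`, `channel`,
#'   `marker`, `distance_um`) is attached as attribute `"assignments"`.
#' @export
call_cells <- function(scene, nuclei, spots, mac_diameter_um = 20,
                       t_diameter_um = 10, marker_classes = default_marker_classes()) {
  if (!inherits(scene, "fish_scene")) stopf("scene must be a fish_scene")
  psz <- scene$pixel_size_um
  if (length(spots) && is.null(names(spots))) stopf("spots must be a named list")
  for (ch in names(spots)) {
    mk <- scene$channel_map[[ch]]
    if (is.null(mk)) stopf("channel '%s' is not in the scene's channel map", ch)
    if (!mk %in% marker_classes$marker)
      stopf("marker '%s' (channel '%s') is not in the marker class table", mk, ch)
  }
  n_nuc <- nrow(nuclei)
  assign_rows <- list()
  for (ch in names(spots)) {
    sp <- spots[[ch]]
    if (!nrow(sp)) next
    mk <- scene$channel_map[[ch]]
    mc <- marker_classes[marker_classes$marker == mk, ]
    radius <- (if (mc$lineage == "macrophage") mac_diameter_um else t_diameter_um) / 2
    for (i in seq_len(n_nuc)) {
      d <- sqrt((sp$x - nuclei$x[i])^2 + (sp$y - nuclei$y[i])^2) * psz
      dmin <- if (length(d)) min(d) else Inf
      if (dmin <= radius)
        assign_rows[[length(assign_rows) + 1L]] <-
          data.frame(nucleus_id = i, channel = ch, marker = mk,
                     distance_um = dmin, stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(assign_rows)) do.call(rbind, assign_rows)
    else data.frame(nucleus_id = integer(0), channel = character(0),
                    marker = character(0), distance_um = numeric(0))
  resolved <- rep("unassigned", n_nuc)
  dp <- rep(FALSE, n_nuc)
  markers_str <- rep("", n_nuc)
  for (i in seq_len(n_nuc)) {
    a <- assignments[assignments$nucleus_id == i, , drop = FALSE]
    if (!nrow(a)) next
    mc <- marker_classes[match(a$marker, marker_classes$marker), ]
    # subtype markers are more specific than lineage markers: resolve to the
    # nearest assigned subtype when one exists, else to the nearest lineage
    # marker (a Clec4f + Spp1 nucleus is an SPP1+ Mac, not a generic Mac)
    sub <- which(mc$role == "subtype")
    nearest <- if (length(sub)) sub[which.min(a$distance_um[sub])]
               else which.min(a$distance_um)
    resolved[i] <- mc$cell_type[nearest]
    markers_str[i] <- paste(a$marker, collapse = ",")
    for (lin in unique(mc$lineage))
      if (any(mc$lineage == lin & mc$role == "lineage") &&
          any(mc$lineage == lin & mc$role == "subtype")) dp[i] <- TRUE
  }
  out <- data.frame(call_id = sprintf("cell_%d", seq_len(n_nuc)),
                    nucleus_id = seq_len(n_nuc),
                    x = nuclei$x, y = nuclei$y,
                    x_um = nuclei$x * psz, y_um = nuclei$y * psz,
                    resolved_type = resolved, double_positive = dp,
                    markers = markers_str, stringsAsFactors = FALSE)
  attr(out, "assignments") <- assignments
  class(out) <- c("cell_calls", "data.frame")
  out
}

#' Distance statistics over cell calls
#'
#' Computes the symmetric pairwise Euclidean distance matrix (micrometres)
#' over all calls (immune calls plus tumor calls), each immune call's
#' nearest-tumor distance (minimum over tumor centroids), the per-type median
#' nearest-tumor distance, and the double-positive pair list: each call
#' carrying a subtype marker is paired with the nearest call carrying the
#' matching lineage marker (itself when both markers sit on one nucleus, in
#' which case the pair distance is 0).
#'
#' @param calls a [call_cells()] result.
#' @param tumor_calls data.frame of tumor cells with columns `call_id`,
#'   `x_um`, `y_um` (see [tumor_calls_from_channel()]); with no tumor calls
#'   the nearest-tumor fields are `NULL` and a warning is emitted.
#' @param marker_classes marker class table (for pairing double positives).
#' @return list of class `distance_report`: `pairwise` (matrix, um),
#'   `nearest_tumor` (data.frame `call_id`, `resolved_type`, `distance_um`),
#'   `type_medians` (data.frame `resolved_type`, `n`, `median_um`),
#'   `double_positive_pairs` (data.frame).
#' @export
distance_report <- function(calls, tumor_calls,
                            marker_classes = default_marker_classes()) {
  tum <- if (!is.null(tumor_calls) && nrow(tumor_calls)) {
    data.frame(call_id = tumor_calls$call_id, x_um = tumor_calls$x_um,
               y_um = tumor_calls$y_um, resolved_type = "tumor",
               stringsAsFactors = FALSE)
  } else NULL
  allc <- rbind(data.frame(call_id = calls$call_id, x_um = calls$x_um,
                           y_um = calls$y_um, resolved_type = calls$resolved_type,
                           stringsAsFactors = FALSE), tum)
  pw <- as.matrix(stats::dist(cbind(allc$x_um, allc$y_um)))
  dimnames(pw) <- list(allc$call_id, allc$call_id)

  if (is.null(tum)) {
    warnf("no tumor calls: nearest-tumor statistics omitted")
    nt <- NULL; med <- NULL
  } else {
    sub <- pw[calls$call_id, tum$call_id, drop = FALSE]
    ntd <- apply(sub, 1L, min)
    nt <- data.frame(call_id = calls$call_id, resolved_type = calls$resolved_type,
                     distance_um = unname(ntd), stringsAsFactors = FALSE)
    med <- do.call(rbind, lapply(split(nt, nt$resolved_type), function(d)
      data.frame(resolved_type = d$resolved_type[1], n = nrow(d),
                 median_um = stats::median(d$distance_um),
                 stringsAsFactors = FALSE)))
    rownames(med) <- NULL
  }

  asn <- attr(calls, "assignments")
  pairs <- list()
  if (!is.null(asn) && nrow(asn)) {
    mc <- marker_classes[match(asn$marker, marker_classes$marker), ]
    sub_rows <- which(mc$role == "subtype")
    for (k in sub_rows) {
      lin <- mc$lineage[k]
      lineage_markers <- marker_classes$marker[marker_classes$lineage == lin &
                                                 marker_classes$role == "lineage"]
      carriers <- unique(asn$nucleus_id[asn$marker %in% lineage_markers])
      if (!length(carriers)) next
      i <- asn$nucleus_id[k]
      d <- sqrt((calls$x_um[match(carriers, calls$nucleus_id)] - calls$x_um[match(i, calls$nucleus_id)])^2 +
                (calls$y_um[match(carriers, calls$nucleus_id)] - calls$y_um[match(i, calls$nucleus_id)])^2)
      j <- carriers[which.min(d)]
      pairs[[length(pairs) + 1L]] <-
        data.frame(subtype_nucleus = i, lineage_nucleus = j,
                   subtype_marker = asn$marker[k],
                   lineage_marker = lineage_markers[1],
                   distance_um = min(d), stringsAsFactors = FALSE)
    }
  }
  dp <- if (length(pairs)) do.call(rbind, pairs)
    else data.frame(subtype_nucleus = integer(0), lineage_nucleus = integer(0),
                    subtype_marker = character(0), lineage_marker = character(0),
                    distance_um = numeric(0))
  structure(list(pairwise = pw, nearest_tumor = nt, type_medians = med,
                 double_positive_pairs = dp), class = "distance_report")
}

#' Tumor-cell calls from the tumor channel
#'
#' @param scene a [fish_scene()] containing a channel named `channel`.
#' @param channel name of the tumor channel.
#' @param threshold,min_component_px passed to [segment_channel()].
#' @return data.frame with `call_id`, `x`, `y`, `x_um`, `y_um`,
#'   `resolved_type = "tumor"`.
#' @export
tumor_calls_from_channel <- function(scene, channel = "Tumor", threshold = NULL,
                                     min_component_px = 5) {
  if (!channel %in% names(scene$channels))
    stopf("scene has no channel '%s'", channel)
  comp <- segment_channel(scene$channels[[channel]], threshold, min_component_px)
  data.frame(call_id = sprintf("tumor_%d", seq_len(nrow(comp))),
             x = comp$x, y = comp$y,
             x_um = comp$x * scene$pixel_size_um,
             y_um = comp$y * scene$pixel_size_um,
             resolved_type = rep("tumor", nrow(comp)), stringsAsFactors = FALSE)
}

#' End-to-end FISH quantification
#'
#' Segments the DAPI channel into nuclei, every mapped marker channel into
#' spots, and the tumor channel into tumor cells; resolves typed cell calls
#' and computes the distance report.
#'
#' @param scene a [fish_scene()].
#' @param threshold single value, named list per channel, or `NULL` (Otsu per
#'   channel).
#' @param min_component_px,mac_diameter_um,t_diameter_um,marker_classes passed
#'   through.
#' @param dapi_channel,tumor_channel channel names.
#' @return list of class `fish_quant`: `nuclei`, `spots`, `calls`,
#'   `tumor_calls`, `report`.
#' @export
fish_quantify <- function(scene, threshold = NULL, min_component_px = 5,
                          mac_diameter_um = 20, t_diameter_um = 10,
                          marker_classes = default_marker_classes(),
                          dapi_channel = "DAPI", tumor_channel = "Tumor") {
  thr <- function(ch) {
    if (is.list(threshold)) threshold[[ch]] else threshold
  }
  nuclei <- segment_channel(scene$channels[[dapi_channel]], thr(dapi_channel),
                            min_component_px)
  marker_channels <- names(scene$channel_map)
  spots <- stats::setNames(lapply(marker_channels, function(ch)
    segment_channel(scene$channels[[ch]], thr(ch), min_component_px)),
    marker_channels)
  calls <- call_cells(scene, nuclei, spots, mac_diameter_um, t_diameter_um,
                      marker_classes)
  tumor <- if (tumor_channel %in% names(scene$channels))
    tumor_calls_from_channel(scene, tumor_channel, thr(tumor_channel),
                             min_component_px)
  else NULL
  report <- distance_report(calls, tumor, marker_classes)
  structure(list(nuclei = nuclei, spots = spots, calls = calls,
                 tumor_calls = tumor, report = report), class = "fish_quant")
}
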