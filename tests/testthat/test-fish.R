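# Segmentation, radius-based cell typing and distance statistics on scenes
# with analytically known geometry.

test_that("segment_channel: block centroid, size filter, empty mask", {
  img <- matrix(0, 32, 32)
  img[10:12, 20:22] <- 1                       # 3x3 block centered at (21, 11)
  comp <- segment_channel(img, threshold = 0.5, min_component_px = 5)
  expect_identical(nrow(comp), 1L)
  expect_equal(comp$x, 21)
  expect_equal(comp$y, 11)
  expect_identical(comp$area_px, 9L)

  img[30, 2:3] <- 1                            # 2-px blob below the size filter
  comp2 <- segment_channel(img, threshold = 0.5, min_component_px = 5)
  expect_identical(nrow(comp2), 1L)

  expect_identical(nrow(segment_channel(matrix(0, 8, 8), threshold = 0.5)), 0L)
})

test_that("labeling is 8-connected", {
  img <- matrix(0, 6, 6)
  img[2, 2] <- 1; img[3, 3] <- 1               # touch only diagonally
  comp <- segment_channel(img, threshold = 0.5, min_component_px = 1)
  expect_identical(nrow(comp), 1L)
})

test_that("noise-free scenes are recovered within a pixel", {
  sim <- make_scene(radius_frac = 0.8, seed = 2)
  fq <- fish_quantify(sim$scene, threshold = 0.5)
  expect_identical(nrow(fq$nuclei), nrow(sim$truth))
  # centroid error <= 1 px for every nucleus (matched by position: component
  # ordering follows the raster scan)
  idx <- match_to_truth(fq$nuclei, sim$truth)
  expect_identical(sort(idx), seq_len(nrow(sim$truth)))
  err <- sqrt((fq$nuclei$x[idx] - sim$truth$x)^2 + (fq$nuclei$y[idx] - sim$truth$y)^2)
  expect_true(all(err <= 1))
})

test_that("typing radii are honored: inside assigns, outside does not", {
  # nucleus at origin-ish, Clec4f spot at 9 um -> macrophage call (10 um radius)
  nuc <- data.frame(x = 100, y = 100, true_type = "Mac")
  mk <- function(ch, d) list(data.frame(channel = ch, dx_um = d, dy_um = 0))
  scene_at <- function(ch, marker, d) {
    cfg <- fish_sim_config(nuclei = nuc, spot_offsets = mk(ch, d))
    sim <- simulate_fish(cfg)
    sim$scene$channel_map <- setNames(list(marker), ch)
    sim$scene
  }
  fq <- suppressWarnings(fish_quantify(scene_at("ch1", "Clec4f", 9), threshold = 0.5))
  expect_identical(fq$calls$resolved_type, "Mac")

  # Cd3 spot at 6 um -> NOT a T-cell call (5 um radius)
  fq2 <- suppressWarnings(fish_quantify(scene_at("ch1", "Cd3", 6), threshold = 0.5))
  expect_identical(fq2$calls$resolved_type, "unassigned")

  # unknown channel in the map is a configuration error
  sc_bad <- scene_at("ch1", "Clec4f", 5)
  expect_error(call_cells(sc_bad, data.frame(x = 1, y = 1),
                          list(mystery = data.frame(component_id = 1, area_px = 9,
                                                    x = 2, y = 2))),
               "not in the scene's channel map")
})

test_that("assignment is perfect for spots at 0.8x and absent at 1.2x radius", {
  for (frac in c(0.8, 1.2)) {
    sim <- make_scene(radius_frac = frac, seed = 3)
    fq <- fish_quantify(sim$scene, threshold = 0.5)
    got <- fq$calls$resolved_type[match_to_truth(fq$calls, sim$truth)]
    if (frac < 1) {
      expect_identical(got, sim$truth$true_type)
    } else {
      # every planted subtype spot now lies outside its radius; only the
      # directly-on-nucleus lineage spots remain assignable
      expect_true(all(got %in% c("Mac", "T", "unassigned")))
      expect_false(any(got %in% c("SPP1+ Mac", "Tc")))
    }
  }
})

test_that("pairwise distances match the all-pairs oracle; metric properties hold", {
  sim <- make_scene(seed = 4)
  fq <- fish_quantify(sim$scene, threshold = 0.5)
  pw <- fq$report$pairwise
  ids <- rownames(pw)
  coords <- rbind(fq$calls[, c("call_id", "x_um", "y_um")],
                  fq$tumor_calls[, c("call_id", "x_um", "y_um")])
  coords <- coords[match(ids, coords$call_id), ]
  want <- oracle_pairwise(coords$x_um, coords$y_um)
  expect_equal(unname(pw), want, tolerance = 1e-9)
  expect_equal(pw, t(pw))
  expect_true(all(diag(pw) == 0))
  # triangle inequality over all triples
  n <- nrow(pw)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(pw[i, j], pw[i, k] + pw[k, j] + 1e-9)
})

test_that("nearest-tumor distances and per-type medians match the generator truth", {
  sim <- make_scene(radius_frac = 0.8, seed = 5)
  fq <- fish_quantify(sim$scene, threshold = 0.5)
  idx <- match_to_truth(fq$calls, sim$truth)
  nt <- fq$report$nearest_tumor
  expect_equal(nt$distance_um[idx], sim$truth$nearest_tumor_um,
               tolerance = sim$scene$pixel_size_um)
  med <- fq$report$type_medians
  truth_med <- tapply(sim$truth$nearest_tumor_um, sim$truth$true_type, median)
  for (ty in med$resolved_type)
    expect_equal(med$median_um[med$resolved_type == ty], unname(truth_med[ty]),
                 tolerance = sim$scene$pixel_size_um)
})

test_that("trivial distance geometry: 3-4-5 and co-location", {
  calls <- data.frame(call_id = "cell_1", nucleus_id = 1, x = 0, y = 0,
                      x_um = 0, y_um = 0, resolved_type = "Tc",
                      double_positive = FALSE, markers = "Cd3",
                      stringsAsFactors = FALSE)
  class(calls) <- c("cell_calls", "data.frame")
  tum <- data.frame(call_id = c("tumor_1", "tumor_2"),
                    x_um = c(30, 60), y_um = c(40, 80),
                    resolved_type = "tumor", stringsAsFactors = FALSE)
  rep1 <- distance_report(calls, tum)
  expect_equal(rep1$nearest_tumor$distance_um, 50)

  tum0 <- data.frame(call_id = "tumor_1", x_um = 0, y_um = 0,
                     resolved_type = "tumor", stringsAsFactors = FALSE)
  expect_equal(distance_report(calls, tum0)$nearest_tumor$distance_um, 0)

  expect_warning(r0 <- distance_report(calls, NULL), "no tumor calls")
  expect_null(r0$nearest_tumor)
})

test_that("double-positive nuclei pair at distance zero", {
  sim <- make_scene(radius_frac = 0.8, seed = 6)
  fq <- fish_quantify(sim$scene, threshold = 0.5)
  expect_true(fq$calls$double_positive[fq$calls$resolved_type == "SPP1+ Mac"])
  dp <- fq$report$double_positive_pairs
  spp1 <- dp[dp$subtype_marker == "Spp1", ]
  expect_identical(spp1$subtype_nucleus, spp1$lineage_nucleus)
  expect_equal(spp1$distance_um, 0)
})

test_that("the report is invariant under scene translation", {
  sim1 <- make_scene(seed = 7)
  # shift all planted coordinates by (7, 13) px and regenerate
  nuc <- data.frame(x = c(40, 110, 180, 60, 200) + 7,
                    y = c(40, 60, 40, 170, 200) + 13,
                    true_type = c("SPP1+ Mac", "Tc", "Mac", "T", "unassigned"))
  sim2 <- make_scene(seed = 7)
  cfg <- fish_sim_config(image_size = c(256, 256), pixel_size_um = 1,
                         nuclei = nuc,
                         spot_offsets = attr(sim1, "spot_offsets"),
                         tumor_centroids = data.frame(x = c(90, 210) + 7,
                                                      y = c(120, 90) + 13),
                         spot_radius_px = 2, nucleus_radius_px = 4, seed = 7)
  # rebuild with the same offsets used by make_scene
  off <- function(r, ang) c(r * cos(ang), r * sin(ang))
  o1 <- off(10 * 0.8, 0.4); o2 <- off(5 * 0.8, 2.1)
  o3 <- off(10 * 0.8, 4.0); o4 <- off(5 * 0.8, 5.5)
  cfg$spot_offsets <- list(
    data.frame(channel = c("ch_spp1", "ch_clec4f"), dx_um = c(o1[1], 0), dy_um = c(o1[2], 0)),
    data.frame(channel = c("ch_klf2", "ch_cd3"), dx_um = c(o2[1], 0), dy_um = c(o2[2], 0)),
    data.frame(channel = "ch_clec4f", dx_um = o3[1], dy_um = o3[2]),
    data.frame(channel = "ch_cd3", dx_um = o4[1], dy_um = o4[2]),
    NULL)
  shifted <- simulate_fish(cfg)
  shifted$scene$channel_map <- sim1$scene$channel_map
  f1 <- fish_quantify(sim1$scene, threshold = 0.5)
  f2 <- fish_quantify(shifted$scene, threshold = 0.5)
  expect_identical(f1$calls$resolved_type, f2$calls$resolved_type)
  expect_equal(unname(f1$report$pairwise), unname(f2$report$pairwise), tolerance = 1e-9)
  expect_equal(f1$report$nearest_tumor$distance_um,
               f2$report$nearest_tumor$distance_um, tolerance = 1e-9)
})
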