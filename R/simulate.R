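# Synthetic-data generators with exact ground truth: cell-type-structured
# negative-binomial single-cell counts with planted markers, a survival cohort
# whose hazard is tied to a planted signature burden, and FISH-like scenes
# with known geometry.

#' Configuration for the single-cell count simulator
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells simulated per type (scalar).
#' @param n_genes size of the gene universe.
#' @param markers_per_type planted marker genes per type; marker sets are
#'   disjoint by construction and `markers_per_type * n_types <= n_genes`.
#' @param marker_log2fc log2 fold change applied to a marker's mean within its
#'   own type.
#' @param nb_dispersion negative-binomial dispersion; variance = mu + mu^2 /
#'   `nb_dispersion`.
#' @param mean_library_size expected total counts per cell.
#' @param mito_fraction_range range (min, max) of the simulated per-cell
#'   mitochondrial fraction, drawn uniformly.
#' @param lib_size_sigma sd (log scale) of the log-normal per-cell library-size
#'   factor; 0 gives every cell the same expected library size so marginal
#'   counts are exactly negative binomial.
#' @param stage_cell_counts optional integer matrix (stages x types, with
#'   dimnames) giving the number of cells per disease stage and type; overrides
#'   `cells_per_type` and attaches the corresponding stage labels. Default: a
#'   single stage `"S1"`.
#' @param seed integer RNG seed; fixes the output bit-for-bit.
#' @return object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_types = 3, cells_per_type = 200, n_genes = 1000,
                          markers_per_type = 10, marker_log2fc = 3,
                          nb_dispersion = 0.5, mean_library_size = 5000,
                          mito_fraction_range = c(0.02, 0.08),
                          lib_size_sigma = 0.3, stage_cell_counts = NULL,
                          seed = 1L) {
  n_types <- assert_count(n_types, "n_types")
  cells_per_type <- assert_count(cells_per_type, "cells_per_type")
  n_genes <- assert_count(n_genes, "n_genes")
  markers_per_type <- assert_count(markers_per_type, "markers_per_type", min = 0L)
  assert_scalar_num(marker_log2fc, "marker_log2fc")
  assert_scalar_num(nb_dispersion, "nb_dispersion", lo = 0, strict_lo = TRUE)
  assert_scalar_num(mean_library_size, "mean_library_size", lo = 0, strict_lo = TRUE)
  assert_scalar_num(lib_size_sigma, "lib_size_sigma", lo = 0)
  if (length(mito_fraction_range) != 2L || any(mito_fraction_range < 0) ||
      any(mito_fraction_range > 1) || diff(mito_fraction_range) < 0)
    stopf("mito_fraction_range must be an increasing pair in [0, 1]")
  if (markers_per_type * n_types > n_genes)
    stopf("markers_per_type * n_types (%d) exceeds n_genes (%d)",
          markers_per_type * n_types, n_genes)
  if (!is.null(stage_cell_counts)) {
    if (!is.matrix(stage_cell_counts) || ncol(stage_cell_counts) != n_types ||
        is.null(rownames(stage_cell_counts)))
      stopf("stage_cell_counts must be a stages x n_types matrix with stage rownames")
    if (any(stage_cell_counts < 0) || any(stage_cell_counts != round(stage_cell_counts)))
      stopf("stage_cell_counts must contain non-negative integers")
  }
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 marker_log2fc = marker_log2fc, nb_dispersion = nb_dispersion,
                 mean_library_size = mean_library_size,
                 mito_fraction_range = mito_fraction_range,
                 lib_size_sigma = lib_size_sigma,
                 stage_cell_counts = stage_cell_counts, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate a labeled single-cell count matrix with planted markers
#'
#' Counts are negative binomial with a log-normal per-cell library-size factor.
#' Gene baseline relative abundances are log-normal; planted marker genes are
#' assigned a fixed moderate baseline weight (0.25) so that their detection
#' fraction outside their own type stays below one half, and their mean is
#' multiplied by `2^marker_log2fc` within their own type.
#'
#' @param config an [sc_sim_config()].
#' @return A [labeled_expression()] whose `cell_meta` carries the true `type`,
#'   `stage`, simulated `mito_fraction` and the observed `n_detected_genes`.
#'   Attribute `"truth"` holds the planted marker sets (named list per type)
#'   and the config.
#' @export
simulate_sc <- function(config) {
  if (!inherits(config, "sc_sim_config")) stopf("config must be an sc_sim_config")
  with_seed(config$seed, {
    ng <- config$n_genes
    nt <- config$n_types
    gene_ids <- sprintf("g%04d", seq_len(ng))
    types <- sprintf("type%d", seq_len(nt))
    nmk <- config$markers_per_type
    markers <- stats::setNames(lapply(seq_len(nt), function(k)
      gene_ids[((k - 1L) * nmk + seq_len(nmk))]), types)
    if (nmk == 0L) markers <- stats::setNames(rep(list(character(0)), nt), types)

    # baseline relative abundance: fixed weight for markers, log-normal pool
    w <- exp(stats::rnorm(ng, 0, 1.2))
    w[seq_len(nmk * nt)] <- 0.25
    w <- w / sum(w)

    if (!is.null(config$stage_cell_counts)) {
      scc <- config$stage_cell_counts
      cell_type <- rep(rep(types, times = nrow(scc)), times = as.vector(t(scc)))
      cell_stage <- rep(rep(rownames(scc), each = nt), times = as.vector(t(scc)))
    } else {
      cell_type <- rep(types, each = config$cells_per_type)
      cell_stage <- rep("S1", length(cell_type))
    }
    nc <- length(cell_type)
    if (nc == 0L) stopf("configuration yields zero cells")

    libf <- exp(stats::rnorm(nc, -config$lib_size_sigma^2 / 2, config$lib_size_sigma))
    lib <- config$mean_library_size * libf

    fc <- matrix(1, ng, nt, dimnames = list(gene_ids, types))
    for (k in seq_len(nt)) fc[markers[[k]], k] <- 2^config$marker_log2fc
    mu <- (w * fc[, match(cell_type, types), drop = FALSE]) *
      rep(lib, each = ng)                     # genes x cells expected counts
    counts <- matrix(stats::rnbinom(ng * nc, mu = as.vector(mu),
                                    size = config$nb_dispersion),
                     ng, nc, dimnames = list(gene_ids, sprintf("cell%05d", seq_len(nc))))

    meta <- data.frame(cell_id = colnames(counts), type = cell_type,
                       stage = cell_stage,
                       mito_fraction = stats::runif(nc, config$mito_fraction_range[1],
                                                    config$mito_fraction_range[2]),
                       n_detected_genes = as.integer(colSums(counts > 0)),
                       stringsAsFactors = FALSE)
    out <- labeled_expression(counts, meta)
    attr(out, "truth") <- list(markers = markers, config = config)
    out
  })
}

#' Configuration for the bulk survival-cohort simulator
#'
#' @param n_samples number of tumor samples.
#' @param n_genes size of the gene universe.
#' @param signature_genes character vector of planted signature genes (must lie
#'   inside the simulated gene universe `g0001 ... gNNNN`); their expression
#'   tracks the per-sample burden.
#' @param planted_hazard_ratio hazard ratio per standard deviation of the
#'   standardized burden z.
#' @param baseline_hazard constant baseline hazard (1 / time unit); survival
#'   times are exponential.
#' @param censor_fraction target expected fraction of censored samples;
#'   censoring is an independent exponential whose rate is tuned numerically.
#' @param age_range integer range of patient ages (years), drawn uniformly.
#' @param sig_effect,immune_effect,tc_effect log2-expression shift per standard
#'   deviation of the corresponding latent variable.
#' @param n_immune_sets,immune_set_size immune reference panel: number of
#'   disjoint immune cell-type gene sets and genes per set.
#' @param tc_set_size number of genes in the cytotoxic T-cell (Tc) set.
#' @param noise_sd residual sd of log2 expression.
#' @param seed integer RNG seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 300, n_genes = 2000,
                              signature_genes = sprintf("g%04d", 1:40),
                              planted_hazard_ratio = 2, baseline_hazard = 0.1,
                              censor_fraction = 0.3, age_range = c(30L, 80L),
                              sig_effect = 1.5, immune_effect = 1.5,
                              tc_effect = 1.5, n_immune_sets = 3,
                              immune_set_size = 25, tc_set_size = 25,
                              noise_sd = 1, seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", min = 10L)
  n_genes <- assert_count(n_genes, "n_genes", min = 10L)
  if (length(signature_genes) == 0L) stopf("signature_genes must be non-empty")
  assert_scalar_num(planted_hazard_ratio, "planted_hazard_ratio", lo = 0, strict_lo = TRUE)
  assert_scalar_num(baseline_hazard, "baseline_hazard", lo = 0, strict_lo = TRUE)
  assert_scalar_num(censor_fraction, "censor_fraction", lo = 0, hi = 1)
  if (length(age_range) != 2L || diff(age_range) < 0)
    stopf("age_range must be an increasing integer pair")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (!all(signature_genes %in% gene_ids))
    stopf("signature_genes outside the simulated gene universe (g0001..g%04d)", n_genes)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 signature_genes = as.character(signature_genes),
                 planted_hazard_ratio = planted_hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_fraction = censor_fraction,
                 age_range = as.integer(age_range), sig_effect = sig_effect,
                 immune_effect = immune_effect, tc_effect = tc_effect,
                 n_immune_sets = assert_count(n_immune_sets, "n_immune_sets"),
                 immune_set_size = assert_count(immune_set_size, "immune_set_size"),
                 tc_set_size = assert_count(tc_set_size, "tc_set_size"),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a bulk expression cohort with a planted prognostic burden
#'
#' Per sample, a standardized signature burden z and an immune-abundance latent
#' u are drawn independently from N(0, 1). Signature genes respond to z + u
#' (signature expression in bulk is confounded by overall immune infiltration
#' — the reason the composite scores divide by an immune score), immune-panel
#' genes respond to u, and the Tc set to its own latent v. Survival time is
#' exponential with hazard `baseline_hazard * planted_hazard_ratio^z`;
#' censoring is an independent exponential tuned so the expected censored
#' fraction matches `censor_fraction`.
#'
#' @param config a [cohort_sim_config()].
#' @return object of class `bulk_cohort`: list with `expression` (genes x
#'   samples, log2 scale) and `clinical` (`sample`, `OS_time`, `event`, `age`,
#'   `group`). Attribute `"truth"` stores z, u, v, the planted gene sets
#'   (`signature`, `immune` list, `tc`) and the config.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config")) stopf("config must be a cohort_sim_config")
  with_seed(config$seed, {
    n <- config$n_samples
    ng <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(ng))
    sample_ids <- sprintf("s%04d", seq_len(n))

    z <- stats::rnorm(n)
    u <- stats::rnorm(n)
    v <- stats::rnorm(n)

    sig <- config$signature_genes
    pool <- setdiff(gene_ids, sig)
    need <- config$n_immune_sets * config$immune_set_size + config$tc_set_size
    if (length(pool) < need)
      stopf("gene universe too small for the immune panel and Tc set")
    imm <- lapply(seq_len(config$n_immune_sets), function(k)
      pool[(k - 1L) * config$immune_set_size + seq_len(config$immune_set_size)])
    names(imm) <- sprintf("immune_set%d", seq_along(imm))
    tc <- pool[config$n_immune_sets * config$immune_set_size + seq_len(config$tc_set_size)]

    mu <- stats::rnorm(ng, 6, 2)
    x <- matrix(stats::rnorm(ng * n, mu, config$noise_sd), ng, n,
                dimnames = list(gene_ids, sample_ids))
    x[sig, ] <- x[sig, ] + config$sig_effect * rep(z + u, each = length(sig))
    for (s in imm) x[s, ] <- x[s, ] + config$immune_effect * rep(u, each = length(s))
    x[tc, ] <- x[tc, ] + config$tc_effect * rep(v, each = length(tc))

    lambda <- config$baseline_hazard * config$planted_hazard_ratio^z
    t_event <- stats::rexp(n, lambda)
    if (config$censor_fraction > 0) {
      crate <- stats::uniroot(function(cr) mean(cr / (cr + lambda)) - config$censor_fraction,
                              interval = c(1e-9, 1e6), tol = 1e-10)$root
      t_cens <- stats::rexp(n, crate)
    } else t_cens <- rep(Inf, n)
    os <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(sample = sample_ids, OS_time = os, event = event,
                           age = sample(seq(config$age_range[1], config$age_range[2]),
                                        n, replace = TRUE),
                           group = "tumor", stringsAsFactors = FALSE)
    out <- structure(list(expression = x, clinical = clinical), class = "bulk_cohort")
    attr(out, "truth") <- list(z = z, u = u, v = v,
                               gene_sets = list(signature = sig, immune = imm, tc = tc),
                               config = config)
    out
  })
}

#' Bulk cohort container
#'
#' @param expression genes x samples numeric matrix (log2 scale expected but
#'   any monotone scale works for the rank-based scores).
#' @param clinical data.frame with columns `sample`, `OS_time` (> 0), `event`
#'   (0/1), `age`; optional `group` in `normal`/`tumor`.
#' @return object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expression, clinical) {
  if (!is.matrix(expression) || is.null(rownames(expression)) || is.null(colnames(expression)))
    stopf("expression must be a matrix with gene rownames and sample colnames")
  for (col in c("sample", "OS_time", "event", "age"))
    if (is.null(clinical[[col]])) stopf("clinical is missing column '%s'", col)
  if (anyDuplicated(clinical$sample)) stopf("sample IDs must be unique")
  if (!all(colnames(expression) %in% clinical$sample))
    stopf("every expression column needs a clinical row")
  if (any(clinical$OS_time <= 0)) stopf("OS_time must be > 0")
  if (!all(clinical$event %in% c(0, 1))) stopf("event must be 0/1")
  if (is.null(clinical$group)) clinical$group <- "tumor"
  structure(list(expression = expression, clinical = clinical), class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("bulk_cohort: %d genes x %d samples, %d events, median OS %.3g\n",
              nrow(x$expression), ncol(x$expression), sum(x$clinical$event),
              stats::median(x$clinical$OS_time)))
  invisible(x)
}

#' Configuration for the FISH scene simulator
#'
#' Coordinates are pixel coordinates (x = column, y = row, 1-based pixel
#' centers); spot offsets are micrometres relative to their nucleus.
#'
#' @param image_size integer pair (rows, cols) in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param nuclei data.frame with columns `x`, `y`, `true_type`.
#' @param spot_offsets list (one element per nucleus) of data.frames with
#'   columns `channel`, `dx_um`, `dy_um`; `NULL` elements mean no spots.
#' @param tumor_centroids data.frame with columns `x`, `y` (may have 0 rows).
#' @param spot_radius_px radius of rendered marker spots in pixels.
#' @param nucleus_radius_px radius of rendered nuclei / tumor cells in pixels.
#' @param noise_level Gaussian pixel noise sd as a fraction of max intensity
#'   (intensities live in `[0, 1]`).
#' @param seed integer RNG seed.
#' @return object of class `fish_sim_config`.
#' @export
fish_sim_config <- function(image_size = c(256L, 256L), pixel_size_um = 1,
                            nuclei, spot_offsets = NULL,
                            tumor_centroids = data.frame(x = numeric(0), y = numeric(0)),
                            spot_radius_px = 3, nucleus_radius_px = 5,
                            noise_level = 0, seed = 1L) {
  assert_scalar_num(pixel_size_um, "pixel_size_um", lo = 0, strict_lo = TRUE)
  assert_scalar_num(noise_level, "noise_level", lo = 0, hi = 1)
  spot_radius_px <- assert_count(spot_radius_px, "spot_radius_px")
  nucleus_radius_px <- assert_count(nucleus_radius_px, "nucleus_radius_px")
  if (length(image_size) != 2L) stopf("image_size must be (rows, cols)")
  if (!is.data.frame(nuclei) || is.null(nuclei$x) || is.null(nuclei$y) ||
      is.null(nuclei$true_type))
    stopf("nuclei must be a data.frame with columns x, y, true_type")
  if (is.null(spot_offsets)) spot_offsets <- vector("list", nrow(nuclei))
  if (length(spot_offsets) != nrow(nuclei))
    stopf("spot_offsets must have one element per nucleus")
  inside <- function(x, y, r)
    all(x - r >= 1 & x + r <= image_size[2] & y - r >= 1 & y + r <= image_size[1])
  if (nrow(nuclei) && !inside(nuclei$x, nuclei$y, nucleus_radius_px))
    stopf("nucleus disc outside image bounds")
  if (nrow(tumor_centroids) && !inside(tumor_centroids$x, tumor_centroids$y, nucleus_radius_px))
    stopf("tumor disc outside image bounds")
  for (i in seq_along(spot_offsets)) {
    so <- spot_offsets[[i]]
    if (is.null(so)) next
    if (!all(c("channel", "dx_um", "dy_um") %in% names(so)))
      stopf("spot_offsets[[%d]] must have columns channel, dx_um, dy_um", i)
    sx <- nuclei$x[i] + so$dx_um / pixel_size_um
    sy <- nuclei$y[i] + so$dy_um / pixel_size_um
    if (nrow(so) && !inside(sx, sy, spot_radius_px))
      stopf("spot outside image bounds (nucleus %d)", i)
  }
  structure(list(image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
                 nuclei = nuclei, spot_offsets = spot_offsets,
                 tumor_centroids = tumor_centroids, spot_radius_px = spot_radius_px,
                 nucleus_radius_px = nucleus_radius_px, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "fish_sim_config")
}

# Rasterize a filled disc (value saturating at 1) onto `mat`.
draw_disc <- function(mat, x, y, r, value = 1) {
  rows <- max(1L, floor(y - r)):min(nrow(mat), ceiling(y + r))
  cols <- max(1L, floor(x - r)):min(ncol(mat), ceiling(x + r))
  for (j in cols) {
    dy2 <- r^2 - (j - x)^2
    if (dy2 < 0) next
    sel <- rows[(rows - y)^2 <= dy2]
    mat[sel, j] <- pmax(mat[sel, j], value)
  }
  mat
}

#' Simulate a multi-channel FISH scene with exact ground truth
#'
#' Renders a DAPI channel (nucleus discs), one channel per marker present in
#' the spot offsets (spot discs), and a Tumor channel (tumor-cell discs), plus
#' Gaussian pixel noise. The returned ground-truth table is analytic: it lists
#' each nucleus's true type and its exact Euclidean nearest-tumor distance in
#' micrometres, independent of rendering.
#'
#' @param config a [fish_sim_config()].
#' @return list with `scene` (a [fish_scene()]) and `truth` (data.frame
#'   `nucleus_id`, `x`, `y`, `true_type`, `nearest_tumor_um`).
#' @export
simulate_fish <- function(config) {
  if (!inherits(config, "fish_sim_config")) stopf("config must be a fish_sim_config")
  with_seed(config$seed, {
    nr <- config$image_size[1]; ncl <- config$image_size[2]
    blank <- function() matrix(0, nr, ncl)
    dapi <- blank()
    for (i in seq_len(nrow(config$nuclei)))
      dapi <- draw_disc(dapi, config$nuclei$x[i], config$nuclei$y[i],
                        config$nucleus_radius_px)
    chans <- unique(unlist(lapply(config$spot_offsets, function(s) s$channel)))
    marker <- stats::setNames(lapply(chans, function(ch) blank()), chans)
    for (i in seq_along(config$spot_offsets)) {
      so <- config$spot_offsets[[i]]
      if (is.null(so) || !nrow(so)) next
      for (k in seq_len(nrow(so))) {
        ch <- as.character(so$channel[k])
        marker[[ch]] <- draw_disc(marker[[ch]],
                                  config$nuclei$x[i] + so$dx_um[k] / config$pixel_size_um,
                                  config$nuclei$y[i] + so$dy_um[k] / config$pixel_size_um,
                                  config$spot_radius_px)
      }
    }
    tumor <- blank()
    for (i in seq_len(nrow(config$tumor_centroids)))
      tumor <- draw_disc(tumor, config$tumor_centroids$x[i], config$tumor_centroids$y[i],
                         config$nucleus_radius_px)
    channels <- c(list(DAPI = dapi), marker, list(Tumor = tumor))
    if (config$noise_level > 0)
      channels <- lapply(channels, function(m)
        pmax(pmin(m + matrix(stats::rnorm(nr * ncl, 0, config$noise_level),
                             nr, ncl), 1), 0))
    channel_map <- stats::setNames(as.list(chans), chans)
    scene <- fish_scene(channels, config$pixel_size_um, channel_map)

    ntd <- if (nrow(config$tumor_centroids)) {
      vapply(seq_len(nrow(config$nuclei)), function(i)
        min(sqrt((config$tumor_centroids$x - config$nuclei$x[i])^2 +
                 (config$tumor_centroids$y - config$nuclei$y[i])^2)) * config$pixel_size_um,
        numeric(1))
    } else rep(NA_real_, nrow(config$nuclei))
    truth <- data.frame(nucleus_id = seq_len(nrow(config$nuclei)),
                        x = config$nuclei$x, y = config$nuclei$y,
                        true_type = config$nuclei$true_type,
                        nearest_tumor_um = ntd, stringsAsFactors = FALSE)
    list(scene = scene, truth = truth)
  })
}
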