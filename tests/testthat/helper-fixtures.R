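# Fixture builders and independent oracles shared across test files.

# Tiny labeled expression object built directly from a matrix.
make_expr <- function(counts, type = rep("A", ncol(counts)),
                      stage = rep("S1", ncol(counts)),
                      mito = rep(0, ncol(counts)), n_detected = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell_id = colnames(counts), type = type, stage = stage,
                     mito_fraction = mito, stringsAsFactors = FALSE)
  if (!is.null(n_detected)) meta$n_detected_genes <- n_detected
  labeled_expression(counts, meta)
}

# Brute-force recovery-curve AUC for one cell: walk the ranking position by
# position, accumulate the hit count, integrate, normalize by the best case.
oracle_auc <- function(ranking_pos, set_genes, top_fraction) {
  n <- length(ranking_pos)
  W <- ceiling(top_fraction * n)
  genes_by_rank <- names(sort(ranking_pos))
  hits <- cumsum(genes_by_rank %in% set_genes)
  m <- sum(set_genes %in% names(ranking_pos))
  best <- cumsum(c(rep(1, min(m, W)), rep(0, max(0, W - m))))
  sum(hits[seq_len(W)]) / sum(best)
}

# Direct running-sum single-sample GSEA statistic (position-by-position loop).
oracle_ssgsea <- function(x, set_genes, alpha) {
  n <- length(x)
  rnk <- rank(x, ties.method = "average")
  ord_genes <- names(x)[order(x, decreasing = TRUE)]
  es <- 0; p_in <- 0; p_out <- 0
  wsum <- sum(rnk[names(x) %in% set_genes]^alpha)
  n_out <- n - sum(names(x) %in% set_genes)
  for (g in ord_genes) {
    if (g %in% set_genes) p_in <- p_in + rnk[g]^alpha / wsum
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Brute-force Mann-Whitney U by pair counting (ties count one half).
oracle_rank_sum_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# All-pairs Euclidean distances by explicit double loop.
oracle_pairwise <- function(x, y) {
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  m
}

# Small standard scene: nuclei with spot offsets given as fractions of the
# typing radius, plus tumor cells; returns the simulate_fish output with the
# channel map filled in.
make_scene <- function(radius_frac = 0.8, seed = 1, noise = 0) {
  nuclei <- data.frame(x = c(40, 110, 180, 60, 200),
                       y = c(40, 60, 40, 170, 200),
                       true_type = c("SPP1+ Mac", "Tc", "Mac", "T", "unassigned"),
                       stringsAsFactors = FALSE)
  mac_r <- 10; t_r <- 5
  off <- function(r, ang) c(r * cos(ang), r * sin(ang))
  o1 <- off(mac_r * radius_frac, 0.4)
  o2 <- off(t_r * radius_frac, 2.1)
  o3 <- off(mac_r * radius_frac, 4.0)
  o4 <- off(t_r * radius_frac, 5.5)
  spot_offsets <- list(
    data.frame(channel = c("ch_spp1", "ch_clec4f"),
               dx_um = c(o1[1], 0), dy_um = c(o1[2], 0)),
    data.frame(channel = c("ch_klf2", "ch_cd3"),
               dx_um = c(o2[1], 0), dy_um = c(o2[2], 0)),
    data.frame(channel = "ch_clec4f", dx_um = o3[1], dy_um = o3[2]),
    data.frame(channel = "ch_cd3", dx_um = o4[1], dy_um = o4[2]),
    NULL)
  cfg <- fish_sim_config(image_size = c(256, 256), pixel_size_um = 1,
                         nuclei = nuclei, spot_offsets = spot_offsets,
                         tumor_centroids = data.frame(x = c(90, 210), y = c(120, 90)),
                         spot_radius_px = 2, nucleus_radius_px = 4,
                         noise_level = noise, seed = seed)
  sim <- simulate_fish(cfg)
  sim$scene$channel_map <- list(ch_spp1 = "Spp1", ch_clec4f = "Clec4f",
                                ch_cd3 = "Cd3", ch_klf2 = "Klf2")
  sim
}

# Index of the call/component row nearest each ground-truth nucleus (component
# ordering follows the raster scan, not the truth table).
match_to_truth <- function(df, truth) {
  vapply(seq_len(nrow(truth)), function(i)
    which.min((df$x - truth$x[i])^2 + (df$y - truth$y[i])^2), integer(1))
}
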