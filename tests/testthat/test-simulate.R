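# Generators: determinism, planted effects, distributional contracts.

test_that("simulate_sc is deterministic and validates its config", {
  cfg <- sc_sim_config(n_types = 2, cells_per_type = 50, n_genes = 100, seed = 11)
  a <- simulate_sc(cfg)
  b <- simulate_sc(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cell_meta, b$cell_meta)
  expect_error(sc_sim_config(n_types = 4, n_genes = 30, markers_per_type = 10),
               "exceeds n_genes")
  expect_error(sc_sim_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("planted markers have the configured mean ratio; no effect under null", {
  # fc = 2^3 = 8: empirical own-type vs other-type mean ratio near 8
  ratios <- sapply(1:5, function(s) {
    sc <- simulate_sc(sc_sim_config(n_types = 3, cells_per_type = 200,
                                    marker_log2fc = 3, seed = s))
    truth <- attr(sc, "truth")$markers
    own <- rowMeans(sc$counts[truth$type1, sc$cell_meta$type == "type1"])
    other <- rowMeans(sc$counts[truth$type1, sc$cell_meta$type != "type1"])
    mean(own) / mean(other)
  })
  expect_true(all(ratios >= 6 & ratios <= 10))

  # no planted effect: per-seed marker-vs-rest mean ratio fluctuates around 1
  null_ratio <- sapply(1:20, function(s) {
    sc <- simulate_sc(sc_sim_config(n_types = 2, cells_per_type = 100,
                                    n_genes = 200, marker_log2fc = 0, seed = s))
    truth <- attr(sc, "truth")$markers
    mean(sc$counts[truth$type1, sc$cell_meta$type == "type1"]) /
      mean(sc$counts[truth$type1, sc$cell_meta$type == "type2"])
  })
  expect_gt(t.test(log(null_ratio))$p.value, 0.01)
})

test_that("marginal counts are negative binomial (chi-square GOF, fixed library)", {
  cfg <- sc_sim_config(n_types = 2, cells_per_type = 5000, n_genes = 6,
                       markers_per_type = 0, lib_size_sigma = 0, seed = 42)
  sc <- simulate_sc(cfg)
  # with markers_per_type = 0 and a fixed library, every gene's counts are iid
  # NB(mu_g, size = dispersion); check the most expressed gene over 10k draws
  g <- which.max(rowMeans(sc$counts))
  x <- as.numeric(sc$counts[g, ])
  mu <- cfg$mean_library_size *
    (function(w) w / sum(w))(local({
      # recover the generator's weights deterministically from the same seed
      set.seed(cfg$seed); w <- exp(rnorm(cfg$n_genes, 0, 1.2)); w
    }))[g]
  size <- cfg$nb_dispersion
  kmax <- max(x)
  probs <- dnbinom(0:kmax, mu = mu, size = size)
  probs <- c(probs, 1 - sum(probs))
  obs <- c(tabulate(x + 1L, nbins = kmax + 1L), 0)
  # merge adjacent bins until every expected count is >= 5
  expct <- probs * length(x)
  grp <- integer(length(expct)); g <- 1L; acc <- 0
  for (i in seq_along(expct)) {
    grp[i] <- g; acc <- acc + expct[i]
    if (acc >= 5) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0) grp[grp == g] <- g - 1L           # fold a light tail into the last bin
  o <- tapply(obs, grp, sum); e <- tapply(expct, grp, sum)
  stat <- sum((o - e)^2 / e)
  p <- pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("cohort simulator: null hazard, censoring contracts, determinism", {
  cfg <- cohort_sim_config(seed = 5)
  expect_identical(simulate_cohort(cfg)$expression, simulate_cohort(cfg)$expression)
  expect_error(cohort_sim_config(signature_genes = character(0)), "non-empty")

  # censor_fraction = 0 -> every event observed
  co0 <- simulate_cohort(cohort_sim_config(n_samples = 100, n_genes = 200,
                                           signature_genes = sprintf("g%04d", 1:10),
                                           n_immune_sets = 2, immune_set_size = 10,
                                           tc_set_size = 10,
                                           censor_fraction = 0, seed = 2))
  expect_true(all(co0$clinical$event == 1))

  # realized censoring near its target in expectation
  cens <- sapply(1:20, function(s)
    1 - mean(simulate_cohort(cohort_sim_config(n_samples = 200, n_genes = 100,
                                               signature_genes = "g0001",
                                               n_immune_sets = 1, immune_set_size = 5,
                                               tc_set_size = 5,
                                               censor_fraction = 0.3,
                                               seed = s))$clinical$event))
  expect_lt(abs(mean(cens) - 0.3), 0.10)

  # planted_hazard_ratio = 1: Cox on the true burden finds log-HR ~ 0
  lhr <- sapply(1:50, function(s) {
    co <- simulate_cohort(cohort_sim_config(n_samples = 150, n_genes = 60,
                                            signature_genes = sprintf("g%04d", 1:5),
                                            n_immune_sets = 1, immune_set_size = 10,
                                            tc_set_size = 10,
                                            planted_hazard_ratio = 1, seed = s))
    tr <- attr(co, "truth")
    coef(survival::coxph(survival::Surv(co$clinical$OS_time, co$clinical$event) ~ tr$z))
  })
  expect_lt(abs(mean(lhr)), 0.1)
})

test_that("cohort ground-truth z recovers the planted log-HR by Cox regression", {
  lhr <- sapply(1:30, function(s) {
    co <- simulate_cohort(cohort_sim_config(n_samples = 300, n_genes = 60,
                                            signature_genes = sprintf("g%04d", 1:5),
                                            n_immune_sets = 1, immune_set_size = 10,
                                            tc_set_size = 10,
                                            planted_hazard_ratio = 2, seed = s))
    tr <- attr(co, "truth")
    coef(survival::coxph(survival::Surv(co$clinical$OS_time, co$clinical$event) ~ tr$z))
  })
  expect_lt(abs(mean(lhr) - log(2)), 0.05)  # Monte-Carlo error at 30 x 300
})

test_that("simulate_fish: exact geometry, bounds checking, background channels", {
  # single nucleus, tumor 30/40 px away at 1 um/px -> 50 um (3-4-5 triangle)
  cfg <- fish_sim_config(image_size = c(256, 256), pixel_size_um = 1,
                         nuclei = data.frame(x = 100, y = 100, true_type = "Mac"),
                         tumor_centroids = data.frame(x = 130, y = 140))
  sim <- simulate_fish(cfg)
  expect_equal(sim$truth$nearest_tumor_um, 50)

  # spots are validated against the bounds
  expect_error(fish_sim_config(
    image_size = c(64, 64),
    nuclei = data.frame(x = 60, y = 32, true_type = "Mac"),
    spot_offsets = list(data.frame(channel = "ch", dx_um = 10, dy_um = 0))),
    "outside image bounds")

  # no spots + no noise -> no marker channels, all-zero tumor channel when empty
  sim0 <- simulate_fish(fish_sim_config(
    nuclei = data.frame(x = 50, y = 50, true_type = "Mac"), noise_level = 0))
  expect_identical(names(sim0$scene$channels), c("DAPI", "Tumor"))
  expect_true(all(sim0$scene$channels$Tumor == 0))

  # determinism with noise
  cfgn <- fish_sim_config(nuclei = data.frame(x = 50, y = 50, true_type = "Mac"),
                          noise_level = 0.05, seed = 9)
  expect_identical(simulate_fish(cfgn)$scene$channels$DAPI,
                   simulate_fish(cfgn)$scene$channels$DAPI)
})
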