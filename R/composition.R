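# Cell-type composition per disease stage with bias-corrected and accelerated
# (BCa) bootstrap confidence intervals, and stage contrasts.

# Adjusted-percentile endpoints given the bootstrap replicates, the point
# estimate's bias-correction z0 and the acceleration a.
bca_endpoints <- function(t_boot, z0, accel, level) {
  a_lo <- (1 - level) / 2
  z_lo <- stats::qnorm(a_lo); z_hi <- stats::qnorm(1 - a_lo)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  B <- length(t_boot)
  p <- pmin(pmax(c(adj(z_lo), adj(z_hi)), 1 / (B + 1)), B / (B + 1))
  stats::quantile(t_boot, p, names = FALSE)
}

# Midrank bias-correction: fraction of bootstrap replicates below the point
# estimate, counting ties at the estimate with half weight (well calibrated
# for discrete statistics such as proportions).
bca_z0 <- function(t_boot, t0) {
  B <- length(t_boot)
  frac <- (sum(t_boot < t0) + 0.5 * sum(t_boot == t0)) / B
  stats::qnorm(pmin(pmax(frac, 1 / (B + 1)), B / (B + 1)))
}

# Jackknife acceleration (skewness of the leave-one-out statistics).
bca_accel <- function(t_jack) {
  d <- mean(t_jack) - t_jack
  denom <- sum(d^2)^1.5
  if (denom == 0) 0 else sum(d^3) / (6 * denom)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated bootstrap interval for an arbitrary
#' statistic of a sample (here typically the proportion of a cell type among
#' the cells of a disease stage). The bias correction z0 is estimated from the
#' fraction of bootstrap statistics below the point estimate (midrank tie
#' handling); the acceleration a from the jackknife skewness. With `z0 = 0`
#' and `accel = 0` the interval reduces exactly to the plain percentile
#' interval — both can be overridden for diagnostics.
#'
#' @param x observation vector (any type the statistic accepts), length >= 10.
#' @param statistic function of a resampled `x` returning a scalar; see
#'   [proportion_of()].
#' @param n_boot number of bootstrap resamples.
#' @param level two-sided confidence level.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param z0,accel optional overrides of the estimated bias correction and
#'   acceleration.
#' @return list with `estimate`, `lo`, `hi`, `level`, `z0`, `accel`,
#'   `n_boot`. If every bootstrap statistic is identical the interval
#'   collapses to the point estimate with a warning.
#' @export
bca_ci <- function(x, statistic, n_boot = 1000, level = 0.95, seed = 1L,
                   z0 = NULL, accel = NULL) {
  n <- length(x)
  if (n < 10L) stopf("need >= 10 observations (got %d)", n)
  assert_scalar_num(level, "level", lo = 0, hi = 1, strict_lo = TRUE)
  n_boot <- assert_count(n_boot, "n_boot", min = 100L)
  t0 <- statistic(x)
  t_boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(b) statistic(x[idx[, b]]), numeric(1))
  })
  if (all(t_boot == t_boot[1])) {
    warnf("degenerate bootstrap distribution; interval collapses to the point estimate")
    return(list(estimate = t0, lo = t0, hi = t0, level = level,
                z0 = 0, accel = 0, n_boot = n_boot))
  }
  if (is.null(z0)) z0 <- bca_z0(t_boot, t0)
  if (is.null(accel)) {
    t_jack <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
    accel <- bca_accel(t_jack)
  }
  ep <- bca_endpoints(t_boot, z0, accel, level)
  list(estimate = t0, lo = ep[1], hi = ep[2], level = level,
       z0 = z0, accel = accel, n_boot = n_boot)
}

#' Proportion-of-type statistic
#'
#' @param type the level whose relative frequency is returned.
#' @return a function suitable as the `statistic` of [bca_ci()].
#' @export
proportion_of <- function(type) {
  force(type)
  function(x) mean(x == type)
}

#' Cell-type composition per stage with BCa confidence intervals
#'
#' For every disease stage, estimates each cell type's proportion among the
#' stage's cells (within-stage proportions sum to 1) with a BCa bootstrap
#' interval. The resampling unit is the cell within its stage, matching data
#' pooled per stage; see [stage_contrast()] for stage comparisons.
#'
#' @param x a [labeled_expression()] or a data.frame with columns `stage`,
#'   `type`.
#' @param n_boot,level,seed passed to [bca_ci()] (the seed is advanced per
#'   stage/type so intervals are independent but reproducible).
#' @return data.frame of class `composition_estimate`: `stage`, `type`,
#'   `n_cells`, `proportion`, `lo`, `hi`.
#' @export
composition_estimate <- function(x, n_boot = 1000, level = 0.95, seed = 1L) {
  meta <- if (inherits(x, "labeled_expr")) x$cell_meta else x
  if (is.null(meta$stage) || is.null(meta$type))
    stopf("need cell metadata with 'stage' and 'type' columns")
  stages <- unique(meta$stage)
  types <- unique(meta$type)
  rows <- list(); k <- 0L
  for (s in stages) {
    cells <- meta$type[meta$stage == s]
    for (ty in types) {
      k <- k + 1L
      ci <- suppressWarnings(
        bca_ci(cells, proportion_of(ty), n_boot = n_boot, level = level,
               seed = seed + k))
      rows[[k]] <- data.frame(stage = s, type = ty, n_cells = length(cells),
                              proportion = ci$estimate, lo = ci$lo, hi = ci$hi,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("composition_estimate", "data.frame")
  out
}

#' Contrast a cell type's proportion between two stages
#'
#' Difference of proportions (stage_a minus stage_b) with a BCa interval from
#' paired independent resampling of each stage's cells; the acceleration is a
#' pooled jackknife over the cells of both stages.
#'
#' @param x a [labeled_expression()] or data.frame with `stage`, `type`.
#' @param stage_a,stage_b stage labels to compare.
#' @param type cell type whose proportion is contrasted; must occur in at
#'   least one of the two stages.
#' @param n_boot,level,seed passed through.
#' @return list of class `stage_contrast`: `stage_a`, `stage_b`, `type`,
#'   `prop_a`, `prop_b`, `diff`, `lo`, `hi`, `level`.
#' @export
stage_contrast <- function(x, stage_a, stage_b, type, n_boot = 1000,
                           level = 0.95, seed = 1L) {
  meta <- if (inherits(x, "labeled_expr")) x$cell_meta else x
  xa <- meta$type[meta$stage == stage_a]
  xb <- meta$type[meta$stage == stage_b]
  if (!length(xa)) stopf("stage '%s' has no cells", stage_a)
  if (!length(xb)) stopf("stage '%s' has no cells", stage_b)
  if (!any(c(xa, xb) == type)) stopf("type '%s' absent from both stages", type)
  pa <- mean(xa == type); pb <- mean(xb == type)
  t0 <- pa - pb
  na <- length(xa); nb <- length(xb)
  t_boot <- with_seed(seed, {
    ba <- matrix(sample(xa == type, na * n_boot, replace = TRUE), nrow = na)
    bb <- matrix(sample(xb == type, nb * n_boot, replace = TRUE), nrow = nb)
    colMeans(ba) - colMeans(bb)
  })
  if (all(t_boot == t_boot[1])) {
    warnf("degenerate bootstrap distribution; interval collapses to the point estimate")
    return(structure(list(stage_a = stage_a, stage_b = stage_b, type = type,
                          prop_a = pa, prop_b = pb, diff = t0, lo = t0, hi = t0,
                          level = level), class = "stage_contrast"))
  }
  # pooled jackknife: leaving out one cell of stage a (resp. b) changes only
  # that stage's proportion -> analytic leave-one-out values
  ja <- (sum(xa == type) - (xa == type)) / (na - 1) - pb
  jb <- pa - (sum(xb == type) - (xb == type)) / (nb - 1)
  accel <- bca_accel(c(ja, jb))
  ep <- bca_endpoints(t_boot, bca_z0(t_boot, t0), accel, level)
  structure(list(stage_a = stage_a, stage_b = stage_b, type = type,
                 prop_a = pa, prop_b = pb, diff = t0, lo = ep[1], hi = ep[2],
                 level = level), class = "stage_contrast")
}

#' @export
print.stage_contrast <- function(x, ...) {
  cat(sprintf("stage_contrast: P(%s | %s) - P(%s | %s) = %.4f [%.4f, %.4f] (%.0f%% BCa)\n",
              x$type, x$stage_a, x$type, x$stage_b, x$diff, x$lo, x$hi, 100 * x$level))
  invisible(x)
}
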