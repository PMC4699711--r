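# Mass-univariate group comparison with Monte-Carlo cluster-extent
# correction, in the AlphaSim tradition: the null is a smooth Gaussian field
# thresholded at the voxel level, and the family-wise cluster-size threshold
# is read off the simulated distribution of the maximum cluster extent.

#' Group design matrix
#'
#' Intercept, group indicator (patient = 1, control = 0) and the nuisance
#' covariates age, sex and education, one row per subject in map order.
#'
#' @param manifest Data frame with columns `group` (values `"patient"` /
#'   `"control"`), `age`, `sex`, `education`.
#' @return Numeric design matrix with named columns, checked for full rank.
#' @export
group_design <- function(manifest) {
  need <- c("group", "age", "sex", "education")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(manifest$group %in% c("patient", "control")))
    stopf("group must be 'patient' or 'control'")
  X <- cbind(intercept = 1,
             group = as.numeric(manifest$group == "patient"),
             age = as.numeric(manifest$age),
             sex = as.numeric(factor(manifest$sex, levels = c("F", "M"))) - 1,
             education = as.numeric(manifest$education))
  if (qr(X)$rank < ncol(X)) stopf("design matrix is rank deficient")
  X
}

#' Stat-map container
#'
#' @param t_values,p_values 3D arrays of t statistics and two-sided p values.
#' @param df Residual degrees of freedom.
#' @param mask 3D logical mask.
#' @param affine Voxel-to-world transform.
#' @param voxel_size_mm Voxel size in mm.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(t_values, p_values, df, mask, affine = NULL,
                     voxel_size_mm = 3) {
  structure(list(t_values = t_values, p_values = p_values, df = df,
                 mask = mask,
                 affine = affine %||% default_affine(dim(t_values), voxel_size_mm),
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3)),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  tv <- x$t_values[x$mask]
  cat(sprintf("<stat_map> %s, df=%d, t range [%.2f, %.2f]\n",
              paste(dim(x$t_values), collapse = "x"), x$df,
              min(tv), max(tv)))
  invisible(x)
}

#' Voxel-wise group GLM
#'
#' Per in-mask voxel, ordinary least-squares fit of the standardized map
#' values on the design; the reported t statistic is the coefficient of
#' `column` divided by its standard error, with two-sided p from Student's t
#' on n - p degrees of freedom. With an intercept + group design this equals
#' the classical pooled-variance two-sample t-test.
#'
#' @param maps List of 3D arrays (one per subject, design row order) or a
#'   voxels x subjects matrix of in-mask values.
#' @param design Numeric design matrix from [group_design()] (or any
#'   full-rank matrix with an `intercept` column).
#' @param mask 3D logical mask (required for list input).
#' @param column Name or index of the effect column (default `"group"`).
#' @param affine Optional affine carried to the result.
#' @return A [stat_map()].
#' @export
fit_group_glm <- function(maps, design, mask, column = "group",
                          affine = NULL) {
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (is.list(maps)) {
    if (length(maps) != n) stopf("got %d maps for %d design rows", length(maps), n)
    mask <- check_mask(mask, dim(maps[[1]]))
    Y <- vapply(maps, function(m) {
      if (!identical(dim(m), dim(mask))) stopf("map/mask shape mismatch")
      m[mask]
    }, numeric(sum(mask)))
  } else {
    Y <- as.matrix(maps)
    if (ncol(Y) != n) stopf("got %d map columns for %d design rows", ncol(Y), n)
  }
  if (n < p + 3) stopf("need at least %d subjects for %d design columns", p + 3, p)
  q <- qr(X)
  if (q$rank < p) stopf("design matrix is rank deficient")
  j <- if (is.character(column)) match(column, colnames(X)) else as.integer(column)
  if (is.na(j)) stopf("design has no column '%s'", column)
  Yt <- t(Y)                                   # n x V
  beta <- qr.coef(q, Yt)                       # p x V
  resid <- Yt - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  XtXinv_jj <- solve(crossprod(X))[j, j]
  se <- sqrt(sigma2 * XtXinv_jj)
  tval <- beta[j, ] / se
  tval[se == 0] <- 0
  pval <- 2 * pt(-abs(tval), df)
  tm <- array(0, dim(mask)); pm <- array(1, dim(mask))
  tm[mask] <- tval; pm[mask] <- pval
  stat_map(tm, pm, df, mask, affine = affine)
}

#' Monte-Carlo cluster-extent parameters
#'
#' @param voxel_p Two-sided voxel-level threshold (default 0.01).
#' @param alpha Corrected family-wise level (default 0.05).
#' @param n_iter Number of simulated noise fields (default 1000, minimum 100).
#' @param fwhm_mm Smoothness of the simulated fields, normally the smoothing
#'   actually applied to the analysed maps.
#' @param connectivity Cluster neighbourhood: 6, 18 or 26 (default 26).
#' @param seed RNG seed for the simulation.
#' @return An object of class `mc_params`.
#' @export
mc_params <- function(voxel_p = 0.01, alpha = 0.05, n_iter = 1000L,
                      fwhm_mm = 6, connectivity = 26L, seed = 1L) {
  if (voxel_p <= 0 || voxel_p >= 1) stopf("voxel_p must be in (0, 1)")
  if (n_iter < 100) stopf("n_iter must be >= 100")
  if (!connectivity %in% c(6L, 18L, 26L)) stopf("connectivity must be 6, 18 or 26")
  structure(list(voxel_p = voxel_p, alpha = alpha, n_iter = as.integer(n_iter),
                 fwhm_mm = fwhm_mm, connectivity = as.integer(connectivity),
                 seed = as.integer(seed)), class = "mc_params")
}

#' 3D connected-component labeling
#'
#' Labels the connected components of a 3D logical array under 6-, 18- or
#' 26-neighbour connectivity.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (length(d) != 3L) stopf("mask must be 3D")
  lab <- .label_components_3d(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  out <- array(lab, d)
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

# max suprathreshold cluster extent (both signs) of a standardized field
max_cluster_extent <- function(z, mask, thr, connectivity) {
  mx <- 0L
  for (sig in list(z > thr & mask, z < -thr & mask)) {
    if (any(sig)) {
      lab <- label_components(sig, connectivity)
      mx <- max(mx, max(tabulate(lab[lab > 0])))
    }
  }
  mx
}

#' Monte-Carlo cluster-extent threshold
#'
#' Estimates the minimum cluster extent controlling the family-wise error at
#' `alpha` for a given voxel-level threshold, by simulating `n_iter` smooth
#' Gaussian noise fields on the mask: each field is white noise smoothed to
#' `fwhm_mm`, re-standardized within the mask, thresholded two-sided at
#' `voxel_p`, and the maximum cluster extent (over both signs) is recorded.
#' `k_min` is the smallest extent k with `P(max cluster >= k) <= alpha`.
#'
#' @param mask 3D logical analysis mask.
#' @param mc An [mc_params()].
#' @param voxel_size_mm Voxel size in mm used to convert the smoothness.
#' @return List with `k_min`, the simulated `null_distribution` of maximum
#'   extents, and the parameters used. Deterministic given `mc$seed`.
#' @export
mc_cluster_extent <- function(mask, mc = mc_params(), voxel_size_mm = 3) {
  stopifnot(inherits(mc, "mc_params"))
  if (!any(mask)) stopf("mask is empty")
  if (mc$alpha < 1 / mc$n_iter)
    stopf("alpha = %g cannot be resolved with %d iterations", mc$alpha, mc$n_iter)
  d <- dim(mask)
  sig <- fwhm_to_sigma_vox(mc$fwhm_mm, rep(voxel_size_mm, length.out = 3))
  thr <- qnorm(1 - mc$voxel_p / 2)
  mvec <- as.vector(mask)
  null_max <- with_seed(mc$seed, {
    vapply(seq_len(mc$n_iter), function(i) {
      z <- array(rnorm(prod(d)), d)
      if (mc$fwhm_mm > 0) z <- smooth3d(z, sig)
      zi <- z[mvec]
      z[mvec] <- (zi - mean(zi)) / sd(zi)
      as.integer(max_cluster_extent(z, mask, thr, mc$connectivity))
    }, integer(1))
  })
  # smallest k with fraction of max extents >= k at most alpha
  k_min <- 1L
  while (mean(null_max >= k_min) > mc$alpha) k_min <- k_min + 1L
  list(k_min = k_min, null_distribution = null_max, params = mc)
}

#' Extract suprathreshold clusters
#'
#' Thresholds a stat map two-sided at the voxel level, labels connected
#' components separately for positive and negative t, drops components
#' smaller than `min_extent`, and reports each surviving cluster's sign, peak
#' |t| voxel (in world mm via the affine), peak t and extent. An empty table
#' is a valid result.
#'
#' @param stat A [stat_map()].
#' @param voxel_p Two-sided voxel-level p threshold (default 0.01).
#' @param min_extent Minimum cluster extent in voxels (default 50; clusters
#'   with extent >= `min_extent` are kept).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param labels Optional function mapping a peak world-coordinate row to an
#'   anatomical label (free text); default produces `NA`.
#' @return A data frame of class `cluster_table` with columns `sign`,
#'   `label`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `peak_t`,
#'   `extent_voxels`, sorted by sign then extent descending, with attribute
#'   `voxel_volume_mm3`.
#' @export
extract_clusters <- function(stat, voxel_p = 0.01, min_extent = 50L,
                             connectivity = 26L, labels = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  if (!any(stat$mask)) stopf("stat map mask is empty")
  if (voxel_p <= 0 || voxel_p >= 1) stopf("voxel_p must be in (0, 1)")
  sig <- stat$p_values < voxel_p & stat$mask
  rows <- list()
  for (sgn in c(1, -1)) {
    part <- sig & (if (sgn > 0) stat$t_values > 0 else stat$t_values < 0)
    if (!any(part)) next
    lab <- label_components(part, connectivity)
    sizes <- tabulate(lab[lab > 0])
    for (cl in which(sizes >= min_extent)) {
      vox <- which(lab == cl)
      peak <- vox[which.max(abs(stat$t_values[vox]))]
      ijk0 <- arrayInd(peak, dim(lab)) - 1L
      world <- voxel_to_world(ijk0, stat$affine)
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "positive" else "negative",
        label = NA_character_,
        peak_x_mm = world[1], peak_y_mm = world[2], peak_z_mm = world[3],
        peak_t = stat$t_values[peak],
        extent_voxels = sizes[cl],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(), label = character(),
               peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric(), peak_t = numeric(),
               extent_voxels = integer(), stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- tab[order(tab$sign == "negative", -tab$extent_voxels), , drop = FALSE]
    rownames(tab) <- NULL
    if (!is.null(labels))
      tab$label <- vapply(seq_len(nrow(tab)), function(i)
        as.character(labels(c(tab$peak_x_mm[i], tab$peak_y_mm[i],
                              tab$peak_z_mm[i]))), character(1))
  }
  attr(tab, "voxel_volume_mm3") <- prod(stat$voxel_size_mm)
  class(tab) <- c("cluster_table", class(tab))
  tab
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d cluster(s), voxel volume %.1f mm3\n",
              nrow(x), attr(x, "voxel_volume_mm3")))
  if (nrow(x)) print.data.frame(x, digits = 3)
  invisible(x)
}
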