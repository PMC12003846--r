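#' Seed-based correlation map
#'
#' The seed time course is the mean over seed voxels; every voxel's Pearson
#' correlation with it is Fisher z-transformed.
#'
#' @param vols a [volume_series()] (typically cleaned; see [clean_volumes()]).
#' @param seed_mask logical 3-D array marking the seed region.
#' @param mask analysis mask (default the `brain` mask if present, else all).
#' @return object of class `stat_map` with `values` (3-D z array, NA outside
#'   mask), `df` (frames - 3), `mask`, `kind = "seed_z"`.
#' @export
seed_map <- function(vols, seed_mask, mask = NULL) {
  if (!any(seed_mask)) stopf("seed mask is empty")
  if (is.null(mask)) mask <- vols$masks[["brain"]]
  if (is.null(mask)) mask <- array(TRUE, dim = dim(vols$data)[1:3])
  if (!all(seed_mask[!mask] == FALSE)) stopf("seed mask must lie inside the analysis mask")
  nt <- vols$frames
  mat <- matrix(vols$data, ncol = nt)
  seed_tc <- colMeans(mat[as.vector(seed_mask), , drop = FALSE])
  if (sd(seed_tc) == 0) stopf("seed time course has zero variance")
  vsel <- as.vector(mask)
  sub <- mat[vsel, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  r <- rep(NA_real_, nrow(sub))
  ok <- sds > 0
  r[ok] <- as.vector(cor(seed_tc, t(sub[ok, , drop = FALSE])))
  z <- atanh_capped(r)
  vals <- array(NA_real_, dim = dim(vols$data)[1:3])
  vals[vsel] <- z
  structure(list(values = vals, df = nt - 3, mask = mask, kind = "seed_z"),
            class = "stat_map")
}

#' Voxelwise group t-test over statistic maps
#'
#' One-sample t against zero (`groups = NULL`), or two-sample t (group A
#' minus group B). The two-sample default is pooled-variance Student's t;
#' `var_equal = FALSE` switches to Welch.
#'
#' @param maps list of `stat_map`s on a common grid.
#' @param groups optional binary labels (factor/character/logical), one per map.
#' @param var_equal pooled-variance (default) vs Welch for two samples.
#' @return `stat_map` with `values` (t), `p` (two-sided), `df`, `mask`,
#'   `n_flagged` zero-variance voxels (p set to 1).
#' @export
group_ttest <- function(maps, groups = NULL, var_equal = TRUE) {
  stacked <- vapply(maps, function(m) as.vector(m$values), numeric(length(maps[[1]]$values)))
  mask <- maps[[1]]$mask
  vsel <- as.vector(mask) & apply(stacked, 1, function(r) all(is.finite(r)))
  X <- stacked[vsel, , drop = FALSE]
  if (is.null(groups)) {
    n <- ncol(X)
    if (n < 3) stopf("need >= 3 maps for a one-sample t-test")
    mu <- rowMeans(X)
    sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
    tt <- rep(NA_real_, length(mu))
    zero <- sdv == 0
    tt[!zero] <- mu[!zero] / (sdv[!zero] / sqrt(n))
    big <- sqrt(.Machine$double.xmax) / 10
    tt[zero] <- sign(mu[zero]) * big      # identical nonzero maps: capped t
    tt[zero & mu == 0] <- 0
    df <- n - 1
    p <- 2 * pt(-abs(tt), df)
    p[zero & mu == 0] <- 1
    n_flagged <- sum(zero)
  } else {
    g <- as.factor(groups)
    if (nlevels(g) != 2) stopf("groups must have exactly 2 levels")
    ia <- g == levels(g)[1]
    na <- sum(ia); nb <- sum(!ia)
    if (na < 3 || nb < 3) stopf("need >= 3 maps per group")
    A <- X[, ia, drop = FALSE]; B <- X[, !ia, drop = FALSE]
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- rowSums((A - ma)^2) / (na - 1)
    vb <- rowSums((B - mb)^2) / (nb - 1)
    if (var_equal) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- rep(na + nb - 2, length(ma))
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        pmax((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1), 1e-300)
    }
    zero <- se == 0
    tt <- rep(0, length(ma))
    tt[!zero] <- (ma[!zero] - mb[!zero]) / se[!zero]
    p <- rep(1, length(ma))
    p[!zero] <- 2 * pt(-abs(tt[!zero]), df[!zero])
    n_flagged <- sum(zero)
    df <- if (var_equal) na + nb - 2 else NA_real_
  }
  tv <- array(NA_real_, dim = dim(maps[[1]]$values))
  pv <- array(NA_real_, dim = dim(maps[[1]]$values))
  tv[vsel] <- tt
  pv[vsel] <- p
  structure(list(values = tv, p = pv, df = df, mask = mask,
                 n_flagged = n_flagged, kind = "t"),
            class = "stat_map")
}

#' Cluster-extent thresholding
#'
#' Binarizes the voxelwise p map at `p_voxel`, labels connected components
#' under the chosen neighborhood, and discards components smaller than
#' `min_cluster` voxels (the conventional extent threshold).
#'
#' @param stat a `stat_map` carrying a `p` array (see [group_ttest()]).
#' @param p_voxel voxelwise threshold (default 0.01).
#' @param min_cluster minimum surviving cluster size (default 40).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners).
#' @return object of class `cluster_result` with `labels` (3-D integer array,
#'   0 = background), `sizes`, `n_clusters`, `frac_significant` (percent of
#'   mask voxels inside surviving clusters), `connectivity`.
#' @export
cluster_threshold <- function(stat, p_voxel = 0.01, min_cluster = 40,
                              connectivity = c(6, 18, 26)) {
  connectivity <- as.integer(match.arg(as.character(connectivity[1]), c("6", "18", "26")))
  if (is.null(stat$p)) stopf("stat map carries no p array; run group_ttest first")
  if (min_cluster < 1) stopf("min_cluster must be >= 1")
  mask <- stat$mask
  supra <- !is.na(stat$p) & stat$p < p_voxel & mask
  lab <- label_components(supra, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_cluster)
  out_lab <- array(0L, dim = dim(lab))
  new_id <- integer(length(sizes))
  new_id[keep] <- seq_along(keep)
  pos <- lab > 0
  out_lab[pos] <- new_id[lab[pos]]
  structure(list(labels = out_lab, sizes = sizes[keep],
                 n_clusters = length(keep),
                 frac_significant = 100 * sum(sizes[keep]) / max(sum(mask), 1),
                 connectivity = connectivity),
            class = "cluster_result")
}

# connected-component labeling by breadth-first search over a 3-D mask
label_components <- function(bin, connectivity = 6L) {
  d <- dim(bin)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx_all <- which(bin)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (bin[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  switch(as.character(connectivity),
         "6" = g[ord == 1, , drop = FALSE],
         "18" = g[ord <= 2, , drop = FALSE],
         "26" = g)
}

#' Low/high-motion subgroups
#'
#' Ranks scans by post-censoring mean FD; the lowest `floor(fraction * N)`
#' form the low-motion group and the highest the high-motion group. Ties are
#' broken by scan id for determinism.
#'
#' @param summaries data.frame with `scan_id` and `fd_ave` (or a named list of
#'   [motion_summary()] objects).
#' @param fraction group fraction (default 0.10).
#' @return list with `low` and `high` character vectors of scan ids.
#' @export
motion_subgroups <- function(summaries, fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5) stopf("fraction must be in (0, 0.5]")
  if (!is.data.frame(summaries)) {
    summaries <- data.frame(scan_id = names(summaries),
                            fd_ave = vapply(summaries, function(s) s$fd_ave, 0),
                            stringsAsFactors = FALSE)
  }
  n <- nrow(summaries)
  k <- floor(fraction * n)
  if (k < 3) stopf("subgroups of size %d < 3; t-test infeasible", k)
  o <- order(summaries$fd_ave, summaries$scan_id)
  list(low = summaries$scan_id[o[seq_len(k)]],
       high = summaries$scan_id[o[(n - k + 1):n]])
}
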