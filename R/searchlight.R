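# Whole-brain searchlight maps, cluster-mass family-wise-error inference by
# sign-flipping, and the timeline-accuracy encoding map.

#' Searchlight center coordinates
#'
#' For side-3 cubes the strict-interior rule is used: centers are voxels
#' whose full cube lies inside the grid. For larger cubes the same interior
#' rule applies; mask coverage is enforced per center via `min_voxels` in
#' [run_searchlight()].
#'
#' @param dims Integer grid dimensions (length 3).
#' @param side Odd cube side.
#' @return Integer matrix of center coordinates (one row per center).
#' @export
searchlight_centers <- function(dims, side = 3) {
  if (side %% 2 != 1) abort("side must be odd")
  half <- (side - 1) / 2
  ranges <- purrr::map(dims, function(d) {
    if (d < side) integer(0) else (half + 1):(d - half)
  })
  as.matrix(expand.grid(x = ranges[[1]], y = ranges[[2]], z = ranges[[3]]))
}

cube_index_offsets <- function(dims, side) {
  half <- (side - 1) / 2
  off <- expand.grid(dx = -half:half, dy = -half:half, dz = -half:half)
  off$dx + off$dy * dims[1] + off$dz * dims[1] * dims[2]
}

#' Run a cubic searchlight over a 4D volume
#'
#' For each in-mask interior center, the cube-and-mask voxel set is
#' collected; centers with fewer than `min_voxels` voxels are skipped; the
#' statistic is written at the center voxel.
#'
#' @param bold 4D array `x,y,z,t`.
#' @param mask Logical 3D array.
#' @param stat_fn Function of a voxel x time matrix returning a scalar.
#' @param side Odd cube side (27-voxel cubes by default).
#' @param min_voxels Minimum cube-and-mask voxels (use 25 for 125-voxel
#'   cubes).
#' @return 3D statistic array (`NA` outside the evaluable region), class
#'   `stat_map` with the mask attached.
#' @export
run_searchlight <- function(bold, mask, stat_fn, side = 3, min_voxels = 1) {
  dims <- dim(mask)
  if (!any(mask)) abort("empty mask")
  centers <- searchlight_centers(dims, side)
  keep <- mask[centers]
  centers <- centers[keep, , drop = FALSE]
  offs <- cube_index_offsets(dims, side)
  T_ <- dim(bold)[4]
  flat <- matrix(bold, prod(dims), T_)
  mask_flat <- as.logical(mask)
  out <- array(NA_real_, dims)
  for (i in seq_len(nrow(centers))) {
    c_lin <- centers[i, 1] + (centers[i, 2] - 1) * dims[1] +
      (centers[i, 3] - 1) * dims[1] * dims[2]
    vox <- c_lin + offs
    vox <- vox[mask_flat[vox]]
    if (length(vox) < min_voxels) next
    out[c_lin] <- stat_fn(flat[vox, , drop = FALSE])
  }
  structure(out, class = c("stat_map", class(out)), mask = mask)
}

#' Group searchlight over per-participant volumes
#'
#' As [run_searchlight()], but `stat_fn` receives one voxel x time matrix
#' per participant; centers where fewer than `min_participants` participants
#' have at least `min_voxels` in-mask brain voxels are skipped.
#'
#' @param bolds List of 4D arrays (shared grid).
#' @param masks List of logical 3D arrays, one per participant.
#' @param stat_fn Function of a list of matrices returning a scalar.
#' @param side,min_voxels As in [run_searchlight()].
#' @param min_participants Minimum participants contributing to a center.
#' @return 3D statistic array of class `stat_map`.
#' @export
run_searchlight_group <- function(bolds, masks, stat_fn, side = 5,
                                  min_voxels = 25, min_participants = 5) {
  dims <- dim(masks[[1]])
  union_mask <- Reduce(`|`, masks)
  if (!any(union_mask)) abort("empty mask")
  centers <- searchlight_centers(dims, side)
  centers <- centers[union_mask[centers], , drop = FALSE]
  offs <- cube_index_offsets(dims, side)
  T_ <- dim(bolds[[1]])[4]
  flats <- purrr::map(bolds, function(b) matrix(b, prod(dims), T_))
  mask_flats <- purrr::map(masks, as.logical)
  out <- array(NA_real_, dims)
  for (i in seq_len(nrow(centers))) {
    c_lin <- centers[i, 1] + (centers[i, 2] - 1) * dims[1] +
      (centers[i, 3] - 1) * dims[1] * dims[2]
    vox_all <- c_lin + offs
    vox_all <- vox_all[vox_all >= 1 & vox_all <= prod(dims)]
    per <- purrr::map(seq_along(flats), function(p) {
      vox <- vox_all[mask_flats[[p]][vox_all]]
      if (length(vox) < min_voxels) return(NULL)
      flats[[p]][vox, , drop = FALSE]
    })
    per <- purrr::compact(per)
    if (length(per) < min_participants) next
    out[c_lin] <- stat_fn(per)
  }
  structure(out, class = c("stat_map", class(out)), mask = union_mask)
}

# 26-connectivity labeling of a logical 3D array by breadth-first search.
label_components <- function(supra) {
  dims <- dim(supra)
  labels <- array(0L, dims)
  idx <- which(supra)
  if (length(idx) == 0) return(labels)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0 & nb$dz == 0), ]
  current <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      z <- (v - 1) %/% (dims[1] * dims[2]) + 1
      rem <- (v - 1) %% (dims[1] * dims[2])
      y <- rem %/% dims[1] + 1
      x <- rem %% dims[1] + 1
      nx <- x + nb$dx; ny <- y + nb$dy; nz <- z + nb$dz
      ok <- nx >= 1 & nx <= dims[1] & ny >= 1 & ny <= dims[2] &
        nz >= 1 & nz <= dims[3]
      lin <- nx[ok] + (ny[ok] - 1) * dims[1] + (nz[ok] - 1) * dims[1] * dims[2]
      lin <- lin[supra[lin] & labels[lin] == 0L]
      if (length(lin) > 0) {
        labels[lin] <- current
        queue <- c(queue, lin)
      }
    }
  }
  labels
}

# Voxelwise right-tailed one-sample t on an n x V matrix (columns = voxels),
# under an optional sign-flip vector.
voxelwise_t <- function(M, signs = NULL) {
  n <- nrow(M)
  if (!is.null(signs)) M <- M * signs
  mu <- colMeans(M)
  ss <- colMeans(M^2)
  v <- (ss - mu^2) * n / (n - 1)
  mu / sqrt(v / n)
}

max_cluster_mass <- function(t_flat, dims, mask_flat, t_thresh) {
  supra_flat <- mask_flat & !is.na(t_flat) & t_flat > t_thresh
  if (!any(supra_flat)) return(0)
  lab <- label_components(array(supra_flat, dims))
  masses <- tapply(t_flat[lab > 0], lab[lab > 0], sum)
  max(masses)
}

#' Cluster-mass family-wise-error inference on one-sample maps
#'
#' Voxelwise right-tailed one-sample t-test across maps, supra-threshold
#' voxels (uncorrected p below `cluster_p`) labeled by 26-connectivity, and
#' each cluster's mass (sum of supra-threshold t) referred to the
#' permutation distribution of the maximum cluster mass under sign-flipping
#' of whole maps. With `n` maps and `2^n <= n_perm` the full sign-pattern
#' set is enumerated and the corrected p-values are deterministic.
#'
#' @param maps List of 3D statistic arrays (one per participant or
#'   interval; `NA` allowed outside the mask).
#' @param mask Logical 3D array; default = voxels finite in every map.
#' @param cluster_p Cluster-forming threshold (uncorrected, one-tailed).
#' @param n_perm Number of sign-flip permutations.
#' @param seed RNG seed.
#' @return A `cluster_result`: list with `clusters` tibble (`cluster_id`,
#'   `mass`, `size`, `p_fwe`, `cog_x`, `cog_y`, `cog_z`), the `labels`
#'   array, `t_map`, and `t_threshold`.
#' @export
cluster_mass_fwe <- function(maps, mask = NULL, cluster_p = 0.01,
                             n_perm = 10000, seed = 1) {
  n <- length(maps)
  if (n < 8) abort("need at least 8 maps for permutation resolution")
  dims <- dim(maps[[1]])
  M <- do.call(rbind, purrr::map(maps, as.numeric))
  if (is.null(mask)) {
    mask <- array(colSums(is.na(M)) == 0, dims)
  }
  mask_flat <- as.logical(mask)
  M[, !mask_flat] <- 0
  M[is.na(M)] <- 0
  t_thresh <- stats::qt(1 - cluster_p, df = n - 1)
  t_obs <- voxelwise_t(M)
  supra <- mask_flat & !is.na(t_obs) & t_obs > t_thresh
  labels <- label_components(array(supra, dims))
  exact <- 2^n <= n_perm
  sign_mat <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                           nrow = n_perm, ncol = n))
  }
  perm_max <- apply(sign_mat, 1, function(s) {
    max_cluster_mass(voxelwise_t(M, s), dims, mask_flat, t_thresh)
  })
  n_eff <- nrow(sign_mat)
  cl_ids <- sort(unique(labels[labels > 0]))
  clusters <- purrr::map_dfr(cl_ids, function(id) {
    vox <- which(labels == id)
    mass <- sum(t_obs[vox])
    coords <- arrayInd(vox, dims)
    p_fwe <- if (exact) {
      sum(perm_max >= mass) / n_eff
    } else {
      (1 + sum(perm_max >= mass)) / (1 + n_eff)
    }
    tibble(cluster_id = id, mass = mass, size = length(vox), p_fwe = p_fwe,
           cog_x = mean(coords[, 1]), cog_y = mean(coords[, 2]),
           cog_z = mean(coords[, 3]))
  })
  structure(list(clusters = clusters, labels = labels,
                 t_map = array(ifelse(mask_flat, t_obs, NA_real_), dims),
                 t_threshold = t_thresh, exact = exact,
                 n_permutations = n_eff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), t threshold %.3f, %s%d permutations\n",
              nrow(x$clusters), x$t_threshold,
              if (x$exact) "exact enumeration of " else "", x$n_permutations))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Voxelwise encoding map of timeline accuracy
#'
#' Each voxel's activity is averaged over the 5-TR window centered on every
#' clip's midpoint; the per-clip activity is correlated with the
#' participant's timeline-placement accuracy (negative absolute regression
#' residual) across clips, and the r map is Fisher-transformed.
#'
#' @param bold 4D array `x,y,z,t`.
#' @param mask Logical 3D array.
#' @param placements One participant's placements (`clip_id`, `placed_s`).
#' @param schedule A `clip_schedule`.
#' @param tr_seconds Sampling period.
#' @param window Clip window (TRs).
#' @return 3D Fisher-z array of class `stat_map`.
#' @export
encoding_accuracy_map <- function(bold, mask, placements, schedule,
                                  tr_seconds = schedule$tr_seconds,
                                  window = 5) {
  if (nrow(schedule$clips) < 3) abort("need at least 3 clips")
  acc_tbl <- timeline_accuracy(
    placements %>% mutate(participant_id = 1L), schedule
  )$per_clip
  acc <- acc_tbl$accuracy[match(schedule$clips$clip_id, acc_tbl$clip_id)]
  if (sd(acc) < 1e-10) abort("zero-variance accuracy (perfect placements)")
  dims <- dim(mask)
  T_ <- dim(bold)[4]
  flat <- matrix(bold, prod(dims), T_)
  half <- (window - 1) / 2
  mids <- clip_middle_tr(schedule$clips$onset_s, schedule$clips$duration_s,
                         tr_seconds)
  clip_act <- vapply(mids, function(m) {
    idx <- m + (-half:half)
    if (idx[1] < 1) idx <- idx - idx[1] + 1
    if (idx[window] > T_) idx <- idx - (idx[window] - T_)
    rowMeans(flat[, idx, drop = FALSE])
  }, numeric(prod(dims)))
  out <- array(NA_real_, dims)
  mask_idx <- which(as.logical(mask))
  r <- as.numeric(cor(t(clip_act[mask_idx, , drop = FALSE]), acc))
  out[mask_idx] <- fisher_z(r, warn_clamp = FALSE)
  structure(out, class = c("stat_map", class(out)), mask = mask)
}
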