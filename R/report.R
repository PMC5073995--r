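#' Cluster-level result report
#'
#' Summarizes the retained clusters of a fitted voxel set: size, centroid
#' (voxel and mm coordinates), the direction of the group effect, and the
#' smallest per-voxel p-value in the cluster. The direction compares the
#' cluster-mean signal between the positive class and controls
#' (`"increased"` when the positive-class mean is higher). The per-voxel
#' test is the two-sided Wilcoxon rank-sum test — a rank test is the
#' defensible default because most voxel intensity distributions fail a
#' normality screen (see [normality_screen()]).
#'
#' @param m A [subject_matrix()] covering (at least) the labeled voxels.
#' @param labeling A [cluster_labeling][grid_dbscan()] over a subset of
#'   `m`'s coordinates (e.g. the `best_labeling` of a [voxrfe()] fit).
#' @param best_columns Column indices of `m` corresponding to the rows of
#'   `labeling$coords`.
#' @return A `data.frame` with one row per cluster, sorted by decreasing
#'   `n_voxels`: `cluster_id`, `n_voxels`, `centroid_x/y/z` (voxel),
#'   `centroid_mm_x/y/z`, `direction`, `min_p`, `atlas_label` (`NA` until
#'   [attach_atlas_labels()] fills it). Empty cluster sets give an empty
#'   report.
#' @export
cluster_report <- function(m, labeling, best_columns) {
  stopifnot(inherits(m, "subject_matrix"))
  if (length(best_columns) != nrow(labeling$coords))
    stop("'best_columns' must index one matrix column per labeled voxel")
  ids <- sort(unique(labeling$cluster_id[labeling$cluster_id > 0L]))
  pos <- m$labels == m$positive_class
  rows <- lapply(ids, function(id) {
    sel <- labeling$cluster_id == id
    cols <- best_columns[sel]
    co <- labeling$coords[sel, , drop = FALSE]
    cluster_mean <- rowMeans(m$values[, cols, drop = FALSE])
    diff <- mean(cluster_mean[pos]) - mean(cluster_mean[!pos])
    pvals <- vapply(cols, function(j)
      stats::wilcox.test(m$values[pos, j], m$values[!pos, j],
                         exact = FALSE)$p.value, numeric(1))
    centroid <- colMeans(co)
    cmm <- if (is.null(m$geometry)) rep(NA_real_, 3) else
      drop(voxel_to_mm(round(centroid), m$geometry))
    data.frame(cluster_id = id, n_voxels = sum(sel),
               centroid_x = centroid[1], centroid_y = centroid[2],
               centroid_z = centroid[3],
               centroid_mm_x = cmm[1], centroid_mm_y = cmm[2],
               centroid_mm_z = cmm[3],
               direction = if (diff >= 0) "increased" else "decreased",
               min_p = min(pvals), atlas_label = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    utils::read.csv(text = paste0("cluster_id,n_voxels,centroid_x,centroid_y,",
                                  "centroid_z,centroid_mm_x,centroid_mm_y,",
                                  "centroid_mm_z,direction,min_p,atlas_label"))
  out <- out[order(-out$n_voxels, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach anatomical atlas labels to a cluster report
#'
#' Labels each cluster with the atlas region containing its centroid voxel.
#' The atlas is an integer-valued volume on the same grid; region names come
#' from a CSV table with columns `id` and `name`. Centroids falling on
#' atlas value 0 (or an id missing from the table) are labeled
#' `"unlabeled"`.
#'
#' @param rows A [cluster_report()] data frame.
#' @param atlas_volume Path to the atlas NIfTI (or a 3D array).
#' @param atlas_names Path to the id/name CSV (or a data frame).
#' @param geometry The report's [vox_geometry()] (required to verify the
#'   atlas grid when `atlas_volume` is a file).
#' @return The report with `atlas_label` filled in.
#' @export
attach_atlas_labels <- function(rows, atlas_volume, atlas_names,
                                geometry = NULL) {
  if (is.character(atlas_volume)) {
    img <- RNifti::readNifti(atlas_volume)
    if (!is.null(geometry) && !geometry_equal(geometry_from_nifti(img),
                                              geometry))
      stop("atlas geometry does not match the report geometry")
    atlas_volume <- as.array(img)
  }
  names_tab <- if (is.data.frame(atlas_names)) atlas_names else
    utils::read.csv(atlas_names, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(names_tab)))
    stop("atlas names table must have columns 'id' and 'name'")
  if (nrow(rows) == 0L) return(rows)
  for (i in seq_len(nrow(rows))) {
    vox <- round(c(rows$centroid_x[i], rows$centroid_y[i],
                   rows$centroid_z[i])) + 1L
    lab <- "unlabeled"
    if (all(vox >= 1L) && all(vox <= dim(atlas_volume))) {
      v <- atlas_volume[vox[1], vox[2], vox[3]]
      hit <- match(v, names_tab$id)
      if (v != 0 && !is.na(hit)) lab <- names_tab$name[hit]
    }
    rows$atlas_label[i] <- lab
  }
  rows
}
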