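#' Subjects-by-voxels data matrix
#'
#' The central exchange type: a real matrix with one row per subject and one
#' column per mask-interior voxel, together with the ordered list of 0-based
#' lattice coordinates each column maps to, the two-class labels, and the
#' grid geometry. Columns always enumerate mask voxels in x-fastest scan
#' order (x varies fastest, then y, then z), so column indices are
#' reproducible across runs and cohorts sharing a mask.
#'
#' @param values Real matrix, rows = subjects, columns = voxels; all entries
#'   finite.
#' @param coords Integer matrix (n_voxels x 3) of 0-based lattice
#'   coordinates, one row per column of `values`; rows must be unique.
#' @param labels Two-class factor (or coercible) of length `nrow(values)`.
#' @param subject_ids Character vector of per-row identifiers.
#' @param geometry A [vox_geometry()].
#' @param positive_class Label treated as the "disease"/positive class for
#'   sensitivity and F-measure; defaults to the second factor level.
#' @return An object of class `subject_matrix`.
#' @export
subject_matrix <- function(values, coords, labels, subject_ids = NULL,
                           geometry = NULL, positive_class = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be a finite numeric matrix")
  coords <- rbind_coords(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) != ncol(values))
    stop("one coordinate triple is required per matrix column")
  if (anyDuplicated(coords))
    stop("'coords' rows must be unique")
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != nrow(values))
    stop("one label is required per matrix row")
  if (nlevels(labels) > 2L) stop("labels must have at most two classes")
  if (is.null(subject_ids))
    subject_ids <- sprintf("s%03d", seq_len(nrow(values)))
  if (anyDuplicated(subject_ids)) stop("'subject_ids' must be unique")
  if (is.null(positive_class)) positive_class <- levels(labels)[nlevels(labels)]
  if (!positive_class %in% levels(labels) && nrow(values) > 0)
    stop("'positive_class' is not one of the label levels")
  structure(list(values = values, coords = coords, labels = labels,
                 subject_ids = as.character(subject_ids),
                 geometry = geometry, positive_class = positive_class),
            class = "subject_matrix")
}

#' @export
print.subject_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<subject_matrix> %d subjects x %d voxels (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.subject_matrix <- function(x) dim(x$values)

## Column subset preserving coordinates; used throughout the RFE loop.
sm_subset <- function(m, cols) {
  m$values <- m$values[, cols, drop = FALSE]
  m$coords <- m$coords[cols, , drop = FALSE]
  m
}

#' Load a cohort of co-registered volumes into a subject matrix
#'
#' Reads one NIfTI volume per subject, checks that every volume shares the
#' mask's grid geometry, and flattens the mask-interior voxels of each
#' volume into one row of the subjects-by-voxels matrix. Rows follow the
#' label table order; columns follow the fixed x-fastest scan order over the
#' mask.
#'
#' @param label_table Path to a CSV file with columns `subject_id`, `path`
#'   and `label` (one row per subject, exactly one volume each), or a
#'   `data.frame` with those columns.
#' @param mask_path Path to the mask NIfTI, or a [brain_mask()].
#' @param volume_paths Optional character vector overriding the table's
#'   `path` column (same order as the table rows).
#' @param positive_class Optional label naming the positive (disease) class.
#' @return A [subject_matrix()].
#' @export
load_cohort <- function(label_table, mask_path, volume_paths = NULL,
                        positive_class = NULL) {
  tab <- if (is.data.frame(label_table)) label_table else
    utils::read.csv(label_table, stringsAsFactors = FALSE)
  need <- c("subject_id", "label")
  if (!all(need %in% names(tab)))
    stop("label table must have columns 'subject_id' and 'label'")
  if (is.null(volume_paths)) {
    if (!"path" %in% names(tab))
      stop("label table must have a 'path' column when 'volume_paths' is not given")
    volume_paths <- tab$path
  }
  if (length(volume_paths) != nrow(tab))
    stop("need exactly one volume per subject in the label table")
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in label table: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "))
  if (any(is.na(tab$label) | tab$label == ""))
    stop("missing label in label table")

  mask <- if (inherits(mask_path, "brain_mask")) mask_path else
    read_mask(mask_path)
  inside_idx <- which(mask$inside)
  values <- matrix(NA_real_, nrow(tab), length(inside_idx))
  for (i in seq_len(nrow(tab))) {
    img <- RNifti::readNifti(volume_paths[i])
    g <- geometry_from_nifti(img)
    if (!geometry_equal(g, mask$geometry))
      stop("volume geometry does not match the mask: ", volume_paths[i])
    v <- as.array(img)[inside_idx]
    if (any(!is.finite(v)))
      stop("non-finite voxel value inside the mask: ", volume_paths[i])
    values[i, ] <- v
  }
  subject_matrix(values, mask_coords(mask), tab$label,
                 subject_ids = tab$subject_id, geometry = mask$geometry,
                 positive_class = positive_class)
}

#' Normalize each subject to its whole-brain mean
#'
#' Divides every row by its own within-mask mean, removing global
#' differences in tracer uptake / cerebral blood flow between subjects.
#' Every output row has mean 1; the operation is idempotent.
#'
#' @param m A [subject_matrix()].
#' @return The normalized [subject_matrix()].
#' @export
whole_brain_normalize <- function(m) {
  mu <- rowMeans(m$values)
  if (any(mu <= 0))
    stop("degenerate scan: nonpositive whole-brain mean for subject(s) ",
         paste(m$subject_ids[mu <= 0], collapse = ", "))
  m$values <- m$values / mu
  m
}

#' Min-max scale columns to [-1, 1], fit on training data only
#'
#' Per column, the affine map sending the training minimum to -1 and the
#' training maximum to +1 is fitted on `train` and applied unchanged to
#' `test` (test values outside the training range are not clipped).
#' Constant training columns map to 0 everywhere.
#'
#' @param train Numeric matrix used to fit the per-column ranges.
#' @param test Optional numeric matrix with the same columns.
#' @return List with elements `train`, `test` (or `NULL`), and the fitted
#'   `min`/`max` vectors.
#' @examples
#' s <- minmax_scale(matrix(c(10, 20), 2, 1), matrix(25, 1, 1))
#' s$test  # 2, extrapolated beyond +1
#' @export
minmax_scale <- function(train, test = NULL) {
  fit <- minmax_fit(train)
  list(train = minmax_apply(train, fit),
       test = if (is.null(test)) NULL else minmax_apply(test, fit),
       min = fit$min, max = fit$max)
}

minmax_fit <- function(train) {
  train <- as.matrix(train)
  list(min = apply(train, 2, min), max = apply(train, 2, max))
}

minmax_apply <- function(x, fit) {
  x <- as.matrix(x)
  rng <- fit$max - fit$min
  const <- rng <= 0
  scale <- ifelse(const, 0, 2 / rng)
  centre <- ifelse(const, 0, (fit$max + fit$min) / 2)
  sweep(sweep(x, 2, centre, "-"), 2, scale, "*")
}

#' Write a cluster labeling as an integer NIfTI map
#'
#' Each labeled voxel carries its cluster ID; all other voxels are 0 (the
#' noise label is also written as 0). The map round-trips through
#' [RNifti::readNifti()].
#'
#' @param labeling A [cluster_labeling][grid_dbscan()].
#' @param geometry A [vox_geometry()] covering all labeled coordinates.
#' @param out_path Output NIfTI path.
#' @return The path, invisibly.
#' @export
write_cluster_map <- function(labeling, geometry, out_path) {
  arr <- array(0L, geometry$shape)
  if (nrow(labeling$coords) > 0) {
    co <- labeling$coords
    if (any(co < 0) || any(co >= matrix(geometry$shape, nrow(co), 3, byrow = TRUE)))
      stop("labeled coordinate outside the geometry")
    arr[co + 1L] <- as.integer(labeling$cluster_id)
  }
  write_nifti_volume(arr, geometry, out_path)
}

#' Export a cohort to the on-disk NIfTI + CSV layout
#'
#' Writes one volume per subject, the mask, and a `labels.csv` table that
#' [load_cohort()] consumes, so a generated cohort can exercise the same
#' input path as real data.
#'
#' @param m A [subject_matrix()] (with geometry).
#' @param mask A [brain_mask()] whose interior matches `m`'s columns.
#' @param dir Output directory (created if needed).
#' @return The path of the written label table, invisibly.
#' @export
write_cohort <- function(m, mask, dir) {
  if (is.null(m$geometry)) stop("subject matrix carries no geometry")
  if (mask$n_inside != ncol(m$values))
    stop("mask interior does not match the matrix columns")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inside_idx <- which(mask$inside)
  paths <- file.path(dir, sprintf("%s.nii.gz", m$subject_ids))
  for (i in seq_len(nrow(m$values))) {
    arr <- array(0, m$geometry$shape)
    arr[inside_idx] <- m$values[i, ]
    write_nifti_volume(arr, m$geometry, paths[i])
  }
  write_mask(mask, file.path(dir, "mask.nii.gz"))
  tab <- data.frame(subject_id = m$subject_ids, path = paths,
                    label = as.character(m$labels))
  utils::write.csv(tab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(file.path(dir, "labels.csv"))
}
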