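#' Dice similarity coefficient between binary masks
#'
#' `2 |A and B| / (|A| + |B|)` on identical grids.  Two empty masks give 1
#' with a warning.  The intersection-over-union is returned as attribute
#' `iou`.
#'
#' @param a,b [VoxelMask()] objects on the same grid.
#' @return DSC fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "VoxelMask"), inherits(b, "VoxelMask"))
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9)
    stop("masks are on different grids")
  na <- sum(a$values)
  nb <- sum(b$values)
  ni <- sum(a$values & b$values)
  if (na + nb == 0L) {
    warning("both masks empty; DSC defined as 1")
    return(structure(1, iou = 1))
  }
  structure(2 * ni / (na + nb), iou = ni / (na + nb - ni))
}

#' Directed and symmetric surface distances between two meshes
#'
#' Each vertex's point-to-triangle distance to the other surface, in both
#' directions.  The Hausdorff distance is the maximum over both directed
#' sets; the average distance is the mean of the concatenated directed
#' distances.
#'
#' @param pred,gt [TriMesh()] surfaces.
#' @return A `DistanceReport` list: `per_vertex_pred_to_gt`,
#'   `per_vertex_gt_to_pred`, `hausdorff`, `average` (all mm).
#' @export
surface_distances <- function(pred, gt) {
  stopifnot(inherits(pred, "TriMesh"), inherits(gt, "TriMesh"))
  if (nrow(pred$faces) == 0L || nrow(gt$faces) == 0L)
    stop("empty mesh")
  d_pg <- mesh_closest(pred$vertices, gt)$dist
  d_gp <- mesh_closest(gt$vertices, pred)$dist
  structure(list(per_vertex_pred_to_gt = d_pg,
                 per_vertex_gt_to_pred = d_gp,
                 hausdorff = max(max(d_pg), max(d_gp)),
                 average = mean(c(d_pg, d_gp))),
            class = "DistanceReport")
}

#' Fraction of predicted surface area farther than a threshold from truth
#'
#' Each predicted vertex owns one third of its incident triangle area; the
#' result is `100 *` (area owned by vertices with distance to the ground
#' truth surface above `threshold`) `/` total predicted area.
#'
#' @param pred,gt [TriMesh()] surfaces.
#' @param threshold distance threshold in mm (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
area_fraction_over <- function(pred, gt, threshold = 1.0) {
  stopifnot(inherits(pred, "TriMesh"), inherits(gt, "TriMesh"))
  if (threshold <= 0) stop("threshold must be > 0")
  d <- mesh_closest(pred$vertices, gt)$dist
  fa <- mesh_face_areas(pred)
  va <- numeric(nrow(pred$vertices))
  for (k in 1:3)
    va <- va + tabulate0(pred$faces[, k], fa / 3, length(va))
  100 * sum(va[d > threshold]) / sum(va)
}

#' Full segmentation-quality report
#'
#' Computes DSC, Hausdorff distance, average surface distance and the
#' area fraction beyond 1 mm between a prediction and a ground truth, each
#' given either as a mask or as a closed mesh.  Meshes are voxelized on
#' `grid` for the DSC; masks are converted to surfaces for the distance
#' metrics.
#'
#' @param pred,gt [TriMesh()] or [VoxelMask()] objects.
#' @param grid a [grid_spec()] for voxelization; defaults to the grid of
#'   `gt` (or `pred`) when one of them is a mask.
#' @param threshold area-fraction distance threshold (mm).
#' @return A `MetricsReport` list with `dsc` (fraction), `dsc_pct`, `iou`,
#'   `hausdorff_mm`, `average_mm`, `area_fraction_gt_1mm` (percent).
#' @export
evaluate_segmentation <- function(pred, gt, grid = NULL, threshold = 1.0) {
  if (is.null(grid)) {
    if (inherits(gt, "VoxelMask")) grid <- grid_from_mask(gt)
    else if (inherits(pred, "VoxelMask")) grid <- grid_from_mask(pred)
    else stop("a grid_spec is required when both inputs are meshes")
  }
  as_mask <- function(x) {
    if (inherits(x, "VoxelMask")) x else voxelize_surface(x, grid)
  }
  as_surf <- function(x) {
    if (inherits(x, "TriMesh")) x else mask_to_surface(x)
  }
  mp <- as_mask(pred)
  mg <- as_mask(gt)
  sp <- as_surf(pred)
  sg <- as_surf(gt)
  dsc <- dice(mp, mg)
  sd <- surface_distances(sp, sg)
  structure(list(dsc = as.numeric(dsc), dsc_pct = 100 * as.numeric(dsc),
                 iou = attr(dsc, "iou"),
                 hausdorff_mm = sd$hausdorff, average_mm = sd$average,
                 area_fraction_gt_1mm = area_fraction_over(sp, sg, threshold)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(paste0("MetricsReport: DSC %.2f%% | Hausdorff %.3f mm | ",
                     "average %.3f mm | area%%>1mm %.2f%%\n"),
              x$dsc_pct, x$hausdorff_mm, x$average_mm, x$area_fraction_gt_1mm))
  invisible(x)
}

#' Write a metrics report as a one-row CSV
#'
#' Columns: `dsc`, `hausdorff_mm`, `average_mm`, `delta_area_pct_gt_1mm`.
#'
#' @param report a `MetricsReport`.
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  stopifnot(inherits(report, "MetricsReport"))
  utils::write.csv(data.frame(dsc = report$dsc,
                              hausdorff_mm = report$hausdorff_mm,
                              average_mm = report$average_mm,
                              delta_area_pct_gt_1mm = report$area_fraction_gt_1mm),
                   path, row.names = FALSE)
  invisible(path)
}
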