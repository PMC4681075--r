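#' Parcellation objects
#'
#' A parcellation is an integer label grid (0 = background, `1..N` = regions)
#' with physical voxel dimensions and a region table giving, for every region
#' id present in the grid, its name, hemisphere (`"L"` or `"R"`) and volume in
#' mm^3 (voxel count times voxel volume). Regions are the nodes of every
#' network downstream.
#'
#' @param labels 3D integer array of region labels; 0 is background.
#' @param voxel_size_mm numeric(3), positive voxel edge lengths in mm.
#' @param regions data.frame with columns `id`, `name`, `hemisphere`; a
#'   `volume_mm3` column is recomputed from the grid.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, voxel_size_mm, regions) {
  .assert(is.array(labels) && length(dim(labels)) == 3L,
          "labels must be a 3D array")
  .assert(all(labels == round(labels)) && all(labels >= 0),
          "labels must be non-negative integers")
  .assert(is.numeric(voxel_size_mm) && length(voxel_size_mm) == 3L &&
            all(voxel_size_mm > 0), "voxel_size_mm must be 3 positive reals")
  .assert(is.data.frame(regions) &&
            all(c("id", "name", "hemisphere") %in% names(regions)),
          "regions must have columns id, name, hemisphere")
  .assert(!anyDuplicated(regions$id), "duplicate region ids in region table")
  .assert(all(regions$hemisphere %in% c("L", "R")),
          "hemisphere must be 'L' or 'R' for every region")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  missing <- setdiff(present, regions$id)
  .assert(length(missing) == 0,
          "labels present in grid but absent from region table: %s",
          paste(missing, collapse = ", "))
  counts <- tabulate(match(as.vector(labels), regions$id), nbins = nrow(regions))
  regions$volume_mm3 <- counts * prod(voxel_size_mm)
  structure(
    list(labels = labels, voxel_size_mm = as.numeric(voxel_size_mm),
         regions = regions),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("parcellation: %d regions on a %dx%dx%d grid (voxel %s mm)\n",
              nrow(x$regions), d[1], d[2], d[3],
              paste(format(x$voxel_size_mm), collapse = "x")))
  cat(sprintf("  hemispheres: %d L / %d R; background voxels: %d\n",
              sum(x$regions$hemisphere == "L"),
              sum(x$regions$hemisphere == "R"),
              sum(x$labels == 0)))
  invisible(x)
}

#' Read a parcellation from a NIfTI label volume and a region table
#'
#' @param label_volume_path path to a NIfTI file holding integer labels.
#' @param region_table_path path to a TSV with columns `id`, `name`,
#'   `hemisphere`.
#' @return A [parcellation] with volumes computed from the grid.
#' @export
read_parcellation <- function(label_volume_path, region_table_path) {
  .assert(file.exists(label_volume_path), "no such file: %s", label_volume_path)
  .assert(file.exists(region_table_path), "no such file: %s", region_table_path)
  img <- RNifti::readNifti(label_volume_path)
  labels <- as.array(img)
  .assert(length(dim(labels)) == 3L, "label volume must be 3D")
  .assert(all(labels == round(labels)), "label volume is not integer-valued")
  .assert(any(labels != 0), "label volume contains no labelled voxels")
  voxel <- RNifti::pixdim(img)[1:3]
  regions <- utils::read.delim(region_table_path, stringsAsFactors = FALSE)
  parcellation(labels, voxel, regions)
}

#' Write a parcellation as a NIfTI label volume plus a TSV region table
#'
#' @param p a [parcellation].
#' @param label_volume_path output NIfTI path.
#' @param region_table_path output TSV path.
#' @export
write_parcellation <- function(p, label_volume_path, region_table_path) {
  .assert(inherits(p, "parcellation"), "p must be a parcellation")
  img <- RNifti::asNifti(p$labels)
  RNifti::pixdim(img) <- p$voxel_size_mm
  RNifti::writeNifti(img, label_volume_path)
  .write_atomic(region_table_path, function(tmp) {
    utils::write.table(p$regions, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(c(label_volume_path, region_table_path))
}
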