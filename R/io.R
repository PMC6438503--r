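#' Read and write b-tensor tables
#'
#' Plain-text sidecar with one row per volume. Full form: nine
#' whitespace-separated row-major tensor components in ms/um^2. Compact form
#' (axisymmetric tensors): five values \code{b b_delta dir_x dir_y dir_z}.
#' The two forms may be mixed row by row; comment lines start with \code{#}.
#'
#' @param path file path.
#' @return \code{read_btens}: a list of \code{btensor} objects.
#' @export
read_btens <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[rows[i]]), "\\s+")[[1]]))
    if (any(is.na(vals)))
      stop("unparseable b-tensor row at line ", rows[i], " of ", path)
    if (length(vals) == 9) {
      out[[i]] <- new_btensor(matrix(vals, 3, 3, byrow = TRUE))
    } else if (length(vals) == 5) {
      b <- vals[1]; bd <- vals[2]; n <- vals[3:5]
      if (b < 0 || bd < -0.5 || bd > 1)
        stop("invalid compact b-tensor row at line ", rows[i],
             ": need b >= 0 and b_delta in [-0.5, 1]")
      nrm <- sqrt(sum(n^2))
      n <- if (nrm > 0) n / nrm else c(0, 0, 1)
      out[[i]] <- new_btensor(btensor_axisym(b, bd, n))
    } else {
      stop("b-tensor rows must have 9 (full) or 5 (compact) values; line ",
           rows[i], " has ", length(vals))
    }
  }
  out
}

#' @param btensors list of \code{btensor} objects (or 3x3 matrices).
#' @rdname read_btens
#' @export
write_btens <- function(btensors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# b-tensor table: nine row-major components per volume, ms/um^2", con)
  for (B in btensors) {
    m <- as_btensor_matrix(B)
    writeLines(paste(format(as.vector(t(m)), digits = 15, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a diffusion-weighted dataset (NIfTI volume plus b-tensor table)
#'
#' @param nifti_path 4D NIfTI file.
#' @param btens_path b-tensor table aligned with the 4th axis.
#' @return an object of class \code{dwi_dataset}: list with \code{data} (4D
#'   array), \code{image} (the \code{niftiImage} carrying the affine),
#'   \code{btensors}, and \code{shells} (per-volume b / b_delta table).
#' @export
read_dataset <- function(nifti_path, btens_path) {
  img <- RNifti::readNifti(nifti_path)
  data <- as.array(img)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(dim(data)), " dimensions")
  btensors <- read_btens(btens_path)
  if (length(btensors) != dim(data)[4])
    stop("b-tensor table has ", length(btensors), " rows but the volume has ",
         dim(data)[4], " samples")
  shells <- btensor_table(btensors)
  if (max(shells$b) > 50)
    warning("largest b-value is ", signif(max(shells$b), 4),
            ": values this large suggest s/mm^2 units; expected ms/um^2 ",
            "(1 ms/um^2 = 1000 s/mm^2)")
  structure(list(data = data, image = img, btensors = btensors,
                 shells = shells), class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI dataset: %d x %d x %d voxels, %d volumes, b in [%g, %g] ms/um^2\n",
              d[1], d[2], d[3], d[4], min(x$shells$b), max(x$shells$b)))
  invisible(x)
}

#' Write parameter maps as NIfTI files with provenance
#'
#' Writes one float32 NIfTI per map (named \code{<name>.nii.gz}) plus a
#' \code{provenance.json} recording the seed, configuration and package
#' version.
#'
#' @param maps named list of 3D arrays.
#' @param out_dir output directory (created if missing).
#' @param template optional \code{niftiImage} (or path) supplying the affine.
#' @param seed,config optional provenance entries.
#' @return invisibly, the vector of files written.
#' @export
write_maps <- function(maps, out_dir, template = NULL, seed = NULL,
                       config = NULL) {
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(maps)) {
    img <- RNifti::asNifti(maps[[nm]], reference = template,
                           datatype = "float")
    f <- file.path(out_dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  prov <- list(
    package = "dividemri",
    version = as.character(utils::packageVersion("dividemri")),
    seed = seed, config = config, maps = names(maps))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(files, file.path(out_dir, "provenance.json")))
}
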