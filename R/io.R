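# Standard-format I/O: NIfTI stacks, a plain-text array-dump dialect, curve
# CSVs and JSON sidecars.

#' Write a noise ensemble to NIfTI files with a JSON sidecar
#'
#' One NIfTI file per repetition (`rep_001.nii.gz`, ...) plus
#' `ensemble.json` recording method, dose fraction, seed and pixel size.
#'
#' @param ens A [noise_ensemble()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the sidecar path.
#' @export
write_ensemble_nifti <- function(ens, dir) {
  stopifnot(inherits(ens, "noise_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(ens$n_rep)) {
    img <- ens$images[, , , r, drop = TRUE]
    if (length(dim(img)) < 3) dim(img) <- c(dim(ens$images)[1:2], 1)
    RNifti::writeNifti(
      RNifti::asNifti(img, pixdim = c(ens$pixel_size, ens$pixel_size, 1)),
      file.path(dir, sprintf("rep_%03d.nii.gz", r)))
  }
  sidecar <- file.path(dir, "ensemble.json")
  jsonlite::write_json(
    list(method = ens$provenance$method %||% NA,
         dose_fraction = ens$provenance$dose_fraction %||% 1,
         seed = ens$provenance$seed %||% NA,
         pixel_size_mm = ens$pixel_size, n_rep = ens$n_rep),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a noise ensemble written by [write_ensemble_nifti()]
#'
#' @param dir Directory holding `rep_*.nii.gz` and `ensemble.json`.
#' @return A [noise_ensemble()].
#' @export
read_ensemble_nifti <- function(dir) {
  sidecar <- file.path(dir, "ensemble.json")
  if (!file.exists(sidecar)) abort(paste("missing sidecar:", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^rep_\\d+\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) < 2) abort("need >= 2 repetition files")
  imgs <- purrr::map(files, function(f) {
    v <- RNifti::readNifti(f)
    a <- as.array(v)
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
    a
  })
  arr <- array(0, dim = c(dim(imgs[[1]]), length(imgs)))
  for (r in seq_along(imgs)) arr[, , , r] <- imgs[[r]]
  noise_ensemble(arr, meta$pixel_size_mm,
                 provenance = list(method = meta$method,
                                   dose_fraction = meta$dose_fraction,
                                   seed = meta$seed))
}

#' Write an image stack as a plain-text array dump
#'
#' Dialect: a one-line JSON header (`H`, `W`, `n_slice`, `pixel_size_mm`)
#' followed by one whitespace-separated line of `W` values per image row,
#' slices concatenated in order. Round-trips values at full double precision.
#'
#' @param stack An `image_stack` (array `[H, W, n_slice]` with a `pixel_size`
#'   attribute).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_array_dump <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) == 3)
  hdr <- jsonlite::toJSON(list(H = d[1], W = d[2], n_slice = d[3],
                               pixel_size_mm = attr(stack, "pixel_size")),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(hdr), con)
  for (s in seq_len(d[3])) {
    write(t(stack[, , s]), file = con, ncolumns = d[2], sep = " ")
  }
  invisible(path)
}

#' Read a plain-text array dump
#'
#' @param path File written by [write_array_dump()].
#' @return An `image_stack`.
#' @export
read_array_dump <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  vals <- scan(text = lines[-1], quiet = TRUE)
  if (length(vals) != meta$H * meta$W * meta$n_slice) {
    abort("array dump payload does not match its header dimensions")
  }
  arr <- array(0, dim = c(meta$H, meta$W, meta$n_slice))
  per <- meta$H * meta$W
  for (s in seq_len(meta$n_slice)) {
    block <- vals[((s - 1) * per + 1):(s * per)]
    arr[, , s] <- matrix(block, meta$H, meta$W, byrow = TRUE)
  }
  structure(arr, pixel_size = meta$pixel_size_mm,
            class = c("image_stack", "array"))
}

#' Read an image stack from disk
#'
#' @param path File (NIfTI or array dump) to read.
#' @param format One of `"nifti"`, `"array_dump"`.
#' @return An `image_stack` with a `pixel_size` attribute.
#' @export
read_image_stack <- function(path, format = c("nifti", "array_dump")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "array_dump") return(read_array_dump(path))
  v <- RNifti::readNifti(path)
  a <- as.array(v)
  if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
  structure(a, pixel_size = RNifti::pixdim(v)[1],
            class = c("image_stack", "array"))
}

#' Write an NPS curve as CSV
#'
#' Columns: `frequency_mm^-1`, `power_HU2mm2` (or percent for relative
#' curves), `support_count`.
#'
#' @param curve A `nps_curve`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_nps_csv <- function(curve, path) {
  stopifnot(inherits(curve, "nps_curve"))
  df <- data.frame(`frequency_mm^-1` = curve$frequency,
                   power = curve$power,
                   support_count = curve$support_count,
                   check.names = FALSE)
  names(df)[2] <- if (curve_kind(curve) == "relative") {
    "relative_improvement_pct"
  } else {
    "power_HU2mm2"
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
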