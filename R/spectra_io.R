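#' Wavelength grid for reflectance spectra
#'
#' Describes an evenly spaced wavelength axis with inclusive endpoints. The
#' canonical grid of the portable Vis--SWIR spectroradiometer covers
#' 350--2500 nm at a 1 nm step, i.e. exactly 2151 variables per spectrum.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm), inclusive.
#' @param step_nm Wavelength increment (nm).
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `end_nm`, `step_nm` and `n_points`.
#' @examples
#' g <- wavelength_grid()
#' g$n_points  # 2151
#' @export
wavelength_grid <- function(start_nm = 350, end_nm = 2500, step_nm = 1) {
  if (!(start_nm < end_nm)) stop("start_nm must be < end_nm")
  if (!(step_nm > 0)) stop("step_nm must be > 0")
  span <- end_nm - start_nm
  if (abs(span / step_nm - round(span / step_nm)) > 1e-9)
    stop("(end_nm - start_nm) must be divisible by step_nm")
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         n_points = as.integer(round(span / step_nm)) + 1L),
    class = "wavelength_grid"
  )
}

#' Wavelengths of a grid
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of wavelengths (nm).
#' @export
grid_wavelengths <- function(grid) {
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

PHYSICAL_STATES <- c("frozen", "thawed")

#' Labeled collection of reflectance spectra
#'
#' Couples an `n x m` reflectance matrix (rows = spectra, columns =
#' wavelengths on a shared grid) with per-spectrum metadata: a sample
#' identifier, the binary product class (1 = Pennette72, 0 = Mezze Penne)
#' and the physical state (`"frozen"` or `"thawed"`). Row order is stable
#' and treated as file order by the systematic splitter.
#'
#' @param reflectance Numeric matrix, one row per spectrum.
#' @param meta `data.frame` with columns `sample_id`, `product_class`,
#'   `physical_state`, one row per spectrum.
#' @param grid A [wavelength_grid()]; defaults to the canonical grid.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(reflectance, meta, grid = wavelength_grid()) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (nrow(reflectance) != nrow(meta))
    stop("reflectance and meta must have the same number of rows")
  if (ncol(reflectance) != grid$n_points)
    stop(sprintf("expected %d reflectance values per spectrum, found %d",
                 grid$n_points, ncol(reflectance)))
  if (!all(is.finite(reflectance)))
    stop("reflectance values must be finite")
  req <- c("sample_id", "product_class", "physical_state")
  if (!all(req %in% names(meta)))
    stop("meta must contain columns: ", paste(req, collapse = ", "))
  meta <- as.data.frame(meta)[, req]
  meta$sample_id <- as.character(meta$sample_id)
  meta$product_class <- as.integer(meta$product_class)
  meta$physical_state <- as.character(meta$physical_state)
  if (!all(meta$product_class %in% c(0L, 1L)))
    stop("product_class must be 0 (Mezze Penne) or 1 (Pennette72)")
  bad <- setdiff(unique(meta$physical_state), PHYSICAL_STATES)
  if (length(bad))
    stop("unknown physical_state token(s): ", paste(bad, collapse = ", "))
  rownames(meta) <- NULL
  dimnames(reflectance) <- NULL
  structure(list(grid = grid, meta = meta, reflectance = reflectance),
            class = "spectra_dataset")
}

#' Number of spectra in a dataset
#' @param ds A `spectra_dataset`.
#' @return Integer count.
#' @export
n_spectra <- function(ds) nrow(ds$reflectance)

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra x %d wavelengths (%g-%g nm @ %g nm)\n",
              n_spectra(x), x$grid$n_points, x$grid$start_nm, x$grid$end_nm,
              x$grid$step_nm))
  tab <- table(class = x$meta$product_class, state = x$meta$physical_state)
  print(tab)
  invisible(x)
}

#' Take a subset of spectra by row index
#' @param ds A `spectra_dataset`.
#' @param idx Integer or logical row index.
#' @return A `spectra_dataset` with the selected rows, order preserved.
#' @export
subset_spectra <- function(ds, idx) {
  spectra_dataset(ds$reflectance[idx, , drop = FALSE],
                  ds$meta[idx, , drop = FALSE], ds$grid)
}

#' Subset a dataset by physical state
#'
#' Returns all and only the spectra measured in the given physical state,
#' preserving row order. With the default study design this yields 600
#' spectra per state.
#'
#' @param ds A `spectra_dataset`.
#' @param state `"frozen"` or `"thawed"`.
#' @return A `spectra_dataset` (possibly with zero rows).
#' @export
subset_by_state <- function(ds, state) {
  state <- match.arg(state, PHYSICAL_STATES)
  subset_spectra(ds, ds$meta$physical_state == state)
}

reflectance_colnames <- function(grid) {
  sprintf("R%g", grid_wavelengths(grid))
}

#' Read a labeled spectra dataset from CSV
#'
#' The canonical tabular format is comma-separated UTF-8 with header
#' `sample_id,product_class,physical_state,R350,...,R2500` (one column per
#' wavelength on the grid). Files ending in `.gz` are decompressed
#' transparently.
#'
#' @param path Path to a CSV (optionally gzip-compressed) file.
#' @param grid Expected [wavelength_grid()].
#' @return A `spectra_dataset` with rows in file order.
#' @export
read_dataset <- function(path, grid = wavelength_grid()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (tools::file_ext(path) == "gz") {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    con_in <- gzfile(path, "rb"); con_out <- file(tmp, "wb")
    while (length(chunk <- readBin(con_in, "raw", 1e6)) > 0)
      writeBin(chunk, con_out)
    close(con_in); close(con_out)
    path <- tmp
  }
  dt <- data.table::fread(path, header = TRUE, sep = ",",
                          colClasses = list(character = "sample_id"),
                          data.table = FALSE, showProgress = FALSE)
  expected <- 3L + grid$n_points
  if (ncol(dt) != expected)
    stop(sprintf(
      "format error: expected %d columns (3 metadata + %d reflectance), found %d",
      expected, grid$n_points, ncol(dt)))
  refl <- dt[, -(1:3), drop = FALSE]
  non_num <- !vapply(refl, is.numeric, logical(1))
  if (any(non_num)) {
    col <- which(non_num)[1] + 3L
    vals <- suppressWarnings(as.numeric(dt[[col]]))
    row <- which(is.na(vals))[1]
    stop(sprintf("parse error: non-numeric reflectance in column %d, row %d",
                 col, if (is.na(row)) 1L else row))
  }
  spectra_dataset(as.matrix(refl), dt[, 1:3], grid)
}

#' Write a labeled spectra dataset to CSV
#'
#' Output is deterministic for a fixed dataset: fixed column order and
#' reflectance serialized at 6 significant digits. A `.gz` extension
#' triggers gzip compression.
#'
#' @param ds A non-empty `spectra_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (n_spectra(ds) == 0) stop("refusing to write an empty dataset")
  refl <- signif(ds$reflectance, 6)
  out <- data.table::as.data.table(cbind(ds$meta, as.data.frame(refl)))
  data.table::setnames(out, c(names(ds$meta), reflectance_colnames(ds$grid)))
  compress <- if (tools::file_ext(path) == "gz") "gzip" else "none"
  data.table::fwrite(out, path, sep = ",", quote = FALSE, compress = compress)
  invisible(path)
}
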