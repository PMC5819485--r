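#' @rdname accessors
#' @export
setMethod("deltaLayer", "BiophysicalDataset", function(object) object@delta)

#' @rdname accessors
#' @export
setMethod("uncertaintyLayer", "BiophysicalDataset",
  function(object) object@sd)

#' @rdname accessors
#' @export
setMethod("sampleCount", "BiophysicalDataset", function(object) object@n)

#' @rdname accessors
#' @export
setMethod("transitionCodes", "BiophysicalDataset",
  function(object) object@itr)

#' @rdname accessors
#' @export
setMethod("monthsOf", "BiophysicalDataset", function(object) object@mon)

#' @rdname accessors
#' @export
setMethod("schemeName", "BiophysicalDataset", function(object) object@scheme)

setMethod("show", "BiophysicalDataset", function(object) {
  cat("BiophysicalDataset '", object@variable, "' [", object@scheme, "]: ",
      length(object@lat), " lat x ", length(object@lon), " lon x ",
      length(object@mon), " mon x ", length(object@itr), " iTr\n", sep = "")
  cat("  non-missing Delta values: ", sum(!is.na(object@delta)), "\n",
      sep = "")
})

#' Canonical product file name
#'
#' Product files are named \code{<Variable>_<Scheme>.nc}, e.g.
#' \code{"HG_IGBPdet.nc"}.
#'
#' @param variable variable name.
#' @param scheme scheme name.
#' @return file name (no directory).
#' @export
productFileName <- function(variable, scheme) {
  paste0(variable, "_", scheme, ".nc")
}

#' Canonical product manifest
#'
#' The 16 files of a full product run: 8 variables (albedo, LE, LWsfc,
#' LSTday, LSTnight, SWreflected, LWemitted, HG) for each of the two
#' classification schemes.
#'
#' @return character vector of 16 file names.
#' @export
productManifest <- function() {
  vars <- c("albedo", "LE", "LWsfc", "LSTday", "LSTnight",
            "SWreflected", "LWemitted", "HG")
  as.vector(vapply(c("IGBPdet", "IGBPgen"), function(s)
    productFileName(vars, s), character(length(vars))))
}

.FILL <- -9999

#' Write a product file
#'
#' Writes one [BiophysicalDataset-class] to a netCDF file with dimensions
#' (lat, lon, mon, iTr) and variables \code{Delta_Z}, \code{SD_Delta_Z}
#' (double) and \code{N_Z} (integer). Coordinates are cell centres, written
#' ascending with explicit coordinate variables; month and transition codes
#' are integer coordinate values. Missing values use an explicit fill value.
#' Interpretive processing parameters passed via \code{params} are echoed
#' into global attributes for provenance.
#'
#' @param ds a [BiophysicalDataset-class]; validity is enforced before
#'   writing.
#' @param path output file path (conventionally
#'   \code{productFileName(variable, scheme)}).
#' @param params optional named list of processing parameters recorded as
#'   global attributes.
#' @return the path, invisibly.
#' @export
writeProduct <- function(ds, path, params = NULL) {
  stopifnot(is(ds, "BiophysicalDataset"))
  validObject(ds)
  n_expect <- length(schemeTransitions(ds@scheme))
  if (length(ds@itr) != n_expect)
    stop("product for scheme ", ds@scheme, " must carry ", n_expect,
         " transitions, found ", length(ds@itr))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", ds@lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", ds@lon)
  dim_mon <- ncdf4::ncdim_def("mon", "month", as.integer(ds@mon),
                              create_dimvar = TRUE)
  dim_itr <- ncdf4::ncdim_def("iTr", "transition_code",
                              as.integer(ds@itr), create_dimvar = TRUE)
  dims <- list(dim_lat, dim_lon, dim_mon, dim_itr)
  v <- ds@variable
  var_d <- ncdf4::ncvar_def(paste0("Delta_", v), "", dims, .FILL,
                            prec = "double")
  var_s <- ncdf4::ncvar_def(paste0("SD_Delta_", v), "", dims, .FILL,
                            prec = "double")
  var_n <- ncdf4::ncvar_def(paste0("N_", v), "", dims, -9L,
                            prec = "integer")
  nc <- ncdf4::nc_create(path, list(var_d, var_s, var_n))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # ncvar_put substitutes the fill value for NA in place; hand it throwaway
  # copies with the substitution already done so caller data are never touched
  fill <- function(a, f) { a[is.na(a)] <- f; a }
  ncdf4::ncvar_put(nc, var_d, fill(ds@delta, .FILL))
  ncdf4::ncvar_put(nc, var_s, fill(ds@sd, .FILL))
  ncdf4::ncvar_put(nc, var_n, fill(ds@n, -9L))
  ncdf4::ncatt_put(nc, 0, "variable", v)
  ncdf4::ncatt_put(nc, 0, "classification_scheme", ds@scheme)
  ncdf4::ncatt_put(nc, 0, "months",
    "climatological months representing the period 2008-2012")
  ncdf4::ncatt_put(nc, 0, "coordinate_convention",
    "lat/lon are cell centres, written ascending")
  if (!is.null(params))
    for (nm in names(params))
      ncdf4::ncatt_put(nc, 0, nm, as.character(params[[nm]]))
  invisible(path)
}

#' Read a product file
#'
#' Inverse of [writeProduct()]: reconstructs the [BiophysicalDataset-class]
#' bit-exactly, including missing values and the transition-axis order.
#'
#' @param path netCDF file path.
#' @return a [BiophysicalDataset-class].
#' @export
readProduct <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vnames <- names(nc$var)
  dname <- grep("^Delta_", vnames, value = TRUE)
  if (length(dname) != 1L)
    stop("not a product file (expected exactly one Delta_* variable): ", path)
  v <- sub("^Delta_", "", dname)
  lat <- as.numeric(nc$dim$lat$vals)
  lon <- as.numeric(nc$dim$lon$vals)
  mon <- as.integer(nc$dim$mon$vals)
  itr <- as.integer(nc$dim$iTr$vals)
  d <- c(length(lat), length(lon), length(mon), length(itr))
  get4 <- function(nm) {
    a <- ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE)
    array(a, d)
  }
  delta <- get4(paste0("Delta_", v))
  sdv <- get4(paste0("SD_Delta_", v))
  n <- get4(paste0("N_", v))
  n[is.na(n)] <- NA_integer_
  scheme <- ncdf4::ncatt_get(nc, 0, "classification_scheme")$value
  new("BiophysicalDataset", variable = v, scheme = scheme, lat = lat,
      lon = lon, mon = mon, itr = itr, delta = delta, sd = sdv,
      n = array(as.integer(n), d))
}

#' Write a synthetic scene to netCDF
#'
#' Stores the scene's inputs (cover fractions, surface-variable rasters, DEM
#' layers and coarse radiation) plus the per-class ground-truth fields in one
#' netCDF file on dimensions (lat, lon, mon, class) and a coarse pair
#' (clat, clon). Ground-truth variables are named \code{pure_<variable>} and
#' are synthetic constructs, not observables.
#'
#' @param scene a [SyntheticScene-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScene <- function(scene, path) {
  stopifnot(is(scene, "SyntheticScene"))
  cfg <- scene@config
  px <- cfg@pixelSizeDeg
  lat <- (seq_len(cfg@nRows) - 0.5) * px
  lon <- (seq_len(cfg@nCols) - 0.5) * px
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dim_mon <- ncdf4::ncdim_def("mon", "month", as.integer(cfg@months))
  k <- nClasses(scene@scheme)
  dim_cls <- ncdf4::ncdim_def("class", "class_code",
    as.integer(classCodes(scene@scheme)))
  rad <- scene@radiation
  dim_clat <- ncdf4::ncdim_def("clat", "degrees_north",
    (seq_len(dim(rad@swDown)[1L]) - 0.5) * px * 20)
  dim_clon <- ncdf4::ncdim_def("clon", "degrees_east",
    (seq_len(dim(rad@swDown)[2L]) - 0.5) * px * 20)
  defs <- list(
    fractions = ncdf4::ncvar_def("fractions", "1",
      list(dim_lat, dim_lon, dim_cls), .FILL, prec = "double"),
    dem_mean = ncdf4::ncvar_def("dem_mean", "m", list(dim_lat, dim_lon),
      .FILL, prec = "double"),
    dem_sd = ncdf4::ncvar_def("dem_sd", "m", list(dim_lat, dim_lon),
      .FILL, prec = "double"),
    sw_down = ncdf4::ncvar_def("sw_down", "W m-2",
      list(dim_clat, dim_clon, dim_mon), .FILL, prec = "double"),
    lw_up_allsky = ncdf4::ncvar_def("lw_up_allsky", "W m-2",
      list(dim_clat, dim_clon, dim_mon), .FILL, prec = "double"),
    lw_up_clearsky = ncdf4::ncvar_def("lw_up_clearsky", "W m-2",
      list(dim_clat, dim_clon, dim_mon), .FILL, prec = "double"))
  for (vn in names(scene@variables))
    defs[[vn]] <- ncdf4::ncvar_def(vn, "", list(dim_lat, dim_lon, dim_mon),
                                   .FILL, prec = "double")
  for (vn in names(scene@truth))
    defs[[paste0("pure_", vn)]] <- ncdf4::ncvar_def(paste0("pure_", vn), "",
      list(dim_lat, dim_lon, dim_cls, dim_mon), .FILL, prec = "double")
  nc <- ncdf4::nc_create(path, defs)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, defs$fractions, scene@fractions)
  ncdf4::ncvar_put(nc, defs$dem_mean, scene@demMean)
  ncdf4::ncvar_put(nc, defs$dem_sd, scene@demSd)
  ncdf4::ncvar_put(nc, defs$sw_down, rad@swDown)
  ncdf4::ncvar_put(nc, defs$lw_up_allsky, rad@lwUpAllsky)
  ncdf4::ncvar_put(nc, defs$lw_up_clearsky, rad@lwUpClearsky)
  for (vn in names(scene@variables))
    ncdf4::ncvar_put(nc, defs[[vn]], scene@variables[[vn]])
  for (vn in names(scene@truth))
    ncdf4::ncvar_put(nc, defs[[paste0("pure_", vn)]],
                     scene@truth[[vn]]@pureValues)
  ncdf4::ncatt_put(nc, 0, "scheme", schemeName(scene@scheme))
  ncdf4::ncatt_put(nc, 0, "seed", cfg@seed)
  ncdf4::ncatt_put(nc, 0, "note",
    "synthetic scene; pure_* variables are ground-truth constructs")
  invisible(path)
}
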