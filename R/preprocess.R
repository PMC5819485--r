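#' Stefan-Boltzmann constant, W m-2 K-4
#' @export
STEFAN_BOLTZMANN <- 5.67e-8

#' Combine black- and white-sky albedo
#'
#' Actual (blue-sky) albedo is approximated by the arithmetic mean of the
#' directional-hemispherical (black-sky) and bihemispherical (white-sky)
#' albedos, which avoids needing the diffuse-radiation fraction. Missing
#' values propagate: the mean is missing wherever either input is.
#'
#' @param black_sky,white_sky numeric rasters (any matching shape).
#' @return raster of the same shape.
#' @export
combineAlbedo <- function(black_sky, white_sky) {
  if (!identical(dim(black_sky), dim(white_sky)) ||
      length(black_sky) != length(white_sky))
    stop("black-sky and white-sky rasters are on different grids")
  (black_sky + white_sky) / 2
}

#' Broadband emissivity from MODIS narrowband emissivities
#'
#' Empirical linear combination of the narrowband emissivities in MODIS bands
#' 29 (8.4-8.7 um), 31 (10.8-11.3 um) and 32 (11.8-12.3 um):
#' \deqn{\epsilon_B = 0.2122 \epsilon_{29} + 0.3859 \epsilon_{31}
#'       + 0.4029 \epsilon_{32}.}
#'
#' @param eps29,eps31,eps32 narrowband emissivities in \code{[0, 1]} (scalars
#'   or rasters).
#' @return broadband emissivity (dimensionless).
#' @examples
#' broadbandEmissivity(0.98, 0.98, 0.98)
#' @export
broadbandEmissivity <- function(eps29, eps31, eps32) {
  rng <- range(c(eps29, eps31, eps32), na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 1))
    stop("narrowband emissivities must lie in [0, 1]")
  0.2122 * eps29 + 0.3859 * eps31 + 0.4029 * eps32
}

#' Clear-sky upwelling longwave radiation
#'
#' Stefan-Boltzmann emission at the daily mean surface temperature, taken as
#' the simple average of the daytime and nighttime land surface temperatures:
#' \deqn{LW^{\uparrow *} = \epsilon_B \sigma \left(\frac{LST_d + LST_n}{2}
#'       \right)^4.}
#' The result refers to clear-sky conditions because the thermal retrievals
#' it derives from are only possible without clouds.
#'
#' @param lst_day,lst_night land surface temperatures, K.
#' @param eps_b broadband emissivity.
#' @return upwelling longwave flux, W m-2.
#' @examples
#' clearskyLwUp(300, 300, 1)  # 459.27 W m-2
#' @export
clearskyLwUp <- function(lst_day, lst_night, eps_b) {
  if (any(lst_day <= 0, na.rm = TRUE) || any(lst_night <= 0, na.rm = TRUE))
    stop("temperatures must be positive (kelvin)")
  if (any(eps_b < 0 | eps_b > 1.1, na.rm = TRUE))
    stop("broadband emissivity out of range [0, 1.1]")
  tmean <- (lst_day + lst_night) / 2
  eps_b * STEFAN_BOLTZMANN * tmean^4
}

#' Monthly median climatology across years
#'
#' Collapses a multi-year monthly stack to a 12-month (or fewer) climatology
#' by taking, per pixel and calendar month, the median across years. Missing
#' years are ignored; a pixel-month with no data at all stays missing. The
#' median of an even number of years is the mean of the two central values.
#'
#' @param stack 4-D array \code{[row, col, year, month]}.
#' @return 3-D array \code{[row, col, month]}.
#' @export
monthlyMedianClimatology <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) != 4L)
    stop("input must be a 4-D [row, col, year, month] array")
  if (d[3L] < 1L) stop("at least one year is required")
  out <- array(NA_real_, d[c(1L, 2L, 4L)])
  for (m in seq_len(d[4L])) {
    sl <- stack[, , , m, drop = FALSE]
    dim(sl) <- c(d[1L] * d[2L], d[3L])
    out[, , m] <- apply(sl, 1L, stats::median, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Read a land-cover crosswalk table
#'
#' Reads a delimited text table with columns \code{source_code},
#' \code{target_class} and \code{percent} describing how each source
#' land-cover code contributes to the target classes.
#'
#' @param path file path; defaults to the bundled LCCS-to-IGBP table in which
#'   every contribution is 100 %.
#' @param scheme \code{"IGBPdet"} or \code{"IGBPgen"}: which target-class
#'   column set of the bundled table to use.
#' @return data.frame with the three columns above.
#' @export
readCrosswalkTable <- function(path = NULL, scheme = "IGBPdet") {
  if (is.null(path))
    path <- system.file("extdata",
      paste0("crosswalk_lccs_", tolower(scheme), ".tsv"),
      package = "vegbiophys", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source_code", "target_class", "percent")
  if (!all(need %in% names(tab)))
    stop("crosswalk table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Crosswalk a fine land-cover class map to per-class fractions
#'
#' Translates a categorical fine-resolution land-cover map (e.g. 300 m LCCS
#' codes) into per-class cover fractions on a coarser grid: each fine pixel
#' contributes its full area to the single target class its code maps to
#' (contributions are 100 %), and the fraction of class j in a coarse cell is
#' the share of fine pixels mapping to j.
#'
#' @param fine_class_map integer matrix of source class codes.
#' @param crosswalk data.frame with columns \code{source_code},
#'   \code{target_class}, \code{percent} (percent must be 100 for the single
#'   mapped class).
#' @param factor integer aggregation factor: coarse cell side in fine pixels.
#' @return array \code{[row, col, class]} of fractions summing to one per
#'   cell; class order follows the crosswalk's target classes.
#' @export
crosswalkLandcover <- function(fine_class_map, crosswalk, factor = 1L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("aggregation factor must be >= 1")
  if (nrow(fine_class_map) %% factor || ncol(fine_class_map) %% factor)
    stop("map dimensions must be multiples of the aggregation factor")
  codes <- unique(fine_class_map[!is.na(fine_class_map)])
  known <- unique(crosswalk$source_code[crosswalk$percent > 0])
  missing_codes <- setdiff(codes, known)
  if (length(missing_codes))
    stop("no crosswalk entry for source code(s): ",
         paste(sort(missing_codes), collapse = ", "))
  classes <- unique(crosswalk$target_class)
  lut <- stats::setNames(crosswalk$target_class[crosswalk$percent > 0],
                         crosswalk$source_code[crosswalk$percent > 0])
  target <- matrix(lut[as.character(fine_class_map)],
                   nrow(fine_class_map), ncol(fine_class_map))
  nr <- nrow(fine_class_map) %/% factor
  nc <- ncol(fine_class_map) %/% factor
  frac <- array(0, c(nr, nc, length(classes)),
                dimnames = list(NULL, NULL, classes))
  for (i in seq_len(nr)) {
    ri <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(nc)) {
      cj <- ((j - 1L) * factor + 1L):(j * factor)
      cell <- target[ri, cj]
      n_ok <- sum(!is.na(cell))
      tab <- table(factor(cell, levels = classes))
      frac[i, j, ] <- if (n_ok) as.numeric(tab) / n_ok else NA_real_
    }
  }
  frac
}
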