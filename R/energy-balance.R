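#' Change in reflected shortwave radiation
#'
#' \code{Delta SW_up = Delta alpha x SW_down}, elementwise per coarse cell
#' and month; incoming shortwave is assumed unchanged by the (at most
#' pixel-scale) vegetation change.
#'
#' @param d_albedo aggregated albedo change (dimensionless).
#' @param sw_down downwelling shortwave, W m-2.
#' @return flux change, W m-2.
#' @export
deltaSwReflected <- function(d_albedo, sw_down) {
  if (any(sw_down < 0, na.rm = TRUE)) stop("sw_down must be non-negative")
  d_albedo * sw_down
}

#' All-sky change in emitted longwave radiation
#'
#' The unmixed longwave change refers to clear-sky conditions only (thermal
#' retrievals need a cloud-free view). As a proxy for cloudiness, it is
#' scaled by the ratio of the all-sky to clear-sky upwelling longwave of the
#' coarse radiation climatology:
#' \code{Delta LW_up = (LW_allsky / LW_clearsky) x Delta LW_up_clearsky}.
#'
#' @param d_lw_clearsky clear-sky longwave change, W m-2.
#' @param lw_up_allsky,lw_up_clearsky coarse upwelling longwave fields,
#'   W m-2.
#' @return all-sky flux change, W m-2; missing where the clear-sky flux is
#'   not positive.
#' @export
deltaLwFullsky <- function(d_lw_clearsky, lw_up_allsky, lw_up_clearsky) {
  ratio <- lw_up_allsky / lw_up_clearsky
  ratio[!is.na(lw_up_clearsky) & lw_up_clearsky <= 0] <- NA_real_
  ratio * d_lw_clearsky
}

#' Residual sensible-plus-ground heat flux change
#'
#' Closes the perturbed surface energy balance under the assumptions that
#' incoming shortwave and longwave radiation are unchanged:
#' \deqn{\Delta(H+G) = -(\Delta\alpha) SW_\downarrow
#'   - (LW_{C\uparrow}/LW^{*}_{C\uparrow}) \Delta LW^{*}_\uparrow
#'   - \Delta LE.}
#' Positive fluxes are surface-to-atmosphere, matching the variables the
#' residual derives from. Missing whenever any input is missing.
#'
#' @param d_albedo,d_lw_clearsky,d_le aggregated changes in albedo, clear-sky
#'   upwelling longwave (W m-2) and latent heat flux (W m-2).
#' @param sw_down downwelling shortwave, W m-2.
#' @param lw_up_allsky,lw_up_clearsky coarse upwelling longwave fields.
#' @return residual flux change, W m-2.
#' @export
residualFlux <- function(d_albedo, d_lw_clearsky, d_le, sw_down,
                         lw_up_allsky, lw_up_clearsky) {
  -deltaSwReflected(d_albedo, sw_down) -
    deltaLwFullsky(d_lw_clearsky, lw_up_allsky, lw_up_clearsky) - d_le
}

#' Propagated uncertainty of the residual flux
#'
#' Quadrature propagation treating the three aggregated changes as
#' independent (each variable is regressed separately, so no cross-variable
#' covariances are produced upstream):
#' \code{sd = sqrt((SW_down sd_alpha)^2 + (ratio sd_LW*)^2 + sd_LE^2)}.
#'
#' @param sd_albedo,sd_lw_clearsky,sd_le component standard deviations.
#' @param sw_down downwelling shortwave, W m-2.
#' @param lw_up_allsky,lw_up_clearsky coarse upwelling longwave fields.
#' @return standard deviation of the residual flux, W m-2.
#' @export
propagateResidualSd <- function(sd_albedo, sd_lw_clearsky, sd_le, sw_down,
                                lw_up_allsky, lw_up_clearsky) {
  ratio <- lw_up_allsky / lw_up_clearsky
  sqrt((sw_down * sd_albedo)^2 + (ratio * sd_lw_clearsky)^2 + sd_le^2)
}

# broadcast a coarse radiation field [clat, clon, mon] to [clat, clon, mon, iTr]
.radToProduct <- function(field, ds) {
  d <- c(length(ds@lat), length(ds@lon), length(ds@mon), length(ds@itr))
  if (!identical(dim(field)[1:2], d[1:2]))
    stop("radiation fields and product are on different coarse grids")
  array(rep(field, d[4L]), d)
}

#' Close the surface energy balance of an aggregated product
#'
#' From the aggregated albedo, clear-sky longwave and latent-heat products
#' and the coarse radiation climatology, derives the three remaining product
#' layers: reflected shortwave (\code{SWreflected}), all-sky emitted longwave
#' (\code{LWemitted}) and the residual sensible-plus-ground heat flux
#' (\code{HG}). Per construction, for every complete cell/month
#' \code{dSW_up + dLW_up + dLE + dHG = 0}. Sample counts are carried from the
#' parent layers (the elementwise minimum of the three parents for HG).
#'
#' @param albedo,lwsfc,le [BiophysicalDataset-class] products for albedo,
#'   clear-sky upwelling longwave and latent heat, on one coarse grid.
#' @param radiation a [CoarseRadiation-class] on the same coarse grid and
#'   months.
#' @return named list of three [BiophysicalDataset-class] objects:
#'   \code{SWreflected}, \code{LWemitted}, \code{HG}.
#' @export
closeEnergyBalance <- function(albedo, lwsfc, le, radiation) {
  for (ds in list(albedo, lwsfc, le)) stopifnot(is(ds, "BiophysicalDataset"))
  stopifnot(is(radiation, "CoarseRadiation"))
  if (!identical(albedo@itr, lwsfc@itr) || !identical(albedo@itr, le@itr))
    stop("products carry different transition axes")
  if (!identical(albedo@mon, radiation@months))
    stop("product and radiation months differ")
  sw <- .radToProduct(radiation@swDown, albedo)
  lwa <- .radToProduct(radiation@lwUpAllsky, albedo)
  lwc <- .radToProduct(radiation@lwUpClearsky, albedo)

  swref <- albedo
  swref@variable <- "SWreflected"
  swref@delta <- deltaSwReflected(albedo@delta, sw)
  swref@sd <- sw * albedo@sd

  lwem <- lwsfc
  lwem@variable <- "LWemitted"
  lwem@delta <- deltaLwFullsky(lwsfc@delta, lwa, lwc)
  lwem@sd <- (lwa / lwc) * lwsfc@sd

  hg <- albedo
  hg@variable <- "HG"
  hg@delta <- residualFlux(albedo@delta, lwsfc@delta, le@delta, sw, lwa, lwc)
  hg@sd <- propagateResidualSd(albedo@sd, lwsfc@sd, le@sd, sw, lwa, lwc)
  hg@n <- pmin(albedo@n, lwsfc@n, le@n)
  hg@sd[is.na(hg@delta)] <- NA_real_

  list(SWreflected = swref, LWemitted = lwem, HG = hg)
}
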