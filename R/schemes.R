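#' Construct a classification scheme
#'
#' @param name scheme name.
#' @param codes named integer vector of class codes (names are abbreviations).
#' @param vegetated logical vector, parallel to \code{codes}.
#' @return a [ClassScheme-class] object.
#' @examples
#' classScheme("toy", c(A = 1L, B = 2L, BSV = 3L), c(TRUE, TRUE, FALSE))
#' @export
classScheme <- function(name, codes, vegetated) {
  new("ClassScheme", name = name, codes = as.integer(codes) |>
        stats::setNames(names(codes)), vegetated = as.logical(vegetated))
}

#' Detailed 10-class vegetation scheme (IGBPdet)
#'
#' Ten vegetated classes coded 1..10 (EBF, DBF, ENF, DNF, MF, SAV, SHR, GRA,
#' CRO, WET) plus the four non-vegetated classes (urban, water, snow/ice,
#' bare soil) that enter the regressions but are never predicted.
#'
#' @return a [ClassScheme-class].
#' @export
igbpDet <- function() {
  veg <- c(EBF = 1L, DBF = 2L, ENF = 3L, DNF = 4L, MF = 5L,
           SAV = 6L, SHR = 7L, GRA = 8L, CRO = 9L, WET = 10L)
  nonveg <- c(URB = 11L, WAT = 12L, SNO = 13L, BSV = 14L)
  classScheme("IGBPdet", c(veg, nonveg),
              c(rep(TRUE, length(veg)), rep(FALSE, length(nonveg))))
}

#' Generic 4-class vegetation scheme (IGBPgen)
#'
#' Four broad vegetated classes coded 1..4 (FOR = forests, SHR = shrublands,
#' C+G = crops and grasses, SAV = savannas). Wetlands, which the generic
#' crosswalk keeps as their own column, are carried as an additional
#' non-predicted regressor class alongside urban, water, snow/ice and bare
#' soil.
#'
#' @return a [ClassScheme-class].
#' @export
igbpGen <- function() {
  veg <- c(FOR = 1L, SHR = 2L, `C+G` = 3L, SAV = 4L)
  nonveg <- c(WET = 5L, URB = 6L, WAT = 7L, SNO = 8L, BSV = 9L)
  classScheme("IGBPgen", c(veg, nonveg),
              c(rep(TRUE, length(veg)), rep(FALSE, length(nonveg))))
}

#' Look up a scheme by name
#' @param name \code{"IGBPdet"} or \code{"IGBPgen"}.
#' @return a [ClassScheme-class].
#' @export
getScheme <- function(name) {
  switch(name,
    IGBPdet = igbpDet(),
    IGBPgen = igbpGen(),
    stop("unknown classification scheme: ", name))
}

#' @rdname accessors
#' @export
setMethod("schemeName", "ClassScheme", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("classCodes", "ClassScheme", function(object) object@codes)

#' @rdname accessors
#' @export
setMethod("vegetatedClasses", "ClassScheme",
  function(object) object@codes[object@vegetated])

setMethod("show", "ClassScheme", function(object) {
  cat("ClassScheme '", object@name, "': ", sum(object@vegetated),
      " vegetated + ", sum(!object@vegetated), " non-vegetated classes\n",
      sep = "")
  cat("  vegetated:    ",
      paste(names(object@codes)[object@vegetated], collapse = " "), "\n")
  cat("  non-vegetated:",
      paste(names(object@codes)[!object@vegetated], collapse = " "), "\n")
})

# number of classes in a scheme
nClasses <- function(scheme) length(scheme@codes)
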