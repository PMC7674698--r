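# Tissue materials: elemental mass fractions (percent) and densities.
# The eight reference organs carry measured paediatric compositions; the
# remaining tissues (kidney, bladder wall, urine, whole-body soft tissue,
# air) are reference-based additions documented in the methods vignette.

.TISSUE_ELEMENTS <- c("H", "C", "N", "O", "Na", "P", "S", "Cl", "K")

.reference_organ_table <- function() {
  m <- rbind(
    lung              = c(10.3, 10.5, 3.1, 74.9, 0.2, 0.2, 0.3, 0.3, 0.1),
    heart             = c(10.4, 13.9, 2.9, 71.8, 0.1, 0.2, 0.2, 0.2, 0.3),
    stomach           = c(10.6, 11.5, 2.2, 75.1, 0.1, 0.1, 0.1, 0.2, 0.1),
    liver             = c(10.3, 18.6, 2.8, 67.1, 0.2, 0.2, 0.3, 0.2, 0.3),
    colon             = c(10.6, 11.5, 2.2, 75.1, 0.1, 0.1, 0.1, 0.2, 0.1),
    `small intestine` = c(10.6, 11.5, 2.2, 75.1, 0.1, 0.1, 0.1, 0.2, 0.1),
    testis            = c(10.6,  9.9, 2.0, 76.6, 0.2, 0.1, 0.2, 0.2, 0.2),
    ovary             = c(10.5,  9.3, 2.4, 76.8, 0.2, 0.2, 0.2, 0.2, 0.2)
  )
  colnames(m) <- .TISSUE_ELEMENTS
  list(
    fractions = m,
    density = c(lung = 0.260, heart = 1.04, stomach = 1.03, liver = 1.05,
                colon = 1.03, `small intestine` = 1.03, testis = 1.04,
                ovary = 1.04),
    volume_cc = c(lung = 980, heart = 218, stomach = 119.4, liver = 562,
                  colon = 149.7, `small intestine` = 265, testis = 1.57,
                  ovary = 1.66)
  )
}

#' Reference organ composition table
#'
#' Elemental mass fractions (percent by mass over H, C, N, O, Na, P, S, Cl,
#' K), density (g/cc) and total organ volume (cc) for the eight reference
#' organs of the 5-year-old phantom.
#'
#' @return data.frame with one row per organ: nine element columns (percent),
#'   `density` (g/cc) and `volume_cc` (cc; pair total for paired organs).
#' @export
#' @examples
#' tissue_table()["lung", "density"]
tissue_table <- function() {
  tb <- .reference_organ_table()
  out <- as.data.frame(tb$fractions)
  out$density <- tb$density[rownames(out)]
  out$volume_cc <- tb$volume_cc[rownames(out)]
  out
}

.soft_tissue_fractions <- function() {
  # average of the reference organ compositions, renormalized to 100
  f <- colMeans(.reference_organ_table()$fractions)
  f / sum(f) * 100
}

.extra_materials <- function() {
  soft <- .soft_tissue_fractions()
  water <- c(H = 11.19, C = 0, N = 0, O = 88.81, Na = 0, P = 0, S = 0,
             Cl = 0, K = 0)
  air <- c(H = 0, C = 0, N = 76.8, O = 23.2, Na = 0, P = 0, S = 0,
           Cl = 0, K = 0)
  tw <- .reference_organ_table()$fractions["testis", ]
  list(
    kidney        = list(fractions = soft,  density = 1.05),
    `bladder wall`= list(fractions = tw,    density = 1.04),
    urine         = list(fractions = water, density = 1.00),
    `soft tissue` = list(fractions = soft,  density = 1.04),
    water         = list(fractions = water, density = 1.00),
    air           = list(fractions = air,   density = 0.0012)
  )
}

new_material <- function(name, mass_fractions, density) {
  mass_fractions <- mass_fractions[.TISSUE_ELEMENTS]
  names(mass_fractions) <- .TISSUE_ELEMENTS
  mass_fractions[is.na(mass_fractions)] <- 0
  s <- sum(mass_fractions)
  if (abs(s - 100) > 0.5)
    stop("mass fractions of '", name, "' sum to ", s, ", expected 100 +/- 0.5")
  if (!is.finite(density) || density <= 0)
    stop("density must be positive")
  structure(list(name = name, mass_fractions = mass_fractions,
                 density = density), class = "material")
}

#' Look up the material (composition + density) of a tissue
#'
#' Returns the elemental composition and density for one of the reference
#' organs, or for one of the additional tissues used by the phantom
#' (`"kidney"`, `"bladder wall"`, `"urine"`, `"soft tissue"`, `"water"`,
#' `"air"`).
#'
#' @param name Organ or tissue name (e.g. `"lung"`, `"testis"`, `"kidney"`).
#' @return A `material` object: list with `name`, `mass_fractions` (named
#'   percent vector over H, C, N, O, Na, P, S, Cl, K) and `density` (g/cc).
#' @export
#' @examples
#' material_from_table("lung")$density          # 0.260
#' material_from_table("testis")$mass_fractions[["H"]]
material_from_table <- function(name) {
  tb <- .reference_organ_table()
  if (name %in% rownames(tb$fractions))
    return(new_material(name, tb$fractions[name, ], tb$density[[name]]))
  ex <- .extra_materials()
  if (name %in% names(ex))
    return(new_material(name, ex[[name]]$fractions, ex[[name]]$density))
  stop("unknown organ/tissue name: '", name, "'. Known: ",
       paste(c(rownames(tb$fractions), names(ex)), collapse = ", "))
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, " density", x$density, "g/cc\n")
  print(round(x$mass_fractions, 2))
  invisible(x)
}
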