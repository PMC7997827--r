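#' @title Elemental species and pathway stoichiometry
#' @description Every metabolic pathway in the process model is written as a
#'   generalized stoichiometric conversion of a carbon substrate with O2 and
#'   a nitrogen source into biomass, CO2, water and (optionally) a product.
#'   Coefficients not fixed by the modeller are solved from the four
#'   elemental balances (C, H, O, N), and mass yields Y_i/S follow from the
#'   molar coefficients and molecular weights.
#' @name stoichiometry
NULL

ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

#' Define an elemental species
#'
#' @param name species identifier, e.g. "glucose".
#' @param formula named numeric vector of element counts over C, H, O, N;
#'   fractional counts are allowed (e.g. the C-mol biomass formula
#'   CH1.8O0.5N0.2).
#' @return object of class \code{mdoe_species} with fields \code{name},
#'   \code{formula} and \code{mw} (g/mol).
#' @examples
#' glucose <- elemental_species("glucose", c(C = 6, H = 12, O = 6))
#' glucose$mw  # 180.156
#' @export
elemental_species <- function(name, formula) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(names(formula) %in% names(ATOMIC_MASS)))
    stop("elemental_species: unknown elements: ",
         paste(setdiff(names(formula), names(ATOMIC_MASS)), collapse = ", "))
  if (any(formula < 0)) stop("elemental_species: negative element count")
  full <- stats::setNames(numeric(4), names(ATOMIC_MASS))
  full[names(formula)] <- formula
  mw <- sum(full * ATOMIC_MASS)
  if (mw <= 0) stop("elemental_species: molecular weight must be positive")
  structure(list(name = name, formula = full, mw = mw),
            class = "mdoe_species")
}

#' @export
print.mdoe_species <- function(x, ...) {
  f <- x$formula[x$formula > 0]
  cat(sprintf("<species> %s  %s  MW = %.4f g/mol\n", x$name,
              paste0(names(f), ifelse(f == 1, "", format(f)), collapse = ""),
              x$mw))
  invisible(x)
}

#' Built-in elemental species
#'
#' The species used by the reference yeast model: glucose C6H12O6, ethanol
#' C2H6O, ethyl acetoacetate (EAA) C6H10O3, its reduction product
#' (S)-ethyl-3-hydroxybutyrate (E3HB) C6H12O3, C-mol biomass CH1.8O0.5N0.2,
#' O2, CO2, H2O, and the lumped yeast-extract/peptone nitrogen source
#' expressed as assimilable-ammonia equivalents HgOhNi (default H3N).
#'
#' @param g,h,i element counts of the nitrogen-source formula HgOhNi.
#' @return an \code{mdoe_species}.
#' @name builtin_species
NULL

#' @rdname builtin_species
#' @export
species_glucose <- function() elemental_species("glucose", c(C = 6, H = 12, O = 6))
#' @rdname builtin_species
#' @export
species_ethanol <- function() elemental_species("ethanol", c(C = 2, H = 6, O = 1))
#' @rdname builtin_species
#' @export
species_eaa     <- function() elemental_species("EAA", c(C = 6, H = 10, O = 3))
#' @rdname builtin_species
#' @export
species_e3hb    <- function() elemental_species("E3HB", c(C = 6, H = 12, O = 3))
#' @rdname builtin_species
#' @export
species_biomass <- function() elemental_species("biomass", c(C = 1, H = 1.8, O = 0.5, N = 0.2))
#' @rdname builtin_species
#' @export
species_o2      <- function() elemental_species("O2", c(O = 2))
#' @rdname builtin_species
#' @export
species_co2     <- function() elemental_species("CO2", c(C = 1, O = 2))
#' @rdname builtin_species
#' @export
species_h2o     <- function() elemental_species("H2O", c(H = 2, O = 1))
#' @rdname builtin_species
#' @export
species_nsource <- function(g = 3, h = 0, i = 1)
  elemental_species("N-source", c(H = g, O = h, N = i))

#' Define a metabolic pathway
#'
#' A pathway converts one substrate (coefficient fixed at 1 mol) plus
#' co-substrates into products.  Coefficients given as \code{NA} are free and
#' are determined by \code{\link{balance_pathway}} from the elemental
#' balances; fixed coefficients (e.g. a biomass yield chosen as a model
#' parameter) are kept as given.
#'
#' @param name pathway identifier.
#' @param substrate an \code{mdoe_species}; the reference substrate S.
#' @param species list of entries \code{list(species =, role =, side =, nu =)}
#'   where role is one of "O2", "N-source", "biomass", "CO2", "H2O",
#'   "product", "cosubstrate"; side is "reactant" or "product"; nu is the
#'   molar coefficient per mol substrate or NA (free).
#' @return object of class \code{mdoe_pathway} (unbalanced until
#'   \code{balance_pathway} is called).
#' @export
pathway <- function(name, substrate, species) {
  stopifnot(inherits(substrate, "mdoe_species"))
  for (sp in species) {
    stopifnot(inherits(sp$species, "mdoe_species"))
    if (!sp$side %in% c("reactant", "product"))
      stop("pathway: side must be 'reactant' or 'product'")
  }
  structure(list(name = name, substrate = substrate, species = species,
                 yields = NULL, balanced = FALSE),
            class = "mdoe_pathway")
}

#' Solve the elemental balances of a pathway
#'
#' Free coefficients (nu = NA) are solved so that C, H, O and N each close
#' to better than 1e-9 mol per mol substrate.  Mass yields
#' Y_i/S = nu_i * MW_i / MW_S are attached for every species.
#'
#' @param p an \code{mdoe_pathway}.
#' @return the balanced pathway, with \code{$yields} a named numeric vector
#'   (g of species per g substrate, positive for products and reactants
#'   alike) and \code{$balanced = TRUE}.
#' @examples
#' # glucose fermentation: C6H12O6 -> 2 C2H6O + 2 CO2
#' p <- pathway("ferm", species_glucose(), list(
#'   list(species = species_ethanol(), role = "product", side = "product", nu = NA),
#'   list(species = species_co2(), role = "CO2", side = "product", nu = NA),
#'   list(species = species_h2o(), role = "H2O", side = "product", nu = NA)))
#' balance_pathway(p)$yields[["ethanol"]]  # ~0.511 g/g
#' @export
balance_pathway <- function(p) {
  stopifnot(inherits(p, "mdoe_pathway"))
  elements <- names(ATOMIC_MASS)
  sgn <- function(side) if (side == "reactant") 1 else -1
  # balance vector: substrate contributes +atoms, products -nu*atoms; sum = 0
  b <- p$substrate$formula            # substrate, nu = 1, reactant
  free <- which(vapply(p$species, function(sp) is.na(sp$nu), logical(1)))
  fixed <- setdiff(seq_along(p$species), free)
  for (j in fixed) {
    sp <- p$species[[j]]
    b <- b + sgn(sp$side) * sp$nu * sp$species$formula
  }
  if (length(free) > 0L) {
    A <- vapply(p$species[free],
                function(sp) -sgn(sp$side) * sp$species$formula,
                numeric(4))
    A <- matrix(A, nrow = 4, dimnames = list(elements, NULL))
    qrA <- qr(A)
    if (qrA$rank < length(free))
      stop("balance_pathway: under-determined balance in pathway '", p$name,
           "': more free coefficients than independent elemental constraints")
    nu_free <- qr.coef(qrA, b)
    resid <- b - A %*% nu_free
  } else {
    resid <- b
  }
  if (max(abs(resid)) > 1e-9) {
    worst <- elements[which.max(abs(resid))]
    stop("balance_pathway: elemental balance for ", worst,
         " does not close in pathway '", p$name,
         "' (residual ", format(max(abs(resid))), " mol/mol)")
  }
  if (length(free) > 0L)
    for (k in seq_along(free)) p$species[[free[k]]]$nu <- unname(nu_free[k])
  nus <- vapply(p$species, `[[`, numeric(1), "nu")
  if (any(nus < -1e-12))
    stop("balance_pathway: negative coefficient solved in pathway '", p$name,
         "'; check fixed coefficients")
  yields <- vapply(p$species, function(sp) sp$nu * sp$species$mw / p$substrate$mw,
                   numeric(1))
  names(yields) <- vapply(p$species, function(sp) sp$species$name, character(1))
  p$yields <- yields
  p$balanced <- TRUE
  p
}

#' @export
print.mdoe_pathway <- function(x, ...) {
  cat(sprintf("<pathway> %s  (%s)\n", x$name,
              if (x$balanced) "balanced" else "unbalanced"))
  if (x$balanced) {
    cat("  yields (g/g substrate):\n")
    for (nm in names(x$yields))
      cat(sprintf("    %-10s %.4f\n", nm, x$yields[[nm]]))
  }
  invisible(x)
}

# elemental closure residual of a balanced pathway, mol per mol substrate
pathway_closure <- function(p) {
  b <- p$substrate$formula
  for (sp in p$species)
    b <- b + (if (sp$side == "reactant") 1 else -1) * sp$nu * sp$species$formula
  b
}
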