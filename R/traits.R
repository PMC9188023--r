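#' The 12 traits used for trait-space comparison
#'
#' Names of the twelve eco-physiological traits entering the bounded-loss
#' distance and multidimensional scaling: ages at birth and puberty, life
#' span, ultimate wet weight, reproduction rate at ultimate size, egg cost,
#' maximum reserve capacity, energy conductance, volume-specific maintenance,
#' area-specific maximum assimilation, supply stress and the precociality
#' coefficient.
#'
#' @return Character vector of column names of a trait table.
#' @export
deb_mds_traits <- function() {
  c("a_b", "a_p", "a_m", "Ww_i", "R_i", "E_0", "E_m",
    "v", "p_M", "p_Am", "s_s", "s_Hbp")
}

#' Build a per-species trait table
#'
#' Runs [deb_life_history()] for every parameter set and assembles the
#' results into a data frame, one row per species, at the reference
#' temperature (20 C). Species whose embryo problem is non-viable, or whose
#' maturation stalls before puberty, are retained with `NA` traits and a
#' raised flag, never dropped silently, so survivor-curve denominators stay
#' explicit.
#'
#' @param params list of [deb_params()] objects with unique `species_id`s.
#' @param const a [chemical_constants()] object.
#' @param f scaled functional response; `NULL` (default) uses each species'
#'   own `f`.
#' @param window reproduction window used for the lifetime cumulated neonate
#'   mass: `"post-puberty"` (`a_m - a_p`, reproduction starts at puberty;
#'   default) or `"lifespan"` (`a_m`).
#' @return A data frame of class `"deb_trait_table"`; columns are the 12
#'   traits of [deb_mds_traits()] plus auxiliaries (`Ww_b`, `Ww_p`, `L_b`,
#'   `L_p`, `L_i`, `r_B`, `r_max`, `jO2_spec`, `N_mass_life`) and the flags
#'   `flag_nonviable`, `flag_stalled`, `flag_demand_bound`.
#' @export
build_trait_table <- function(params, const = chemical_constants(),
                              f = NULL, window = c("post-puberty",
                                                   "lifespan")) {
  window <- match.arg(window)
  ids <- vapply(params, function(p) p$species_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate species_id: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "), call. = FALSE)
  rows <- lapply(params, function(p) {
    fi <- if (is.null(f)) p$f else f
    base <- list(species_id = p$species_id, taxon = p$taxon,
                 sub_taxon = p$sub_taxon,
                 v = p$v, p_M = p$p_M, p_Am = p$p_Am,
                 E_m = p$p_Am / p$v)
    lh <- tryCatch(deb_life_history(p, const, fi),
                   deb_nonviable = function(e) NULL)
    if (is.null(lh)) {
      na <- as.list(rep(NA_real_, 18L))
      names(na) <- c("a_b", "a_p", "a_m", "Ww_i", "R_i", "E_0", "s_s",
                     "s_Hbp", "Ww_b", "Ww_p", "L_b", "L_p", "L_i", "r_B",
                     "r_max", "jO2_spec", "N_mass_life", "unused")
      na$unused <- NULL
      return(c(base, na, list(flag_nonviable = TRUE, flag_stalled = NA,
                              flag_demand_bound = NA)))
    }
    N_mass <- lifetime_neonate_mass(lh$R_i, lh$a_m, lh$a_p, lh$Ww_b,
                                    window = window)
    c(base,
      list(a_b = lh$a_b, a_p = lh$a_p, a_m = lh$a_m, Ww_i = lh$Ww_i,
           R_i = lh$R_i, E_0 = lh$E_0, s_s = lh$s_s, s_Hbp = lh$s_Hbp,
           Ww_b = lh$Ww_b, Ww_p = lh$Ww_p, L_b = lh$L_b, L_p = lh$L_p,
           L_i = lh$L_i, r_B = lh$r_B, r_max = lh$r_max,
           jO2_spec = lh$jO2_spec, N_mass_life = N_mass,
           flag_nonviable = FALSE, flag_stalled = lh$stalled,
           flag_demand_bound = lh$demand_bound))
  })
  cols <- c("species_id", "taxon", "sub_taxon",
            "a_b", "a_p", "a_m", "Ww_i", "R_i", "E_0", "E_m", "v", "p_M",
            "p_Am", "s_s", "s_Hbp", "Ww_b", "Ww_p", "L_b", "L_p", "L_i",
            "r_B", "r_max", "jO2_spec", "N_mass_life",
            "flag_nonviable", "flag_stalled", "flag_demand_bound")
  if (length(rows) == 0L) {
    proto <- c(rep(list(character(0)), 3L), rep(list(numeric(0)), 21L),
               rep(list(logical(0)), 3L))
    tab <- as.data.frame(stats::setNames(proto, cols))
  } else {
    tab <- as.data.frame(do.call(rbind, lapply(rows, function(r) r[cols])))
    tab[] <- lapply(tab, unlist)
    rownames(tab) <- NULL
  }
  attr(tab, "window") <- window
  attr(tab, "generator_config") <- attr(params, "config")
  class(tab) <- c("deb_trait_table", "data.frame")
  tab
}

#' Lifetime cumulated neonate mass
#'
#' Total neonate wet mass produced over the reproductive life:
#' `R_i * (a_m - a_p) * Ww_b` under the default post-puberty window (egg
#' production at the ultimate-size rate over the adult life), or
#' `R_i * a_m * Ww_b` with `window = "lifespan"`.
#'
#' @param R_i reproduction rate at ultimate size (d^-1).
#' @param a_m mean life span (d).
#' @param a_p age at puberty (d).
#' @param Ww_b wet weight at birth (g).
#' @param window `"post-puberty"` or `"lifespan"`.
#' @return Mass (g), or `NA` if any input is missing.
#' @export
lifetime_neonate_mass <- function(R_i, a_m, a_p, Ww_b,
                                  window = c("post-puberty", "lifespan")) {
  window <- match.arg(window)
  span <- if (window == "post-puberty") a_m - a_p else a_m
  out <- R_i * span * Ww_b
  out[!is.finite(out)] <- NA_real_
  out
}

#' @export
print.deb_trait_table <- function(x, ...) {
  cat("DEB trait table:", nrow(x), "species,",
      sum(x$flag_nonviable, na.rm = TRUE), "non-viable,",
      sum(x$flag_stalled, na.rm = TRUE), "stalled\n")
  NextMethod()
}
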