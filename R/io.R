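#' Read a DEB parameter table from CSV
#'
#' Reads a comma-separated parameter table (UTF-8, decimal point) with one
#' row per species. Required columns (units encoded in the names):
#' `species_id, taxon, T_A_K, p_Am_J_d_cm2, v_cm_d, kappa, kappa_R,
#' p_M_J_d_cm3, k_J_1_d, E_G_J_cm3, E_Hb_J, E_Hp_J, h_a_1_d2, s_G`;
#' optional: `sub_taxon`, `f`. Every row is validated; errors name the row
#' and column.
#'
#' @param path file path.
#' @return A list of [deb_params()] objects.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("species_id", "taxon", "T_A_K", "p_Am_J_d_cm2", "v_cm_d",
                "kappa", "kappa_R", "p_M_J_d_cm3", "k_J_1_d", "E_G_J_cm3",
                "E_Hb_J", "E_Hp_J", "h_a_1_d2", "s_G")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  if (!"sub_taxon" %in% names(df)) df$sub_taxon <- NA_character_
  if (!"f" %in% names(df)) df$f <- 1
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    tryCatch(
      deb_params(species_id = r$species_id, taxon = r$taxon,
                 sub_taxon = as.character(r$sub_taxon), T_A = r$T_A_K,
                 p_Am = r$p_Am_J_d_cm2, v = r$v_cm_d, kappa = r$kappa,
                 kappa_R = r$kappa_R, p_M = r$p_M_J_d_cm3, k_J = r$k_J_1_d,
                 E_G = r$E_G_J_cm3, E_Hb = r$E_Hb_J, E_Hp = r$E_Hp_J,
                 h_a = r$h_a_1_d2, s_G = r$s_G, f = r$f),
      error = function(e)
        stop("row ", i, " (", r$species_id, "): ", conditionMessage(e),
             call. = FALSE))
  })
}

#' Write a DEB parameter table to CSV
#'
#' Inverse of [read_parameter_table()]: any table written by this function
#' reads back to identical records.
#'
#' @param params list of [deb_params()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  df <- do.call(rbind, lapply(params, function(p) data.frame(
    species_id = p$species_id, taxon = p$taxon, sub_taxon = p$sub_taxon,
    T_A_K = p$T_A, p_Am_J_d_cm2 = p$p_Am, v_cm_d = p$v, kappa = p$kappa,
    kappa_R = p$kappa_R, p_M_J_d_cm3 = p$p_M, k_J_1_d = p$k_J,
    E_G_J_cm3 = p$E_G, E_Hb_J = p$E_Hb, E_Hp_J = p$E_Hp,
    h_a_1_d2 = p$h_a, s_G = p$s_G, f = p$f)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a trait table to CSV
#'
#' One row per species, columns in the [build_trait_table()] order, missing
#' values as empty fields.
#'
#' @param table a `"deb_trait_table"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#'
#' @param path file path.
#' @return A `"deb_trait_table"` data frame.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  class(tab) <- c("deb_trait_table", "data.frame")
  tab
}

#' Run a pipeline task and write its artifacts
#'
#' Ties the modules together behind one entry point with five tasks:
#' \describe{
#'   \item{simulate}{generate a synthetic parameter table
#'     ([generate_parameter_table()]) and write `parameters.csv`.}
#'   \item{traits}{build the trait table from `input` (a parameter CSV) or a
#'     synthetic family, write `traits.csv`.}
#'   \item{survivors}{per trait and taxon, write the sorted survivor-curve
#'     support to `survivors.csv`.}
#'   \item{scaling}{log-log fits of `Ww_b`, `Ww_p`, `s_Hbp`, `jO2_spec` and
#'     `N_mass_life` against `Ww_i`, written to `scaling.csv`.}
#'   \item{mds}{bounded-loss distances, classical MDS coordinates,
#'     eigenvalues and trait-axis correlations, written to `distances.csv`,
#'     `mds_coordinates.csv`, `mds_eigenvalues.csv`,
#'     `mds_trait_correlations.csv`.}
#' }
#' Every run writes `run_log.json` with the package version, seed and
#' configuration, sufficient to reproduce the outputs. Species that fail
#' (non-viable, stalled) are flagged in the trait table and summarized in
#' the log, never dropped silently.
#'
#' @param task one of `"simulate"`, `"traits"`, `"survivors"`, `"scaling"`,
#'   `"mds"`.
#' @param output_dir directory for artifacts (created if needed).
#' @param input optional path to a parameter CSV; if `NULL`, a synthetic
#'   family from `config` is used.
#' @param config a [synthetic_config()]; defaults to
#'   `synthetic_config(seed = seed)`.
#' @param seed integer seed used when `config` is not supplied.
#' @param f optional scaled functional response overriding each species' own.
#' @param traits trait subset for the `survivors` and `mds` tasks.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(task = c("simulate", "traits", "survivors",
                                  "scaling", "mds"),
                         output_dir, input = NULL, config = NULL,
                         seed = 1L, f = NULL, traits = deb_mds_traits()) {
  task <- match.arg(task)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config)) config <- synthetic_config(seed = seed)
  params <- if (is.null(input)) generate_parameter_table(config)
            else read_parameter_table(input)
  written <- list()
  pth <- function(x) file.path(output_dir, x)

  if (task == "simulate") {
    written$parameters <- write_parameter_table(params, pth("parameters.csv"))
  } else {
    tab <- build_trait_table(params, f = f)
    if (task == "traits") {
      written$traits <- write_trait_table(tab, pth("traits.csv"))
    } else if (task == "survivors") {
      traits <- intersect(traits, names(tab))
      rows <- do.call(rbind, lapply(traits, function(tr) {
        do.call(rbind, lapply(split(tab, tab$taxon), function(g) {
          v <- g[[tr]][is.finite(g[[tr]])]
          if (!length(v)) return(NULL)
          vs <- sort(v)
          data.frame(trait = tr, taxon = g$taxon[1], value = vs,
                     survivor = vapply(vs, function(x) mean(v > x),
                                       numeric(1)))
        }))
      }))
      utils::write.csv(rows, pth("survivors.csv"), row.names = FALSE)
      written$survivors <- pth("survivors.csv")
    } else if (task == "scaling") {
      pairs <- c("Ww_b", "Ww_p", "s_Hbp", "jO2_spec", "N_mass_life")
      rows <- do.call(rbind, lapply(pairs, function(yv) {
        ok <- is.finite(tab$Ww_i) & is.finite(tab[[yv]]) &
          tab$Ww_i > 0 & tab[[yv]] > 0
        ft <- loglog_slope(tab$Ww_i[ok], tab[[yv]][ok])
        data.frame(y = yv, x = "Ww_i", slope = ft$slope,
                   se_slope = ft$se_slope, intercept = ft$intercept,
                   se_intercept = ft$se_intercept,
                   r_squared = ft$r_squared, n = ft$n)
      }))
      utils::write.csv(rows, pth("scaling.csv"), row.names = FALSE)
      written$scaling <- pth("scaling.csv")
    } else if (task == "mds") {
      D <- trait_distance_matrix(tab, traits = traits)
      mds <- classical_mds(D, n_axes = 2L)
      corr <- trait_axis_correlations(tab, mds, traits = traits)
      utils::write.csv(as.data.frame(unclass(D)), pth("distances.csv"))
      utils::write.csv(as.data.frame(mds$points), pth("mds_coordinates.csv"))
      utils::write.csv(data.frame(axis = seq_along(mds$eig),
                                  eigenvalue = mds$eig),
                       pth("mds_eigenvalues.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(corr), pth("mds_trait_correlations.csv"))
      written <- c(written, list(
        distances = pth("distances.csv"),
        coordinates = pth("mds_coordinates.csv"),
        eigenvalues = pth("mds_eigenvalues.csv"),
        correlations = pth("mds_trait_correlations.csv")))
    }
    n_flag <- sum(tab$flag_nonviable | (!is.na(tab$flag_stalled) &
                                          tab$flag_stalled), na.rm = TRUE)
    if (n_flag > 0)
      warning(n_flag, " species flagged non-viable or stalled; see ",
              "trait-table flags", call. = FALSE)
  }

  log <- list(package = "debtraits",
              version = as.character(utils::packageVersion("debtraits")),
              task = task, seed = config$seed,
              input = if (is.null(input)) NA else input,
              f = if (is.null(f)) NA else f,
              config = config[!(names(config) %in% "omega_mode")],
              omega_mode = config$omega_mode,
              files = unlist(written))
  jsonlite::write_json(log, pth("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  written$run_log <- pth("run_log.json")
  invisible(written)
}
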