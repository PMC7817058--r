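#' Shipped parameter presets
#'
#' Published response parameters and resistance-enzyme settings used in the
#' examples: chloramphenicol (`CHL`, alpha = 1.04), streptomycin (`STR`,
#' alpha = 0.46), the strong easily-saturated resistance enzyme
#' (`cerg_strong`: \eqn{V'_{max} = 1000\,\mu M h^{-1}},
#' \eqn{K_{rem} = 0.1\,\mu M}) and the resistance-activity sweep
#' `cerg_vmax_sweep = c(0, 100, 950)` \eqn{\mu M h^{-1}}.
#'
#' @return Named list of presets.
#' @export
ribocomb_presets <- function() {
  list(
    CHL = list(alpha = 1.04),
    STR = list(alpha = 0.46),
    cerg_strong = list(v_max_prime = 1000, k_rem = 0.1),
    cerg_vmax_sweep = c(0, 100, 950),
    growth_defaults = list(kappa_t = 0.06, r_min = 19.3, r_max = 65.8)
  )
}

#' Write / read a dose-response curve as CSV
#'
#' Columns: `concentration`, `concentration_units` (`"ic50"` or `"uM"`),
#' `growth_relative`, `branch`.
#'
#' @param curve a `dose_response_curve`.
#' @param path output file.
#' @return `write_curve_csv`: the path, invisibly.  `read_curve_csv`: a
#'   `dose_response_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  df <- data.frame(concentration = curve$concentration,
                   concentration_units = attr(curve, "units"),
                   growth_relative = curve$growth_relative,
                   branch = curve$branch)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concentration", "concentration_units", "growth_relative",
            "branch")
  stopifnot(all(need %in% names(df)))
  out <- df[c("concentration", "growth_relative", "branch")]
  structure(out, class = c("dose_response_curve", "data.frame"),
            alpha = NA_real_, units = df$concentration_units[1],
            branch_policy = "as-read")
}

#' Write / read a dose-response surface as long-format CSV
#'
#' Columns `c_A`, `c_B`, `y`; the grid is reconstructed on read.
#'
#' @param surface a `dose_response_surface`.
#' @param path file path.
#' @return `write_surface_csv`: path invisibly; `read_surface_csv`: a
#'   `dose_response_surface`.
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "dose_response_surface"))
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("c_A", "c_B", "y") %in% names(df)))
  c_A <- sort(unique(df$c_A)); c_B <- sort(unique(df$c_B))
  y <- matrix(NA_real_, length(c_A), length(c_B))
  y[cbind(match(df$c_A, c_A), match(df$c_B, c_B))] <- df$y
  dose_response_surface(c_A, c_B, y, meta = list(source = path))
}

#' Write / read a dose-response surface as JSON (grids + matrix + metadata)
#'
#' @param surface a `dose_response_surface`.
#' @param path file path.
#' @return `write_surface_json`: path invisibly; `read_surface_json`: a
#'   `dose_response_surface`.
#' @export
write_surface_json <- function(surface, path) {
  stopifnot(inherits(surface, "dose_response_surface"))
  obj <- list(schema = "ribocomb/surface/v1",
              c_A = surface$c_A, c_B = surface$c_B,
              y = surface$y, meta = surface$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_surface_json
#' @export
read_surface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dose_response_surface(obj$c_A, obj$c_B, obj$y,
                        meta = if (is.null(obj$meta)) list() else obj$meta)
}

# ---- configuration ---------------------------------------------------------

config_defaults <- function() {
  list(growth = list(kappa_t = 0.06, r_min = 19.3, r_max = 65.8,
                     lambda0 = 1),
       delta = list(delta_on_A = 1, delta_on_B = 1,
                    delta_off_A = 1, delta_off_B = 1),
       grid = list(c_max = 3, n = 121),
       seed = 1L)
}

validate_drug_block <- function(block, name) {
  has_kin <- !is.null(block$kinetics)
  has_shape <- !is.null(block$shape)
  if (has_kin == has_shape)
    stop(sprintf("drug '%s': specify exactly one of kinetics or shape",
                 name))
  if (has_kin) {
    need <- c("p_in", "p_out", "k_on", "k_off")
    miss <- setdiff(need, names(block$kinetics))
    if (length(miss))
      stop(sprintf("drug '%s': kinetics missing fields: %s", name,
                   paste(miss, collapse = ", ")))
  } else if (is.null(block$shape$alpha)) {
    stop(sprintf("drug '%s': shape needs an alpha", name))
  }
  invisible(TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration (dispatch on file extension), fills
#' in the growth-law defaults and standard delta/grid blocks, and checks
#' that each drug block specifies exactly one of `kinetics` or `shape`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return Validated configuration list of class `ribocomb_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  def <- config_defaults()
  for (blk in names(def)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- def[[blk]]
    else if (is.list(def[[blk]]))
      for (f in names(def[[blk]]))
        if (is.null(cfg[[blk]][[f]])) cfg[[blk]][[f]] <- def[[blk]][[f]]
  }
  for (d in intersect(c("drug_A", "drug_B"), names(cfg)))
    validate_drug_block(cfg[[d]], d)
  g <- cfg$grid
  if (!(g$c_max > 0 && g$n >= 2)) stop("grid block: need c_max > 0, n >= 2")
  structure(cfg, class = c("ribocomb_config", "list"))
}

config_laws <- function(cfg) {
  do.call(growth_laws, cfg$growth)
}

config_drug <- function(cfg, which, laws) {
  blk <- cfg[[paste0("drug_", which)]]
  if (is.null(blk)) stop("config lacks drug_", which)
  if (!is.null(blk$kinetics)) do.call(drug_kinetics, blk$kinetics)
  else shape_to_kinetics(blk$shape$alpha, laws)
}

config_deltas <- function(cfg) do.call(binding_modifiers, cfg$delta)
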