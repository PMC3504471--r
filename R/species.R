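#' Species maturation-clock parameters
#'
#' Bundle the parameters of one species' cortical FA maturation clock:
#' the postconceptional age \code{t_init} at which cortical FA starts its
#' exponential decline (the end of pyramidal neurogenesis and migration),
#' the decay time constant \code{tau} (the species' rate of neuropil
#' maturation), the FA plateau and asymptote, and gestation length used to
#' convert postnatal ages to postconceptional ones.
#'
#' All ages are days post conception (dpc). Postnatal ages exist only at the
#' I/O boundary; see [pn_to_pc()].
#'
#' @param species_name character label, e.g. \code{"rat"}.
#' @param gestation_days gestation length in days (> 0).
#' @param t_init onset of FA decay, days post conception (> 0).
#' @param tau exponential decay time constant in days (> 0). May be \code{NA}
#'   for species with no published FA trajectory (e.g. cat), in which case the
#'   clock cannot be evaluated but frame conversions still work.
#' @param fa_max FA plateau value before \code{t_init}, in (0, 1].
#' @param fa_min asymptotic mature FA, in [0, 1), strictly below
#'   \code{fa_max}. Window translation depends only on the decay fraction, so
#'   the defaults \code{fa_max = 1, fa_min = 0} are benign nominal bounds.
#' @return an object of class \code{species_fa_params}.
#' @examples
#' rat <- species_params("rat", gestation_days = 21.5, t_init = 22, tau = 5)
#' fa_at_age(rat, 25.5)
#' @export
species_params <- function(species_name, gestation_days, t_init = NA_real_,
                           tau = NA_real_, fa_max = 1, fa_min = 0) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  assert_pos(gestation_days, "gestation_days")
  if (!is.na(t_init)) assert_pos(t_init, "t_init")
  if (!is.na(tau)) assert_pos(tau, "tau")
  if (!is.numeric(fa_max) || !is.numeric(fa_min) ||
      fa_min < 0 || fa_max > 1 || fa_min >= fa_max) {
    stop_input("need 0 <= fa_min < fa_max <= 1 (got fa_min=%s, fa_max=%s)",
               fa_min, fa_max)
  }
  structure(
    list(species_name = species_name, gestation_days = as.numeric(gestation_days),
         t_init = as.numeric(t_init), tau = as.numeric(tau),
         fa_max = as.numeric(fa_max), fa_min = as.numeric(fa_min)),
    class = "species_fa_params"
  )
}

#' @export
print.species_fa_params <- function(x, ...) {
  cat(sprintf("<species_fa_params> %s\n", x$species_name))
  cat(sprintf("  gestation: %g d   t_init: %g dpc   tau: %g d\n",
              x$gestation_days, x$t_init, x$tau))
  cat(sprintf("  FA range: [%g, %g]\n", x$fa_min, x$fa_max))
  invisible(x)
}

has_clock <- function(params) {
  !is.na(params$t_init) && !is.na(params$tau)
}

#' Built-in species registry
#'
#' Published clock parameters for the species with fitted cortical FA
#' trajectories: rat (t_init = 22 dpc, tau = 5 d, gestation 21.5 d), ferret
#' (49 dpc, 10.7 d, gestation 41 d), human (173 dpc, 39.8 d, gestation 270 d),
#' plus the cat (gestation 65 d, no published FA trajectory). FA bounds
#' default to the nominal [0, 1] since every prediction in this package
#' depends only on decay fractions.
#'
#' @return named list of [species_params()] objects.
#' @export
default_species_registry <- function() {
  list(
    rat    = species_params("rat",    gestation_days = 21.5, t_init = 22,  tau = 5),
    ferret = species_params("ferret", gestation_days = 41,   t_init = 49,  tau = 10.7),
    human  = species_params("human",  gestation_days = 270,  t_init = 173, tau = 39.8),
    cat    = species_params("cat",    gestation_days = 65)
  )
}

#' Read a species registry from YAML or JSON
#'
#' The file maps species name to fields \code{gestation_days}, \code{t_init},
#' \code{tau} and optionally \code{fa_max}, \code{fa_min}.
#'
#' @param path file path (extension .yaml/.yml or .json).
#' @return named list of [species_params()] objects.
#' @export
read_species_registry <- function(path) {
  if (!file.exists(path)) stop_input("registry file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0) stop_input("registry is empty: %s", path)
  out <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    species_params(
      species_name = nm,
      gestation_days = entry$gestation_days,
      t_init = entry$t_init %||% NA_real_,
      tau = entry$tau %||% NA_real_,
      fa_max = entry$fa_max %||% 1,
      fa_min = entry$fa_min %||% 0
    )
  })
  stats::setNames(out, names(raw))
}

#' Write a species registry to YAML
#'
#' @param registry named list of [species_params()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_registry <- function(registry, path) {
  entries <- lapply(registry, function(p) {
    list(gestation_days = p$gestation_days, t_init = p$t_init, tau = p$tau,
         fa_max = p$fa_max, fa_min = p$fa_min)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
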