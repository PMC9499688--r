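# Analysis configuration: defaults are the study's stated parameters
# (contact 0.54 nm; H-bond 0.35 nm / 150 deg; cluster cutoff 0.45 nm;
# SASA probe 0.14 nm; 310 K).

analysisDefaults <- function() {
  list(
    contact_cutoff = 0.54,
    hbond_distance = 0.35,
    hbond_angle = 150,
    cluster_cutoff = 0.45,
    stacking_parallel_max = 30,
    stacking_herringbone_min = 50,
    temperature = 310,
    sasa_probe = 0.14,
    sasa_points = 960L,
    pmf_bins = c(50L, 50L),
    chpi_mode = "centroid",
    convergence_threshold = 0.05,
    window_a = NULL,
    window_b = NULL,
    cluster_max_frames = 600L,
    seed = 1L)
}

#' Validate an analysis configuration
#'
#' Reads a YAML key-value file (or takes a named list), applies the
#' package defaults for absent keys, rejects unknown keys (with a
#' closest-match suggestion) and aggregates all range errors into a
#' single message.
#'
#' @param config path to a YAML file, a named list, or \code{NULL} for
#'   pure defaults.
#' @return a validated configuration list.
#' @export
validateConfig <- function(config = NULL) {
  def <- analysisDefaults()
  user <- list()
  if (is.character(config)) {
    if (!file.exists(config)) stop("validateConfig: no such file: ", config)
    user <- yaml::read_yaml(config)
    if (is.null(user)) user <- list()
  } else if (is.list(config)) {
    user <- config
  } else if (!is.null(config)) {
    stop("validateConfig: config must be a file path or a named list")
  }
  errors <- character(0)
  for (key in names(user)) {
    if (!key %in% names(def)) {
      sug <- agrep(key, names(def), max.distance = 0.3, value = TRUE)
      errors <- c(errors, sprintf("unknown key '%s'%s", key,
                                  if (length(sug)) paste0(" (did you mean '",
                                                          sug[1], "'?)") else ""))
    }
  }
  cfg <- def
  for (key in intersect(names(user), names(def))) cfg[[key]] <- user[[key]]
  checkPos <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      errors <<- c(errors, sprintf("%s: must be a positive number (got %s)",
                                   key, paste(v, collapse = ",")))
  }
  for (key in c("contact_cutoff", "hbond_distance", "cluster_cutoff",
                "temperature", "sasa_probe", "convergence_threshold"))
    checkPos(key)
  for (key in c("hbond_angle", "stacking_parallel_max",
                "stacking_herringbone_min")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v >= 180)
      errors <- c(errors, sprintf("%s: must be an angle in (0, 180) degrees", key))
  }
  if (!is.numeric(cfg$sasa_points) || cfg$sasa_points < 92)
    errors <- c(errors, "sasa_points: must be at least 92")
  if (!is.numeric(cfg$pmf_bins) || length(cfg$pmf_bins) != 2 ||
      any(cfg$pmf_bins < 2))
    errors <- c(errors, "pmf_bins: must be two bin counts of at least 2")
  if (!cfg$chpi_mode %in% c("centroid", "ringatoms"))
    errors <- c(errors, "chpi_mode: must be 'centroid' or 'ringatoms'")
  if (length(errors))
    stop("validateConfig: ", paste(errors, collapse = "; "))
  cfg$sasa_points <- as.integer(cfg$sasa_points)
  cfg$pmf_bins <- as.integer(cfg$pmf_bins)
  cfg
}
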