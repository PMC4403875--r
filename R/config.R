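# Run configuration: YAML file with CLI-flag overrides.

default_config <- function() {
  list(
    criteria = unclass(hbond_criteria()),
    geometry = "engh_huber",
    flags = list(shared_double_count = TRUE, strict_audit = FALSE,
                 rama_scope = "helical"),
    rama_bin_size = 1
  )
}

#' Read a run configuration
#'
#' Loads a YAML configuration for the survey pipeline and merges it
#' over the package defaults.  Recognised keys: `criteria` (max_ha,
#' max_da, min_dha, min_hac), `geometry` (a [geometry_set()] name),
#' `flags` (shared_double_count, strict_audit, rama_scope), and
#' `rama_bin_size`.  Unknown keys are rejected rather than silently
#' ignored.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Named list with entries `criteria` (an [hbond_criteria()]),
#'   `geometry`, `flags`, `rama_bin_size`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    check_keys <- function(given, allowed, where) {
      extra <- setdiff(names(given), allowed)
      if (length(extra))
        stop(sprintf("unknown config key(s) in %s: %s", where,
                     paste(extra, collapse = ", ")), call. = FALSE)
    }
    check_keys(user, names(cfg), "config")
    for (sec in c("criteria", "flags")) {
      if (!is.null(user[[sec]])) {
        check_keys(user[[sec]], names(cfg[[sec]]), sec)
        cfg[[sec]][names(user[[sec]])] <- user[[sec]]
      }
    }
    if (!is.null(user$geometry)) cfg$geometry <- user$geometry
    if (!is.null(user$rama_bin_size)) cfg$rama_bin_size <- user$rama_bin_size
  }
  cfg$criteria <- do.call(hbond_criteria, cfg$criteria)
  geometry_set(cfg$geometry)  # validate the name
  stopifnot(cfg$flags$rama_scope %in% c("helical", "all"))
  cfg
}
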