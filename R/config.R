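#' Pipeline configuration
#'
#' Defaults follow the published operating point of the method: burrs are
#' skeleton branches shorter than 6 px; local line fits use 5 centerline
#' pixels; a child vessel attaches when the Manhattan gap to its parent's
#' end is at most 10 px; two vessels in different frames are the same when
#' their start and end points are each within 65 px and the length ratio
#' exceeds 0.80; stenosis findings below 30% are reported normal; a bridge
#' fires on a stenosis-degree swing of at least 0.25 or a mean-diameter
#' ratio of at most 0.75, with the extreme frames at least 3 apart.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters.
#' @export
angio_config <- function(...) {
  cfg <- list(
    burr_min_len = 6L,          # px, strict less-than removes
    line_fit_N = 5L,            # centerline pixels per local fit
    d_n_threshold = 10,         # px, Manhattan, inclusive
    d_s_max = 65,               # px, Manhattan, strict
    d_e_max = 65,               # px, Manhattan, strict
    rate_min = 0.80,            # length ratio, strict greater-than
    smooth_N_w = 5L,            # moving-average window (odd)
    stenosis_floor = 30,        # percent; below -> normal
    bridge_stenosis_delta = 0.25,
    bridge_diameter_ratio = 0.75,
    bridge_frame_gap = 3L,      # frames, inclusive
    junction_exclusion = 2,     # px around intersections skipped in profiles
    normal_search_cap = 50,     # px per side when marching to the edge
    normal_step = 0.25          # px march step
  )
  over <- list(...)
  if (length(over) > 0L) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0L) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$burr_min_len > 0, cfg$line_fit_N >= 2, cfg$d_n_threshold > 0,
            cfg$d_s_max > 0, cfg$d_e_max > 0,
            cfg$rate_min > 0, cfg$rate_min < 1,
            cfg$smooth_N_w >= 1, cfg$smooth_N_w %% 2 == 1,
            cfg$bridge_frame_gap > 0, cfg$normal_search_cap > 0,
            cfg$normal_step > 0)
  cfg
}

#' Read a configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are [angio_config()] fields.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  do.call(angio_config, yaml::read_yaml(path))
}
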