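#' Read and write quench-flow time-course tables
#'
#' CSV dialect: columns `time_s`, `fraction_extended` and optionally
#' `sigma` (per-point standard deviation); header row mandatory.
#'
#' @param tc a [time_course()].
#' @param path file path.
#' @return `write_timecourse` returns `path` invisibly; `read_timecourse`
#'   returns a [time_course()].
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "fraction_extended") %in% names(df)))
    stop("time-course CSV needs columns time_s, fraction_extended",
         call. = FALSE)
  time_course(df$time_s, df$fraction_extended, sigma = df$sigma)
}

#' Read and write titration tables
#'
#' CSV dialect: columns `enzyme_nM`, `anisotropy`, `rel_intensity`.
#'
#' @param curve a `titration_curve`.
#' @param path file path.
#' @param dna_total total DNA (nM) to attach when reading.
#' @return `write_titration` returns `path` invisibly; `read_titration`
#'   returns a `titration_curve`.
#' @export
write_titration <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path, dna_total = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("enzyme_nM", "anisotropy") %in% names(df)))
    stop("titration CSV needs columns enzyme_nM, anisotropy", call. = FALSE)
  titration_curve(df$enzyme_nM, df$anisotropy, df$rel_intensity,
                  dna_total = dna_total)
}

#' Read and write gel-lane series
#'
#' Long-format CSV dialect: columns `time_s`, `length_nt`, `intensity`,
#' one row per band.
#'
#' @param lanes a list of [lane_profile()] objects.
#' @param path file path.
#' @return `write_lanes` returns `path` invisibly; `read_lanes` returns a
#'   list of [lane_profile()] objects ordered by quench time.
#' @export
write_lanes <- function(lanes, path) {
  rows <- do.call(rbind, lapply(lanes, function(l) {
    data.frame(time_s = attr(l, "time"), length_nt = l$length,
               intensity = l$intensity)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lanes
#' @export
read_lanes <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "length_nt", "intensity") %in% names(df)))
    stop("lane CSV needs columns time_s, length_nt, intensity", call. = FALSE)
  lapply(sort(unique(df$time_s)), function(t) {
    sub <- df[df$time_s == t, ]
    sub <- sub[order(sub$length_nt), ]
    lane_profile(sub$intensity, sub$length_nt, time = t)
  })
}

#' Read and write simulation/fit configuration files
#'
#' Key-value configuration with nested sections, stored as YAML; used by
#' the analysis drivers to record ground-truth parameters alongside the
#' datasets they generate, so recovery runs are self-describing.
#'
#' @param config a named list.
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
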