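#' Gel-lane band intensities indexed by product length
#'
#' A quantified denaturing-gel lane: one intensity per product length from
#' the unextended primer (length 0) up to primer+n. Lanes are indexed by
#' product length, not gel migration distance, which keeps quantification
#' exact; the synthetic gel generator owns the length-to-position map.
#'
#' @param intensity band intensities (arbitrary units, >= 0, at least one
#'   positive), ordered by length.
#' @param lengths product lengths in nucleotides; must be contiguous from 0.
#' @param time quench time label in seconds.
#' @param condition optional condition label.
#' @return An object of class `lane_profile` (a data.frame with columns
#'   `length`, `intensity`).
#' @export
lane_profile <- function(intensity, lengths = seq_along(intensity) - 1,
                         time = NA_real_, condition = NA_character_) {
  if (any(intensity < 0) || !any(intensity > 0))
    stop("lane needs non-negative intensities with at least one positive band",
         call. = FALSE)
  if (!identical(as.integer(lengths), seq.int(0L, length.out = length(lengths))))
    stop("lengths must be contiguous from 0", call. = FALSE)
  structure(data.frame(length = as.integer(lengths), intensity = intensity),
            time = time, condition = condition,
            class = c("lane_profile", "data.frame"))
}

#' Normalize a lane to its peak band
#'
#' Divides every band by the lane maximum so the most intense band is
#' exactly 1 -- the normalization used to compare product distributions
#' across conditions on a common scale.
#'
#' @param lane a [lane_profile()].
#' @return A `lane_profile` with the maximum intensity equal to 1 and a
#'   `normalized = "peak"` attribute.
#' @export
normalize_to_peak <- function(lane) {
  stopifnot(inherits(lane, "lane_profile"))
  m <- max(lane$intensity)
  if (m <= 0) stop("all-zero lane cannot be normalized", call. = FALSE)
  out <- lane
  out$intensity <- lane$intensity / m
  attr(out, "normalized") <- "peak"
  out
}

#' Modal product length of a distribution or lane
#'
#' The length with the highest probability/intensity; ties are broken toward
#' the shorter product and flagged.
#'
#' @param dist a `length_distribution` or `lane_profile` (any data.frame
#'   with a `length` column and a `probability` or `intensity` column).
#' @param tie_tol relative tolerance for declaring a tie.
#' @return The modal length (nucleotides) with attribute `tie` (logical).
#' @export
modal_length <- function(dist, tie_tol = 1e-9) {
  v <- if (!is.null(dist$probability)) dist$probability else dist$intensity
  m <- max(v)
  at_max <- which(v >= m * (1 - tie_tol))
  structure(dist$length[at_max[1]], tie = length(at_max) > 1)
}

#' Fraction of primer molecules extended by at least one nucleotide
#'
#' `1 - band(0) / total intensity`: the fractional extension observable of
#' the single-nucleotide quench-flow assays, computed from a quantified
#' lane.
#'
#' @param lane a [lane_profile()].
#' @return Fraction extended in `[0, 1]`.
#' @export
fraction_extended <- function(lane) {
  stopifnot(inherits(lane, "lane_profile"))
  tot <- sum(lane$intensity)
  if (tot <= 0) stop("all-zero lane", call. = FALSE)
  1 - lane$intensity[lane$length == 0] / tot
}
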