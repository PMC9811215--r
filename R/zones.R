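#' The five biosecurity zones
#'
#' The farm is partitioned into three main risk areas following the FAO
#' three-zone model -- the access-restricted broiler house (green), the paved
#' professional farmyard (orange) and the external surroundings (red) -- plus
#' the two transition zones covering the crossings between them. Reporting
#' order is inside to outside: green, orange-green, orange, red-orange, red.
#'
#' @return Character vector of the five zone labels, in reporting order.
#' @export
#' @examples
#' beat_zones()
beat_zones <- function() {
  c("green", "orange_green", "orange", "red_orange", "red")
}

#' @noRd
assert_zone <- function(zone) {
  if (!is.character(zone) || !all(zone %in% beat_zones())) {
    stop("unknown zone label(s): ",
         paste(setdiff(as.character(zone), beat_zones()), collapse = ", "),
         "; valid zones are ", paste(beat_zones(), collapse = ", "),
         call. = FALSE)
  }
  invisible(zone)
}

#' @noRd
zone_factor <- function(zone) {
  factor(zone, levels = beat_zones())
}

#' Classify a relative score as a traffic light
#'
#' Maps a relative compliance score in \[0, 1\] to red / amber / green. The
#' instrument itself colours full compliance (1) green and no compliance (0)
#' red; the intermediate cut points are package defaults and configurable.
#'
#' @param relative Numeric vector of relative scores in \[0, 1\].
#' @param thresholds Length-2 increasing numeric vector `c(red_upper,
#'   amber_upper)`: scores `< thresholds[1]` are red, scores in
#'   `[thresholds[1], thresholds[2])` amber, scores `>= thresholds[2]` green.
#'   Default `c(0.4, 0.7)`.
#' @return Factor with levels red < amber < green, same length as `relative`.
#' @export
#' @examples
#' traffic_light(c(0, 0.55, 1))
traffic_light <- function(relative, thresholds = c(0.4, 0.7)) {
  stopifnot(is.numeric(relative), is.numeric(thresholds),
            length(thresholds) == 2L)
  if (thresholds[1] >= thresholds[2] || thresholds[1] <= 0 || thresholds[2] >= 1) {
    stop("thresholds must satisfy 0 < red_upper < amber_upper < 1", call. = FALSE)
  }
  bad <- !is.na(relative) & (relative < 0 | relative > 1)
  if (any(bad)) {
    stop("relative score(s) outside [0, 1]: ",
         paste(utils::head(relative[bad], 3), collapse = ", "), call. = FALSE)
  }
  cut(relative, breaks = c(-Inf, thresholds, Inf),
      labels = c("red", "amber", "green"), right = FALSE,
      ordered_result = TRUE)
}
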