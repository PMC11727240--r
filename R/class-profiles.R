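# Class-conditioned site-gain profiles. Each occlusion class or oral habit
# is encoded as a deterministic map from tooth site to a nonnegative gain
# that multiplies the biphasic pulse amplitudes at that site, plus a pulse
# rate and (for teeth grinding) a left/right alternation flag.

#' Occlusion classes and oral habits
#'
#' Two disjoint label sets are supported and never mixed in one task:
#' malocclusions `AnI`, `AnII`, `AnIII` (Angle classes I-III), `OB` (open
#' bite), `MD` (mandibular deviation); and habits `CO` (centric occlusion),
#' `LB` (lip biting), `TS` (thumb sucking), `GT` (teeth grinding).
#'
#' @return Character vector of labels.
#' @export
malocclusion_classes <- function() c("AnI", "AnII", "AnIII", "OB", "MD")

#' @rdname malocclusion_classes
#' @export
habit_classes <- function() c("CO", "LB", "TS", "GT")

.check_label <- function(label) {
  valid <- c(malocclusion_classes(), habit_classes())
  if (!(is.character(label) && length(label) == 1 && label %in% valid)) {
    stop("unknown class label ", deparse(label), "; valid labels: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  label
}

#' Site-gain profile for an occlusion class or habit
#'
#' Returns the deterministic per-site amplitude pattern that characterises a
#' class. Gains encode the clinical signatures: Angle II has weaker
#' mandibular second molars and weaker maxillary incisors than Angle I
#' (Angle III the reverse); open bite suppresses incisors in both jaws;
#' mandibular deviation loads the left side more than the right; lip biting
#' and thumb sucking silence the molars (and differ in premolar engagement);
#' teeth grinding loads posterior teeth in alternating left/right bursts.
#'
#' @param label One of [malocclusion_classes()] or [habit_classes()].
#'
#' @return An object of class `occl_profile`: a list with `label`, `gains`
#'   (tibble `site`, `gain` over all 16 sites), `pulse_rate` (Hz),
#'   `alternation` (`"none"` or `"left_right"`) and `active_sites` (sites
#'   with gain > 0).
#' @export
#' @examples
#' class_profile("AnII")$gains
class_profile <- function(label) {
  .check_label(label)
  sites <- tooth_sites("both")
  gain <- rep(1, nrow(sites))
  names(gain) <- sites$site
  alternation <- "none"
  set_gain <- function(g, jaw, type, side = NULL, value) {
    sel <- sites$jaw %in% jaw & sites$tooth_type %in% type
    if (!is.null(side)) sel <- sel & sites$side %in% side
    g[sel] <- value
    g
  }
  switch(label,
    AnI = NULL,
    CO  = NULL,
    AnII = {
      gain <- set_gain(gain, "mandible", "second_molar", value = 0.4)
      gain <- set_gain(gain, "maxilla", "incisor", value = 0.4)
    },
    AnIII = {
      gain <- set_gain(gain, "maxilla", "second_molar", value = 0.4)
      gain <- set_gain(gain, "mandible", "incisor", value = 0.4)
    },
    OB = {
      gain <- set_gain(gain, c("maxilla", "mandible"), "incisor", value = 0.3)
    },
    MD = {
      gain[sites$site[sites$side == "right"]] <- 0.5
    },
    LB = {
      gain <- set_gain(gain, c("maxilla", "mandible"), "premolar", value = 0.6)
      gain <- set_gain(gain, c("maxilla", "mandible"),
                       c("first_molar", "second_molar"), value = 0.2)
    },
    TS = {
      gain <- set_gain(gain, c("maxilla", "mandible"), "premolar", value = 0.2)
      gain <- set_gain(gain, c("maxilla", "mandible"),
                       c("first_molar", "second_molar"), value = 0.2)
    },
    GT = {
      gain <- set_gain(gain, c("maxilla", "mandible"), "incisor", value = 0.1)
      gain <- set_gain(gain, c("maxilla", "mandible"), "premolar", value = 0.8)
      alternation <- "left_right"
    }
  )
  structure(
    list(
      label = label,
      gains = tibble::tibble(site = sites$site, gain = unname(gain[sites$site])),
      pulse_rate = 1.0,
      alternation = alternation,
      active_sites = sites$site[gain[sites$site] > 0]
    ),
    class = "occl_profile"
  )
}

#' @export
print.occl_profile <- function(x, ...) {
  cat(sprintf("<occl_profile> %s, pulse rate %g Hz, alternation %s\n",
              x$label, x$pulse_rate, x$alternation))
  print(tidyr::pivot_wider(
    dplyr::mutate(x$gains,
                  jaw = substr(.data$site, 1, 3),
                  position = substr(.data$site, 5, 7)),
    id_cols = "jaw", names_from = "position", values_from = "gain"
  ))
  invisible(x)
}
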