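# Tooth-site vocabulary shared by the simulator, the feature extractor and
# the importance report. Eight sensor positions per jaw, mirrored left/right.

#' @keywords internal
.POSITIONS <- c("LCI", "RCI", "LFP", "RFP", "LFM", "RFM", "LSM", "RSM")

#' @keywords internal
.JAW_CODES <- c(maxilla = "MAX", mandible = "MAN")

#' Enumerate tooth sensor sites
#'
#' The sensor array covers eight positions per jaw: left/right central
#' incisors (LCI, RCI), first premolars (LFP, RFP), first molars (LFM, RFM)
#' and second molars (LSM, RSM). A two-jaw recording therefore has 16 sites,
#' maxilla first.
#'
#' @param jaws Which jaws to include: `"both"`, `"maxilla"` or `"mandible"`.
#'
#' @return A tibble with columns `jaw`, `position`, `side` (`"left"`/
#'   `"right"`), `tooth_type` (`incisor`/`premolar`/`first_molar`/
#'   `second_molar`) and `site` (e.g. `"MAX_LCI"`), in canonical channel
#'   order.
#' @export
#' @examples
#' tooth_sites("mandible")
tooth_sites <- function(jaws = c("both", "maxilla", "mandible")) {
  jaws <- match.arg(jaws)
  which_jaws <- if (jaws == "both") c("maxilla", "mandible") else jaws
  tidyr::expand_grid(jaw = which_jaws, position = .POSITIONS) |>
    dplyr::mutate(
      side = ifelse(startsWith(.data$position, "L"), "left", "right"),
      tooth_type = dplyr::case_match(
        substr(.data$position, 2, 3),
        "CI" ~ "incisor",
        "FP" ~ "premolar",
        "FM" ~ "first_molar",
        "SM" ~ "second_molar"
      ),
      site = paste(.JAW_CODES[.data$jaw], .data$position, sep = "_")
    )
}

# Mirror a site name across the midline (MAX_LCI <-> MAX_RCI).
.mirror_site <- function(site) {
  pos <- substr(site, 5, 7)
  flipped <- ifelse(startsWith(pos, "L"), sub("^L", "R", pos), sub("^R", "L", pos))
  paste0(substr(site, 1, 4), flipped)
}

.site_channels <- function(jaws) tooth_sites(jaws)$site
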