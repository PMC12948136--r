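# Modality and marker registries: the fixed shape contract every stage of
# the pipeline validates against.

#' Modality registry
#'
#' Returns the specification of the four recording modalities: 3D reflective
#' marker trajectories, ground reaction forces (GRF), surface EMG and the
#' foot forces-and-moments (F&M) channels.  `temporal` is the fixed
#' (zero-padded) number of frames per trial, `dim` the dimensionality of each
#' data point (3 for 3D signals, 1 for EMG) and `spatial` the number of
#' channels.
#'
#' @return A data.frame with one row per modality and columns `name`,
#'   `rate_hz`, `temporal`, `dim` and `spatial`.
#' @examples
#' modality_registry()
#' @export
modality_registry <- function() {
  data.frame(
    name     = c("markers", "grf", "emg", "fm"),
    rate_hz  = c(100, 1500, 1500, 1500),
    temporal = c(585L, 585L, 8985L, 8985L),
    dim      = c(3L, 3L, 1L, 3L),
    spatial  = c(156L, 24L, 8L, 12L),
    stringsAsFactors = FALSE
  )
}

modality_spec <- function(name) {
  reg <- modality_registry()
  row <- reg[reg$name == name, ]
  assert_that(nrow(row) == 1L, sprintf("unknown modality '%s'", name))
  row
}

modality_names <- function() modality_registry()$name

#' Anatomical marker registry
#'
#' The 52 reflective skin markers used by the motion-capture protocol, in
#' the order that defines the 156 marker channels.  Channel `c` of marker
#' `m` at coordinate `d` (x, y, z) is `3 * (m - 1) + d`.
#'
#' @return A data.frame with columns `index` (1-52), `label` (e.g.
#'   `"L_IAS"`), `description`, `side` (`"L"`, `"R"` or `"M"` for midline)
#'   and `region` (pelvis, leg, foot, trunk, shoulder, arm).
#' @examples
#' nrow(marker_registry())
#' @export
marker_registry <- function() {
  m <- function(index, label, description, region) {
    side <- if (startsWith(label, "L_")) "L" else if (startsWith(label, "R_")) "R" else "M"
    data.frame(index = index, label = label, description = description,
               side = side, region = region, stringsAsFactors = FALSE)
  }
  out <- rbind(
    m(1L,  "L_IAS", "left anterior superior iliac spine", "pelvis"),
    m(2L,  "L_IPS", "left posterior superior iliac spine", "pelvis"),
    m(3L,  "L_FTC", "left greater trochanter", "leg"),
    m(4L,  "L_FLE", "left lateral femoral epicondyle", "leg"),
    m(5L,  "L_FME", "left medial femoral epicondyle", "leg"),
    m(6L,  "L_FAX", "left fibula head", "leg"),
    m(7L,  "L_TTC", "left tibial tuberosity", "leg"),
    m(8L,  "L_FAL", "left lateral malleolus", "leg"),
    m(9L,  "L_TAM", "left medial malleolus", "leg"),
    m(10L, "L_FCC", "left posterior calcaneus", "foot"),
    m(11L, "L_FM1", "left first metatarsal head", "foot"),
    m(12L, "L_FM2", "left second metatarsal head", "foot"),
    m(13L, "L_FM5", "left fifth metatarsal head", "foot"),
    m(14L, "CV7",   "seventh cervical vertebra", "trunk"),
    m(15L, "SXS",   "suprasternal notch", "trunk"),
    m(16L, "L_SIA", "left acromial tip", "shoulder"),
    m(17L, "L_SRS", "left spine root of scapula", "shoulder"),
    m(18L, "L_SAA", "left acromial angle", "shoulder"),
    m(19L, "L_SAE", "left acromial edge", "shoulder"),
    m(20L, "L_HLE", "left lateral humeral epicondyle", "arm"),
    m(21L, "L_HME", "left medial humeral epicondyle", "arm"),
    m(22L, "L_UOA", "left olecranon apex", "arm"),
    m(23L, "L_RSP", "left radial styloid process", "arm"),
    m(24L, "L_UHE", "left ulnar styloid process", "arm"),
    m(25L, "L_HM2", "left second metacarpal head", "arm"),
    m(26L, "L_HM5", "left fifth metacarpal head", "arm"),
    m(27L, "R_IPS", "right posterior superior iliac spine", "pelvis"),
    m(28L, "R_IAS", "right anterior superior iliac spine", "pelvis"),
    m(29L, "R_FTC", "right greater trochanter", "leg"),
    m(30L, "R_FLE", "right lateral femoral epicondyle", "leg"),
    m(31L, "R_FME", "right medial femoral epicondyle", "leg"),
    m(32L, "R_FAX", "right fibula head", "leg"),
    m(33L, "R_TTC", "right tibial tuberosity", "leg"),
    m(34L, "R_FAL", "right lateral malleolus", "leg"),
    m(35L, "R_TAM", "right medial malleolus", "leg"),
    m(36L, "R_FCC", "right posterior calcaneus", "foot"),
    m(37L, "R_FM1", "right first metatarsal head", "foot"),
    m(38L, "R_FM2", "right second metatarsal head", "foot"),
    m(39L, "R_FM5", "right fifth metatarsal head", "foot"),
    m(40L, "TV10",  "tenth thoracic vertebra spinous process", "trunk"),
    m(41L, "SJN",   "xiphoid process", "trunk"),
    m(42L, "R_SIA", "right acromial tip", "shoulder"),
    m(43L, "R_SRS", "right spine root of scapula", "shoulder"),
    m(44L, "R_SAA", "right acromial angle", "shoulder"),
    m(45L, "R_SAE", "right acromial edge", "shoulder"),
    m(46L, "R_HLE", "right lateral humeral epicondyle", "arm"),
    m(47L, "R_HME", "right medial humeral epicondyle", "arm"),
    m(48L, "R_UOA", "right olecranon apex", "arm"),
    m(49L, "R_RSP", "right radial styloid process", "arm"),
    m(50L, "R_UHE", "right ulnar styloid process", "arm"),
    m(51L, "R_HM2", "right second metacarpal head", "arm"),
    m(52L, "R_HM5", "right fifth metacarpal head", "arm")
  )
  rownames(out) <- NULL
  out
}

#' Map markers to flattened channel indices
#'
#' The 156 marker channels are ordered marker-major, then (x, y, z):
#' marker `m`, coordinate `d` occupies channel `3 * (m - 1) + d`.
#'
#' @param markers integer marker indices (1-52) or character labels.
#' @return Integer vector of channel indices (1-156).
#' @examples
#' marker_channels("R_SIA")  # channels 124:126
#' @export
marker_channels <- function(markers) {
  reg <- marker_registry()
  if (is.character(markers)) {
    idx <- match(markers, reg$label)
    assert_that(!anyNA(idx),
                paste("unknown marker label(s):",
                      paste(markers[is.na(idx)], collapse = ", ")))
    markers <- idx
  }
  markers <- as.integer(markers)
  assert_that(all(markers >= 1L & markers <= 52L),
              "marker indices must lie in 1..52")
  as.integer(as.vector(vapply(markers, function(m) 3L * (m - 1L) + 1:3,
                              integer(3))))
}

#' Map flattened channel indices back to markers and coordinates
#'
#' Inverse of [marker_channels()].
#'
#' @param channels integer channel indices (1-156).
#' @return A data.frame with columns `channel`, `marker` (index), `label`
#'   and `coordinate` (`"x"`, `"y"` or `"z"`).
#' @export
channel_to_marker <- function(channels) {
  channels <- as.integer(channels)
  assert_that(all(channels >= 1L & channels <= 156L),
              "marker channel indices must lie in 1..156")
  reg <- marker_registry()
  marker <- (channels - 1L) %/% 3L + 1L
  coord <- c("x", "y", "z")[(channels - 1L) %% 3L + 1L]
  data.frame(channel = channels, marker = marker,
             label = reg$label[marker], coordinate = coord,
             stringsAsFactors = FALSE)
}
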