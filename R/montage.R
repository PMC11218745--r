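#' Electrode montage
#'
#' A montage names the recorded data channels, assigns each a role (scalp
#' electrode, left- or right-ear cEEGrid electrode) and defines the vertical
#' bipolar derivations computed from the ear arrays. Ground and reference
#' electrodes are carried as metadata only; they are not data channels.
#'
#' @param name Montage label.
#' @param channels Character vector of data-channel labels, in recording order.
#' @param roles Named character vector mapping every channel to one of
#'   `"scalp"`, `"ceegrid_left"`, `"ceegrid_right"`.
#' @param bipolar_pairs Tibble/data frame with columns `minuend`, `subtrahend`,
#'   `label`; each derived channel is `minuend - subtrahend`, sample-wise.
#' @param ground,reference Labels of the ground and reference electrodes
#'   (metadata; excluded from `channels`).
#' @return An object of class `gt_montage`.
#' @seealso [default_montage()], [derive_bipolar()]
#' @export
montage <- function(name, channels, roles, bipolar_pairs,
                    ground = NA_character_, reference = NA_character_) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) abort("montage channels must be unique")
  roles <- roles[channels]
  if (anyNA(roles)) abort("every channel needs a role")
  bad_role <- setdiff(unique(roles), c("scalp", "ceegrid_left", "ceegrid_right"))
  if (length(bad_role)) abort(paste0("unknown channel role: ", bad_role[1]))
  bp <- as_tibble(bipolar_pairs)
  stopifnot(all(c("minuend", "subtrahend", "label") %in% names(bp)))
  missing <- setdiff(c(bp$minuend, bp$subtrahend), channels)
  if (length(missing))
    abort(paste0("bipolar pair member not in montage: ",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(bp$label) || any(bp$label %in% channels))
    abort("derived labels must be unique and disjoint from data channels")
  structure(
    list(name = name, channels = channels, roles = roles,
         bipolar_pairs = bp, ground = ground, reference = reference),
    class = "gt_montage"
  )
}

#' The study montage: 12-channel scalp cap plus two cEEGrids
#'
#' Returns the montage used throughout: twelve passive scalp electrodes (Fz,
#' FC1, FC2, C3, Cz, C4, P3, Pz, P4, O1, Oz, O2) and the two around-the-ear
#' cEEGrid arrays. On the right ear, electrodes R4a and R4b serve as ground
#' and reference and are therefore not data channels, leaving 18 recordable
#' ear channels (L1--L8, L4a, L4b, R1--R8) by default. Eight vertical bipolar
#' derivations are defined: R1-R8, R2-R7, R3-R6, R4-R5 and their left-ear
#' counterparts.
#'
#' @param mirror_ear_exclusions If `TRUE`, also drop L4a/L4b so the left ear
#'   mirrors the right ear's ground/reference exclusions (16 ear channels).
#'   Whether the left array mirrors the right is not fixed by the hardware
#'   description, so it is configurable; the default keeps 18 ear channels.
#' @return A [montage()] object.
#' @export
#' @examples
#' m <- default_montage()
#' sum(m$roles == "scalp")      # 12
#' nrow(m$bipolar_pairs)        # 8
default_montage <- function(mirror_ear_exclusions = FALSE) {
  scalp <- c("Fz", "FC1", "FC2", "C3", "Cz", "C4", "P3", "Pz", "P4",
             "O1", "Oz", "O2")
  left <- c(paste0("L", 1:4), "L4a", "L4b", paste0("L", 5:8))
  if (mirror_ear_exclusions) left <- setdiff(left, c("L4a", "L4b"))
  right <- paste0("R", 1:8)
  channels <- c(scalp, left, right)
  roles <- setNames(
    c(rep("scalp", length(scalp)),
      rep("ceegrid_left", length(left)),
      rep("ceegrid_right", length(right))),
    channels
  )
  pair <- function(side) tibble(
    minuend = paste0(side, 1:4),
    subtrahend = paste0(side, 8:5),
    label = paste0(side, 1:4, "-", side, 8:5)
  )
  montage("ceegrid-tactile-study", channels, roles,
          dplyr::bind_rows(pair("R"), pair("L")),
          ground = "R4a", reference = "R4b")
}

#' @export
print.gt_montage <- function(x, ...) {
  cat("<gt_montage> ", x$name, "\n", sep = "")
  cat("  scalp channels:   ", sum(x$roles == "scalp"), "\n")
  cat("  cEEGrid channels: ", sum(x$roles != "scalp"), "\n")
  cat("  bipolar pairs:    ", nrow(x$bipolar_pairs),
      paste0("(", paste(x$bipolar_pairs$label, collapse = ", "), ")"), "\n")
  invisible(x)
}

# channel labels for a named channel set, resolved against a montage
resolve_channel_set <- function(montage, set = c("cap", "ceegrid", "all")) {
  set <- match.arg(set)
  scalp <- montage$channels[montage$roles == "scalp"]
  ear <- montage$channels[montage$roles != "scalp"]
  switch(set,
    cap = scalp,
    ceegrid = c(ear, montage$bipolar_pairs$label),
    all = c(montage$channels, montage$bipolar_pairs$label)
  )
}
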