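#' fNIRS montage description
#'
#' A montage describes the optode layout of the fNIRS cap: one row per
#' measurement channel (`"Tx<i>-Rx<j>"`), with its hemisphere, Brodmann-area
#' label and source-detector separation, plus the catalogue of homologous
#' right/left channel pairs used for laterality analysis and the device
#' wavelengths.
#'
#' `read_montage()` loads a montage from a YAML file; `default_montage()`
#' loads the 2x12-channel prefrontal layout shipped with the package
#' (24 channels over Brodmann areas 9, 10 and 44-47, 3 cm separation,
#' wavelengths 760 and 850 nm).
#'
#' @param path path to a montage YAML file with keys `channels`, `pairs`
#'   and `wavelengths_nm`.
#' @return a list of class `"fnirs_montage"` with elements
#'   \describe{
#'     \item{channels}{tibble: `channel_id`, `hemisphere` (`"left"`/`"right"`),
#'       `brodmann_area` (integer), `distance_cm`.}
#'     \item{pairs}{tibble: `right_channel`, `left_channel` — oriented so the
#'       first member is the right-hemisphere channel.}
#'     \item{wavelengths_nm}{numeric length 2.}
#'   }
#' @examples
#' m <- default_montage()
#' nrow(m$channels)   # 24
#' m$pairs
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("montage file not found: %s", path),
          class = "stressphys_io_error")
  }
  raw <- yaml::read_yaml(path)
  channels <- purrr::map_dfr(raw$channels, function(ch) {
    tibble(
      channel_id = as.character(ch$channel_id),
      hemisphere = as.character(ch$hemisphere),
      brodmann_area = as.integer(ch$brodmann_area),
      distance_cm = as.numeric(ch$distance_cm)
    )
  })
  pairs <- purrr::map_dfr(raw$pairs, function(p) {
    tibble(a = as.character(p[[1]]), b = as.character(p[[2]]))
  })
  montage <- new_montage(channels, pairs,
                         wavelengths_nm = as.numeric(raw$wavelengths_nm))
  montage
}

new_montage <- function(channels, pairs, wavelengths_nm = c(760, 850)) {
  validate_montage_channels(channels)
  hemi <- setNames(channels$hemisphere, channels$channel_id)
  oriented <- purrr::pmap_dfr(pairs, function(a, b) {
    for (id in c(a, b)) {
      if (!id %in% names(hemi)) {
        abort(sprintf("laterality pair references unknown channel '%s'", id),
              class = "stressphys_config_error")
      }
    }
    if (hemi[[a]] == hemi[[b]]) {
      abort(sprintf("pair [%s, %s] does not span both hemispheres", a, b),
            class = "stressphys_config_error")
    }
    if (hemi[[a]] == "right") {
      tibble(right_channel = a, left_channel = b)
    } else {
      tibble(right_channel = b, left_channel = a)
    }
  })
  structure(
    list(channels = channels, pairs = oriented,
         wavelengths_nm = wavelengths_nm),
    class = "fnirs_montage"
  )
}

validate_montage_channels <- function(channels) {
  if (anyDuplicated(channels$channel_id)) {
    abort("montage channel ids must be unique",
          class = "stressphys_config_error")
  }
  if (!all(channels$hemisphere %in% c("left", "right"))) {
    abort("montage hemisphere labels must be 'left' or 'right'",
          class = "stressphys_config_error")
  }
  if (any(channels$distance_cm <= 0)) {
    abort("source-detector distance must be positive",
          class = "stressphys_config_error")
  }
  invisible(channels)
}

#' @rdname read_montage
#' @export
default_montage <- function() {
  read_montage(system.file("extdata", "montage.yaml", package = "stressphys",
                           mustWork = TRUE))
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat(sprintf("<fnirs_montage> %d channels (%d right / %d left), %d laterality pairs, wavelengths %s nm\n",
              nrow(x$channels),
              sum(x$channels$hemisphere == "right"),
              sum(x$channels$hemisphere == "left"),
              nrow(x$pairs),
              paste(x$wavelengths_nm, collapse = "/")))
  invisible(x)
}
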