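#' Dark-noise subtraction and mean normalization of channel pixels
#'
#' Each photographed channel is corrected by subtracting the constant
#' sensor dark noise and dividing by the mean of all unmasked corrected
#' pixels in the photograph, so that pixel values become quantum catches
#' adapted to the background intensity. The mean of the unmasked output
#' is exactly 1.
#'
#' @param pixels Numeric vector (or array) of raw pixel values of one
#'   channel-image.
#' @param dark Scalar dark-noise level.
#' @param mask Logical vector/array marking pixels to exclude
#'   (over/under-exposed); excluded pixels are returned as `NA`.
#' @return Normalized pixels, same shape as `pixels`.
#' @export
normalize_image <- function(pixels, dark = 0, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(pixels))
  stopifnot(length(mask) == length(pixels))
  corrected <- pixels - dark
  if (any(corrected[!mask] < 0))
    stop("pixels below the dark level found among unmasked pixels",
         call. = FALSE)
  m <- mean(corrected[!mask])
  if (!is.finite(m) || m <= 0)
    stop("zero mean after dark subtraction: cannot normalize", call. = FALSE)
  out <- corrected / m
  out[mask] <- NA_real_
  out
}

#' Load a pixel-selection dataset from JSON
#'
#' Reads the selection-dataset schema written by
#' [write_selection_dataset()] (one object with `channels`, `normalized`
#' and a `plants` array whose entries carry `plant_id`, `image_id`,
#' `habitat`, `sunlit` and per-channel `upper`/`lower` pixel arrays).
#' Field names used by other deposits can be mapped via `field_map`, the
#' single translation layer for external schemas. Every plant must have
#' both surfaces and every channel; violations are reported by plant.
#'
#' @param path JSON file path.
#' @param field_map Named character vector renaming top-level plant
#'   fields, e.g. `c(plant_id = "plantName")`.
#' @return An object of class `lc_selection_dataset`.
#' @export
load_selection_dataset <- function(path, field_map = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$plants) || is.null(raw$channels))
    stop("not a selection dataset: missing `plants` or `channels`",
         call. = FALSE)
  channels <- unlist(raw$channels)
  rename <- function(p) {
    if (is.null(field_map)) return(p)
    for (std in names(field_map)) {
      ext <- field_map[[std]]
      if (!is.null(p[[ext]]) && is.null(p[[std]])) p[[std]] <- p[[ext]]
    }
    p
  }
  plants <- lapply(raw$plants, function(p) {
    p <- rename(p)
    p$upper <- lapply(p$upper, function(v) as.numeric(unlist(v)))
    p$lower <- lapply(p$lower, function(v) as.numeric(unlist(v)))
    p$sunlit <- isTRUE(p$sunlit)
    p
  })
  ds <- structure(list(channels = channels, plants = plants,
                       normalized = isTRUE(raw$normalized)),
                  class = "lc_selection_dataset")
  validate_selection_dataset(ds)
  ds
}

#' @export
print.lc_selection_dataset <- function(x, ...) {
  habs <- table(vapply(x$plants, `[[`, character(1), "habitat"))
  cat(sprintf("<lc_selection_dataset> %d plants, channels: %s\n",
              length(x$plants), paste(x$channels, collapse = ", ")))
  for (h in names(habs)) cat(sprintf("  %s: %d plants\n", h, habs[[h]]))
  invisible(x)
}

validate_selection_dataset <- function(ds) {
  problems <- character(0)
  for (p in ds$plants) {
    id <- p$plant_id %||% "<unnamed plant>"
    for (surf in c("upper", "lower")) {
      if (is.null(p[[surf]])) {
        problems <- c(problems, sprintf("%s: missing %s surface", id, surf))
        next
      }
      missing_ch <- setdiff(ds$channels, names(p[[surf]]))
      if (length(missing_ch))
        problems <- c(problems, sprintf("%s: %s surface missing channel(s) %s",
                                        id, surf,
                                        paste(missing_ch, collapse = ", ")))
      empty <- vapply(ds$channels[ds$channels %in% names(p[[surf]])],
                      function(ch) length(p[[surf]][[ch]]) < 1, logical(1))
      if (any(empty))
        problems <- c(problems, sprintf("%s: empty %s selection", id, surf))
    }
  }
  if (length(problems))
    stop("selection dataset failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Write a pixel-selection dataset to JSON
#'
#' @param ds An `lc_selection_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "lc_selection_dataset"))
  out <- list(channels = ds$channels, normalized = ds$normalized,
              plants = ds$plants)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-plant contrast table
#'
#' For every plant: the median normalized pixel value of each channel on
#' each surface, the per-channel Michelson contrast between the surfaces,
#' and the receptor-noise-limited color distance (JND, log-transformed
#' quantum catches) for each requested visual system.
#'
#' @param ds An `lc_selection_dataset`.
#' @param systems Named list of visual systems; each element is a list
#'   with `channels` (channel tags) and `weber` (matching Weber
#'   fractions). See [channel_system()].
#' @return Data.frame with one row per plant: `plant_id`, `image_id`,
#'   `habitat`, `sunlit`, one `C_<channel>` column per channel and one
#'   `JND_<system>` column per system.
#' @export
plant_contrast_table <- function(ds, systems = list()) {
  stopifnot(inherits(ds, "lc_selection_dataset"))
  for (s in systems)
    if (!all(s$channels %in% ds$channels))
      stop("system requires channels absent from the dataset: ",
           paste(setdiff(s$channels, ds$channels), collapse = ", "),
           call. = FALSE)
  rows <- lapply(ds$plants, function(p) {
    med_u <- vapply(ds$channels, function(ch)
      stats::median(p$upper[[ch]], na.rm = TRUE), numeric(1))
    med_l <- vapply(ds$channels, function(ch)
      stats::median(p$lower[[ch]], na.rm = TRUE), numeric(1))
    row <- data.frame(plant_id = p$plant_id, image_id = p$image_id,
                      habitat = p$habitat, sunlit = p$sunlit,
                      stringsAsFactors = FALSE)
    for (ch in ds$channels)
      row[[paste0("C_", ch)]] <- michelson(med_u[[ch]], med_l[[ch]])
    for (nm in names(systems)) {
      s <- systems[[nm]]
      row[[paste0("JND_", nm)]] <-
        if (all(med_u[s$channels] == med_l[s$channels])) 0 else
          rnl_color_distance(med_u[s$channels], med_l[s$channels], s$weber)
    }
    row
  })
  do.call(rbind, rows)
}

#' Define a visual system over camera channels
#'
#' Helper for [plant_contrast_table()]: a combination of channels with
#' per-channel noise. With `equal_noise = TRUE` every channel gets the
#' same Weber fraction (0.069), the convention for comparing systems with
#' equal numbers of each receptor; otherwise noise follows the
#' 1/sqrt(abundance) calibration of [weber_fractions()] using the
#' terrestrial-bird cone ratio L:M:S:UV = 3:2.5:1.7:1.
#'
#' @param channels Character vector of channel tags, e.g.
#'   `c("L", "M", "S(U)", "U")`.
#' @param equal_noise All Weber fractions equal 0.069.
#' @param anchor_value Anchor Weber fraction (L cone, or every channel
#'   when `equal_noise`).
#' @return List with `channels` and `weber`.
#' @export
channel_system <- function(channels, equal_noise = TRUE,
                           anchor_value = 0.069) {
  stopifnot(length(channels) >= 2)
  if (equal_noise) {
    weber <- stats::setNames(rep(anchor_value, length(channels)), channels)
  } else {
    abundance <- c(L = 3, M = 2.5, "S(U)" = 1.7, "S(V)" = 1.7, U = 1, V = 1)
    if (!all(channels %in% names(abundance)))
      stop("no abundance known for channel(s): ",
           paste(setdiff(channels, names(abundance)), collapse = ", "),
           call. = FALSE)
    ratios <- abundance[channels]
    anchor <- if ("L" %in% channels) "L" else channels[which.max(ratios)]
    weber <- weber_fractions(ratios, anchor_class = anchor,
                             anchor_value = anchor_value)
  }
  list(channels = channels, weber = weber)
}

#' Habitat-level paired sign tests
#'
#' For each habitat and each hypothesis (a pair of per-plant columns of
#' the contrast table), counts how often the first member exceeds the
#' second across plants and computes the exact two-sided sign-test
#' probability.
#'
#' @param table Output of [plant_contrast_table()].
#' @param hypotheses List of character pairs; each is either two channel
#'   tags (Michelson columns) or two system names (JND columns), e.g.
#'   `list(c("U", "S(U)"), c("LMSU", "LMS"))`.
#' @return Data.frame: `habitat`, `hypothesis`, `n`, `statistic`, `p`.
#' @export
habitat_sign_tests <- function(table, hypotheses) {
  col_for <- function(tag) {
    for (cand in paste0(c("C_", "JND_"), tag))
      if (cand %in% names(table)) return(cand)
    stop("no contrast column for '", tag, "' in the table", call. = FALSE)
  }
  out <- list()
  for (hab in sort(unique(table$habitat))) {
    sub <- table[table$habitat == hab, ]
    for (h in hypotheses) {
      stopifnot(length(h) == 2)
      d <- sub[[col_for(h[1])]] - sub[[col_for(h[2])]]
      st <- sign_test(d)
      out[[length(out) + 1L]] <- data.frame(
        habitat = hab, hypothesis = paste0(h[1], " - ", h[2]),
        n = st$n, statistic = st$statistic, p = st$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# linear -> sRGB electro-optical encoding (undoes display gamma)
srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Render three channels as an 8-bit false-color image
#'
#' Display pipeline for normalized channel images: (1) mean-normalize
#' each channel, (2) stretch linearly so the darkest unmasked pixel maps
#' to 0 and the brightest to 1 (one common stretch across the three
#' channels, preserving relative intensities), (3) apply the sRGB
#' transfer curve so that a calibrated display shows intensity linear in
#' quantum catch. Pixels masked as overexposed come out white, as
#' underexposed black.
#'
#' @param r,g,b Numeric matrices of equal dimensions (channel images).
#' @param mask_over,mask_under Logical matrices marking masked pixels.
#' @return Integer array `dim(h, w, 3)` with values in \[0, 255\].
#' @export
render_false_color <- function(r, g, b, mask_over = NULL, mask_under = NULL) {
  if (!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)))
    stop("the three channel images must have identical dimensions",
         call. = FALSE)
  if (is.null(mask_over)) mask_over <- array(FALSE, dim(r))
  if (is.null(mask_under)) mask_under <- array(FALSE, dim(r))
  masked <- mask_over | mask_under
  planes <- lapply(list(r, g, b), function(ch) ch / mean(ch[!masked]))
  all_v <- unlist(lapply(planes, function(ch) ch[!masked]))
  lo <- min(all_v); hi <- max(all_v)
  stretch <- function(v) if (hi > lo) (v - lo) / (hi - lo) else
    array(0.5, dim(v))
  out <- array(0L, c(dim(r), 3L))
  for (k in 1:3) {
    v <- srgb_encode(pmin(pmax(stretch(planes[[k]]), 0), 1))
    v[mask_over] <- 1
    v[mask_under] <- 0
    out[, , k] <- as.integer(round(v * 255))
  }
  out
}
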