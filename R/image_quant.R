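# Pixel classification for three-channel fluorescence images, plus a
# synthetic image generator so the rule is testable without microscopy data.

#' Three-channel fluorescence image
#'
#' @param red,yellow_green,cyan single-channel intensity matrices of
#'   identical shape (DsRed / YFP / CFP roles; non-negative).
#' @param background per-channel background levels, named or in (red,
#'   yellow_green, cyan) order; if `NULL`, estimated per channel as the
#'   mode (median) of the lowest-decile pixels.
#' @return a `channel_image` object.
#' @export
channel_image <- function(red, yellow_green, cyan, background = NULL) {
  ch <- list(R = red, G = yellow_green, C = cyan)
  d <- dim(red)
  for (m in ch) {
    if (!identical(dim(m), d)) abort("channel shapes differ")
    if (any(m < 0)) abort("intensities must be >= 0")
  }
  if (is.null(background)) {
    background <- vapply(ch, function(m) {
      cut <- quantile(m, 0.1)
      stats::median(m[m <= cut])
    }, numeric(1))
  }
  background <- setNames(as.numeric(background), c("R", "G", "C"))
  structure(list(channels = ch, background = background),
            class = "channel_image")
}

#' Classify pixels into strain labels
#'
#' The two-step rule: pixels whose raw intensity is less than 30% above the
#' per-channel background in all three channels are "no signal". All other
#' pixels are assigned the identity of the channel with the highest
#' intensity after each channel is normalized to its image-wide 90th
#' percentile. Argmax ties break by fixed channel priority R, G, C.
#'
#' @param image a [channel_image()].
#' @param threshold_factor above-background factor for the no-signal test
#'   (default 1.3, the 30% rule).
#' @return a character matrix with entries `"R"`, `"G"`, `"C"`, or `""`
#'   (no signal).
#' @export
classify_pixels <- function(image, threshold_factor = 1.3) {
  stopifnot(inherits(image, "channel_image"))
  ch <- image$channels
  bg <- image$background
  above <- Reduce(`|`, Map(function(m, b) m >= threshold_factor * b, ch, bg))
  p90 <- vapply(ch, function(m) unname(quantile(m, 0.9)), numeric(1))
  if (any(p90 <= 0 & vapply(seq_along(ch), function(i) any(above & ch[[i]] > 0), logical(1))))
    abort("degenerate-normalization: a channel's 90th percentile is zero")
  norm <- Map(function(m, q) if (q > 0) m / q else m * 0, ch, p90)
  d <- dim(ch[[1]])
  # argmax with fixed R > G > C priority on exact ties
  best <- norm$R
  lab <- array("R", d)
  lab[norm$G > best] <- "G"
  best <- pmax(best, norm$G)
  lab[norm$C > best] <- "C"
  lab[!above] <- ""
  lab
}

#' Generate a synthetic fluorescence image from a label raster
#'
#' Emits three channels in which pixels of each label fluoresce in their own
#' channel at a set mean intensity on top of a common background, with
#' optional Gaussian noise and channel bleed-through. With zero noise and no
#' bleed-through, [classify_pixels()] recovers the labels exactly.
#'
#' @param labels character matrix of `"R"`, `"G"`, `"C"`, `""`.
#' @param intensity per-label signal intensity above background (named
#'   vector, default 200 for each).
#' @param background per-channel background level (default 100).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param bleed_through fraction of a pixel's signal leaking into the other
#'   two channels.
#' @return a [channel_image()] with the generating backgrounds attached.
#' @export
synth_fluor_image <- function(labels,
                              intensity = c(R = 200, G = 200, C = 200),
                              background = 100, noise_sd = 0,
                              bleed_through = 0) {
  stopifnot(is.character(labels), !is.null(dim(labels)))
  d <- dim(labels)
  mk <- function(own) {
    sig <- array(0, d)
    for (l in c("R", "G", "C")) {
      amp <- if (l == own) intensity[[l]] else bleed_through * intensity[[l]]
      sig[labels == l] <- sig[labels == l] + amp
    }
    m <- background + sig
    if (noise_sd > 0) m <- m + array(stats::rnorm(prod(d), 0, noise_sd), d)
    pmax(m, 0)
  }
  channel_image(mk("R"), mk("G"), mk("C"),
                background = rep(background, 3))
}

#' Write or read a label raster as PNG
#'
#' Labels are encoded as colors: R red, G green, C blue, no-signal black.
#' Requires the `png` package.
#'
#' @param labels character matrix from [classify_pixels()].
#' @param path output file.
#' @return `write_label_png()` returns `path` invisibly; `read_label_png()`
#'   the decoded character matrix.
#' @export
write_label_png <- function(labels, path) {
  if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required")
  d <- dim(labels)
  img <- array(0, c(d[1], d[2], 3))
  img[, , 1][labels == "R"] <- 1
  img[, , 2][labels == "G"] <- 1
  img[, , 3][labels == "C"] <- 1
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required")
  img <- png::readPNG(path)
  lab <- array("", dim(img)[1:2])
  lab[img[, , 1] > 0.5] <- "R"
  lab[img[, , 2] > 0.5] <- "G"
  lab[img[, , 3] > 0.5] <- "C"
  lab
}
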