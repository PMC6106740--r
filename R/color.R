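#' Colour specifications
#'
#' A colour spec is the unit of theme styling: an RGB foreground, a derived
#' ANSI-256 index, a bold flag, and an optional RGB background. The ANSI
#' index is always recomputed from the RGB channels so the two can never
#' disagree.
#'
#' @param r,g,b Integer channels in 0--255.
#' @param bold Logical; render with SGR bold.
#' @param bg `NULL`, or a length-3 integer vector giving a background RGB.
#' @return An object of class `shade_color`: a list with elements `r`, `g`,
#'   `b`, `ansi256`, `bold`, `bg`, `bg_ansi256`.
#' @examples
#' color_spec(255, 0, 0)
#' color_spec(0, 0, 0, bold = TRUE, bg = c(255, 255, 0))
#' @export
color_spec <- function(r, g, b, bold = FALSE, bg = NULL) {
  chk_channel(r); chk_channel(g); chk_channel(b)
  if (!is.null(bg)) {
    stopifnot(length(bg) == 3)
    for (v in bg) chk_channel(v)
    bg <- as.integer(bg)
  }
  structure(
    list(
      r = as.integer(r), g = as.integer(g), b = as.integer(b),
      ansi256 = ansi256_of_rgb(r, g, b),
      bold = isTRUE(bold),
      bg = bg,
      bg_ansi256 = if (is.null(bg)) NULL else ansi256_of_rgb(bg[1], bg[2], bg[3])
    ),
    class = "shade_color"
  )
}

chk_channel <- function(v) {
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 255) {
    stop("colour channel must be a single number in [0, 255]", call. = FALSE)
  }
}

#' @export
print.shade_color <- function(x, ...) {
  cat(sprintf(
    "<shade_color %s ansi256=%d%s%s>\n",
    rgb_to_hex(x$r, x$g, x$b), x$ansi256,
    if (x$bold) " bold" else "",
    if (is.null(x$bg)) "" else paste0(" bg=", rgb_to_hex(x$bg[1], x$bg[2], x$bg[3]))
  ))
  invisible(x)
}

#' @export
format.shade_color <- function(x, ...) rgb_to_hex(x$r, x$g, x$b)

#' Convert between hex notation and RGB channels
#'
#' @param hex A string `"#RRGGBB"`.
#' @return `hex_to_rgb()` returns an integer vector `c(r, g, b)`;
#'   `rgb_to_hex()` returns a `"#RRGGBB"` string.
#' @examples
#' hex_to_rgb("#20B2AA")
#' rgb_to_hex(32, 178, 170)
#' @export
hex_to_rgb <- function(hex) {
  if (!is.character(hex) || length(hex) != 1 ||
      !grepl("^#[0-9A-Fa-f]{6}$", hex)) {
    stop("expected colour in \"#RRGGBB\" notation, got: ", hex, call. = FALSE)
  }
  as.integer(strtoi(substring(hex, c(2, 4, 6), c(3, 5, 7)), base = 16L))
}

#' @rdname hex_to_rgb
#' @param r,g,b Integer channels in 0--255.
#' @export
rgb_to_hex <- function(r, g, b) sprintf("#%02X%02X%02X", r, g, b)

# The 240 non-system xterm-256 colours: the 6x6x6 cube (indices 16-231, channel
# levels 0,95,135,175,215,255) and the grayscale ramp (232-255, 8+10k).
# System colours 0-15 vary with the terminal theme and are never emitted.
ansi_cube_levels <- c(0L, 95L, 135L, 175L, 215L, 255L)

ansi256_palette <- local({
  cube <- expand.grid(b = ansi_cube_levels, g = ansi_cube_levels,
                      r = ansi_cube_levels)[, c("r", "g", "b")]
  gray <- 8L + 10L * (0:23)
  m <- rbind(as.matrix(cube), cbind(r = gray, g = gray, b = gray))
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m  # row i corresponds to ANSI index 15 + i
})

#' Nearest ANSI-256 palette index for an RGB colour
#'
#' Maps an RGB triple to the nearest entry (Euclidean distance in RGB space)
#' of the standard xterm 256-colour palette, considering only indices
#' 16--255: the 6x6x6 colour cube and the 24-step grayscale ramp. The 16
#' system colours are excluded because their appearance depends on the
#' terminal theme. Ties are broken by the lowest index, so the mapping is
#' deterministic and idempotent.
#'
#' @param r,g,b Integer channels in 0--255.
#' @return An integer index in 16--255.
#' @examples
#' ansi256_of_rgb(0, 0, 0)       # 16, cube black
#' ansi256_of_rgb(255, 255, 255) # 231, cube white
#' @export
ansi256_of_rgb <- function(r, g, b) {
  chk_channel(r); chk_channel(g); chk_channel(b)
  d <- (ansi256_palette[, 1] - r)^2 + (ansi256_palette[, 2] - g)^2 +
    (ansi256_palette[, 3] - b)^2
  15L + which.min(d)  # which.min takes the first (lowest-index) minimum
}
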