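#' Load a highlighting theme
#'
#' A theme is a total mapping from biological style classes to colour
#' specs for one rendering mode. Two themes ship with the package:
#' `"default"` (the additive IUPAC palette) and `"high-contrast"` (a
#' lightness-separated palette that stays legible under simulated
#' colour-blindness and in monochrome). Themes are YAML data, not code, so
#' they can be copied and edited; a custom theme is loaded by path.
#'
#' @param name `"default"`, `"high-contrast"`, or a path to a theme YAML
#'   file with fields `name`, `mode` and `classes`.
#' @return An object of class `shade_theme`.
#' @examples
#' th <- shade_theme("default")
#' th$classes[["coordinate"]]
#' @export
shade_theme <- function(name = "default") {
  stopifnot(is.character(name), length(name) == 1)
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("themes", paste0(name, ".yaml"), package = "bioshade")
    if (!nzchar(p)) {
      stop("unknown theme: ", name,
           " (shipped themes: default, high-contrast)", call. = FALSE)
    }
    p
  }
  raw <- yaml::read_yaml(path)
  wanted <- style_classes()
  missing <- setdiff(wanted, names(raw$classes))
  if (length(missing) > 0) {
    stop("theme '", raw$name, "' is not total; missing classes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  classes <- lapply(raw$classes[wanted], function(e) {
    if (is.null(e) || is.null(e$fg)) return(NULL)
    fg <- hex_to_rgb(e$fg)
    bg <- if (!is.null(e$bg)) hex_to_rgb(e$bg) else NULL
    color_spec(fg[1], fg[2], fg[3], bold = isTRUE(e$bold), bg = bg)
  })
  th <- structure(
    list(name = raw$name, mode = raw$mode, classes = classes),
    class = "shade_theme"
  )
  th$escapes <- build_escape_table(th)
  th
}

# Precomputed SGR parameter strings per class ("" = unstyled). Every escape
# begins with a reset parameter (0) so adjacent tokens never inherit bold or
# background state from each other.
build_escape_table <- function(theme) {
  vapply(style_classes(), function(cls) {
    col <- theme$classes[[cls]]
    if (is.null(col)) return("")
    code <- paste0("0", if (col$bold) ";1", ";38;5;", col$ansi256)
    if (!is.null(col$bg)) code <- paste0(code, ";48;5;", col$bg_ansi256)
    paste0("\033[", code, "m")
  }, character(1))
}

#' @export
print.shade_theme <- function(x, ...) {
  styled <- sum(!vapply(x$classes, is.null, logical(1)))
  cat(sprintf("<shade_theme '%s' mode=%s: %d classes, %d styled>\n",
              x$name, x$mode, length(x$classes), styled))
  invisible(x)
}

#' Tabulate a theme's class-to-colour mapping
#'
#' @param theme A [shade_theme()].
#' @return A tibble with one row per style class: `class`, `fg` (hex or NA),
#'   `bg` (hex or NA), `bold`, `ansi256`, `luminance`.
#' @examples
#' theme_classes(shade_theme("default"))
#' @export
theme_classes <- function(theme) {
  stopifnot(inherits(theme, "shade_theme"))
  rows <- lapply(names(theme$classes), function(cls) {
    col <- theme$classes[[cls]]
    if (is.null(col)) {
      tibble::tibble(class = cls, fg = NA_character_, bg = NA_character_,
                     bold = FALSE, ansi256 = NA_integer_,
                     luminance = NA_real_)
    } else {
      tibble::tibble(
        class = cls,
        fg = rgb_to_hex(col$r, col$g, col$b),
        bg = if (is.null(col$bg)) NA_character_ else
          rgb_to_hex(col$bg[1], col$bg[2], col$bg[3]),
        bold = col$bold,
        ansi256 = col$ansi256,
        luminance = relative_luminance(col)
      )
    }
  })
  do.call(rbind, rows)
}

#' Plot a theme's nucleotide and quality palettes
#'
#' Draws the 16 IUPAC nucleotide tiles (ordered by ambiguity) and the
#' quality-gradient ramp for a theme, as a quick visual check that the
#' palette behaves as intended (N white, G/C warm, A/T cool, gradient
#' monotone).
#'
#' @param object A [shade_theme()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(shade_theme("default"))
#' @exportS3Method ggplot2::autoplot
autoplot.shade_theme <- function(object, ...) {
  tc <- theme_classes(object)
  nt <- tc[grepl("^nucleotide\\.", tc$class), ]
  nt$label <- sub("nucleotide.", "", nt$class, fixed = TRUE)
  nt$n_bases <- vapply(nt$label, function(ch) length(iupac_bases(ch)),
                       integer(1))
  nt <- nt[order(nt$n_bases, nt$label), ]
  nt$x <- seq_len(nrow(nt))
  nt$row <- "IUPAC nucleotides"
  qu <- tc[grepl("^quality\\.", tc$class), ]
  qu$label <- sub("quality.", "Q", qu$class, fixed = TRUE)
  qu$x <- seq_len(nrow(qu))
  qu$row <- "quality gradient"
  d <- rbind(nt[c("x", "row", "label", "fg")], qu[c("x", "row", "label", "fg")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = 1)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fg), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_identity() +
    ggplot2::facet_wrap(~row, ncol = 1, scales = "free_x") +
    ggplot2::theme_void() +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 10)) +
    ggplot2::labs(title = paste0("bioshade theme: ", object$name))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
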