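#' Rendering specification for map frames
#'
#' Display parameters shared by every frame so maps are visually comparable:
#' one diverging dark-blue-to-dark-red color scale centred at OR = 1 on the
#' log scale, one shared OR range, black contour outlines around flagged
#' cells, a window/p-value annotation, and the per-frame play duration.
#'
#' @param or_range length-2 shared OR display range (must straddle 1);
#'   typically `run_pipeline()$or_range`.
#' @param frame_duration_s seconds per frame in the assembled animation.
#' @param width,height frame pixel dimensions.
#' @param palette_n number of color steps.
#' @param annotate draw the window label and global p-value.
#' @export
render_spec <- function(or_range = c(0.5, 2), frame_duration_s = 0.5,
                        width = 480, height = 420, palette_n = 101,
                        annotate = TRUE) {
  stopifnot(length(or_range) == 2, or_range[1] < 1, or_range[2] > 1,
            frame_duration_s > 0)
  structure(list(or_range = or_range, frame_duration_s = frame_duration_s,
                 width = width, height = height, palette_n = palette_n,
                 annotate = annotate),
            class = "ed_render_spec")
}

#' Diverging odds-ratio palette
#'
#' Dark blue (decreased odds) through white (OR = 1) to dark red (increased
#' odds).
#'
#' @param n number of colors (odd keeps white exactly at the centre).
#' @export
or_palette <- function(n = 101) {
  grDevices::colorRampPalette(c("#08306B", "#2166AC", "#92C5DE", "#F7F7F7",
                                "#F4A582", "#B2182B", "#67001F"))(n)
}

# per-point OR values as an nx x ny matrix in grid order
ormap_matrix <- function(ormap, what = "or") {
  matrix(ormap[[what]], nrow = ormap$grid$nx, ncol = ormap$grid$ny)
}

#' Connected components of flagged grid cells
#'
#' Labels 4-neighbour connected components of `hot` (or `cold`) flags; one
#' component corresponds to one closed contour outline on the rendered map.
#'
#' @param ormap an `ed_ormap`.
#' @param which `"hot"` or `"cold"`.
#' @return list with `n` (component count) and `labels` (nx x ny integer
#'   matrix, 0 = unflagged).
#' @export
flag_components <- function(ormap, which = c("hot", "cold")) {
  which <- match.arg(which)
  fl <- ormap_matrix(ormap, "flag") == which
  fl[is.na(fl)] <- FALSE
  lab <- matrix(0L, nrow(fl), ncol(fl))
  comp <- 0L
  for (i in seq_len(nrow(fl))) for (j in seq_len(ncol(fl))) {
    if (!fl[i, j] || lab[i, j] != 0L) next
    comp <- comp + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      a <- p[1]; b <- p[2]
      if (a < 1 || b < 1 || a > nrow(fl) || b > ncol(fl)) next
      if (!fl[a, b] || lab[a, b] != 0L) next
      lab[a, b] <- comp
      stack <- c(stack, list(c(a - 1L, b), c(a + 1L, b),
                             c(a, b - 1L), c(a, b + 1L)))
    }
  }
  list(n = comp, labels = lab)
}

#' Render one OR map frame to a PNG file
#'
#' Raster of the odds-ratio surface on the shared diverging scale (values
#' clipped to the shared range; masked cells transparent), black contour
#' outlines around contiguous hot/cold flagged cells, and an annotation with
#' the window label and global p-value. Output is written atomically.
#'
#' @param ormap an `ed_ormap` from [analyze_window()].
#' @param spec a [render_spec()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_frame <- function(ormap, spec = render_spec(), path) {
  stopifnot(inherits(ormap, "ed_ormap"), inherits(spec, "ed_render_spec"))
  atomic_write(path, function(tmp) {
    grDevices::png(tmp, width = spec$width, height = spec$height,
                   bg = "transparent")
    on.exit(grDevices::dev.off())
    op <- graphics::par(mar = c(2.5, 2.5, 2.2, 0.6), mgp = c(1.5, 0.4, 0))
    on.exit(graphics::par(op), add = TRUE, after = FALSE)
    lz <- log(ormap_matrix(ormap, "or"))
    lim <- log(spec$or_range)
    lz <- pmin(pmax(lz, lim[1]), lim[2])
    breaks <- seq(lim[1], lim[2], length.out = spec$palette_n + 1)
    graphics::image(ormap$grid$xs, ormap$grid$ys, lz,
                    col = or_palette(spec$palette_n), breaks = breaks,
                    xlab = "x", ylab = "y", useRaster = FALSE)
    for (w in c("hot", "cold")) {
      fl <- ormap_matrix(ormap, "flag") == w
      fl[is.na(fl)] <- FALSE
      if (any(fl))
        graphics::contour(ormap$grid$xs, ormap$grid$ys, fl + 0,
                          levels = 0.5, drawlabels = FALSE, add = TRUE,
                          col = "black", lwd = 2)
    }
    if (spec$annotate) {
      lab <- if (ormap$status == "ok")
        sprintf("window %s  day %s  global p = %.4g",
                ormap$window_id, ormap$median_day, ormap$global_p)
      else sprintf("window %s  day %s  (%s)", ormap$window_id,
                   ormap$median_day, ormap$status)
      graphics::title(main = lab, cex.main = 0.95)
    }
  })
  invisible(path)
}

#' Render every window of a map series
#'
#' Writes one PNG per window, named `frame_0001.png`, ..., using the series'
#' shared OR range, and returns the file paths in window order.
#'
#' @param stmap an `ed_stmap` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param spec optional [render_spec()]; default uses the series OR range and
#'   the configured frame duration.
#' @export
render_series <- function(stmap, dir, spec = NULL) {
  stopifnot(inherits(stmap, "ed_stmap"))
  if (is.null(spec))
    spec <- render_spec(or_range = stmap$or_range,
                        frame_duration_s = stmap$config$frame_duration_s)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(stmap$maps), function(i) {
    p <- file.path(dir, sprintf("frame_%04d.png", i))
    render_frame(stmap$maps[[i]], spec, p)
    p
  }, character(1))
}
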