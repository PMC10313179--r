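#' Event-map rendering spec
#'
#' An event map overlays one colour-coded dot per fly per frame over a
#' video segment (default 2,700 frames = 90 s at 30 fps), exposing the
#' trajectories and behavior states of the group. Default colours: gray
#' for resting/walking, blue for following (chase), salmon for singing
#' (wing extension), purple for mounting.
#'
#' @param segment_frames Segment length in frames. Default 2700.
#' @param dot_radius_px Dot radius in px (plot size hint). Default 2.
#' @param colors Named character vector mapping states
#'   (`rest_walk`, `chase`, `wing_ext`, `mount`) to colours.
#' @return A list of class `event_map_spec`.
#' @export
event_map_spec <- function(segment_frames = 2700, dot_radius_px = 2,
                           colors = c(rest_walk = "gray60", chase = "blue",
                                      wing_ext = "salmon", mount = "purple")) {
  stopifnot(segment_frames > 0, dot_radius_px > 0)
  needed <- c("rest_walk", "chase", "wing_ext", "mount")
  if (!all(needed %in% names(colors))) {
    stop("colors must name all of: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structure(list(segment_frames = as.integer(segment_frames),
                 dot_radius_px = dot_radius_px, colors = colors),
            class = "event_map_spec")
}

#' Render an event map
#'
#' One dot per fly per frame of the segment, coloured by the fly's
#' behavior state in that frame: a fly acting in an event takes the event
#' colour (mount over wing_ext over chase when several apply); all other
#' dots are gray (resting/walking). The dot table is the authoritative
#' output; the ggplot is derived from it.
#'
#' @param tracks A tracks tibble.
#' @param events An events tibble.
#' @param config An [arena_config()].
#' @param spec An [event_map_spec()].
#' @param segment_start First frame of the segment (default: first track
#'   frame).
#' @return A list with `table` (tibble `frame, fly_id, x, y, state`) and
#'   `plot` (a ggplot).
#' @export
render_event_map <- function(tracks, events, config,
                             spec = event_map_spec(),
                             segment_start = NULL) {
  if (nrow(tracks) == 0) {
    tab <- tibble(frame = integer(), fly_id = integer(),
                  x = double(), y = double(), state = character())
    return(list(table = tab, plot = event_map_plot(tab, config, spec)))
  }
  if (is.null(segment_start)) segment_start <- min(tracks$frame)
  seg <- tracks[tracks$frame >= segment_start &
                tracks$frame < segment_start + spec$segment_frames, ,
                drop = FALSE]
  state <- rep("rest_walk", nrow(seg))
  for (type in c("chase", "wing_ext", "mount")) {  # later types win
    ev <- events[events$type == type, , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      sel <- seg$track_id == ev$actor_id[i] &
        seg$frame >= ev$start_frame[i] & seg$frame < ev$end_frame[i]
      state[sel] <- type
    }
  }
  tab <- tibble(frame = seg$frame, fly_id = seg$track_id,
                x = seg$cx, y = seg$cy, state = state)
  list(table = tab, plot = event_map_plot(tab, config, spec))
}

event_map_plot <- function(tab, config, spec) {
  cc <- config$chamber
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$state)) +
    ggplot2::geom_point(size = spec$dot_radius_px / 2, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = unclass(spec$colors),
                                 drop = FALSE) +
    ggplot2::scale_y_reverse(limits = unname(c(cc["cy"] + cc["r"],
                                               cc["cy"] - cc["r"]))) +
    ggplot2::scale_x_continuous(limits = unname(c(cc["cx"] - cc["r"],
                                                  cc["cx"] + cc["r"]))) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "state")
}

#' Occupancy heatmap
#'
#' Bins fly-frame centroids over the chamber bounding square. Every
#' observed fly-frame lands in exactly one cell, so the matrix total
#' equals the observed fly-frame count.
#'
#' @param tracks A tracks tibble.
#' @param grid_shape `c(nx, ny)` cell counts. Default `c(32, 32)`.
#' @param config An [arena_config()].
#' @return A list with `matrix` (ny rows x nx columns, row 1 = top of the
#'   image) and `plot` (a ggplot raster).
#' @export
occupancy_heatmap <- function(tracks, grid_shape = c(32, 32), config) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  nx <- grid_shape[1]
  ny <- grid_shape[2]
  cc <- config$chamber
  x0 <- unname(cc["cx"] - cc["r"])
  y0 <- unname(cc["cy"] - cc["r"])
  side <- 2 * unname(cc["r"])
  m <- matrix(0L, nrow = ny, ncol = nx)
  if (nrow(tracks) > 0) {
    ix <- pmin(pmax(floor((tracks$cx - x0) / side * nx) + 1, 1), nx)
    iy <- pmin(pmax(floor((tracks$cy - y0) / side * ny) + 1, 1), ny)
    tab <- table(factor(iy, levels = seq_len(ny)),
                 factor(ix, levels = seq_len(nx)))
    m <- matrix(as.integer(tab), nrow = ny, ncol = nx)
  }
  df <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  df$count <- as.vector(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "fly-frames")
  list(matrix = m, plot = p)
}

#' Export the per-frame chaining series for rug plots
#'
#' @param chains A chain-record tibble ([detect_chaining()]).
#' @return A tibble with one row per frame: `frame`, `chain_count` —
#'   lossless with respect to the chains.csv dialect.
#' @export
export_chain_series <- function(chains) {
  tibble(frame = chains$frame, chain_count = chains$chain_count)
}

#' Rug plot of per-frame chaining events
#'
#' Each frame with chaining draws a vertical line coloured by the number
#' of chain events detected in that frame.
#'
#' @param chains A chain-record tibble.
#' @param fps Frames per second used to label the time axis. Default 30.
#' @return A ggplot.
#' @export
plot_chain_rug <- function(chains, fps = 30) {
  series <- export_chain_series(chains)
  active <- series[series$chain_count > 0, , drop = FALSE]
  ggplot2::ggplot(active,
                  ggplot2::aes(x = .data$frame / fps,
                               colour = factor(.data$chain_count))) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$frame / fps,
                                     colour = factor(.data$chain_count)),
                        linewidth = 0.3) +
    ggplot2::scale_x_continuous(limits = range(series$frame) / fps) +
    ggplot2::labs(x = "time (s)", colour = "chain events") +
    ggplot2::theme_minimal()
}

#' Plot a behavior index series
#'
#' @param object A [behavior_index()] object.
#' @param ... Unused.
#' @return A ggplot of the per-frame index with the mean as a horizontal
#'   line.
#' @method autoplot behavior_index
#' @export
autoplot.behavior_index <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$frame,
                                              y = .data$index)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$index, linetype = 2) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "frame", y = "index (%)",
                  title = sprintf("%s index: %.1f%%", object$behavior,
                                  object$index)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
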