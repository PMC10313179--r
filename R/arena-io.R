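#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

DETECTION_LABELS <- c("body", "head", "chase", "wing_ext", "mount")

# Full-precision numeric formatting so write -> read is the identity on
# doubles; deterministic, so identical objects give byte-identical files.
fmt_g <- function(x) sprintf("%.17g", x)

#' Read per-frame object detections
#'
#' Reads a detection stream CSV with header `frame,label,conf,x,y,w,h`:
#' `frame` is the 0-based frame index, `label` one of
#' `body, head, chase, wing_ext, mount`, `conf` a confidence in \[0, 1\],
#' and `x, y, w, h` the box left edge, top edge, width and height in pixels
#' (image coordinates, origin top-left, y downward).
#'
#' @param path Path to a detections CSV file.
#' @return A tibble with columns `frame` (int), `label` (chr), `conf`, `x`,
#'   `y`, `w`, `h` (dbl) plus derived centroid columns `cx = x + w/2`,
#'   `cy = y + h/2`, sorted by `(frame, label, x, y)`.
#' @seealso [write_detections()]
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  needed <- c("frame", "label", "conf", "x", "y", "w", "h")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("detections file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(empty_detections())
  }
  num_cols <- c("frame", "conf", "x", "y", "w", "h")
  parsed <- lapply(num_cols, function(cl) suppressWarnings(as.numeric(raw[[cl]])))
  names(parsed) <- num_cols
  for (cl in num_cols) {
    bad <- which(is.na(parsed[[cl]]))
    if (length(bad) > 0) {
      # +1 for the header row
      stop(sprintf("non-numeric value in column '%s' at line %d: '%s'",
                   cl, bad[1] + 1L, raw[[cl]][bad[1]]), call. = FALSE)
    }
  }
  bad_label <- which(!(raw$label %in% DETECTION_LABELS))
  if (length(bad_label) > 0) {
    stop(sprintf("unknown label at line %d: '%s'",
                 bad_label[1] + 1L, raw$label[bad_label[1]]), call. = FALSE)
  }
  bad_conf <- which(parsed$conf < 0 | parsed$conf > 1)
  if (length(bad_conf) > 0) {
    stop(sprintf("conf outside [0, 1] at line %d: %s",
                 bad_conf[1] + 1L, raw$conf[bad_conf[1]]), call. = FALSE)
  }
  bad_geom <- which(parsed$w <= 0 | parsed$h <= 0 | parsed$frame < 0)
  if (length(bad_geom) > 0) {
    stop(sprintf("invalid geometry at line %d (need frame >= 0, w > 0, h > 0)",
                 bad_geom[1] + 1L), call. = FALSE)
  }
  out <- tibble(
    frame = as.integer(parsed$frame),
    label = raw$label,
    conf = parsed$conf,
    x = parsed$x, y = parsed$y, w = parsed$w, h = parsed$h
  )
  out <- dplyr::mutate(out, cx = .data$x + .data$w / 2, cy = .data$y + .data$h / 2)
  dplyr::arrange(out, .data$frame, .data$label, .data$x, .data$y)
}

empty_detections <- function() {
  tibble(frame = integer(), label = character(), conf = double(),
         x = double(), y = double(), w = double(), h = double(),
         cx = double(), cy = double())
}

#' Write per-frame object detections
#'
#' @param detections A detections tibble (see [read_detections()]); the
#'   derived `cx`/`cy` columns, if present, are not written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  d <- dplyr::arrange(detections, .data$frame, .data$label, .data$x, .data$y)
  header <- "frame,label,conf,x,y,w,h"
  if (nrow(d) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- paste(d$frame, d$label, fmt_g(d$conf),
                fmt_g(d$x), fmt_g(d$y), fmt_g(d$w), fmt_g(d$h), sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read identity-stable tracks
#'
#' Reads a track CSV (MOT-style dialect) with header
#' `frame,id,x,y,w,h,conf,observed,heading`. `observed` is 1 when the point
#' was matched to a detection in that frame and 0 when the track was
#' coasting at its last observed position; `heading` is in radians in
#' (-pi, pi\] measured in a y-up mathematical frame, empty when no head was
#' assigned.
#'
#' @param path Path to a tracks CSV file.
#' @return A tibble with columns `frame` (int), `track_id` (int), `x`, `y`,
#'   `w`, `h`, `conf` (dbl), `observed` (lgl), `heading` (dbl, `NA` when
#'   absent) plus centroids `cx`, `cy`; sorted by `(frame, track_id)`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  needed <- c("frame", "id", "x", "y", "w", "h", "conf", "observed", "heading")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("tracks file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_tracks())
  num <- function(cl) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & raw[[cl]] != "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s' at line %d: '%s'",
                   cl, bad[1] + 1L, raw[[cl]][bad[1]]), call. = FALSE)
    }
    v
  }
  out <- tibble(
    frame = as.integer(num("frame")),
    track_id = as.integer(num("id")),
    x = num("x"), y = num("y"), w = num("w"), h = num("h"),
    conf = num("conf"),
    observed = num("observed") != 0,
    heading = num("heading")
  )
  dup <- duplicated(out[, c("frame", "track_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (frame, id) pair at line %d: (%d, %d)",
                 i + 1L, out$frame[i], out$track_id[i]), call. = FALSE)
  }
  out <- dplyr::mutate(out, cx = .data$x + .data$w / 2, cy = .data$y + .data$h / 2)
  dplyr::arrange(out, .data$frame, .data$track_id)
}

empty_tracks <- function() {
  tibble(frame = integer(), track_id = integer(),
         x = double(), y = double(), w = double(), h = double(),
         conf = double(), observed = logical(), heading = double(),
         cx = double(), cy = double())
}

#' Write identity-stable tracks
#'
#' Headings are serialised to 6 decimal places; absent headings are written
#' as empty fields. Output is sorted by `(frame, id)` and byte-stable.
#'
#' @param tracks A tracks tibble (see [read_tracks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  header <- "frame,id,x,y,w,h,conf,observed,heading"
  if (nrow(tracks) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  t <- dplyr::arrange(tracks, .data$frame, .data$track_id)
  hd <- ifelse(is.na(t$heading), "", sprintf("%.6f", t$heading))
  rows <- paste(t$frame, t$track_id,
                fmt_g(t$x), fmt_g(t$y), fmt_g(t$w), fmt_g(t$h),
                fmt_g(t$conf), as.integer(t$observed), hd, sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read and write behavior events (events.json)
#'
#' Events are typed half-open frame intervals `[start_frame, end_frame)`
#' with an actor and an optional target, serialised as a JSON array of
#' `{type, start_frame, end_frame, actor_id, target_id, source}` objects
#' (`target_id` is `null` when absent).
#'
#' @param events An events tibble with columns `type`, `start_frame`,
#'   `end_frame`, `actor_id`, `target_id` (may be `NA`), `source`.
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns the events tibble sorted by `(start_frame, actor_id, type)`.
#' @export
write_events <- function(events, path) {
  ev <- dplyr::arrange(events, .data$start_frame, .data$actor_id, .data$type)
  jsonlite::write_json(ev, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(x) == 0) return(empty_events())
  out <- as_tibble(x)
  if (!"target_id" %in% names(out)) out$target_id <- NA_integer_
  out <- dplyr::mutate(out,
    type = as.character(.data$type),
    start_frame = as.integer(.data$start_frame),
    end_frame = as.integer(.data$end_frame),
    actor_id = as.integer(.data$actor_id),
    target_id = as.integer(.data$target_id),
    source = as.character(.data$source)
  )
  dplyr::arrange(out[, c("type", "start_frame", "end_frame",
                         "actor_id", "target_id", "source")],
                 .data$start_frame, .data$actor_id, .data$type)
}

empty_events <- function() {
  tibble(type = character(), start_frame = integer(), end_frame = integer(),
         actor_id = integer(), target_id = integer(), source = character())
}

#' Read and write per-frame chain records (chains.csv)
#'
#' One row per frame with columns `frame,chain_count,components`.
#' `components` lists the chain components (fly-id sets of size >= 3) as
#' semicolon-separated groups with ids joined by `-`, e.g. `1-2-3;7-8-9`;
#' empty when the frame has no chain.
#'
#' @param chains A chain-record tibble with columns `frame` (int),
#'   `chain_count` (int) and `components` (list column of integer vectors).
#' @param path File path.
#' @return `write_chains()` returns `path` invisibly; `read_chains()` the
#'   chain tibble.
#' @export
write_chains <- function(chains, path) {
  header <- "frame,chain_count,components"
  if (nrow(chains) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  comp_str <- vapply(chains$components, function(comps) {
    if (length(comps) == 0) return("")
    paste(vapply(comps, function(ids) paste(sort(ids), collapse = "-"), ""),
          collapse = ";")
  }, "")
  rows <- paste(chains$frame, chains$chain_count, comp_str, sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_chains
#' @export
read_chains <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  needed <- c("frame", "chain_count", "components")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("chains file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  comps <- lapply(raw$components, function(s) {
    if (is.na(s) || s == "") return(list())
    lapply(strsplit(s, ";", fixed = TRUE)[[1]],
           function(g) as.integer(strsplit(g, "-", fixed = TRUE)[[1]]))
  })
  tibble(frame = as.integer(raw$frame),
         chain_count = as.integer(raw$chain_count),
         components = comps)
}

#' Write a metrics report to JSON
#'
#' @param metrics A `fly_metrics` object or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

# ---- config file (flat TOML) -------------------------------------------

# Minimal reader for the flat TOML subset the arena config uses: scalar
# `key = value` lines (numbers, booleans, quoted strings) and one-line
# numeric arrays, with `#` comments. Nested tables are not needed and not
# supported.
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    # strip comments (naive: our values never contain '#' inside strings)
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (line == "") next
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop(sprintf("config line %d is not a 'key = value' pair: '%s'",
                   i, lines[i]), call. = FALSE)
    }
    key <- m[2]
    val <- trimws(m[3])
    out[[key]] <- parse_toml_value(val, key, i)
  }
  out
}

parse_toml_value <- function(val, key, line_no) {
  if (grepl("^\\[", val)) {
    inner <- sub("^\\[", "", sub("\\]$", "", val))
    if (trimws(inner) == "") return(numeric(0))
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (any(is.na(nums))) {
      stop(sprintf("config key '%s' (line %d): non-numeric array element",
                   key, line_no), call. = FALSE)
    }
    return(nums)
  }
  if (val %in% c("true", "false")) return(val == "true")
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    stop(sprintf("config key '%s' (line %d): cannot parse value '%s'",
                 key, line_no, val), call. = FALSE)
  }
  num
}

CONFIG_KEYS <- c("n_flies", "fps", "mm_per_px", "chamber_cx", "chamber_cy",
                 "chamber_r", "body_length_mm", "food_cx", "food_cy", "food_r",
                 "food_poly_x", "food_poly_y")

#' Read an arena configuration file
#'
#' The config is a flat TOML file of `key = value` pairs. Recognised keys:
#' `n_flies`, `mm_per_px` (required), `fps` (default 30), `chamber_cx`,
#' `chamber_cy`, `chamber_r` (default: a 4 cm chamber at the configured
#' scale, i.e. radius `20 / mm_per_px` px, centred at `(r, r)`),
#' `body_length_mm` (default 2.5), and an optional food region as either
#' `food_cx`/`food_cy`/`food_r` (circle) or `food_poly_x`/`food_poly_y`
#' (polygon vertex arrays). Unknown keys raise a warning, not an error.
#'
#' @param path Path to a config TOML file.
#' @return An [arena_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  kv <- parse_flat_toml(path)
  unknown <- setdiff(names(kv), CONFIG_KEYS)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (req in c("n_flies", "mm_per_px")) {
    if (is.null(kv[[req]])) {
      stop("config is missing required key '", req, "'.", call. = FALSE)
    }
  }
  mm_per_px <- kv$mm_per_px
  if (!is.numeric(mm_per_px) || mm_per_px <= 0) {
    stop("config key 'mm_per_px' must be > 0.", call. = FALSE)
  }
  r_default <- 20 / mm_per_px  # 4 cm chamber
  chamber <- c(
    cx = kv$chamber_cx %||% (kv$chamber_r %||% r_default),
    cy = kv$chamber_cy %||% (kv$chamber_r %||% r_default),
    r = kv$chamber_r %||% r_default
  )
  food_roi <- NULL
  if (!is.null(kv$food_r)) {
    food_roi <- list(type = "circle", cx = kv$food_cx, cy = kv$food_cy,
                     r = kv$food_r)
  } else if (!is.null(kv$food_poly_x)) {
    food_roi <- list(type = "polygon", x = kv$food_poly_x, y = kv$food_poly_y)
  }
  arena_config(
    n_flies = kv$n_flies,
    mm_per_px = mm_per_px,
    fps = kv$fps %||% 30,
    chamber = chamber,
    food_roi = food_roi,
    body_length_mm = kv$body_length_mm %||% 2.5
  )
}

#' Write an arena configuration file
#'
#' @param config An [arena_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- c(
    sprintf("n_flies = %d", config$n_flies),
    sprintf("fps = %s", fmt_g(config$fps)),
    sprintf("mm_per_px = %s", fmt_g(config$mm_per_px)),
    sprintf("chamber_cx = %s", fmt_g(unname(config$chamber["cx"]))),
    sprintf("chamber_cy = %s", fmt_g(unname(config$chamber["cy"]))),
    sprintf("chamber_r = %s", fmt_g(unname(config$chamber["r"]))),
    sprintf("body_length_mm = %s", fmt_g(config$body_length_mm))
  )
  roi <- config$food_roi
  if (!is.null(roi)) {
    if (roi$type == "circle") {
      lines <- c(lines,
                 sprintf("food_cx = %s", fmt_g(roi$cx)),
                 sprintf("food_cy = %s", fmt_g(roi$cy)),
                 sprintf("food_r = %s", fmt_g(roi$r)))
    } else {
      lines <- c(lines,
                 sprintf("food_poly_x = [%s]", paste(fmt_g(roi$x), collapse = ", ")),
                 sprintf("food_poly_y = [%s]", paste(fmt_g(roi$y), collapse = ", ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
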