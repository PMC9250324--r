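#' Track file dialects
#'
#' A dialect maps a tracking-system export onto the canonical track columns
#' `t`, `x`, `y` in pool-centred cm. The `"generic"` dialect expects a
#' delimited text file with a header row and columns `t` (or `time`), `x`,
#' `y` already in pool-centred cm. The `"anymaze"` dialect expects the
#' common export column names (`Time`, `Centre position X`, `Centre
#' position Y`) in metres with an arbitrary origin, and needs the pool
#' centre's position in that frame.
#'
#' @param name `"generic"` or `"anymaze"`.
#' @param col_map Named character vector mapping canonical names (`t`, `x`,
#'   `y`) to file column names.
#' @param unit_scale Multiplier converting file length units to cm.
#' @param origin Length-2 numeric: pool-centre position in file coordinates
#'   (file units), subtracted before scaling.
#' @param flip_y Set `TRUE` when the file's y axis points south (screen
#'   coordinates).
#' @param sep Field separator (`""` lets [utils::read.delim()] guess via
#'   [utils::read.csv()] for `.csv`, tab otherwise).
#' @return A `track_dialect` object.
#' @export
track_dialect <- function(name = c("generic", "anymaze"),
                          col_map = NULL, unit_scale = NULL, origin = c(0, 0),
                          flip_y = NULL, sep = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    generic = list(col_map = c(t = "t", x = "x", y = "y"),
                   unit_scale = 1, flip_y = FALSE, sep = ","),
    anymaze = list(col_map = c(t = "Time", x = "Centre.position.X", y = "Centre.position.Y"),
                   unit_scale = 100, flip_y = TRUE, sep = ",")
  )
  structure(
    list(
      name = name,
      col_map = col_map %||% defaults$col_map,
      unit_scale = unit_scale %||% defaults$unit_scale,
      origin = origin,
      flip_y = flip_y %||% defaults$flip_y,
      sep = sep %||% defaults$sep
    ),
    class = "track_dialect"
  )
}

#' Read one swim trial from a delimited track file
#'
#' Reads a time-stamped position track (one trial per file), maps it to
#' pool-centred cm via the dialect, drops non-finite rows (with a warning
#' stating how many), and validates the result. Loading fails when required
#' columns are missing, when more than 10% of rows had to be dropped, when
#' time is non-monotone after cleaning, or when the track contains a gap
#' longer than `max_gap` seconds (occlusion gaps up to `max_gap` are closed
#' later by linear interpolation in [resample_track()]).
#'
#' @param path Path to a delimited text file.
#' @param dialect A [track_dialect()] (or a dialect name).
#' @param cfg Optional [pool_config()] used to reject out-of-pool points.
#' @param max_gap Longest tolerated time gap between samples (s).
#' @param ... Trial metadata passed to [swim_track()] (`animal_id`, `group`,
#'   `day`, `trial_index`, `trial_type`, `trial_duration`, `start_octant`).
#' @return A [swim_track()].
#' @export
read_track <- function(path, dialect = track_dialect("generic"), cfg = NULL,
                       max_gap = 1, ...) {
  if (is.character(dialect)) dialect <- track_dialect(dialect)
  stopifnot(inherits(dialect, "track_dialect"))
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           check.names = TRUE, stringsAsFactors = FALSE)
  cm <- dialect$col_map
  have <- make.names(unname(cm)) %in% names(raw) | unname(cm) %in% names(raw)
  if (!all(have)) {
    stop(sprintf("track file %s is missing column(s): %s", basename(path),
                 paste(cm[!have], collapse = ", ")), call. = FALSE)
  }
  pick <- function(col) {
    nm <- if (col %in% names(raw)) col else make.names(col)
    as.numeric(raw[[nm]])
  }
  df <- data.frame(t = pick(cm[["t"]]), x = pick(cm[["x"]]), y = pick(cm[["y"]]))
  ok <- is.finite(df$t) & is.finite(df$x) & is.finite(df$y)
  n_drop <- sum(!ok)
  if (n_drop > 0) {
    if (n_drop > 0.1 * nrow(df)) {
      stop(sprintf("%s: %d of %d rows non-finite (> 10%%); refusing to load",
                   basename(path), n_drop, nrow(df)), call. = FALSE)
    }
    warning(sprintf("%s: dropped %d non-finite row(s)", basename(path), n_drop))
    df <- df[ok, ]
  }
  if (nrow(df) < 2L) stop(basename(path), ": fewer than 2 usable samples", call. = FALSE)
  if (any(diff(df$t) <= 0)) {
    stop(basename(path), ": time is not strictly increasing after cleaning", call. = FALSE)
  }
  if (max(diff(df$t)) > max_gap) {
    stop(sprintf("%s: gap of %.2f s exceeds max_gap = %.2f s; trial invalid",
                 basename(path), max(diff(df$t)), max_gap), call. = FALSE)
  }
  df$x <- (df$x - dialect$origin[1]) * dialect$unit_scale
  df$y <- (df$y - dialect$origin[2]) * dialect$unit_scale
  if (dialect$flip_y) df$y <- -df$y
  df$t <- df$t - df$t[1]
  swim_track(df, cfg = cfg, ...)
}

#' Write a swim track to a delimited file
#'
#' Inverse of [read_track()]: emits coordinates in the dialect's units and
#' frame with fixed 6-decimal formatting, so a write/read round trip
#' reproduces coordinates to 1e-6 cm (generic dialect).
#'
#' @param track A [swim_track()].
#' @param path Output file path.
#' @param dialect A [track_dialect()] (or name).
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path, dialect = track_dialect("generic")) {
  if (is.character(dialect)) dialect <- track_dialect(dialect)
  x <- track$x; y <- if (dialect$flip_y) -track$y else track$y
  x <- x / dialect$unit_scale + dialect$origin[1]
  y <- y / dialect$unit_scale + dialect$origin[2]
  hdr <- paste(unname(dialect$col_map), collapse = dialect$sep)
  rows <- sprintf(paste0("%.6f", dialect$sep, "%.6f", dialect$sep, "%.6f"),
                  track$t, x, y)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
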