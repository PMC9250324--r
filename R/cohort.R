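#' Cohort simulation specification
#'
#' Describes a simulated cohort: group, number of rats, protocol length,
#' and the per-day category mixture from which each trial's ground-truth
#' strategy is drawn. The default mixtures emulate the qualitative learning
#' progression seen in acquisition protocols: young animals shift from
#' ineffective searching toward effective, direct, and increasingly precise
#' strategies within ten days; aged animals progress more slowly, gaining
#' effectiveness mostly through indirect strategies and rarely refining
#' precision.
#'
#' @param group `"young"` or `"aged"`.
#' @param n_rats Number of animals.
#' @param days Number of acquisition days.
#' @param trials_per_day Trials per animal per day.
#' @param mixtures A `days` x 10 matrix of category weights (columns A-J,
#'   rows summing to 1); defaults depend on `group`.
#' @param noise_sd Tracking-noise level passed to the trajectory generator.
#' @param seed Integer seed for reproducible simulation.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(group = c("young", "aged"), n_rats = 8, days = 10,
                        trials_per_day = 4, mixtures = NULL, noise_sd = 0.5,
                        seed = 1L) {
  group <- match.arg(group)
  if (is.null(mixtures)) mixtures <- default_mixtures(group, days)
  mixtures <- as.matrix(mixtures)
  if (nrow(mixtures) != days || ncol(mixtures) != 10) {
    stop("mixtures must be a days x 10 matrix (columns A-J)", call. = FALSE)
  }
  if (any(mixtures < 0) || any(abs(rowSums(mixtures) - 1) > 1e-6)) {
    stop("mixture rows must be non-negative and sum to 1", call. = FALSE)
  }
  colnames(mixtures) <- LETTERS[1:10]
  structure(
    list(group = group, n_rats = n_rats, days = days,
         trials_per_day = trials_per_day, mixtures = mixtures,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_mixtures <- function(group = c("young", "aged"), days = 10) {
  group <- match.arg(group)
  f <- (seq_len(days) - 1) / max(1, days - 1) # training progress 0..1
  lerp <- function(a, b) a + (b - a) * f
  if (group == "young") {
    p_dir <- lerp(0.05, 0.75)
    p_non <- lerp(0.60, 0.05)
    within_dir <- rbind(lerp(0.05, 0.45), lerp(0.45, 0.40),
                        lerp(0.35, 0.12), lerp(0.15, 0.03))
    within_ind <- rbind(lerp(0.30, 0.60), lerp(0.40, 0.30), lerp(0.30, 0.10))
    within_non <- rbind(lerp(0.20, 0.50), lerp(0.35, 0.40), lerp(0.45, 0.10))
  } else {
    p_dir <- lerp(0.02, 0.20)
    p_non <- lerp(0.70, 0.22)
    within_dir <- rbind(lerp(0.02, 0.15), lerp(0.40, 0.55),
                        lerp(0.40, 0.25), lerp(0.18, 0.05))
    within_ind <- rbind(lerp(0.25, 0.45), lerp(0.40, 0.35), lerp(0.35, 0.20))
    within_non <- rbind(lerp(0.15, 0.40), lerp(0.35, 0.40), lerp(0.50, 0.20))
  }
  p_ind <- 1 - p_dir - p_non
  norm <- function(m) sweep(m, 2, colSums(m), "/")
  mix <- cbind(
    t(norm(within_dir)) * p_dir,
    t(norm(within_ind)) * p_ind,
    t(norm(within_non)) * p_non
  )
  colnames(mix) <- LETTERS[1:10]
  mix
}

# Draw a feasible change-count composition for a category.
draw_counts <- function(category) {
  band <- category_band(category)
  if (band[2] == 0) {
    return(c(curve = 0, zigzag = 0, spiral = 0, peripheral = 0))
  }
  total <- sample(band[1]:min(band[2], 8L), 1)
  zig <- if (total >= 1) stats::rbinom(1, 1, 0.3) else 0
  spi <- if (total - zig >= 1) stats::rbinom(1, 1, 0.2) else 0
  per <- if (total - zig - spi >= 1 && total <= 4) stats::rbinom(1, 1, 0.15) else 0
  c(curve = total - zig - spi - per, zigzag = zig, spiral = spi, peripheral = per)
}

#' Simulate a cohort of swim trials with ground-truth labels
#'
#' For every rat, day, and trial, draws a ground-truth category from the
#' day's mixture and constructs a matching synthetic trajectory
#' ([generate_archetype()]). Release points rotate among three
#' pseudo-random octants per day. Fully reproducible under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @param cfg A [pool_config()].
#' @param labels_only If `TRUE`, skip trajectory construction and return
#'   only the drawn ground-truth labels (fast; used for large statistical
#'   simulations that consume labels, not tracks).
#' @return A tibble with one row per trial: `animal_id`, `group`, `day`,
#'   `trial_index`, `trial_type`, `start_octant`, `category` (ground
#'   truth), and (unless `labels_only`) a list-column `track`.
#' @export
generate_cohort <- function(spec, cfg = pool_config(), labels_only = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    octant_pool <- 3:7
    grid <- tidyr::expand_grid(
      rat = seq_len(spec$n_rats),
      day = seq_len(spec$days),
      trial_index = seq_len(spec$trials_per_day)
    )
    day_octants <- lapply(seq_len(spec$days), function(d) sample(octant_pool, 3))
    out <- tibble::tibble(
      animal_id = sprintf("%s_%02d", spec$group, grid$rat),
      group = spec$group,
      day = grid$day,
      trial_index = grid$trial_index,
      trial_type = "acquisition",
      start_octant = vapply(seq_len(nrow(grid)), function(i) {
        day_octants[[grid$day[i]]][(grid$trial_index[i] - 1L) %% 3L + 1L]
      }, integer(1)),
      category = vapply(grid$day, function(d) {
        sample(LETTERS[1:10], 1, prob = spec$mixtures[d, ])
      }, character(1))
    )
    if (!labels_only) {
      out$track <- purrr::pmap(
        list(out$category, out$start_octant, out$animal_id, out$day, out$trial_index),
        function(category, so, animal_id, day, trial_index) {
          track <- NULL
          for (attempt in 1:3) {
            counts <- draw_counts(if (attempt < 3) category else category)
            if (attempt == 3) counts <- c(curve = unname(counts["curve"]) +
                                            unname(counts["zigzag"]) + unname(counts["spiral"]) +
                                            unname(counts["peripheral"]),
                                          zigzag = 0, spiral = 0, peripheral = 0)
            aspec <- try(archetype_spec(
              category,
              n_curves = counts[["curve"]], n_zigzags = counts[["zigzag"]],
              n_spirals = counts[["spiral"]], n_peripheral = counts[["peripheral"]],
              start_octant = so, noise_sd = spec$noise_sd
            ), silent = TRUE)
            if (inherits(aspec, "try-error")) next
            gen <- try(generate_archetype_impl(aspec, cfg), silent = TRUE)
            if (!inherits(gen, "try-error")) {
              track <- gen$track
              break
            }
          }
          if (is.null(track)) {
            stop("could not construct a trajectory for category ", category,
                 call. = FALSE)
          }
          m <- track_meta(track)
          m$animal_id <- animal_id; m$group <- spec$group
          m$day <- day; m$trial_index <- trial_index
          attr(track, "meta") <- m
          track
        }
      )
    }
    out
  })
}

#' Write a set of trials to track files plus a metadata sidecar
#'
#' Emits one delimited track file per trial (via [write_track()]) and a
#' `metadata.csv` sidecar holding the trial metadata and, when available,
#' the ground-truth category. Output is byte-stable for a given trial set.
#'
#' @param trials A tibble with a `track` list-column (see
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param dialect A [track_dialect()] or dialect name.
#' @return Invisibly, the metadata tibble (with a `file` column).
#' @export
write_tracks <- function(trials, dir, dialect = track_dialect("generic")) {
  if (is.character(dialect)) dialect <- track_dialect(dialect)
  stopifnot("track" %in% names(trials))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dplyr::select(trials, -dplyr::any_of("track"))
  meta$file <- sprintf("track_%04d.csv", seq_len(nrow(trials)))
  purrr::walk2(trials$track, meta$file, function(tr, f) {
    write_track(tr, file.path(dir, f), dialect)
  })
  cols <- c("file", setdiff(names(meta), "file"))
  utils::write.csv(meta[cols], file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(tibble::as_tibble(meta[cols]))
}

#' Read a directory of track files written by [write_tracks()]
#'
#' @param dir Directory containing track files and `metadata.csv`.
#' @param dialect A [track_dialect()] or dialect name.
#' @param cfg Optional [pool_config()] for in-pool validation.
#' @return A trial tibble with a `track` list-column.
#' @export
read_tracks <- function(dir, dialect = track_dialect("generic"), cfg = NULL) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("metadata.csv not found in ", dir, call. = FALSE)
  meta <- tibble::as_tibble(utils::read.csv(meta_path, stringsAsFactors = FALSE))
  meta$track <- purrr::pmap(meta, function(file, ...) {
    m <- list(...)
    read_track(
      file.path(dir, file), dialect = dialect, cfg = cfg,
      animal_id = as.character(m$animal_id %||% NA),
      group = as.character(m$group %||% NA),
      day = m$day %||% NA_integer_,
      trial_index = m$trial_index %||% NA_integer_,
      trial_type = as.character(m$trial_type %||% "acquisition"),
      trial_duration = m$trial_duration %||% 90,
      start_octant = m$start_octant %||% NA_integer_
    )
  })
  meta
}
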