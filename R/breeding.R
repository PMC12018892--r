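# Breeding-habit descriptors from the reconstruction: remigration
# intervals (years between nesting seasons), internesting intervals (days
# between clutches within a season) and nest-site fidelity (pairwise
# distances between a female's nests). A season is a calendar year.

#' Per-nest table for a reconstruction
#'
#' One row per nest with its assigned mother and, when available, date and
#' coordinates.
#'
#' @param result a `reconstruction` from [assign_parents()].
#' @param nests per-hatchling nest metadata (`nest_id`, `sample_id`, and
#'   optionally `date`, `lat`, `lon`).
#' @return Data frame with `nest_id`, `mother`, `date`, `year`, `lat`, `lon`.
#' @export
nesting_table <- function(result, nests) {
  stopifnot(inherits(result, "reconstruction"))
  ids <- result$nests$nest_id
  i <- match(ids, nests$nest_id)
  out <- data.frame(
    nest_id = ids,
    mother = result$nests$mother,
    stringsAsFactors = FALSE
  )
  out$date <- if ("date" %in% names(nests)) as.Date(nests$date[i]) else
    as.Date(NA)
  out$year <- as.integer(format(out$date, "%Y"))
  out$lat <- if ("lat" %in% names(nests)) nests$lat[i] else NA_real_
  out$lon <- if ("lon" %in% names(nests)) nests$lon[i] else NA_real_
  out
}

#' Remigration intervals (years between nesting seasons)
#'
#' @param tbl a [nesting_table()] (or any data frame with `mother` and
#'   `year`).
#' @return Data frame with one row per consecutive season pair per mother:
#'   `mother`, `from_year`, `to_year`, `gap_years`. Mothers seen in a single
#'   season contribute no rows.
#' @export
remigration_intervals <- function(tbl) {
  out <- lapply(split(tbl, tbl$mother), function(d) {
    yrs <- sort(unique(d$year[!is.na(d$year)]))
    if (length(yrs) < 2L) return(NULL)
    data.frame(
      mother = d$mother[1L],
      from_year = yrs[-length(yrs)],
      to_year = yrs[-1L],
      gap_years = diff(yrs),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mother = character(0), from_year = integer(0),
                      to_year = integer(0), gap_years = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Internesting intervals (days between same-season clutches)
#'
#' Consecutive day gaps between a mother's nests within one calendar year.
#' Duplicate dates (same-day clutches) are kept but flagged with a warning.
#'
#' @param tbl a [nesting_table()].
#' @return Data frame with `mother`, `year`, `from_date`, `to_date`,
#'   `gap_days`.
#' @export
internesting_intervals <- function(tbl) {
  tbl <- tbl[!is.na(tbl$date), , drop = FALSE]
  out <- lapply(split(tbl, list(tbl$mother, tbl$year), drop = TRUE),
    function(d) {
      if (nrow(d) < 2L) return(NULL)
      dts <- sort(d$date)
      if (anyDuplicated(dts)) {
        warning("same-day clutches for mother ", d$mother[1L], " in ",
                d$year[1L])
      }
      data.frame(
        mother = d$mother[1L],
        year = d$year[1L],
        from_date = dts[-length(dts)],
        to_date = dts[-1L],
        gap_days = as.integer(diff(dts)),
        stringsAsFactors = FALSE
      )
    })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mother = character(0), year = integer(0),
                      from_date = as.Date(character(0)),
                      to_date = as.Date(character(0)), gap_days = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Great-circle distance between nest sites
#'
#' Haversine distance on a sphere of radius 6371 km; vectorized over
#' coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84 treated
#'   as spherical).
#' @return Distance(s) in kilometres.
#' @export
nest_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range: |lat| <= 90, |lon| <= 180")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Pairwise distances between a mother's nests
#'
#' @param tbl a [nesting_table()] with coordinates.
#' @return Data frame with `mother`, `nest1`, `nest2`, `same_season`,
#'   `distance_km`.
#' @export
nest_distances <- function(tbl) {
  tbl <- tbl[!is.na(tbl$lat) & !is.na(tbl$lon), , drop = FALSE]
  out <- lapply(split(tbl, tbl$mother), function(d) {
    if (nrow(d) < 2L) return(NULL)
    idx <- combn(nrow(d), 2L)
    data.frame(
      mother = d$mother[1L],
      nest1 = d$nest_id[idx[1L, ]],
      nest2 = d$nest_id[idx[2L, ]],
      same_season = d$year[idx[1L, ]] == d$year[idx[2L, ]],
      distance_km = nest_distance(d$lat[idx[1L, ]], d$lon[idx[1L, ]],
                                  d$lat[idx[2L, ]], d$lon[idx[2L, ]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(mother = character(0), nest1 = character(0),
                      nest2 = character(0), same_season = logical(0),
                      distance_km = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Philopatry summary per mother
#'
#' Maximum and median pairwise nest distance per mother, with a flag for
#' long-range nesting events.
#'
#' @param distances a [nest_distances()] table.
#' @param long_range_km distance above which an event is flagged.
#' @return Data frame with `mother`, `n_pairs`, `max_km`, `median_km`,
#'   `long_range`.
#' @export
philopatry_summary <- function(distances, long_range_km = 50) {
  if (!nrow(distances)) {
    return(data.frame(mother = character(0), n_pairs = integer(0),
                      max_km = numeric(0), median_km = numeric(0),
                      long_range = logical(0)))
  }
  out <- do.call(rbind, lapply(split(distances, distances$mother), function(d) {
    data.frame(
      mother = d$mother[1L],
      n_pairs = nrow(d),
      max_km = max(d$distance_km),
      median_km = median(d$distance_km),
      long_range = any(d$distance_km > long_range_km),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Breeding-habit report
#'
#' Bundles remigration intervals, internesting intervals, pairwise nest
#' distances and the philopatry summary for a reconstruction.
#'
#' @inheritParams nesting_table
#' @param long_range_km threshold for flagging long-range nesting.
#' @return An object of class `breeding_habits`.
#' @export
breeding_habits <- function(result, nests, long_range_km = 50) {
  tbl <- nesting_table(result, nests)
  dists <- nest_distances(tbl)
  structure(
    list(
      nesting = tbl,
      remigration = remigration_intervals(tbl),
      internesting = internesting_intervals(tbl),
      distances = dists,
      philopatry = philopatry_summary(dists, long_range_km = long_range_km)
    ),
    class = "breeding_habits"
  )
}

#' @export
print.breeding_habits <- function(x, ...) {
  cat(sprintf(
    "<breeding_habits> %d nests, %d remigration gap(s), %d internesting gap(s), %d distance pair(s)\n",
    nrow(x$nesting), nrow(x$remigration), nrow(x$internesting),
    nrow(x$distances)
  ))
  if (nrow(x$internesting)) {
    cat(sprintf("  internesting: mean %.1f d, range %d-%d d\n",
                mean(x$internesting$gap_days), min(x$internesting$gap_days),
                max(x$internesting$gap_days)))
  }
  invisible(x)
}
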