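#' Fracture outcome definitions
#'
#' Four nested fracture outcome sets are used throughout the package:
#' \describe{
#'   \item{any}{any incident fracture, regardless of site.}
#'   \item{osteoporotic}{the Kanis osteoporotic set: clinical vertebral,
#'     ribs, pelvis, humerus, clavicle, scapula, sternum, hip, other femoral,
#'     tibia, fibula and distal forearm/wrist fractures.}
#'   \item{mof}{major osteoporotic fracture: hip, clinical vertebral,
#'     proximal humerus and distal forearm/wrist.}
#'   \item{hip}{hip fracture only.}
#' }
#' The sets are nested: \code{hip} is a subset of \code{mof}, which is a
#' subset of \code{osteoporotic}, which is a subset of \code{any}.
#'
#' The site-to-outcome map is shipped as a plain-text table
#' (\code{system.file("extdata", "fracture_sites.tsv", package = "fracgr")})
#' and can be overridden via the \code{site_map} argument of
#' [classify_fracture()] and [first_event_time()]. Cohort-specific recording
#' conventions are mapped to their closest category: \code{wrist} stands for
#' distal forearm/wrist, \code{vertebra} for clinical vertebral,
#' \code{shoulder} for proximal humerus, \code{femur} for non-hip femoral
#' shaft fractures. The generic codes \code{arm} and \code{humerus} cannot be
#' localized to the proximal humerus and are counted as osteoporotic but not
#' major osteoporotic.
#'
#' @return [outcome_names()] returns the outcome labels in nesting order
#'   (widest first). [site_vocabulary()] returns the site-to-outcome map as a
#'   data frame with columns \code{site}, \code{osteoporotic}, \code{mof},
#'   \code{hip}.
#' @examples
#' outcome_names()
#' head(site_vocabulary())
#' @export
outcome_names <- function() c("any", "osteoporotic", "mof", "hip")

#' @rdname outcome_names
#' @export
site_vocabulary <- function() {
  path <- system.file("extdata", "fracture_sites.tsv", package = "fracgr")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# cached copy so per-event classification does not re-read the table
.fracgr_env <- new.env(parent = emptyenv())

default_site_map <- function() {
  if (is.null(.fracgr_env$site_map)) .fracgr_env$site_map <- site_vocabulary()
  .fracgr_env$site_map
}

#' Classify a fracture site into outcome sets
#'
#' Maps fracture site codes onto the nested outcome sets described in
#' [outcome_names()]. Every known site belongs to \code{any}; membership in
#' the narrower sets follows the Kanis osteoporotic and major osteoporotic
#' definitions.
#'
#' @param site character vector of site codes (see [site_vocabulary()]).
#' @param site_map optional replacement map, a data frame with the same
#'   columns as [site_vocabulary()].
#' @return For a single site, the character vector of outcome names it
#'   belongs to; for several sites, a named list of such vectors.
#' @examples
#' classify_fracture("hip")    # all four outcomes
#' classify_fracture("ribs")   # any + osteoporotic
#' classify_fracture("fingers")# any only
#' @export
classify_fracture <- function(site, site_map = NULL) {
  map <- if (is.null(site_map)) default_site_map() else site_map
  idx <- match(site, map$site)
  if (anyNA(idx)) {
    bad <- unique(site[is.na(idx)])
    stop("unknown fracture site code(s): ", paste(bad, collapse = ", "),
         "\n  known sites: ", paste(map$site, collapse = ", "))
  }
  one <- function(i) {
    c("any",
      if (map$osteoporotic[i] == 1) "osteoporotic",
      if (map$mof[i] == 1) "mof",
      if (map$hip[i] == 1) "hip")
  }
  if (length(site) == 1L) return(one(idx))
  stats::setNames(lapply(idx, one), site)
}

# 0/1 membership of each site in `outcome`; vectorized over sites
site_in_outcome <- function(site, outcome, site_map = NULL) {
  map <- if (is.null(site_map)) default_site_map() else site_map
  outcome <- match.arg(outcome, outcome_names())
  idx <- match(site, map$site)
  if (anyNA(idx)) {
    bad <- unique(site[is.na(idx)])
    stop("unknown fracture site code(s): ", paste(bad, collapse = ", "))
  }
  if (outcome == "any") rep(TRUE, length(site)) else map[[outcome]][idx] == 1
}

# parse "site:time;site:time" strings into a long table (row, site, time)
parse_fracture_events <- function(x) {
  has <- !is.na(x) & nzchar(x)
  if (!any(has)) {
    return(data.frame(row = integer(), site = character(),
                      time = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(x[has], ";", fixed = TRUE)
  n_ev <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  colon <- regexpr(":", flat, fixed = TRUE)
  if (any(colon < 0)) stop("malformed fracture_events entry: expected 'site:time' pairs")
  data.frame(
    row  = rep(which(has), n_ev),
    site = substr(flat, 1L, colon - 1L),
    time = as.numeric(substr(flat, colon + 1L, nchar(flat))),
    stringsAsFactors = FALSE
  )
}

serialize_fracture_events <- function(events_list) {
  vapply(events_list, function(ev) {
    if (is.null(ev) || nrow(ev) == 0L) return("")
    paste(sprintf("%s:%.17g", ev$site, ev$time), collapse = ";")
  }, character(1))
}

#' Time to first qualifying fracture
#'
#' Returns, for each subject, the time of the first fracture whose site
#' belongs to the requested outcome set; only the first qualifying fracture
#' per person is counted. Subjects with no qualifying event get \code{NA}.
#'
#' @param subjects a person-level data frame with a \code{fracture_events}
#'   column in \code{"site:time;site:time"} form (see [generate_cohort()]).
#' @param outcome one of \code{"any"}, \code{"osteoporotic"}, \code{"mof"},
#'   \code{"hip"}.
#' @param site_map optional replacement site map (see [classify_fracture()]).
#' @return numeric vector of first-event times in years, \code{NA} where no
#'   qualifying event occurred.
#' @export
first_event_time <- function(subjects, outcome = "any", site_map = NULL) {
  outcome <- match.arg(outcome, outcome_names())
  ev <- parse_fracture_events(subjects$fracture_events)
  out <- rep(NA_real_, nrow(subjects))
  if (nrow(ev) == 0L) return(out)
  keep <- site_in_outcome(ev$site, outcome, site_map)
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0L) return(out)
  first <- tapply(ev$time, ev$row, min)
  out[as.integer(names(first))] <- as.numeric(first)
  out
}
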