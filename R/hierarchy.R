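#' Location hierarchies
#'
#' The analysis follows a four-level location hierarchy: a single global
#' node, super-regions, regions, and countries. A hierarchy is represented
#' as a data frame with columns `location_id`, `name`, `level` (one of
#' `"global"`, `"super_region"`, `"region"`, `"country"`) and `parent_id`
#' (`NA` only for the global node). `location_hierarchy()` validates the
#' table and attaches the class `"location_hierarchy"`.
#'
#' Validation enforces: exactly one global node; every non-global node has
#' exactly one parent, one level coarser than its own; no cycles; ids
#' unique. Countries therefore partition into regions and regions into
#' super-regions.
#'
#' @param x Data frame with columns `location_id`, `name`, `level`,
#'   `parent_id`.
#' @return The validated data frame with class `"location_hierarchy"`.
#' @export
location_hierarchy <- function(x) {
  need <- c("location_id", "name", "level", "parent_id")
  if (!all(need %in% names(x))) {
    stop("hierarchy table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$location_id <- as.character(x$location_id)
  x$parent_id <- as.character(x$parent_id)
  x$parent_id[!is.na(x$parent_id) & x$parent_id == ""] <- NA_character_
  lv <- .loc_levels()
  if (any(!x$level %in% lv)) {
    stop("unknown location level(s): ",
         paste(setdiff(unique(x$level), lv), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$location_id)) {
    stop("duplicate location_id in hierarchy", call. = FALSE)
  }
  if (sum(x$level == "global") != 1L) {
    stop("hierarchy must contain exactly one global node", call. = FALSE)
  }
  nonglobal <- x[x$level != "global", , drop = FALSE]
  if (any(is.na(nonglobal$parent_id))) {
    stop("orphan node(s): ",
         paste(nonglobal$location_id[is.na(nonglobal$parent_id)],
               collapse = ", "), call. = FALSE)
  }
  if (!is.na(x$parent_id[x$level == "global"])) {
    stop("the global node must have no parent", call. = FALSE)
  }
  idx <- match(nonglobal$parent_id, x$location_id)
  if (anyNA(idx)) {
    stop("parent_id not in hierarchy: ",
         paste(unique(nonglobal$parent_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  child_rank <- match(nonglobal$level, lv)
  parent_rank <- match(x$level[idx], lv)
  if (any(parent_rank != child_rank - 1L)) {
    bad <- nonglobal$location_id[parent_rank != child_rank - 1L]
    stop("parent level must be exactly one coarser than child for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # level-rank check above precludes cycles, but verify reachability anyway
  # so malformed tables fail loudly rather than looping downstream
  for (id in x$location_id) .walk_up(x, id)
  class(x) <- c("location_hierarchy", "data.frame")
  x
}

.loc_levels <- function() c("global", "super_region", "region", "country")

.walk_up <- function(h, id) {
  seen <- character()
  cur <- id
  repeat {
    row <- match(cur, h$location_id)
    if (is.na(row)) stop("location '", cur, "' not in hierarchy", call. = FALSE)
    if (cur %in% seen) stop("cycle in hierarchy at '", cur, "'", call. = FALSE)
    seen <- c(seen, cur)
    p <- h$parent_id[row]
    if (is.na(p)) return(seen)
    cur <- p
  }
}

#' Ancestors of a location, child to root
#'
#' @param hierarchy A [location_hierarchy()].
#' @param location_id Location id present in the hierarchy.
#' @return Character vector of ancestor ids from the node's parent up to
#'   the global node (empty for global).
#' @export
ancestors <- function(hierarchy, location_id) {
  path <- .walk_up(hierarchy, location_id)
  path[-1L]
}

#' Descendants of a location
#'
#' @inheritParams ancestors
#' @param include_self Include `location_id` itself? Default `TRUE`.
#' @return Character vector of ids of all nodes at or below `location_id`.
#' @export
descendants <- function(hierarchy, location_id, include_self = TRUE) {
  if (!location_id %in% hierarchy$location_id) {
    stop("location '", location_id, "' not in hierarchy", call. = FALSE)
  }
  out <- location_id
  frontier <- location_id
  while (length(frontier)) {
    kids <- hierarchy$location_id[hierarchy$parent_id %in% frontier &
                                    !is.na(hierarchy$parent_id)]
    out <- c(out, kids)
    frontier <- kids
  }
  if (include_self) out else setdiff(out, location_id)
}

#' Children of a location
#' @inheritParams ancestors
#' @return Character vector of immediate child ids.
#' @export
children <- function(hierarchy, location_id) {
  hierarchy$location_id[!is.na(hierarchy$parent_id) &
                          hierarchy$parent_id == location_id]
}

#' Look up the healthcare access and quality index for country-years
#'
#' The HAQI is a 0-100 country-year covariate. Years missing from the
#' table are linearly interpolated within a country's observed span and
#' held constant outside it (no extrapolation of the trend).
#'
#' @param haqi Data frame with columns `location_id`, `year`, `haqi`.
#' @param location_id Character vector of country ids.
#' @param year Numeric vector of years (recycled against `location_id`).
#' @return Numeric vector of HAQI values.
#' @export
haqi_lookup <- function(haqi, location_id, year) {
  n <- max(length(location_id), length(year))
  location_id <- rep_len(as.character(location_id), n)
  year <- rep_len(year, n)
  out <- numeric(n)
  for (loc in unique(location_id)) {
    sub <- haqi[haqi$location_id == loc, , drop = FALSE]
    i <- location_id == loc
    if (nrow(sub) == 0L) {
      stop("no HAQI values for location '", loc, "'", call. = FALSE)
    }
    sub <- sub[order(sub$year), , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[i] <- sub$haqi
    } else {
      out[i] <- stats::approx(sub$year, sub$haqi, xout = year[i],
                              rule = 2, ties = "ordered")$y
    }
  }
  if (any(out < 0 | out > 100)) {
    stop("HAQI values must lie in [0, 100]", call. = FALSE)
  }
  out
}
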