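# Multi-objective "spatial analysis": per-response acceptability masks on a
# shared (ET, N) grid, their intersection, and projection to recommended ET
# and N intervals.

#' Evaluation grid over a domain box
#'
#' @param domain list with `x1` and `x2` ranges.
#' @param n number of cells per axis (length 1 or 2).
#' @return list with coordinate vectors `x1`, `x2` and the step sizes.
#' @export
surface_grid <- function(domain, n = 1000) {
  n <- rep(as.integer(n), length.out = 2)
  if (any(n < 2)) stop("grid needs at least 2 cells per axis")
  x1 <- seq(domain$x1[1], domain$x1[2], length.out = n[1])
  x2 <- seq(domain$x2[1], domain$x2[2], length.out = n[2])
  list(x1 = x1, x2 = x2, step = c(x1 = x1[2] - x1[1], x2 = x2[2] - x2[1]))
}

#' Acceptability mask of a surface at a fractional threshold
#'
#' A grid cell is acceptable when the surface value is at least
#' `threshold * reference`, where the reference defaults to the
#' box-constrained maximum of the surface (the relevant ceiling when a
#' response peaks on the domain boundary, as NPFP does at the low-N edge).
#'
#' @param surface a `quad_surface`.
#' @param threshold fraction in (0, 1).
#' @param grid a [surface_grid()]; defaults to a 1000 x 1000 grid over the
#'   surface's own domain.
#' @param reference value whose fraction defines acceptability; defaults to
#'   `constrained_max(surface)$value`, which must be positive.
#' @return Logical matrix (rows = x1, cols = x2) with the grid attached as
#'   attributes.
#' @export
acceptability_mask <- function(surface, threshold, grid = NULL,
                               reference = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be strictly between 0 and 1")
  if (is.null(grid)) grid <- surface_grid(surface$domain)
  if (is.null(reference)) reference <- constrained_max(surface)$value
  if (reference <= 0)
    stop("surface maximum over the box must be positive for a fractional threshold")
  vals <- outer(grid$x1, grid$x2, function(a, b) predict(surface, a, b))
  mask <- vals >= threshold * reference
  attr(mask, "grid") <- grid
  mask
}

#' Intersect acceptability masks and project to intervals
#'
#' Logical AND of the per-response masks; the ET and N intervals are the
#' exact min/max grid coordinates of the surviving cells. Projections with
#' internal gaps (possible for non-convex intersections) are reported as the
#' bounding interval with the `contiguous` flag cleared.
#'
#' @param masks named list of logical mask matrices sharing one grid.
#' @param thresholds named numeric vector echoed into the result.
#' @param year optional season label.
#' @return An object of class `accept_region`: masks, intersection,
#'   `et_interval`, `n_interval`, per-axis contiguity flags and an `empty`
#'   flag (intervals are `NULL` when the intersection is empty).
#' @export
intersect_regions <- function(masks, thresholds = NULL, year = NA) {
  if (length(masks) < 1) stop("need at least one mask")
  dims <- vapply(masks, dim, integer(2))
  if (any(dims != dims[, 1])) stop("masks do not share one grid")
  grid <- attr(masks[[1]], "grid")
  inter <- Reduce(`&`, masks)
  idx <- which(inter, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    region <- list(masks = masks, intersection = inter, grid = grid,
                   thresholds = thresholds, year = year, empty = TRUE,
                   et_interval = NULL, n_interval = NULL,
                   contiguous = c(et = NA, n = NA))
    return(structure(region, class = "accept_region"))
  }
  rows <- sort(unique(idx[, 1]))
  cols <- sort(unique(idx[, 2]))
  region <- list(
    masks = masks, intersection = inter, grid = grid,
    thresholds = thresholds, year = year, empty = FALSE,
    et_interval = range(grid$x1[rows]),
    n_interval = range(grid$x2[cols]),
    contiguous = c(et = all(diff(rows) == 1), n = all(diff(cols) == 1)))
  structure(region, class = "accept_region")
}

#' @export
print.accept_region <- function(x, ...) {
  cat("Multi-objective acceptability region",
      if (!is.na(x$year)) paste0(" (", x$year, ")"), "\n", sep = "")
  if (!is.null(x$thresholds))
    cat("  thresholds: ",
        paste(sprintf("%s >= %g%% of max", names(x$thresholds),
                      100 * x$thresholds), collapse = ", "), "\n", sep = "")
  if (x$empty) {
    cat("  empty intersection: no (ET, N) cell satisfies all objectives\n")
  } else {
    cat(sprintf("  ET interval: %.1f - %.1f mm%s\n", x$et_interval[1],
                x$et_interval[2],
                if (!x$contiguous[["et"]]) " (gapped projection)" else ""))
    cat(sprintf("  N interval:  %.1f - %.1f kg/ha%s\n", x$n_interval[1],
                x$n_interval[2],
                if (!x$contiguous[["n"]]) " (gapped projection)" else ""))
  }
  invisible(x)
}

#' Acceptability region for one year's response surfaces
#'
#' High-level wrapper: shares one grid across the year's surfaces (their
#' common domain box), thresholds each response at its configured fraction
#' of the box-constrained maximum, and intersects. Default thresholds are
#' 95% for yield and WUE and 75% for NPFP; the lower NPFP fraction reflects
#' that its maximum sits at the low-N design boundary, where the other
#' objectives collapse, so no 95% overlap exists.
#'
#' @param surfaces named list of `quad_surface` objects (same domain box).
#' @param thresholds named fractions per response.
#' @param grid_n grid cells per axis.
#' @return An `accept_region`; also records which response constrains each
#'   interval endpoint (`active_constraints`).
#' @export
acceptability_region <- function(surfaces,
                                 thresholds = c(yield = 0.95, wue = 0.95,
                                                npfp = 0.75),
                                 grid_n = 1000) {
  if (!all(names(surfaces) %in% names(thresholds)))
    stop("no threshold configured for: ",
         paste(setdiff(names(surfaces), names(thresholds)), collapse = ", "))
  domain <- surfaces[[1]]$domain
  grid <- surface_grid(domain, grid_n)
  masks <- lapply(setNames(names(surfaces), names(surfaces)), function(r)
    acceptability_mask(surfaces[[r]], thresholds[[r]], grid))
  region <- intersect_regions(masks, thresholds[names(surfaces)],
                              year = surfaces[[1]]$year)
  if (!region$empty) region$active_constraints <- .active_constraints(region)
  region
}

# Which response's mask stops the projection just beyond each interval
# endpoint: probe one grid line outside the interval and name the responses
# whose mask is empty on that line. If every single mask still has cells
# there, the endpoint comes from the shape of the intersection itself.
.active_constraints <- function(region) {
  grid <- region$grid
  ans <- list()
  for (axis in c("et", "n")) {
    iv <- if (axis == "et") region$et_interval else region$n_interval
    coords <- if (axis == "et") grid$x1 else grid$x2
    for (side in 1:2) {
      key <- paste0(axis, c("_lower", "_upper")[side])
      pos <- which.min(abs(coords - iv[side]))
      probe <- pos + if (side == 1) -1L else 1L
      if (probe < 1 || probe > length(coords)) {
        ans[[key]] <- "domain_edge"
        next
      }
      blocking <- vapply(region$masks, function(m) {
        line <- if (axis == "et") m[probe, ] else m[, probe]
        !any(line)
      }, logical(1))
      nm <- names(blocking)[blocking]
      ans[[key]] <- if (length(nm)) nm else "intersection_shape"
    }
  }
  ans
}

#' Combine two seasons' recommended intervals
#'
#' Per-axis interval intersection: \[max of lower bounds, min of upper
#' bounds\]. Disjoint intervals yield an explicit empty result rather than
#' an error.
#'
#' @param region_a,region_b `accept_region` objects (or lists with
#'   `et_interval` and `n_interval`).
#' @return list with `et_interval`, `n_interval` and `empty` flags per axis;
#'   an empty axis has a `NULL` interval.
#' @export
combine_years <- function(region_a, region_b) {
  if ((inherits(region_a, "accept_region") && region_a$empty) ||
      (inherits(region_b, "accept_region") && region_b$empty))
    stop("cannot combine an empty region")
  comb <- function(i1, i2) {
    lo <- max(i1[1], i2[1]); hi <- min(i1[2], i2[2])
    if (lo > hi) NULL else c(lo, hi)
  }
  et <- comb(region_a$et_interval, region_b$et_interval)
  nn <- comb(region_a$n_interval, region_b$n_interval)
  list(et_interval = et, n_interval = nn,
       empty = c(et = is.null(et), n = is.null(nn)))
}
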