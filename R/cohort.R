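#' Geometric parameters of one synthetic tricuspid valve
#'
#' Bundles the seven measurements that define a pseudo-patient valve:
#' the two principal annular diameters, the annular bending angle, the
#' three leaflet heights, and the prescribed systolic annular area change.
#'
#' @param d_ap Anterior-posterior annular diameter (mm).
#' @param d_sl Septal-lateral annular diameter (mm).
#' @param phi_bend Annular bending angle (degrees); 180 is a flat (planar)
#'   annulus, smaller values fold the annulus about its AP axis.
#' @param h_sept,h_ant,h_post Septal, anterior and posterior leaflet
#'   heights (mm), i.e. the annulus-to-free-edge extent of each leaflet.
#' @param delta_area Prescribed systolic annular area change (percent of the
#'   diastolic area lost during closure).
#'
#' @return An object of class `valve_params` (a named list).
#' @export
#' @examples
#' p <- valve_params(30, 25, 160, 13, 15, 16, 12)
#' p$d_ap
valve_params <- function(d_ap, d_sl, phi_bend, h_sept, h_ant, h_post,
                         delta_area) {
  lengths <- c(d_ap = d_ap, d_sl = d_sl, h_sept = h_sept,
               h_ant = h_ant, h_post = h_post)
  if (any(!is.finite(c(lengths, phi_bend, delta_area))))
    stop("valve parameters must be finite numbers")
  if (any(lengths <= 0))
    stop("all length parameters must be > 0 (offending: ",
         paste(names(lengths)[lengths <= 0], collapse = ", "), ")")
  if (phi_bend <= 0 || phi_bend > 180)
    stop("phi_bend must lie in (0, 180] degrees")
  if (delta_area < 0 || delta_area >= 100)
    stop("delta_area must lie in [0, 100) percent")
  structure(list(d_ap = d_ap, d_sl = d_sl, phi_bend = phi_bend,
                 h_sept = h_sept, h_ant = h_ant, h_post = h_post,
                 delta_area = delta_area),
            class = "valve_params")
}

#' @export
print.valve_params <- function(x, ...) {
  cat("Tricuspid valve geometry parameters:\n")
  cat(sprintf("  annulus: d_ap %.2f mm, d_sl %.2f mm, bending %.1f deg\n",
              x$d_ap, x$d_sl, x$phi_bend))
  cat(sprintf("  leaflet heights (sept/ant/post): %.2f / %.2f / %.2f mm\n",
              x$h_sept, x$h_ant, x$h_post))
  cat(sprintf("  systolic annular area change: %.1f%%\n", x$delta_area))
  invisible(x)
}

#' Default sampling ranges for the pseudo-population
#'
#' Sampling intervals for the seven valve parameters, spanning 100-200% of
#' the cohort-average annular diameters (emulating annular dilation),
#' +/-10% of the average bending angle, +/-50% of the average leaflet
#' heights, and a 5-20% systolic annular area change.
#'
#' @return A named list of `c(lower, upper)` intervals; lengths in mm,
#'   angles in degrees, area change in percent.
#' @export
default_ranges <- function() {
  list(d_ap       = c(20.1, 40.2),
       d_sl       = c(16.5, 33.1),
       phi_bend   = c(143.5, 175.4),
       h_sept     = c(6.6, 19.9),
       h_ant      = c(7.7, 23.0),
       h_post     = c(8.2, 24.5),
       delta_area = c(5, 20))
}

#' Specify a pseudo-population cohort
#'
#' @param n Cohort size (number of pseudo-patients).
#' @param ranges Named list of `c(lower, upper)` sampling intervals for the
#'   seven parameters; defaults to [default_ranges()].
#' @param scheme Sampling scheme: `"uniform"` draws each parameter
#'   independently and uniformly inside its interval; `"grid"` lays a full
#'   factorial grid (levels per parameter chosen to reach at least `n`
#'   points) and keeps the first `n` rows.
#' @param seed Integer RNG seed; the cohort is a pure function of the spec.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100, ranges = default_ranges(),
                        scheme = c("uniform", "grid"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n))
    stop("cohort size must be a non-negative integer")
  wanted <- names(default_ranges())
  missing <- setdiff(wanted, names(ranges))
  if (length(missing))
    stop("ranges is missing parameters: ", paste(missing, collapse = ", "))
  for (nm in wanted) {
    iv <- ranges[[nm]]
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] >= iv[2])
      stop("invalid interval for '", nm, "': lower must be < upper")
  }
  structure(list(n = as.integer(n), ranges = ranges[wanted],
                 scheme = scheme, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Evaluate expr with a temporarily-seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a pseudo-population of valve geometries
#'
#' Draws `spec$n` parameter sets from the cohort specification. With the
#' `"uniform"` scheme every parameter is drawn independently and uniformly
#' inside its interval; the same seed always reproduces the same cohort.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with one row per pseudo-patient and columns
#'   `d_ap, d_sl, phi_bend, h_sept, h_ant, h_post, delta_area`.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_spec(n = 5, seed = 1))
#' nrow(cohort)
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nms <- names(spec$ranges)
  if (spec$n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(nms),
                                dimnames = list(NULL, nms)))
    return(out)
  }
  if (spec$scheme == "uniform") {
    draws <- with_seed(spec$seed, {
      vapply(spec$ranges,
             function(iv) stats::runif(spec$n, iv[1], iv[2]),
             numeric(spec$n))
    })
    out <- as.data.frame(matrix(draws, nrow = spec$n,
                                dimnames = list(NULL, nms)))
  } else {
    k <- max(2L, ceiling(spec$n^(1 / length(nms))))
    levels <- lapply(spec$ranges, function(iv) seq(iv[1], iv[2], length.out = k))
    out <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
    out <- out[seq_len(min(spec$n, nrow(out))), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Convert one cohort row to valve parameters
#'
#' @param row A single-row data frame (or named list) with the seven
#'   parameter columns produced by [sample_cohort()].
#' @return A [valve_params()] object.
#' @export
row_params <- function(row) {
  valve_params(d_ap = row$d_ap, d_sl = row$d_sl, phi_bend = row$phi_bend,
               h_sept = row$h_sept, h_ant = row$h_ant, h_post = row$h_post,
               delta_area = row$delta_area)
}
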