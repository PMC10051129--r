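# Unsupervised binary TR severity grading: two-cluster k-means on the
# natural logarithm of the maximum regurgitant orifice area. In one
# dimension the optimal two-cluster partition is contiguous on the sorted
# data, so it is found exactly by scanning the n-1 split points with
# prefix sums; stats::kmeans with restarts is used only for very large n.

#' Grade TR severity by k-means on log orifice area
#'
#' Clusters `ln(max(ROA, floor))` into two groups; the cluster with the
#' strictly larger center is labeled severe. For cohorts up to
#' `exact_limit` the optimal 1D partition is computed exactly; beyond
#' that, seeded [stats::kmeans()] with restarts is used.
#'
#' @param roa_values Maximum regurgitant orifice areas (mm^2), one per
#'   pseudo-patient.
#' @param floor Lower floor (mm^2) applied before the log transform so
#'   fully coapted valves (ROA = 0) remain finite.
#' @param seed,restarts RNG seed and number of k-means restarts (only used
#'   when the exact path is bypassed; recorded either way).
#' @param exact_limit Largest cohort size for which the exact 1D split is
#'   used.
#' @return An object of class `severity_labeling`: `severe` (0/1 integer
#'   per patient), `centers` (sorted, ln mm^2), `inertia` (within-cluster
#'   sum of squares), `floor`, `seed`, `restarts`, `method`.
#' @export
#' @examples
#' lab <- label_severity(c(0.01, 0.012, 9, 11, 10, 0.011))
#' lab$severe
label_severity <- function(roa_values, floor = 1e-3, seed = 1L,
                           restarts = 10L, exact_limit = 1e4) {
  if (length(roa_values) < 4)
    stop("need at least 4 ROA values to grade severity")
  if (floor <= 0) stop("floor must be > 0")
  x <- log(pmax(roa_values, floor))
  if (diff(range(x)) < 1e-12)
    stop("all ROA values identical after flooring: no valid 2-partition")
  n <- length(x)
  if (n <= exact_limit) {
    sp <- optimal_1d_split(x)
    assign <- sp$assign
    centers <- sp$centers
    inertia <- sp$wcss
    method <- "exact-1d"
  } else {
    km <- with_seed(seed, stats::kmeans(x, centers = 2, nstart = restarts))
    assign <- km$cluster
    centers <- as.vector(km$centers)
    inertia <- km$tot.withinss
    method <- "kmeans"
  }
  hi <- which.max(centers)
  severe <- as.integer(assign == hi)
  structure(list(severe = severe,
                 centers = sort(centers),
                 inertia = inertia, floor = floor, seed = as.integer(seed),
                 restarts = as.integer(restarts), method = method),
            class = "severity_labeling")
}

# Exact optimal contiguous two-segment split of 1D data by within-cluster
# sum of squares, via prefix sums over the sorted values.
optimal_1d_split <- function(x) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  S <- cumsum(xs); S2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  wl <- S2[k] - S[k]^2 / k
  Sr <- S[n] - S[k]; S2r <- S2[n] - S2[k]
  wr <- S2r - Sr^2 / (n - k)
  wcss <- wl + wr
  kbest <- which.min(wcss)
  assign <- integer(n)
  assign[ord] <- ifelse(seq_len(n) <= kbest, 1L, 2L)
  centers <- c(S[kbest] / kbest, (S[n] - S[kbest]) / (n - kbest))
  list(assign = assign, centers = centers, wcss = wcss[kbest],
       split_index = kbest)
}

#' @export
print.severity_labeling <- function(x, ...) {
  cat(sprintf(paste0("TR severity labeling (%s): %d severe / %d total\n",
                     "  centers (ln mm^2): %.3f (non-severe), %.3f (severe); ",
                     "inertia %.4f\n"),
              x$method, sum(x$severe), length(x$severe),
              x$centers[1], x$centers[2], x$inertia))
  invisible(x)
}
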