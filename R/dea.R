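#' Construct a DEA problem
#'
#' Bundles the input and output matrices for one cross-section (typically
#' one calendar year) together with the returns-to-scale assumption. The
#' package solves output-oriented problems only: the Farrell distance
#' \eqn{\theta \ge 1} is the maximal equiproportionate expansion of a DMU's
#' outputs that remains inside the estimated technology, and the reported
#' efficiency score is its reciprocal \eqn{1/\theta \in (0, 1]}.
#'
#' @param X numeric matrix, n DMUs x p inputs, non-negative. Every column
#'   must contain at least one positive entry (all-zero inputs are vacuous
#'   constraints; drop them before building the problem, as
#'   [score_year()] does).
#' @param Y numeric matrix, n DMUs x q outputs, non-negative; no row may be
#'   all zero.
#' @param rts returns to scale, `"vrs"` (BCC, convexity constraint
#'   \eqn{\sum\lambda = 1}) or `"crs"` (CCR, constraint dropped).
#' @param year optional integer label carried through to results.
#' @param dmu_ids optional character ids, defaults to rownames or 1..n.
#' @return an object of class `dea_problem`.
#' @export
dea_problem <- function(X, Y, rts = c("vrs", "crs"), year = NA_integer_,
                        dmu_ids = NULL) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  n <- nrow(X)
  if (n < 1L) stop("need at least one DMU")
  if (anyNA(X) || anyNA(Y)) stop("X/Y contain missing values")
  if (any(X < 0) || any(Y < 0)) stop("inputs and outputs must be non-negative")
  if (any(colSums(X > 0) == 0L))
    stop("input column(s) with no positive entry: ",
         paste(which(colSums(X > 0) == 0L), collapse = ", "))
  if (any(rowSums(Y) <= 0))
    stop("DMU row(s) with all-zero outputs: ",
         paste(which(rowSums(Y) <= 0), collapse = ", "))
  if (is.null(dmu_ids)) {
    dmu_ids <- rownames(X)
    if (is.null(dmu_ids)) dmu_ids <- as.character(seq_len(n))
  }
  structure(list(X = X, Y = Y, rts = rts, year = year,
                 dmu_ids = as.character(dmu_ids)),
            class = "dea_problem")
}

#' @export
print.dea_problem <- function(x, ...) {
  cat(sprintf("<dea_problem> %d DMUs, %d inputs, %d outputs, %s, output-oriented%s\n",
              nrow(x$X), ncol(x$X), ncol(x$Y), toupper(x$rts),
              if (is.na(x$year)) "" else sprintf(", year %d", x$year)))
  invisible(x)
}

# Solve one envelopment LP: evaluate the point (x0, y0) against the
# reference technology spanned by (X, Y).
#   max theta  s.t.  Y'lambda >= theta * y0,  X'lambda <= x0,
#                    [sum lambda = 1 under VRS],  lambda >= 0
# Constraint rows are rescaled before solving: input rows to the
# evaluated DMU's own levels, output rows to the geometric mean of the
# DMU's level and the column mean (a compromise that tames reference sets
# whose outputs span many orders of magnitude), and the theta variable is
# rescaled so its tableau column is O(1) even when the optimal distance
# is huge. Row and variable scaling leave theta unchanged (DEA is units
# invariant); on numerical failure mean-scaled and raw problems are
# retried before giving up.
solve_envelopment <- function(X, Y, x0, y0, rts = "vrs") {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  attempt <- function(sx, sy) {
    y0s <- y0 / sy
    k <- 1 / max(y0s, 1e-300)         # theta-column rescale
    A <- rbind(cbind(t(X) / sx, rep(0, p)),        # p input rows, <=
               cbind(t(Y) / sy, -y0s * k),         # q output rows, >=
               if (rts == "vrs") c(rep(1, n), 0))
    rel <- c(rep(-1L, p), rep(1L, q), if (rts == "vrs") 0L)
    b <- c(x0 / sx, rep(0, q), if (rts == "vrs") 1)
    sol <- .simplex_lp(A, rel, b, c(rep(0, n), 1), TRUE)
    if (sol$status == 0L) sol$objval <- sol$objval * k
    sol
  }
  mx <- pmax(colMeans(X), 1e-12); my <- pmax(colMeans(Y), 1e-12)
  sx <- ifelse(x0 > 0, x0, mx)
  sy <- ifelse(y0 > 0, sqrt(y0 * my), my)
  sol <- attempt(sx, sy)
  if (sol$status != 0L) sol <- attempt(mx, my)
  if (sol$status != 0L) sol <- attempt(rep(1, p), rep(1, q))
  if (sol$status == 1L)
    stop("envelopment LP infeasible (malformed reference set)")
  if (sol$status != 0L)
    stop("envelopment LP failed numerically (status ", sol$status, ")")
  list(theta = sol$objval, lambda = sol$x[seq_len(n)])
}

#' Farrell output distance of one DMU
#'
#' Solves the output-oriented envelopment program for DMU `dmu_index` of a
#' [dea_problem()]: maximize \eqn{\theta} subject to
#' \eqn{Y^\top\lambda \ge \theta y_0}, \eqn{X^\top\lambda \le x_0},
#' \eqn{\sum\lambda = 1} (VRS; dropped under CRS), \eqn{\lambda \ge 0}.
#' The DMU itself is always feasible with \eqn{\theta = 1}, so
#' \eqn{\theta \ge 1} and efficiency \eqn{= 1/\theta \in (0, 1]}.
#'
#' @param problem a [dea_problem()].
#' @param dmu_index integer index of the evaluated DMU.
#' @return a list with `dmu_id`, `theta`, `efficiency` and the intensity
#'   weights `lambda` (an optimal vertex; not unique in general).
#' @export
farrell_output_distance <- function(problem, dmu_index) {
  stopifnot(inherits(problem, "dea_problem"))
  i <- as.integer(dmu_index)
  if (i < 1L || i > nrow(problem$X)) stop("dmu_index out of range")
  sol <- solve_envelopment(problem$X, problem$Y,
                           problem$X[i, ], problem$Y[i, ], problem$rts)
  theta <- max(sol$theta, 1)   # clip solver jitter below the self-feasible 1
  list(dmu_id = problem$dmu_ids[i], theta = theta,
       efficiency = 1 / theta, lambda = sol$lambda)
}

# Distances of every row of (Xe, Ye) against the reference set (X, Y).
# Used by the bootstrap, where the reference outputs are pseudo-outputs
# while evaluated points keep their observed data; bootstrap distances may
# then fall below 1 and are not clipped.
farrell_against_reference <- function(X, Y, Xe, Ye, rts = "vrs") {
  vapply(seq_len(nrow(Xe)), function(i) {
    solve_envelopment(X, Y, Xe[i, ], Ye[i, ], rts)$theta
  }, numeric(1))
}

#' Score all DMUs of one year slice
#'
#' Runs [farrell_output_distance()] for every jurisdiction in a one-year
#' slice of the panel. Input columns that are entirely zero within the year
#' (e.g. a facility type that no longer exists) are vacuous constraints and
#' are dropped before solving, with a message.
#'
#' @param panel_year data frame: one row per DMU for a single year.
#' @param input_cols,output_cols character vectors of column names.
#' @param rts returns to scale, `"vrs"` (default) or `"crs"`.
#' @param id_col,year_col names of the id and year columns.
#' @return data frame with `jurisdiction_id`, `year`, `theta`, `efficiency`.
#' @export
score_year <- function(panel_year, input_cols, output_cols, rts = "vrs",
                       id_col = "jurisdiction_id", year_col = "year") {
  if (nrow(panel_year) < 2L) stop("need at least 2 DMUs in a year slice")
  miss <- setdiff(c(input_cols, output_cols, id_col, year_col),
                  names(panel_year))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  yrs <- unique(panel_year[[year_col]])
  if (length(yrs) != 1L) stop("panel_year must contain exactly one year")
  bad <- !complete.cases(panel_year[, c(input_cols, output_cols)])
  if (any(bad))
    stop("missing values in rows: ", paste(which(bad), collapse = ", "))

  X <- as.matrix(panel_year[, input_cols, drop = FALSE])
  Y <- as.matrix(panel_year[, output_cols, drop = FALSE])
  zero <- colSums(X > 0) == 0L
  if (any(zero)) {
    message("score_year: dropping all-zero input column(s) for year ", yrs,
            ": ", paste(input_cols[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no usable input columns remain")
  pr <- dea_problem(X, Y, rts = rts, year = yrs,
                    dmu_ids = as.character(panel_year[[id_col]]))
  theta <- vapply(seq_len(nrow(X)),
                  function(i) farrell_output_distance(pr, i)$theta,
                  numeric(1))
  data.frame(jurisdiction_id = pr$dmu_ids, year = yrs,
             theta = theta, efficiency = 1 / theta,
             stringsAsFactors = FALSE)
}

#' Concave-hull frontier oracle for single-input single-output problems
#'
#' Independent geometric construction of the output-oriented VRS frontier
#' for the 1-input/1-output case: the least concave monotone envelope of
#' the points (upper concave hull over x, extended flat past the last
#' vertex). Returns the Farrell distance
#' \eqn{\theta_i = \mathrm{frontier}(x_i) / y_i}. Exists to cross-validate
#' the LP route; shares no code with it.
#'
#' @param x,y positive numeric vectors of equal length.
#' @return numeric vector of Farrell distances, one per point.
#' @export
hull_oracle_1in_1out <- function(x, y) {
  stopifnot(length(x) == length(y), all(x > 0), all(y > 0))
  # one candidate frontier point per distinct x: the max y
  agg <- vapply(split(y, x), max, numeric(1))
  xs <- as.numeric(names(agg)); ys <- unname(agg)
  o <- order(xs); xs <- xs[o]; ys <- ys[o]
  # keep only points not dominated from the left (frontier is monotone)
  keep <- ys >= cummax(ys) - 1e-12
  xs <- xs[keep]; ys <- ys[keep]
  # upper concave hull by Andrew's monotone chain
  hx <- numeric(0); hy <- numeric(0)
  for (k in seq_along(xs)) {
    while (length(hx) >= 2) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1]) * (ys[k] - hy[m - 1]) -
               (hy[m] - hy[m - 1]) * (xs[k] - hx[m - 1])
      if (cross >= -1e-12) { hx <- hx[-m]; hy <- hy[-m] } else break
    }
    hx <- c(hx, xs[k]); hy <- c(hy, ys[k])
  }
  frontier <- function(x0) {
    if (x0 <= hx[1]) return(if (x0 < hx[1] - 1e-12) NA_real_ else hy[1])
    if (x0 >= hx[length(hx)]) return(hy[length(hx)])  # flat extension
    k <- findInterval(x0, hx)
    hy[k] + (hy[k + 1] - hy[k]) * (x0 - hx[k]) / (hx[k + 1] - hx[k])
  }
  f <- vapply(x, frontier, numeric(1))
  # points left of the first hull vertex can only envelop themselves
  f[is.na(f)] <- y[is.na(f)]
  pmax(f / y, 1)
}
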