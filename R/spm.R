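#' Time-normalized scalar trajectory
#'
#' @param values numeric vector of Q measurements (e.g. MPa).
#' @param nodes strictly increasing time base (default 0-100% stance over
#'   `length(values)` nodes).
#' @return An object of class `Trajectory`.
#' @export
Trajectory <- function(values, nodes = seq(0, 100, length.out = length(values))) {
  values <- as.numeric(values)
  nodes <- as.numeric(nodes)
  if (length(values) != length(nodes)) stop("values/nodes length mismatch")
  if (any(!is.finite(values))) stop("non-finite trajectory values")
  if (any(diff(nodes) <= 0)) stop("nodes must be strictly increasing")
  structure(list(values = values, nodes = nodes), class = "Trajectory")
}

#' Resample a trajectory onto a common equally spaced time base
#'
#' Linear interpolation onto `Q` nodes spanning the input time range.
#'
#' @param values measurements.
#' @param times measurement times (strictly increasing).
#' @param Q number of output nodes.
#' @return A [Trajectory()] whose nodes span `range(times)`.
#' @export
resample_trajectory <- function(values, times, Q = 101) {
  if (length(values) < 2L) stop("need at least 2 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  grid <- seq(min(times), max(times), length.out = Q)
  Trajectory(stats::approx(times, values, xout = grid)$y, grid)
}

trajectory_matrix <- function(trajs) {
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  if (is.matrix(trajs)) return(trajs)
  Q <- length(trajs[[1]]$values)
  nodes <- trajs[[1]]$nodes
  for (tr in trajs) {
    if (length(tr$values) != Q || max(abs(tr$nodes - nodes)) > 1e-9)
      stop("trajectories must share the same node grid")
  }
  do.call(rbind, lapply(trajs, function(tr) tr$values))
}

#' Estimate residual-field smoothness (FWHM) in node units
#'
#' Standard 1-D random-field smoothness estimator:
#' `FWHM = sqrt(4 log 2) / RMS gradient` of the unit-variance-normalized
#' residual curves.
#'
#' @param residuals n x Q matrix of residual curves.
#' @return FWHM in node units.
#' @export
estimate_fwhm <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 2L) stop("need at least 2 residual curves")
  ssq <- colSums(residuals^2)
  if (any(ssq <= 0)) stop("zero-variance residuals")
  dr <- residuals[, -1L, drop = FALSE] - residuals[, -ncol(residuals),
                                                   drop = FALSE]
  v <- colSums(dr^2) / sqrt(ssq[-1L] * ssq[-length(ssq)])
  if (mean(v) <= 0) stop("zero-variance residuals (constant curves)")
  sqrt(4 * log(2) / mean(v))
}

# expected Euler characteristic of a 1-D t field above u (two EC densities)
ec_t_field <- function(u, df, resels) {
  p0 <- stats::pt(u, df, lower.tail = FALSE)
  p1 <- resels * sqrt(4 * log(2)) / (2 * pi) *
    (1 + u^2 / df)^(-(df - 1) / 2)
  p0 + p1
}

#' Random-field-theory critical t threshold for a 1-D field
#'
#' Smallest `t` with expected suprathreshold Euler characteristic (the RFT
#' approximation to `P(max |t| field| > t)`) at most `alpha`, for a field of
#' `Q` nodes and smoothness `fwhm` (resel count `(Q-1)/fwhm`), solved by
#' bisection to 1e-6.  With `two_tailed = TRUE` (default) the budget is
#' split across both tails.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @param Q number of field nodes.
#' @param fwhm field smoothness in node units (> 0).
#' @param two_tailed split `alpha` over both tails.
#' @return Critical t value.
#' @export
rft_critical_t <- function(alpha = 0.05, df, Q, fwhm, two_tailed = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  if (fwhm <= 0) stop("fwhm must be > 0")
  a <- if (two_tailed) alpha / 2 else alpha
  resels <- (Q - 1) / fwhm
  f <- function(u) ec_t_field(u, df, resels) - a
  lo <- 0
  hi <- 10
  while (f(hi) > 0) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Two-sample 1-D SPM t-test with RFT inference
#'
#' Pointwise pooled-variance (or Welch) two-sample t statistic along the
#' trajectory, residual smoothness estimation, RFT critical threshold at
#' `alpha`, and suprathreshold clusters of `|t|`.
#'
#' @param groupA,groupB lists of [Trajectory()] objects (or n x Q matrices)
#'   on a common node grid, each with >= 2 members.
#' @param alpha family-wise error rate.
#' @param two_tailed threshold `|t|` with `alpha` split over both tails.
#' @param welch use the Welch (unpooled) statistic.
#' @return An `SPMResult` list: `t_curve`, `df`, `fwhm_est`, `t_critical`,
#'   `clusters` (list of node-index ranges), `significant`, `nodes`.
#' @export
spm_ttest2 <- function(groupA, groupB, alpha = 0.05, two_tailed = TRUE,
                       welch = FALSE) {
  A <- trajectory_matrix(groupA)
  B <- trajectory_matrix(groupB)
  if (ncol(A) != ncol(B)) stop("groups have different numbers of nodes")
  nA <- nrow(A)
  nB <- nrow(B)
  if (nA < 2L || nB < 2L) stop("need at least 2 trajectories per group")
  Q <- ncol(A)
  mA <- colMeans(A)
  mB <- colMeans(B)
  vA <- apply(A, 2L, stats::var)
  vB <- apply(B, 2L, stats::var)
  if (welch) {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    df <- min(df)
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  }
  t_curve <- (mA - mB) / se
  resid <- rbind(sweep(A, 2L, mA), sweep(B, 2L, mB))
  fwhm <- estimate_fwhm(resid)
  t_crit <- rft_critical_t(alpha, df, Q, fwhm, two_tailed = two_tailed)
  over <- if (two_tailed) abs(t_curve) > t_crit else t_curve > t_crit
  clusters <- runs_true(over)
  nodes <- if (inherits(groupA[[1]], "Trajectory")) groupA[[1]]$nodes
           else seq(0, 100, length.out = Q)
  structure(list(t_curve = t_curve, df = df, fwhm_est = fwhm,
                 t_critical = t_crit, clusters = clusters,
                 significant = length(clusters) > 0L, nodes = nodes,
                 alpha = alpha, two_tailed = two_tailed),
            class = "SPMResult")
}

runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(function(s, e) c(start = s, end = e),
      starts[r$values], ends[r$values])
}

#' @export
print.SPMResult <- function(x, ...) {
  cat(sprintf(paste0("SPMResult: max|t| %.3f vs t* %.3f (df %.1f, ",
                     "FWHM %.1f nodes) -> %s\n"),
              max(abs(x$t_curve)), x$t_critical, x$df, x$fwhm_est,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Read stance-phase trajectories from long-format CSV
#'
#' Expected columns: `subject`, `group`, `time_pct`, `parameter`, `value`
#' (optionally `zone`).  Returns, for one parameter (and zone), the two
#' groups as lists of trajectories resampled to `Q` common nodes.
#'
#' @param path CSV path.
#' @param parameter parameter name to extract.
#' @param zone optional zone filter (e.g. "superficial", "deep").
#' @param Q common node count.
#' @return List with elements `groups` (named list of trajectory lists) and
#'   `parameter`.
#' @export
read_trajectories_csv <- function(path, parameter = NULL, zone = NULL, Q = 101) {
  d <- utils::read.csv(path)
  need <- c("subject", "group", "time_pct", "parameter", "value")
  if (!all(need %in% names(d)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(parameter)) d <- d[d$parameter == parameter, ]
  if (!is.null(zone) && "zone" %in% names(d)) d <- d[d$zone == zone, ]
  if (nrow(d) == 0L) stop("no rows left after filtering")
  groups <- lapply(split(d, d$group), function(g) {
    lapply(split(g, g$subject), function(s) {
      s <- s[order(s$time_pct), ]
      resample_trajectory(s$value, s$time_pct, Q)
    })
  })
  list(groups = groups, parameter = parameter)
}

#' Write an SPM result as JSON plus a plot-ready CSV of the t curve
#'
#' @param result an `SPMResult`.
#' @param json_path output JSON path (`NULL` to skip).
#' @param csv_path output CSV path with columns `node`, `t`, `t_critical`
#'   (`NULL` to skip).
#' @export
write_spm_result <- function(result, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(result, "SPMResult"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(t_curve = result$t_curve, df = result$df,
           fwhm_est = result$fwhm_est, t_critical = result$t_critical,
           clusters = result$clusters, significant = result$significant,
           alpha = result$alpha, two_tailed = result$two_tailed),
      json_path, digits = NA, auto_unbox = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(node = result$nodes, t = result$t_curve,
                                t_critical = result$t_critical),
                     csv_path, row.names = FALSE)
  }
  invisible(result)
}
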