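# Output-oriented data envelopment analysis.
#
# For a unit (hospital) 0 with inputs x0 and outputs y0 evaluated against
# a frontier set J, the radial output-expansion LP is
#
#   max phi  s.t.  sum_j lambda_j x_j <= x0   (componentwise)
#                  sum_j lambda_j y_j >= phi * y0
#                  lambda >= 0, and sum_j lambda_j = 1 under VRS.
#
# Technical efficiency is te = 1 / phi in (0, 1]. A second phase maximises
# total slack at fixed phi to obtain deterministic peers and projected
# targets under degenerate optima. The dual (multiplier) form, used as an
# internal cross-check, is
#
#   min nu'x0 + omega  s.t.  mu'y0 = 1,  nu'x_j - mu'y_j + omega >= 0,
#   nu, mu >= 0, omega free (omega = 0 under CRS).

PEER_TOL <- 1e-6

as_dea_matrix <- function(frontier) {
  list(X = t(as.matrix(frontier$inputs)), Y = t(as.matrix(frontier$outputs)))
}

#' Build DEA inputs from hospital aggregates
#'
#' Inputs are bed count and the simplicity index; the single output is the
#' safety rate in percent. A safety rate of 0 is replaced by
#' `epsilon_output` (radial output expansion requires positive outputs)
#' and a zero simplicity index is clamped to a tiny positive value, both
#' with a warning.
#'
#' @param aggregates a `hospital_aggregates` table.
#' @param epsilon_output replacement for a zero safety rate, on the
#'   percent scale.
#' @return data.frame with `dmu_id`, `group`, input columns `beds`,
#'   `simplicity` and output column `safety_rate`, plus an attribute
#'   layout used by the solvers.
#' @export
dea_inputs <- function(aggregates, epsilon_output = 0.1) {
  out <- data.frame(dmu_id = aggregates$hospital_id,
                    group = as.character(aggregates$region),
                    beds = as.numeric(aggregates$beds),
                    simplicity = aggregates$simplicity,
                    safety_rate = aggregates$safety_rate,
                    stringsAsFactors = FALSE)
  zero_y <- out$safety_rate <= 0
  if (any(zero_y)) {
    warning(sum(zero_y), " DMU(s) with zero safety rate replaced by ",
            epsilon_output)
    out$safety_rate[zero_y] <- epsilon_output
  }
  zero_x <- out$simplicity <= 0
  if (any(zero_x)) {
    warning(sum(zero_x), " DMU(s) with zero simplicity clamped to 1e-6")
    out$simplicity[zero_x] <- 1e-6
  }
  out
}

# Internal: extract input/output matrices (m x n, s x n) from a dea_inputs
# frame given declared column roles.
dea_xy <- function(d, input_cols = c("beds", "simplicity"),
                   output_cols = "safety_rate") {
  list(X = t(as.matrix(d[, input_cols, drop = FALSE])),
       Y = t(as.matrix(d[, output_cols, drop = FALSE])),
       ids = d$dmu_id)
}

#' Solve the output-oriented envelopment problem for one DMU
#'
#' @param x0,y0 numeric input and output vectors of the evaluated unit
#'   (all positive).
#' @param X,Y frontier input (m x n) and output (s x n) matrices, columns
#'   are frontier DMUs.
#' @param rts returns-to-scale assumption: `"vrs"` (adds the convexity
#'   constraint `sum(lambda) = 1`) or `"crs"`.
#' @param frontier_ids optional DMU ids naming the frontier columns.
#' @return list of class `dea_result`: `phi`, `te = 1/phi`, `lambda`,
#'   `slack_in`, `slack_out`, `targets` (projected inputs/outputs),
#'   `peers` (ids with `lambda > 1e-6`, ascending id), `is_efficient`.
#' @export
solve_output_oriented <- function(x0, y0, X, Y, rts = c("vrs", "crs"),
                                  frontier_ids = NULL) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  stopifnot(n >= 1, ncol(Y) == n, length(x0) == m, length(y0) == s)
  if (any(x0 <= 0) || any(y0 <= 0) || any(X <= 0) || any(Y <= 0))
    stop("DEA requires strictly positive inputs and outputs")
  if (is.null(frontier_ids)) frontier_ids <- sprintf("D%03d", seq_len(n))

  # Phase 1: maximise phi. Variables: (phi, lambda_1..n).
  A1 <- rbind(cbind(0, X),                      # inputs:  X lambda <= x0
              cbind(-y0, Y))                    # outputs: Y lambda - phi y0 >= 0
  dir1 <- c(rep("<=", m), rep(">=", s))
  rhs1 <- c(x0, rep(0, s))
  if (rts == "vrs") {
    A1 <- rbind(A1, c(0, rep(1, n)))
    dir1 <- c(dir1, "=")
    rhs1 <- c(rhs1, 1)
  }
  sol1 <- simplex_solve(c(1, rep(0, n)), A1, dir1, rhs1, maximise = TRUE)
  if (sol1$status != "optimal")
    stop("envelopment LP not solvable (status: ", sol1$status,
         "); check frontier positivity / RTS")
  phi <- sol1$value

  # Phase 2: maximise total slack at fixed phi.
  # Variables: (lambda_1..n, s_in_1..m, s_out_1..s).
  A2 <- rbind(cbind(X, diag(m), matrix(0, m, s)),
              cbind(Y, matrix(0, s, m), -diag(s)))
  dir2 <- rep("=", m + s)
  rhs2 <- c(x0, phi * y0)
  if (rts == "vrs") {
    A2 <- rbind(A2, c(rep(1, n), rep(0, m + s)))
    dir2 <- c(dir2, "=")
    rhs2 <- c(rhs2, 1)
  }
  obj2 <- c(rep(0, n), rep(1, m + s))
  sol2 <- simplex_solve(obj2, A2, dir2, rhs2, maximise = TRUE)
  if (sol2$status != "optimal")
    stop("slack-maximisation LP failed (status: ", sol2$status, ")")
  lambda <- sol2$x[seq_len(n)]
  slack_in <- sol2$x[n + seq_len(m)]
  slack_out <- sol2$x[n + m + seq_len(s)]
  names(lambda) <- frontier_ids

  peers <- frontier_ids[lambda > PEER_TOL]
  peers <- peers[order(peers)]
  te <- 1 / phi
  structure(list(
    phi = phi, te = te, lambda = lambda,
    slack_in = slack_in, slack_out = slack_out,
    targets = list(inputs = x0 - slack_in, outputs = phi * y0 + slack_out),
    peers = peers,
    is_efficient = abs(phi - 1) < 1e-7 && all(slack_in < 1e-6) &&
      all(slack_out < 1e-6),
    rts = rts), class = "dea_result")
}

#' Output-oriented efficiency via the dual (multiplier) LP
#'
#' Cross-check formulation: returns the same `phi` as the envelopment
#' problem by LP duality.
#'
#' @inheritParams solve_output_oriented
#' @return list with `phi` and `te`.
#' @export
solve_output_oriented_dual <- function(x0, y0, X, Y, rts = c("vrs", "crs")) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  if (any(x0 <= 0) || any(y0 <= 0) || any(X <= 0) || any(Y <= 0))
    stop("DEA requires strictly positive inputs and outputs")
  # Variables: nu (m), mu (s), and under VRS omega = wp - wm (free).
  nfree <- if (rts == "vrs") 2L else 0L
  obj <- c(x0, rep(0, s), if (rts == "vrs") c(1, -1))
  A <- rbind(c(rep(0, m), y0, rep(0, nfree)),
             cbind(t(X), -t(Y),
                   if (rts == "vrs") matrix(rep(c(1, -1), each = n), n, 2)
                   else NULL))
  dir <- c("=", rep(">=", n))
  rhs <- c(1, rep(0, n))
  sol <- simplex_solve(obj, A, dir, rhs, maximise = FALSE)
  if (sol$status != "optimal")
    stop("multiplier LP not solvable (status: ", sol$status, ")")
  list(phi = sol$value, te = 1 / sol$value)
}

#' Score every hospital against its regional and the state frontier
#'
#' Each DMU is scored against (a) the DMUs of its own region ("group"
#' frontier) and (b) all DMUs pooled ("meta"/state frontier). A singleton
#' region scores itself efficient with a logged caveat. The comparison
#' table reports the metatechnology ratio `te_meta / te_group`.
#'
#' @param aggregates a `hospital_aggregates` table (or a `dea_inputs`
#'   frame).
#' @param rts `"vrs"` (default) or `"crs"`.
#' @param epsilon_output see [dea_inputs()].
#' @return list with `scores` (one row per DMU x frontier: `phi`,
#'   `te` as fraction, `te_pct`, slacks, targets, `is_efficient`),
#'   `peers` (long table `dmu_id`, `frontier`, `peer_id`, `lambda`) and
#'   `comparison` (per DMU: `te_group`, `te_meta`,
#'   `metatechnology_ratio`).
#' @export
score_frontiers <- function(aggregates, rts = c("vrs", "crs"),
                            epsilon_output = 0.1) {
  rts <- match.arg(rts)
  d <- if (inherits(aggregates, "hospital_aggregates"))
    dea_inputs(aggregates, epsilon_output) else aggregates
  singletons <- names(which(table(d$group) == 1))
  if (length(singletons) > 0)
    message("singleton region(s) scored as self-efficient: ",
            paste(singletons, collapse = ", "))

  score_one <- function(i, frontier_rows, frontier_label) {
    xy <- dea_xy(d[frontier_rows, , drop = FALSE])
    res <- solve_output_oriented(
      x0 = c(d$beds[i], d$simplicity[i]), y0 = d$safety_rate[i],
      X = xy$X, Y = xy$Y, rts = rts, frontier_ids = xy$ids)
    list(row = data.frame(
      dmu_id = d$dmu_id[i], region = d$group[i], frontier = frontier_label,
      rts = rts, phi = res$phi, te = res$te, te_pct = 100 * res$te,
      slack_beds = res$slack_in[1], slack_simplicity = res$slack_in[2],
      slack_safety = res$slack_out[1],
      target_beds = res$targets$inputs[1],
      target_simplicity = res$targets$inputs[2],
      target_safety = res$targets$outputs[1],
      is_efficient = res$is_efficient, stringsAsFactors = FALSE),
      peers = if (length(res$peers) > 0) data.frame(
        dmu_id = d$dmu_id[i], frontier = frontier_label,
        peer_id = res$peers,
        lambda = unname(res$lambda[res$peers]),
        stringsAsFactors = FALSE) else NULL)
  }

  rows <- list(); peer_rows <- list()
  for (i in seq_len(nrow(d))) {
    grp_rows <- which(d$group == d$group[i])
    g <- score_one(i, grp_rows, "group")
    m <- score_one(i, seq_len(nrow(d)), "meta")
    rows[[length(rows) + 1]] <- g$row
    rows[[length(rows) + 1]] <- m$row
    peer_rows[[length(peer_rows) + 1]] <- g$peers
    peer_rows[[length(peer_rows) + 1]] <- m$peers
  }
  scores <- do.call(rbind, rows)
  peers <- do.call(rbind, peer_rows)

  te_g <- scores$te[scores$frontier == "group"]
  te_m <- scores$te[scores$frontier == "meta"]
  ids <- scores$dmu_id[scores$frontier == "group"]
  comparison <- data.frame(
    dmu_id = ids,
    region = scores$region[scores$frontier == "group"],
    te_group = te_g,
    te_meta = te_m[match(ids, scores$dmu_id[scores$frontier == "meta"])],
    stringsAsFactors = FALSE)
  comparison$metatechnology_ratio <- comparison$te_meta / comparison$te_group
  list(scores = scores, peers = peers, comparison = comparison)
}

#' Bootstrap percentile interval for a weighted mean efficiency
#'
#' Naive percentile bootstrap over DMUs resampled with replacement
#' (smoothed DEA bootstraps are out of scope and noted as such in the
#' methods vignette).
#'
#' @param te_scores numeric efficiency scores.
#' @param weights non-negative weights (e.g. episode counts); default
#'   uniform.
#' @param B number of resamples (>= 2).
#' @param alpha two-sided level, in (0, 1).
#' @param seed integer seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(te_scores, weights = NULL, B = 1000L,
                         alpha = 0.05, seed = 1L) {
  if (B < 2) stop("bootstrap requires B >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- length(te_scores)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  if (n == 1) {
    warning("single DMU: degenerate bootstrap interval")
    return(c(te_scores, te_scores))
  }
  set.seed(seed)
  stat <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    stats::weighted.mean(te_scores[idx], weights[idx])
  }, numeric(1))
  unname(stats::quantile(stat, c(alpha / 2, 1 - alpha / 2)))
}

#' Regional mean efficiency with bootstrap confidence intervals
#'
#' Per-region weighted mean technical efficiency (percent) with
#' percentile-bootstrap CIs, plus the overall weighted mean over all
#' DMUs. Weights default to hospital episode counts.
#'
#' @param scores the `scores` table from [score_frontiers()], restricted
#'   to one frontier (or pass `frontier` to filter).
#' @param weights named vector of DMU weights (names = dmu_id); `NULL` =
#'   uniform.
#' @param frontier which frontier to summarise (`"group"` or `"meta"`).
#' @param B,alpha,seed bootstrap settings, see [bootstrap_ci()].
#' @return data.frame with one row per region plus an `"average"` row:
#'   `mean_te_pct`, `ci_low_pct`, `ci_high_pct`, `n_dmus`.
#' @export
group_mean_scores <- function(scores, weights = NULL,
                              frontier = c("group", "meta"),
                              B = 1000L, alpha = 0.05, seed = 1L) {
  frontier <- match.arg(frontier)
  sc <- scores[scores$frontier == frontier, , drop = FALSE]
  if (nrow(sc) == 0) stop("no scores for frontier '", frontier, "'")
  w <- if (is.null(weights)) stats::setNames(rep(1, nrow(sc)), sc$dmu_id)
       else weights
  if (!all(sc$dmu_id %in% names(w)))
    stop("weights must cover every DMU")
  w <- w[sc$dmu_id]
  regions <- unique(as.character(sc$region))
  out <- lapply(c(regions, "average"), function(r) {
    sel <- if (r == "average") rep(TRUE, nrow(sc)) else sc$region == r
    te <- sc$te[sel]; ww <- w[sel]
    ci <- bootstrap_ci(te, ww, B = B, alpha = alpha,
                       seed = seed + match(r, c(regions, "average")))
    data.frame(region = r,
               mean_te_pct = 100 * stats::weighted.mean(te, ww),
               ci_low_pct = 100 * ci[1], ci_high_pct = 100 * ci[2],
               n_dmus = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
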