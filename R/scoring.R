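#' PC1 score for a block of correlated behavioral metrics
#'
#' Standardizes the metric columns (zero mean, unit variance: PCA of the
#' correlation matrix) and returns the first principal component as the
#' behavioral score, with the fraction of variance it explains and the
#' loadings. The sign of a principal component is arbitrary, so the
#' component is flipped if its loading on `orientation_metric` is negative
#' -- the convention that positive scores mean "more of the trait".
#'
#' @param metric_matrix numeric matrix or data.frame, one row per
#'   (individual, trial), one column per metric (>= 2 columns, >= 3 rows).
#'   Rows with missing values are dropped with a warning.
#' @param orientation_metric column name whose loading is forced positive.
#' @param standardize logical; standardize columns (default TRUE).
#' @return list with `scores` (named by rownames), `variance_fraction`,
#'   `loadings`, and `dropped` (row indices removed as incomplete).
#' @export
pc1_score <- function(metric_matrix, orientation_metric,
                      standardize = TRUE) {
  m <- as.matrix(metric_matrix)
  if (ncol(m) < 2) stop("need at least 2 metric columns")
  if (!orientation_metric %in% colnames(m))
    stop("orientation_metric '", orientation_metric, "' not a column")
  cc <- complete.cases(m)
  dropped <- which(!cc)
  if (length(dropped)) {
    warning(length(dropped), " incomplete rows dropped before PCA")
    m <- m[cc, , drop = FALSE]
  }
  if (nrow(m) < 3) stop("need at least 3 complete rows")
  if (nrow(m) < ncol(m)) warning("fewer rows than metric columns")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  pr <- prcomp(m, center = TRUE, scale. = standardize)
  scores <- pr$x[, 1]
  loadings <- pr$rotation[, 1]
  if (loadings[orientation_metric] < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = scores,
       variance_fraction = pr$sdev[1]^2 / sum(pr$sdev^2),
       loadings = loadings,
       dropped = dropped)
}

# metric sets and orientation conventions per behavioral axis; min-distance
# and latency metrics are negated so that positive = more of the trait
axis_definitions <- function() {
  list(
    exploration = list(
      metrics = c("approaches", "time_outside_s", "min_distance_px",
                  "interaction_time_s"),
      negate = "min_distance_px",
      orientation = "interaction_time_s",
      test = "exploration"),
    sociability = list(
      metrics = c("time_outside_s", "min_distance_px", "interaction_time_s"),
      negate = "min_distance_px",
      orientation = "interaction_time_s",
      test = "sociability"),
    boldness = list(
      metrics = c("head_latency_s", "body_latency_s", "bite_latency_s"),
      negate = c("head_latency_s", "body_latency_s", "bite_latency_s"),
      orientation = "head_latency_s",
      test = "boldness"),
    activity = list(
      metrics = c("time_outside_s", "total_distance_px", "turn_mu_rad",
                  "turn_kappa", "area95_px2", "area50_px2"),
      negate = character(0),
      orientation = "total_distance_px",
      test = "activity"))
}

#' Assemble the metric matrix for one behavioral axis
#'
#' Pivots a long metrics table to the wide matrix expected by
#' [pc1_score()], selecting exactly the metrics that define the axis:
#' exploration (4 metrics: approaches, time outside, min distance,
#' interaction time), sociability (3), boldness (3 latencies), activity (6).
#' Min-distance and latency columns are negated so that larger values mean
#' more exploratory / more social / bolder.
#'
#' @param metrics long `data.frame` with columns `id`, `trial`, `test`,
#'   `metric`, `value`.
#' @param axis one of `"exploration"`, `"sociability"`, `"boldness"`,
#'   `"activity"`.
#' @return numeric matrix, rows named `id:trial`, with an `orientation`
#'   attribute naming the orientation metric.
#' @export
prepare_axis_inputs <- function(metrics, axis) {
  defs <- axis_definitions()
  if (!axis %in% names(defs)) stop("unknown axis: ", axis)
  def <- defs[[axis]]
  sub <- metrics[metrics$test == def$test & metrics$metric %in% def$metrics, ]
  missing <- setdiff(def$metrics, unique(sub$metric))
  if (length(missing))
    stop("missing required metric(s) for ", axis, ": ",
         paste(missing, collapse = ", "))
  key <- paste(sub$id, sub$trial, sep = ":")
  wide <- matrix(NA_real_, nrow = length(unique(key)),
                 ncol = length(def$metrics),
                 dimnames = list(unique(key), def$metrics))
  for (mname in def$metrics) {
    rows <- sub[sub$metric == mname, ]
    wide[paste(rows$id, rows$trial, sep = ":"), mname] <- rows$value
  }
  for (mname in def$negate) wide[, mname] <- -wide[, mname]
  structure(wide, orientation = def$orientation)
}

#' Transform PC scores for mixed-model residual normality
#'
#' Exploration and sociability scores are log-transformed before model
#' fitting. PC scores are signed, so a positivity shift is applied first:
#' `y' = log(y - min(y) + 1)`; the shift constant is recorded in the
#' `shift` attribute. Other axes are returned unchanged.
#'
#' @param scores numeric vector of PC1 scores.
#' @param axis behavioral axis name.
#' @return transformed scores (with a `shift` attribute when transformed).
#' @export
transform_for_lmm <- function(scores, axis) {
  if (!axis %in% c("exploration", "sociability")) return(scores)
  shift <- 1 - min(scores)
  out <- log(scores + shift)
  attr(out, "shift") <- shift
  out
}

#' Score all behavioral axes from a long metrics table
#'
#' Runs one PCA per axis present in the metrics table and returns scores in
#' long format, applying the axis transform ([transform_for_lmm()]) when
#' `transform = TRUE`. Aggressiveness is not PCA-derived (single metric,
#' approach counts) and is passed through unchanged when present as an
#' `approaches` metric under test `"aggressiveness"`.
#'
#' @param metrics long metrics `data.frame` (`id`, `trial`, `test`,
#'   `metric`, `value`).
#' @param axes axes to score (default: all four PCA axes).
#' @param transform apply the log-shift transform to exploration and
#'   sociability scores.
#' @return list with `scores` (long `data.frame`: `id`, `trial`, `axis`,
#'   `score`) and `pca` (per-axis variance fractions and loadings).
#' @export
score_axes <- function(metrics, axes = c("exploration", "sociability",
                                         "boldness", "activity"),
                       transform = TRUE) {
  score_rows <- list(); pca_info <- list()
  for (ax in axes) {
    mat <- prepare_axis_inputs(metrics, ax)
    res <- pc1_score(mat, attr(mat, "orientation"))
    sc <- res$scores
    if (transform) sc <- as.numeric(transform_for_lmm(sc, ax))
    ids <- strsplit(names(res$scores), ":", fixed = TRUE)
    score_rows[[ax]] <- data.frame(
      id = vapply(ids, `[`, "", 1),
      trial = as.integer(vapply(ids, `[`, "", 2)),
      axis = ax, score = sc, row.names = NULL)
    pca_info[[ax]] <- list(variance_fraction = res$variance_fraction,
                           loadings = res$loadings)
  }
  agg <- metrics[metrics$test == "aggressiveness" &
                   metrics$metric == "approaches", ]
  if (nrow(agg)) {
    score_rows$aggressiveness <- data.frame(
      id = agg$id, trial = agg$trial, axis = "aggressiveness",
      score = agg$value, row.names = NULL)
  }
  list(scores = do.call(rbind, c(score_rows, list(make.row.names = FALSE))),
       pca = pca_info)
}
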