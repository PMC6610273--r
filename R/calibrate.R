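# Calibration of the measurement parameters (shell distance D and the
# probability window T_L, T_H) against ordinal visual scores: stratified
# training-set sampling over severity categories, exhaustive grid search
# maximizing the Pearson correlation with the total visual score, and
# leave-one-out assessment of the atlas-driven tendon segmentation.

#' Severity category from a score sheet
#'
#' Patients are stratified by V_max, the maximum per-region visual grade:
#' category 0 has V_max = 0, category 1 has 0 < V_max <= 1, category 2 has
#' 1 < V_max <= 3.
#'
#' @param scores a [visual_score_sheet()].
#' @return Integer category index (0, 1 or 2).
#' @export
categorize_vmax <- function(scores) {
  stopifnot(inherits(scores, "visual_score_sheet"))
  vmax <- max(scores$grades)
  if (vmax == 0) 0L else if (vmax <= 1) 1L else 2L
}

#' Stratified training/validation split
#'
#' Uniform random sampling without replacement of `n_per_category` patients
#' from each severity category; everyone else forms the validation set.
#' Balancing the training set over the categories guarantees the rarer
#' moderate-severe patients are represented when the parameters are tuned.
#' Deterministic given `seed`.
#'
#' @param categories integer vector of per-patient category indices (0-2).
#' @param n_per_category training patients drawn per category (default 20).
#' @param seed integer seed.
#' @return List with integer index vectors `training` and `validation`.
#' @export
sample_training_set <- function(categories, n_per_category = 20, seed = 1L) {
  categories <- as.integer(categories)
  ids <- with_seed(seed, {
    unlist(lapply(0:2, function(k) {
      members <- which(categories == k)
      if (length(members) < n_per_category)
        stop("category ", k, " has only ", length(members),
             " patients, need ", n_per_category, call. = FALSE)
      sort(members[sample.int(length(members), n_per_category)])
    }))
  })
  training <- sort(ids)
  list(training = training,
       validation = setdiff(seq_along(categories), training))
}

#' Pearson correlation with t-based p value
#'
#' Product-moment correlation between the quantitative measurement and the
#' visual score total, with the two-sided p value from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (length >= 3, both non-constant).
#' @return Named numeric: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two vectors of equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Cumulative counts #{p < t} of a probability sample at the threshold grid
# t = 0, step, ..., 1. Column k corresponds to threshold (k-1)*step.
cum_below <- function(p, step = 0.01) {
  # round so grid thresholds are bitwise the literal multiples of `step`
  # (seq() accumulates float error, which would flip the half-open boundary)
  breaks <- round(seq(0, 1, by = step), 10)
  # findInterval with left-open intervals counts p < t exactly for grid t
  counts <- vapply(breaks, function(t) sum(p < t), 0L)
  counts
}

#' Exhaustive grid search for (D, T_L, T_H)
#'
#' Sweeps the shell distance over the supplied D values and every ordered
#' threshold pair on the step-0.01 grid (`0 <= T_L < T_H <= 1`, 5050 pairs
#' per D), returning the parameter set maximizing the Pearson correlation
#' between the per-patient fraction and the total visual score. Ties
#' resolve to the lexicographically smallest `(D, T_L, T_H)`.
#'
#' The sweep is performed on per-patient cumulative histograms of the
#' one-sided C2 probabilities inside the ROI, so after the per-(patient, D)
#' measurement its cost is independent of image size: for thresholds `t`,
#' `fraction(T_L, T_H) = (cum(T_H) - cum(T_L)) / n_ROI`, and the
#' correlations for all pairs follow from the 101-point covariance
#' structure of the cumulative fractions.
#'
#' @param pvals nested list: `pvals[[d]][[i]]` is the numeric vector of
#'   one-sided C2 probabilities inside patient i's ROI at distance
#'   `D_values[d]` (may be empty for an empty ROI).
#' @param totals numeric vector of per-patient total visual scores.
#' @param D_values distances (mm) corresponding to the first index of
#'   `pvals` (default 1:6).
#' @param step threshold grid step (default 0.01).
#' @return An object of class `parameter_set`: `D`, `t_low`, `t_high`, `r`.
#' @export
grid_search <- function(pvals, totals, D_values = 1:6, step = 0.01) {
  stopifnot(length(pvals) == length(D_values))
  n_pat <- length(totals)
  if (length(unique(totals)) < 2)
    stop("training totals must span at least two distinct values", call. = FALSE)
  y <- totals - mean(totals)
  sy <- sqrt(sum(y^2))
  n_grid <- length(seq(0, 1, by = step))

  best <- list(r = -Inf, D = NA_real_, t_low = NA_real_, t_high = NA_real_)
  for (d in order(D_values)) {
    FF <- matrix(0, n_pat, n_grid)
    for (i in seq_len(n_pat)) {
      p <- pvals[[d]][[i]]
      if (length(p))
        FF[i, ] <- cum_below(p, step) / length(p)
    }
    Fc <- sweep(FF, 2, colMeans(FF))
    cvec <- as.numeric(crossprod(Fc, y))        # sum over patients of Fc * y
    S <- crossprod(Fc)                          # n_grid x n_grid
    dS <- diag(S)
    # r(L, H) = (c_H - c_L) / (sy * sqrt(S_HH + S_LL - 2 S_HL))
    num <- outer(cvec, cvec, function(h, l) h - l)       # [H, L]
    den2 <- outer(dS, dS, `+`) - 2 * S                   # [H, L]
    r_mat <- num / (sy * sqrt(pmax(den2, 0)))
    r_mat[den2 <= 1e-24] <- NA_real_
    for (Li in 1:(n_grid - 1)) {          # lexicographic: T_L, then T_H
      for (Hi in (Li + 1):n_grid) {
        r <- r_mat[Hi, Li]
        if (!is.na(r) && r > best$r + 1e-12) {
          best <- list(r = r, D = D_values[d],
                       t_low = round((Li - 1) * step, 10),
                       t_high = round((Hi - 1) * step, 10))
        }
      }
    }
  }
  if (!is.finite(best$r))
    stop("all correlations undefined on the grid", call. = FALSE)
  structure(best[c("D", "t_low", "t_high", "r")], class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> D = %g mm, T_L = %.2f, T_H = %.2f (training r = %.4f)\n",
              x$D, x$t_low, x$t_high, x$r))
  invisible(x)
}

#' Leave-one-out cross-validation of atlas-driven tendon segmentation
#'
#' Holds out each atlas case in turn, segments it with the remaining cases
#' through `segmenter`, and scores per-region precision and recall against
#' the held-out manual labels. A region with empty automatic output is a
#' failed segmentation: it is counted per region and excluded from the
#' medians.
#'
#' @param atlas an [atlas_set()] with at least two cases.
#' @param segmenter function `(target_image, atlas_subset) ->`
#'   [region_label_map()] of segmented tendons on the target grid.
#' @return data.frame with one row per tendon region: median and IQR of
#'   precision and recall, and the failure count.
#' @export
loocv_atlas <- function(atlas, segmenter) {
  stopifnot(inherits(atlas, "atlas_set"))
  n <- length(atlas$pairs)
  if (n < 2) stop("need at least two atlas cases", call. = FALSE)
  prec <- rec <- matrix(NA_real_, n, 10)
  fail <- matrix(FALSE, n, 10)
  for (i in seq_len(n)) {
    held <- atlas$pairs[[i]]
    rest <- atlas_set(atlas$pairs[-i], handedness = atlas$handedness)
    auto <- segmenter(held$image, rest)
    for (code in tendon_codes()) {
      a <- auto$labels == code
      m <- held$labels$labels == code
      if (!any(m)) next                 # region absent from the manual truth
      if (!any(a)) { fail[i, code] <- TRUE; next }
      pr <- precision_recall(a, m)
      prec[i, code] <- pr["precision"]
      rec[i, code] <- pr["recall"]
    }
  }
  iqr <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_))
    quantile(v, c(0.25, 0.75), names = FALSE)
  }
  res <- data.frame(region = region_names(),
                    precision_median = apply(prec, 2, median, na.rm = TRUE),
                    precision_q25 = apply(prec, 2, function(v) iqr(v)[1]),
                    precision_q75 = apply(prec, 2, function(v) iqr(v)[2]),
                    recall_median = apply(rec, 2, median, na.rm = TRUE),
                    recall_q25 = apply(rec, 2, function(v) iqr(v)[1]),
                    recall_q75 = apply(rec, 2, function(v) iqr(v)[2]),
                    failures = colSums(fail),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
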