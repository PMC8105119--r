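# SMOTE minority oversampling. Canonical mode interpolates between a
# minority point and one of its k nearest minority neighbours,
# x_new = x + r (x_n - x), r ~ U(0,1), so every synthetic point lies on a
# segment between two minority points. The "as_printed" mode implements
# the variant x_new = x + r (x - x_n), which extrapolates away from the
# neighbour; it is kept selectable because some descriptions of the
# method print the update with that sign, but interpolation is the
# default.

#' SMOTE configuration
#'
#' @param k_neighbors number of nearest minority neighbours (default 5);
#'   must be smaller than the minority class size.
#' @param target_ratio desired minority/majority size ratio in (0, 1]
#'   (default 1 = full balance).
#' @param seed RNG seed for reproducibility.
#' @param formula_mode `"canonical"` (interpolation, default) or
#'   `"as_printed"` (extrapolation variant).
#' @param scale z-scale features before computing neighbour distances
#'   (default `FALSE`: Euclidean distance on raw features).
#' @return list of class `msm_smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, target_ratio = 1, seed = 1,
                         formula_mode = c("canonical", "as_printed"),
                         scale = FALSE) {
  stopifnot(k_neighbors >= 1, target_ratio > 0, target_ratio <= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed),
                 formula_mode = match.arg(formula_mode), scale = scale),
            class = "msm_smote_config")
}

#' Oversample the minority class with SMOTE
#'
#' Repeatedly: draw a minority sample x, draw one of its `k_neighbors`
#' nearest minority neighbours x_n (Euclidean distance), draw
#' r ~ Uniform(0,1), and append the synthetic row (see
#' [smote_config()] for the two formula modes) with the minority label,
#' until the minority/majority ratio reaches `target_ratio`. Original
#' rows are returned untouched, synthetic rows appended after them.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y logical or two-level label vector.
#' @param config an `msm_smote_config`.
#' @return list `X`, `y`, `n_synthetic`; `attr(, "synthetic")` marks the
#'   appended rows.
#' @export
smote <- function(X, y, config = smote_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.logical(y)
  counts <- table(y)
  if (length(counts) != 2L)
    stop("smote needs both classes present", call. = FALSE)
  minority <- as.logical(names(counts)[which.min(counts)])
  n_min <- min(counts); n_maj <- max(counts)
  if (n_min <= config$k_neighbors)
    stop("minority class has ", n_min, " samples; k_neighbors = ",
         config$k_neighbors, " requires at least ",
         config$k_neighbors + 1L, call. = FALSE)
  n_target <- ceiling(config$target_ratio * n_maj)
  n_new <- max(0L, n_target - n_min)
  if (n_new == 0L)
    return(list(X = X, y = y, n_synthetic = 0L))
  Xm <- X[y == minority, , drop = FALSE]
  Xd <- if (config$scale) {
    sdv <- apply(Xm, 2, stats::sd); sdv[sdv == 0] <- 1
    scale(Xm, center = TRUE, scale = sdv)
  } else Xm
  D <- as.matrix(stats::dist(Xd))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(config$k_neighbors)]))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(config$seed)
  i <- sample.int(nrow(Xm), n_new, replace = TRUE)
  j_pick <- sample.int(config$k_neighbors, n_new, replace = TRUE)
  r <- stats::runif(n_new)
  xn <- Xm[nn[cbind(i, j_pick)], , drop = FALSE]
  x <- Xm[i, , drop = FALSE]
  Xnew <- if (config$formula_mode == "canonical")
    x + r * (xn - x) else x + r * (x - xn)
  out_X <- rbind(X, Xnew)
  rownames(out_X) <- NULL
  out_y <- c(y, rep(minority, n_new))
  res <- list(X = out_X, y = out_y, n_synthetic = n_new)
  attr(res, "synthetic") <- c(rep(FALSE, nrow(X)), rep(TRUE, n_new))
  res
}
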