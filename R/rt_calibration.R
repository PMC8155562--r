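# Iterative selection of endogenous retention-time anchor peptides and
# lasso RT calibration.

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Configuration for endogenous RT-anchor selection
#'
#' Defaults follow the anchor-selection filters of the iterative DIA
#' workflow: peptides must elute close to their library retention time
#' (at most 10 min), with a sharp peak (base width under 16.5 s), at
#' usable intensity (at least 1e5), and be detected in enough runs
#' (at least 20). Surviving candidates are spread over the gradient by
#' splitting it into equal-width RT bins and randomly subsampling each
#' bin to a cap.
#'
#' @param max_rt_delta Maximum |observed - library| RT in seconds
#'   (inclusive; default 600 s = 10 min).
#' @param max_width Maximum peak width at base in seconds (strict `<`;
#'   default 16.5 s).
#' @param min_intensity Minimum apex intensity (inclusive; default 1e5).
#' @param min_runs Minimum number of runs with qualifying observations
#'   (inclusive; default 20).
#' @param n_bins Number of equal-width RT bins over the gradient (default 20).
#' @param per_bin Maximum peptides kept per bin (default 100).
#' @param gradient Numeric length-2: gradient start and end (s) used for
#'   binning on library RT.
#' @param seed Seed for the per-bin random subsampling.
#' @param count_qualifying If TRUE (default) the run-count filter counts
#'   runs with observations passing the per-observation filters; if FALSE
#'   it counts any detection.
#' @return List of class `nrt_config`.
#' @export
nrt_config <- function(max_rt_delta = 600, max_width = 16.5,
                       min_intensity = 1e5, min_runs = 20L, n_bins = 20L,
                       per_bin = 100L, gradient = c(0, 5400), seed = 1L,
                       count_qualifying = TRUE) {
  stopifnot(max_rt_delta > 0, max_width > 0, min_intensity > 0,
            min_runs >= 1, n_bins >= 1, per_bin >= 1,
            length(gradient) == 2, diff(gradient) > 0)
  structure(
    list(max_rt_delta = max_rt_delta, max_width = max_width,
         min_intensity = min_intensity, min_runs = as.integer(min_runs),
         n_bins = as.integer(n_bins), per_bin = as.integer(per_bin),
         gradient = gradient, seed = as.integer(seed),
         count_qualifying = isTRUE(count_qualifying)),
    class = "nrt_config"
  )
}

.check_features <- function(features) {
  need <- c("peptide", "run", "rt_obs", "rt_lib", "width", "intensity")
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols)) {
    stop("feature table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  features
}

#' Filter RT-anchor candidate peptides
#'
#' An observation qualifies when its RT deviation is at most
#' `max_rt_delta`, its peak width is strictly below `max_width` and its
#' intensity is at least `min_intensity`. A peptide survives when it has
#' qualifying observations in at least `min_runs` distinct runs.
#'
#' @param features data.frame with columns `peptide`, `run`, `rt_obs`,
#'   `rt_lib`, `width`, `intensity`.
#' @param cfg An [nrt_config()].
#' @param delta Optional per-observation RT deviation overriding the raw
#'   `rt_obs - rt_lib` (used after model realignment).
#' @return Character vector of surviving peptides (sorted).
#' @export
filter_rt_candidates <- function(features, cfg = nrt_config(), delta = NULL) {
  .check_features(features)
  if (!nrow(features)) return(character(0))
  if (is.null(delta)) delta <- features$rt_obs - features$rt_lib
  ok <- abs(delta) <= cfg$max_rt_delta &
    features$width < cfg$max_width &
    features$intensity >= cfg$min_intensity
  tab <- if (cfg$count_qualifying) features[ok, c("peptide", "run")]
         else features[, c("peptide", "run")]
  if (!nrow(tab)) return(character(0))
  runs_per_pep <- tapply(tab$run, tab$peptide, function(r) length(unique(r)))
  if (!cfg$count_qualifying) {
    # still require at least one qualifying observation
    qual_pep <- unique(features$peptide[ok])
    runs_per_pep <- runs_per_pep[names(runs_per_pep) %in% qual_pep]
  }
  sort(names(runs_per_pep)[runs_per_pep >= cfg$min_runs])
}

#' Bin candidates over the gradient and subsample each bin
#'
#' The gradient span is split into `cfg$n_bins` equal-width, half-open
#' bins `[lo, hi)` on library RT (the last bin closed). Bins holding more
#' than `cfg$per_bin` peptides are randomly subsampled to the cap using
#' `cfg$seed`, so the anchor set is reproducible.
#'
#' @param candidates Character vector of candidate peptides.
#' @param lib_rt Named numeric: library RT (s) per peptide.
#' @param cfg An [nrt_config()].
#' @return Character vector of anchor peptides (sorted).
#' @export
bin_subsample <- function(candidates, lib_rt, cfg = nrt_config()) {
  if (!length(candidates)) return(character(0))
  rt <- lib_rt[candidates]
  if (anyNA(rt)) stop("library RT missing for some candidates")
  edges <- seq(cfg$gradient[1], cfg$gradient[2], length.out = cfg$n_bins + 1L)
  bin <- findInterval(rt, edges, rightmost.closed = TRUE, all.inside = TRUE)
  picked <- with_seed(cfg$seed, {
    unlist(lapply(split(candidates, bin), function(peps) {
      if (length(peps) <= cfg$per_bin) peps
      else sample(peps, cfg$per_bin)
    }), use.names = FALSE)
  })
  sort(picked)
}

#' Fit a lasso retention-time calibration model
#'
#' L1-regularized least squares of observed RT on a polynomial basis in
#' library RT (glmnet), with the penalty chosen by k-fold cross-validation.
#' Basis columns beyond the requested degree are constrained to zero so the
#' design always has the two columns glmnet requires.
#'
#' @param rt_lib,rt_obs Paired library and observed RTs (s).
#' @param degree Polynomial degree of the basis (default 1, i.e. affine).
#' @param lambda Penalty grid; default spans strong to effectively
#'   unpenalized.
#' @param nfolds Cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Object of class `rt_model` with elements `degree`, `fit`,
#'   `lambda`, `coefficients` (intercept first) and `residuals` summary.
#' @export
fit_rt_model <- function(rt_lib, rt_obs, degree = 1L, lambda = NULL,
                         nfolds = 5L, seed = 1L) {
  n <- length(rt_lib)
  if (length(rt_obs) != n) stop("rt_lib and rt_obs must have equal length")
  keep <- is.finite(rt_lib) & is.finite(rt_obs)
  rt_lib <- rt_lib[keep]; rt_obs <- rt_obs[keep]
  n <- length(rt_lib)
  if (n < max(10, degree + 2)) {
    stop("too few calibration pairs (", n, ") for degree ", degree)
  }
  if (stats::sd(rt_lib) == 0) stop("library RTs are constant; cannot calibrate")
  ncol_basis <- max(2L, as.integer(degree))
  x <- outer(rt_lib, seq_len(ncol_basis), `^`)
  colnames(x) <- paste0("rt", seq_len(ncol_basis))
  upper <- ifelse(seq_len(ncol_basis) <= degree, Inf, 0)
  lower <- -upper
  if (is.null(lambda)) lambda <- 10^seq(2, -8, length.out = 60)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  fit <- glmnet::cv.glmnet(x, rt_obs, family = "gaussian", lambda = lambda,
                           foldid = foldid, standardize = TRUE,
                           upper.limits = upper, lower.limits = lower)
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  pred <- as.numeric(stats::predict(fit, newx = x, s = "lambda.min"))
  structure(
    list(degree = as.integer(degree), fit = fit, lambda = fit$lambda.min,
         coefficients = beta[seq_len(degree + 1L)],
         residuals = summary(rt_obs - pred)),
    class = "rt_model"
  )
}

#' Predict observed RT from library RT
#'
#' @param object An `rt_model`.
#' @param newdata Numeric vector of library RTs.
#' @param ... Unused.
#' @return Predicted observed RT (s).
#' @export
predict.rt_model <- function(object, newdata, ...) {
  ncol_basis <- max(2L, object$degree)
  x <- outer(as.numeric(newdata), seq_len(ncol_basis), `^`)
  as.numeric(stats::predict(object$fit, newx = x, s = "lambda.min"))
}

#' @export
print.rt_model <- function(x, ...) {
  cat("RT calibration model (lasso, degree ", x$degree, ")\n", sep = "")
  cat("  lambda:", format(x$lambda, digits = 4), "\n")
  cat("  coefficients:", paste(format(x$coefficients, digits = 6),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Iterative endogenous RT-anchor calibration
#'
#' Iteration 0 filters against raw library RTs, bins and subsamples the
#' candidates into an anchor set, fits one lasso RT model per run on the
#' anchors' (library, observed) RT pairs, re-aligns every feature against
#' its run's model prediction, and recounts identifications (features whose
#' model-corrected RT deviation is within `cfg$max_rt_delta`). Later
#' iterations repeat the cycle on the realigned deviations. The loop stops
#' after `max_iter` iterations or when the identified-peptide count changes
#' by less than `rel_tol` relative to the previous iteration, mirroring the
#' plateau this workflow reaches after about five iterations.
#'
#' @param features Feature table (columns `peptide`, `run`, `rt_obs`,
#'   `rt_lib`, `width`, `intensity`, optional `protein`).
#' @param cfg An [nrt_config()].
#' @param max_iter Maximum iterations (default 5).
#' @param rel_tol Relative-change convergence threshold on the identified
#'   peptide count (default 0.005).
#' @param degree Polynomial degree of the per-run RT models.
#' @return List with `anchors` (final anchor peptides), `models` (named
#'   list, one `rt_model` per run), and `trace` (data.frame: iteration,
#'   n_anchors, n_identified_peptides, n_identified_proteins).
#' @export
iterate_nrt <- function(features, cfg = nrt_config(), max_iter = 5L,
                        rel_tol = 0.005, degree = 1L) {
  .check_features(features)
  if (!nrow(features)) stop("empty feature table")
  runs <- sort(unique(features$run))
  lib_rt <- tapply(features$rt_lib, features$peptide, stats::median)
  delta <- features$rt_obs - features$rt_lib
  trace <- list()
  models <- NULL
  anchors <- character(0)
  prev_count <- NA_real_
  for (it in seq_len(max_iter)) {
    candidates <- filter_rt_candidates(features, cfg, delta = delta)
    if (!length(candidates)) {
      if (it == 1L) {
        stop("no anchor candidates pass the filters; ",
             "consider loosening max_rt_delta, max_width, min_intensity ",
             "or min_runs")
      }
      break
    }
    anchors <- bin_subsample(candidates, lib_rt, cfg)
    anchor_rows <- features$peptide %in% anchors
    models <- lapply(runs, function(r) {
      rows <- anchor_rows & features$run == r
      fit_rt_model(features$rt_lib[rows], features$rt_obs[rows],
                   degree = degree, seed = cfg$seed)
    })
    names(models) <- runs
    # realign: deviation of every feature from its run model's prediction
    pred <- numeric(nrow(features))
    for (r in runs) {
      rows <- features$run == r
      pred[rows] <- predict(models[[as.character(r)]], features$rt_lib[rows])
    }
    delta <- features$rt_obs - pred
    identified <- abs(delta) <= cfg$max_rt_delta
    n_pep <- length(unique(features$peptide[identified]))
    n_prot <- if ("protein" %in% names(features)) {
      length(unique(features$protein[identified]))
    } else NA_integer_
    trace[[it]] <- data.frame(iteration = it, n_anchors = length(anchors),
                              n_identified_peptides = n_pep,
                              n_identified_proteins = n_prot)
    if (!is.na(prev_count) && prev_count > 0 &&
        abs(n_pep - prev_count) / prev_count < rel_tol) {
      prev_count <- n_pep
      break
    }
    prev_count <- n_pep
  }
  list(anchors = anchors, models = models,
       trace = do.call(rbind, trace))
}
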