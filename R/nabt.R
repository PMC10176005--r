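# Annual-rate-of-change inference in normal-appearing tissues: median
# extraction, ARoC, status regression, permutation p values, FDR and
# post-hoc t tests.

#' Median parameter values within tissue masks
#'
#' @param maps a [ParameterMaps-class] object.
#' @param tissueMasks named list of logical arrays (e.g. from
#'   [binarizeTissues()]); only the named tissues are used.
#' @param tissues which tissues to extract; default the three
#'   normal-appearing classes.
#' @param parameters which parameters to extract.
#' @return data.frame with columns `tissue`, `parameter`, `median`.
#'   Invalid voxels are excluded; an empty mask is an error naming the
#'   tissue.
#' @export
extractTissueMedians <- function(maps, tissueMasks, tissues = .NA_TISSUES,
                                 parameters = .PARAMETERS) {
  valid <- if (length(maps@valid)) maps@valid else NULL
  out <- expand.grid(tissue = tissues, parameter = parameters,
                     stringsAsFactors = FALSE)
  out$median <- NA_real_
  for (i in seq_len(nrow(out))) {
    m <- tissueMasks[[out$tissue[i]]]
    if (!is.null(valid)) m <- m & valid
    if (!any(m)) stop("empty mask for tissue ", out$tissue[i])
    out$median[i] <- stats::median(.getParam(maps, out$parameter[i])[m],
                                   na.rm = TRUE)
  }
  out
}

#' Annual rate of change
#'
#' Change between the initial and final median accounting for the
#' interscan interval: absolute mode (default) returns
#' `(t1 - t0) / years` in parameter units per year; relative mode returns
#' `100 * (t1 - t0) / t0 / years` in percent per year.
#'
#' @param medianT0,medianT1 initial and final values; vectorized.
#' @param intervalYears interval in years, positive.
#' @param mode `"absolute"` or `"relative"`.
#' @return Rate of change per year.
#' @examples
#' aroc(2.0, 2.1, 2)                      # 0.05 per year
#' aroc(80, 82, 2.5, mode = "relative")   # 1 %/yr
#' @export
aroc <- function(medianT0, medianT1, intervalYears,
                 mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  if (any(intervalYears <= 0)) stop("intervalYears must be positive")
  if (mode == "relative" && any(medianT0 == 0))
    stop("relative mode requires non-zero initial values")
  d <- (medianT1 - medianT0) / intervalYears
  if (mode == "relative") d <- 100 * d / medianT0 else d
}

# R^2 of a binary regressor: between-group over total sum of squares.
# X may be a 0/1 matrix with one permutation per column.
.r2Binary <- function(y, X) {
  n <- length(y)
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  X <- as.matrix(X)
  n1 <- colSums(X)
  s1 <- as.vector(crossprod(X, y))
  m1 <- s1 / n1
  m0 <- (sum(y) - s1) / (n - n1)
  ssb <- n1 * (m1 - ybar)^2 + (n - n1) * (m0 - ybar)^2
  as.vector(ssb / sst)
}

#' Regress an annual rate of change on disease status
#'
#' Ordinary least squares of `Y = b0 + b1 * X + e` with a binary status
#' regressor: `b1` is the between-group mean difference and the observed
#' R^2 the between-group over total sum of squares.
#'
#' @param y numeric response (one rate of change per subject), length >= 3.
#' @param x binary 0/1 status vector containing both groups.
#' @return An [ArocRegression-class] object. A constant `y` yields
#'   `r2 = 0` with a warning; a constant `x` is an error.
#' @export
fitStatusGlm <- function(y, x) {
  if (length(y) != length(x)) stop("y and x lengths differ")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (!all(x %in% c(0, 1))) stop("x must be binary 0/1")
  if (length(unique(x)) < 2L) stop("x is constant: both groups required")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) {
    warning("constant response: R^2 defined as 0")
    0
  } else .r2Binary(y, matrix(x, ncol = 1))
  new("ArocRegression", beta0 = unname(stats::coef(fit)[1]),
      beta1 = unname(stats::coef(fit)[2]),
      residuals = unname(stats::residuals(fit)), r2 = r2,
      n = length(y))
}

#' Permutation p value for the status regression
#'
#' The status labels are shuffled `n` times (every permuted regressor is
#' required to differ from the observed one; collisions are redrawn), the
#' permuted R^2 values are compared with the observed R^2, and
#' `p = #(Rpi > Robs) / (n + 1)` with a strict inequality (ties do not
#' count). Exhaustive mode enumerates all distinct label assignments
#' other than the observed one (feasible when `choose(n, n1) <= 1e6`) and
#' uses their number as `n`.
#'
#' @param y numeric response.
#' @param x binary 0/1 status vector.
#' @param n number of sampled permutations (default 5000); ignored in
#'   exhaustive mode.
#' @param seed integer seed for sampling mode.
#' @param mode `"sample"` or `"exhaustive"`.
#' @return A [PermutationResult-class] object.
#' @export
permutationPvalue <- function(y, x, n = 5000, seed = 1L,
                              mode = c("sample", "exhaustive")) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (!all(x %in% c(0, 1)) || length(unique(x)) < 2L)
    stop("x must be binary with both groups present")
  if (stats::var(y) == 0)
    stop("constant response: permutation R^2 is degenerate")
  nobs <- length(y)
  rObs <- .r2Binary(y, matrix(x, ncol = 1))
  if (mode == "sample") {
    set.seed(seed)
    P <- matrix(0, nobs, n)
    for (b in seq_len(n)) {
      repeat {
        px <- sample(x)
        if (any(px != x)) break
      }
      P[, b] <- px
    }
    nPerm <- as.integer(n)
    usedSeed <- as.integer(seed)
  } else {
    n1 <- sum(x == 1)
    if (choose(nobs, n1) > 1e6)
      stop("exhaustive enumeration infeasible (> 1e6 assignments); ",
           "use mode = \"sample\"")
    combs <- utils::combn(nobs, n1)
    P <- matrix(0, nobs, ncol(combs))
    P[cbind(as.vector(combs),
            rep(seq_len(ncol(combs)), each = n1))] <- 1
    identity <- colSums(P == x) == nobs
    P <- P[, !identity, drop = FALSE]
    nPerm <- ncol(P)
    usedSeed <- NA_integer_
  }
  rPerm <- .r2Binary(y, P)
  new("PermutationResult", n = as.integer(nPerm), rPerm = rPerm,
      rObs = rObs, p = sum(rPerm > rObs) / (nPerm + 1),
      seed = usedSeed, mode = mode)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param p vector of p values in \[0, 1\] (the full test family; the
#'   normal-appearing-tissue stage submits exactly 12: 3 tissue classes
#'   times 4 parameters).
#' @param q FDR level, default 0.05.
#' @return Integer indices of the rejected hypotheses.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  which(stats::p.adjust(p, method = "BH") <= q)
}

#' Post-hoc two-sample t test between status groups
#'
#' Welch (unequal-variance) two-sided t test comparing the rate-of-change
#' distribution between the two disease-status groups.
#'
#' @param values numeric vector.
#' @param status binary 0/1 labels; both groups need n >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
posthocGroupTtest <- function(values, status) {
  g0 <- values[status == 0]
  g1 <- values[status == 1]
  if (length(g0) < 2L || length(g1) < 2L)
    stop("both status groups need at least 2 observations")
  ht <- stats::t.test(g1, g0, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Run the normal-appearing-tissue inference stage
#'
#' For every tissue-by-parameter cell of the rate-of-change table, fits
#' the status regression, computes a permutation p value, controls the
#' FDR over the full family with Benjamini-Hochberg, and applies the
#' post-hoc Welch t test to the FDR-significant cells.
#'
#' @param arocTable data.frame with columns `subject_id`, `tissue`,
#'   `parameter`, `aroc` (one row per subject, tissue and parameter).
#' @param status data.frame with `subject_id` and binary `status`.
#' @param nPerm permutations per test (default 5000).
#' @param seed master seed; each test derives its own.
#' @param q FDR level.
#' @param mode permutation mode, see [permutationPvalue()].
#' @return data.frame with one row per tissue and parameter: `beta0`,
#'   `beta1`, `r2`, `p_perm`, `rejected`, `posthoc_t`, `posthoc_p` (NA
#'   where not rejected).
#' @export
runNabtInference <- function(arocTable, status, nPerm = 5000, seed = 1L,
                             q = 0.05, mode = "sample") {
  stopifnot(all(c("subject_id", "tissue", "parameter", "aroc") %in%
                names(arocTable)))
  cells <- unique(arocTable[c("tissue", "parameter")])
  cells <- cells[order(match(cells$tissue, .NA_TISSUES),
                       match(cells$parameter, .PARAMETERS)), ]
  res <- cells
  res$beta0 <- res$beta1 <- res$r2 <- res$p_perm <- NA_real_
  for (i in seq_len(nrow(res))) {
    rows <- arocTable$tissue == res$tissue[i] &
            arocTable$parameter == res$parameter[i]
    tab <- arocTable[rows, ]
    x <- status$status[match(tab$subject_id, status$subject_id)]
    fit <- fitStatusGlm(tab$aroc, x)
    perm <- permutationPvalue(tab$aroc, x, n = nPerm,
                              seed = .deriveSeed(seed, i), mode = mode)
    res$beta0[i] <- fit@beta0
    res$beta1[i] <- fit@beta1
    res$r2[i] <- fit@r2
    res$p_perm[i] <- perm@p
  }
  res$rejected <- seq_len(nrow(res)) %in% bhFdr(res$p_perm, q)
  res$posthoc_t <- res$posthoc_p <- NA_real_
  for (i in which(res$rejected)) {
    rows <- arocTable$tissue == res$tissue[i] &
            arocTable$parameter == res$parameter[i]
    tab <- arocTable[rows, ]
    x <- status$status[match(tab$subject_id, status$subject_id)]
    ph <- tryCatch(posthocGroupTtest(tab$aroc, x),
                   error = function(e) list(t = NA_real_, df = NA_real_,
                                            p = NA_real_))
    res$posthoc_t[i] <- ph$t
    res$posthoc_p[i] <- ph$p
  }
  rownames(res) <- NULL
  res
}

#' Rate-of-change table for a phantom cohort
#'
#' Adds map-level observation noise to each subject's ground-truth maps,
#' binarizes the tissue posteriors, extracts per-tissue medians at both
#' timepoints and assembles the annual-rate-of-change table.
#'
#' @param cohort a [PhantomCohort-class].
#' @param noiseFrac map noise fraction; defaults to the cohort config.
#' @param seed integer seed for the noise draws.
#' @param mode ARoC mode, see [aroc()].
#' @return data.frame with `subject_id`, `tissue`, `parameter`, `aroc`.
#' @export
cohortArocTable <- function(cohort, noiseFrac = NULL, seed = 1L,
                            mode = "absolute") {
  if (is.null(noiseFrac)) noiseFrac <- cohort@config@mapNoiseFrac
  out <- list()
  for (s in seq_along(cohort@subjects)) {
    subj <- cohort@subjects[[s]]
    med <- list()
    for (tp in c("T0", "T1")) {
      el <- subj[[tp]]
      obs <- perturbParameterMaps(el$truth, noiseFrac,
                                  seed = .deriveSeed(seed, 2L * s +
                                                       (tp == "T1")))
      masks <- binarizeTissues(el$posteriors)
      med[[tp]] <- extractTissueMedians(obs, masks)
    }
    tab <- med$T0
    names(tab)[names(tab) == "median"] <- "median_t0"
    tab$median_t1 <- med$T1$median
    tab$subject_id <- subj$id
    tab$interval_years <- subj$intervalYears
    tab$aroc <- aroc(tab$median_t0, tab$median_t1, subj$intervalYears,
                     mode = mode)
    out[[s]] <- tab
  }
  do.call(rbind, out)
}

#' Replicate the normal-appearing-tissue pipeline over phantom cohorts
#'
#' Generates `nReplicates` independent phantom cohorts from the given
#' configuration (each with a derived seed), runs the full
#' median-to-FDR inference chain on each, and records which
#' tissue-by-parameter tests were rejected. Used to estimate the type-I
#' error rate (with the status effect set to zero) and the power to
#' detect a programmed effect. Replicates whose generated cohort has only
#' one status group are redrawn with a bumped seed, since the regression
#' is undefined there.
#'
#' @param nReplicates number of replicate cohorts.
#' @param config a [PhantomConfig-class].
#' @param nPerm permutations per test.
#' @param seed master seed.
#' @param q FDR level.
#' @return data.frame with `replicate`, `tissue`, `parameter`,
#'   `rejected`.
#' @export
rejectionStudy <- function(nReplicates, config, nPerm = 5000, seed = 1L,
                           q = 0.05) {
  out <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    bump <- 0L
    repeat {
      cfg <- config
      cfg@seed <- .deriveSeed(seed, 7919L * r + bump)
      cohort <- generatePhantom(cfg)
      if (length(unique(cohort@clinical$status)) == 2L) break
      bump <- bump + 1L
      if (bump > 20L) stop("could not draw a two-group cohort")
    }
    tab <- cohortArocTable(cohort, seed = .deriveSeed(seed, 7919L * r + 1L))
    res <- runNabtInference(tab,
                            cohort@clinical[c("subject_id", "status")],
                            nPerm = nPerm,
                            seed = .deriveSeed(seed, 7919L * r + 2L), q = q)
    out[[r]] <- data.frame(replicate = r, res[c("tissue", "parameter",
                                                "rejected")])
  }
  do.call(rbind, out)
}
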