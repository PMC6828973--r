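#' Smoothing-spline ANOVA model design
#'
#' Describes a mixed-effects smoothing-spline ANOVA model: a smooth function
#' of one continuous axis (cubic smoothing spline) or two (thin-plate
#' smoothing spline), nominal factors, optional factor-specific smooth
#' deviations for the first factor, and a subject random intercept realised
#' as a ridge-penalised factor block.
#'
#' @param smooth Character vector of one (time) or two (space) column names
#'   in the data holding the continuous axes.
#' @param kernel `"cubic"` (1D) or `"thin_plate"` (2D); defaults to the one
#'   matching the axis dimensionality.
#' @param factors Character vector of nominal factor columns; the first is
#'   the grouping factor of interest and receives smooth deviations when
#'   `interaction = TRUE`.
#' @param subject Column name of the subject identifier for the random
#'   intercept, or `NULL`.
#' @param interaction Include group-specific smooth (and linear) deviations.
#' @param max_knots Cap on the number of representer knots; unique axis
#'   locations are used when fewer, otherwise a farthest-point subset.
#' @return A list of class `ssanova_design`.
#' @export
ssanova_design <- function(smooth, kernel = NULL, factors = NULL,
                           subject = NULL, interaction = TRUE,
                           max_knots = 100L) {
  d <- length(smooth)
  if (!d %in% 1:2) stop("smooth must name one or two continuous axes")
  if (is.null(kernel)) kernel <- if (d == 1L) "cubic" else "thin_plate"
  if ((kernel == "cubic") != (d == 1L))
    stop("kernel kind must match axis dimensionality (cubic <-> 1D, thin_plate <-> 2D)")
  structure(list(smooth = smooth, kernel = kernel, factors = factors,
                 subject = subject, interaction = interaction,
                 max_knots = as.integer(max_knots)),
            class = "ssanova_design")
}

# radial basis generators (conditionally positive definite with their
# polynomial null spaces: {1, t} for |r|^3, {1, x, y} for r^2 log r)
.eta_radial <- function(r, kernel) {
  if (kernel == "cubic") abs(r)^3
  else ifelse(r <= 0, 0, r^2 * log(r))
}

.pairwise_dist <- function(a, b) {
  # a: n x d, b: k x d
  n <- nrow(a); k <- nrow(b)
  d2 <- outer(rowSums(a^2), rep(1, k)) + outer(rep(1, n), rowSums(b^2)) -
    2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# deterministic farthest-point subset of rows
.farthest_points <- function(x, k) {
  n <- nrow(x)
  if (n <= k) return(seq_len(n))
  ctr <- colMeans(x)
  sel <- integer(k)
  sel[1] <- which.min(rowSums(sweep(x, 2, ctr)^2))
  dmin <- .pairwise_dist(x, x[sel[1], , drop = FALSE])[, 1]
  for (i in 2:k) {
    sel[i] <- which.max(dmin)
    dmin <- pmin(dmin, .pairwise_dist(x, x[sel[i], , drop = FALSE])[, 1])
  }
  sort(sel)
}

# null-space (polynomial) basis columns for the smooth
.null_basis <- function(coords, kernel) {
  if (kernel == "cubic") cbind(1, coords[, 1]) else cbind(1, coords)
}

# Build the penalised design for given data; returns X, penalty blocks and
# everything needed to rebuild rows at new points.
.build_ssanova_matrices <- function(data, response, design) {
  y <- data[[response]]
  if (anyNA(y)) stop("response contains missing values")
  coords <- as.matrix(data[design$smooth])
  if (!all(is.finite(coords))) stop("smooth axis values must be finite")

  # scale axes to the unit box (per-axis), remember scaling
  rng <- apply(coords, 2, range)
  scl <- pmax(rng[2, ] - rng[1, ], .Machine$double.eps)
  cs <- sweep(sweep(coords, 2, rng[1, ]), 2, scl, "/")

  uni <- unique(cs)
  knots <- uni[.farthest_points(uni, design$max_knots), , drop = FALSE]

  Ek <- .eta_radial(.pairwise_dist(knots, knots), design$kernel)
  Tk <- .null_basis(knots, design$kernel)
  m <- ncol(Tk)
  qrT <- qr(Tk)
  Z <- qr.Q(qrT, complete = TRUE)[, (m + 1):nrow(knots), drop = FALSE]
  P <- crossprod(Z, Ek %*% Z)
  P <- (P + t(P)) / 2
  P <- P / mean(diag(P))          # unit scale so lambda grids are comparable

  T_obs <- .null_basis(cs, design$kernel)
  B_obs <- .eta_radial(.pairwise_dist(cs, knots), design$kernel) %*% Z

  blocks <- list()      # list(name, cols, penalty = matrix or "identity")
  Xparts <- list(null = T_obs)
  pen <- list()

  flevels <- list()
  if (!is.null(design$factors)) {
    for (f in design$factors) {
      fv <- factor(data[[f]])
      if (nlevels(fv) < 2) stop(sprintf("factor '%s' has a single level", f))
      if (any(table(fv) == 0)) stop(sprintf("factor '%s' has an empty level", f))
      flevels[[f]] <- levels(fv)
      D <- model.matrix(~ fv)[, -1, drop = FALSE]
      colnames(D) <- paste0(f, levels(fv)[-1])
      Xparts[[paste0("factor_", f)]] <- D
    }
  }

  if (design$interaction && !is.null(design$factors)) {
    f <- design$factors[1]
    fv <- factor(data[[f]], levels = flevels[[f]])
    for (l in flevels[[f]][-1]) {
      d_l <- as.numeric(fv == l)
      if (ncol(T_obs) > 1)
        Xparts[[paste0("ilin_", l)]] <- d_l * T_obs[, -1, drop = FALSE]
      Xparts[[paste0("ismooth_", l)]] <- d_l * B_obs
      pen[[paste0("ismooth_", l)]] <- list(term = "interaction", P = P)
    }
  }

  Xparts$smooth <- B_obs
  pen$smooth <- list(term = "smooth", P = P)

  subj_levels <- NULL
  if (!is.null(design$subject)) {
    sv <- factor(data[[design$subject]])
    subj_levels <- levels(sv)
    S <- model.matrix(~ sv - 1)
    colnames(S) <- paste0("subj_", subj_levels)
    Xparts$subject <- S
    pen$subject <- list(term = "subject", P = "identity")
  }

  X <- do.call(cbind, Xparts)
  idx <- list(); at <- 0L
  for (nm in names(Xparts)) {
    k <- ncol(Xparts[[nm]])
    idx[[nm]] <- at + seq_len(k)
    at <- at + k
  }
  list(X = X, y = y, idx = idx, pen = pen, P = P, Z = Z, knots = knots,
       rng = rng, scl = scl, flevels = flevels, subj_levels = subj_levels,
       coords_scaled = cs)
}

# assemble the full penalty matrix for a lambda vector (named by term)
.penalty_matrix <- function(mats, lambda) {
  p <- ncol(mats$X)
  L <- matrix(0, p, p)
  for (nm in names(mats$pen)) {
    b <- mats$pen[[nm]]
    lam <- lambda[[b$term]]
    cols <- mats$idx[[nm]]
    L[cols, cols] <- if (identical(b$P, "identity")) diag(lam, length(cols))
                     else lam * b$P
  }
  L
}

.solve_penalized <- function(XtX, Xty, L) {
  A <- XtX + L
  Ainv <- tryCatch(solve(A), error = function(e)
    solve(A + diag(1e-8 * mean(diag(A)), nrow(A))))
  beta <- Ainv %*% Xty
  edf <- sum(Ainv * XtX)  # tr(A^-1 X'X), X'X symmetric
  list(beta = beta, edf = edf, A = A, Ainv = Ainv)
}

#' Select smoothing parameters by generalised cross-validation
#'
#' Minimises the GCV criterion `n * RSS / (n - tr(H))^2` over a logarithmic
#' grid for each penalised term (the shared smooth, the group-deviation
#' smooths, and the subject ridge), by coordinate descent over the grid
#' followed by local golden-section refinement on the log scale.
#'
#' @param data,response,design As for [fit_ssanova()].
#' @param lambda_grid Numeric vector of candidate penalty weights; it should
#'   span at least six orders of magnitude.
#' @param refine Run local refinement after the grid search.
#' @return A list with `lambda` (named vector), `gcv` (the attained score)
#'   and `trace` (data.frame of evaluated points).
#' @export
gcv_select <- function(data, response, design,
                       lambda_grid = 10^seq(-6, 8, by = 1), refine = TRUE) {
  mats <- .build_ssanova_matrices(data, response, design)
  sel <- .gcv_search(mats, lambda_grid, refine)
  list(lambda = sel$lambda, gcv = sel$gcv, trace = sel$trace)
}

.gcv_score <- function(mats, lambda, XtX, Xty) {
  n <- length(mats$y)
  L <- .penalty_matrix(mats, lambda)
  s <- .solve_penalized(XtX, Xty, L)
  rss <- sum((mats$y - mats$X %*% s$beta)^2)
  denom <- n - s$edf
  if (denom <= 0.5) return(Inf)
  n * rss / denom^2
}

.gcv_search <- function(mats, lambda_grid, refine = TRUE) {
  terms <- unique(vapply(mats$pen, function(b) b$term, character(1)))
  XtX <- crossprod(mats$X)
  Xty <- crossprod(mats$X, mats$y)
  lambda <- setNames(rep(stats::median(lambda_grid), length(terms)), terms)
  trace <- list()
  for (sweep_i in 1:2) {
    for (tm in terms) {
      scores <- vapply(lambda_grid, function(lv) {
        lam <- lambda; lam[[tm]] <- lv
        .gcv_score(mats, lam, XtX, Xty)
      }, numeric(1))
      best <- min(scores)
      # GCV flattens once a term is smoothed away; among numerically tied
      # scores prefer the heaviest smoothing (parsimony)
      lambda[[tm]] <- max(lambda_grid[scores <= best + 1e-12 * abs(best)])
      trace[[length(trace) + 1L]] <-
        data.frame(sweep = sweep_i, term = tm, lambda = lambda_grid, gcv = scores)
    }
  }
  if (refine) {
    for (tm in terms) {
      lg <- log10(lambda[[tm]])
      step <- diff(log10(range(lambda_grid))) / (length(lambda_grid) - 1)
      opt <- stats::optimize(function(lg1) {
        lam <- lambda; lam[[tm]] <- 10^lg1
        .gcv_score(mats, lam, XtX, Xty)
      }, interval = c(lg - step, lg + step), tol = 0.02)
      # keep the refinement only if it does not lose to the grid point
      if (opt$objective <= .gcv_score(mats, lambda, XtX, Xty))
        lambda[[tm]] <- 10^opt$minimum
    }
  }
  gcv <- .gcv_score(mats, lambda, XtX, Xty)
  list(lambda = lambda, gcv = gcv, trace = do.call(rbind, trace),
       XtX = XtX, Xty = Xty)
}

#' Fit a mixed-effects smoothing-spline ANOVA model
#'
#' Solves the penalised least-squares problem: response = intercept + factor
#' main effects + smooth(axes) + factor-specific smooth deviations + subject
#' random intercept, with a roughness penalty per smooth term and a ridge
#' penalty on the subject block. The smooth uses a representer (radial)
#' basis on at most `max_knots` knots: `|r|^3` with a linear null space for
#' the 1D cubic spline, `r^2 log r` with an affine null space for the 2D
#' thin-plate spline. Penalty weights are selected by generalised
#' cross-validation unless supplied. The posterior covariance of the
#' coefficients under the standard Bayesian reading of the roughness penalty
#' (penalty as Gaussian prior) is returned for interval estimation.
#'
#' @param data Long-format data.frame of observations.
#' @param response Name of the response column.
#' @param design An [ssanova_design()].
#' @param lambda Optional named penalty weights (`smooth`, `interaction`,
#'   `subject`) to use as-is, skipping GCV.
#' @param lambda_grid Grid for [gcv_select()] when `lambda` is missing.
#' @param refine Local refinement of the GCV optimum.
#' @return An object of class `ssanova_fit` with coefficients, fitted
#'   values, smoothing parameters, effective degrees of freedom, residual
#'   variance, posterior covariance, `r_squared` and `gcv_score`.
#' @export
fit_ssanova <- function(data, response, design, lambda = NULL,
                        lambda_grid = 10^seq(-6, 8, by = 1), refine = TRUE) {
  stopifnot(inherits(design, "ssanova_design"))
  data <- as.data.frame(data)
  mats <- .build_ssanova_matrices(data, response, design)
  n <- length(mats$y)

  if (is.null(lambda)) {
    sel <- .gcv_search(mats, lambda_grid, refine)
    lambda <- sel$lambda
    XtX <- sel$XtX; Xty <- sel$Xty
    gcv <- sel$gcv
  } else {
    terms <- unique(vapply(mats$pen, function(b) b$term, character(1)))
    if (!all(terms %in% names(lambda)))
      stop("lambda must be named with entries: ", paste(terms, collapse = ", "))
    XtX <- crossprod(mats$X)
    Xty <- crossprod(mats$X, mats$y)
    gcv <- .gcv_score(mats, lambda, XtX, Xty)
  }
  if (any(unlist(lambda) <= 0)) stop("penalty weights must be positive")

  L <- .penalty_matrix(mats, lambda)
  s <- .solve_penalized(XtX, Xty, L)
  fitted <- as.vector(mats$X %*% s$beta)
  rss <- sum((mats$y - fitted)^2)
  tss <- sum((mats$y - mean(mats$y))^2)
  df_resid <- max(1, n - s$edf)
  sigma2 <- rss / df_resid
  Vp <- sigma2 * s$Ainv

  structure(list(
    coefficients = as.vector(s$beta),
    fitted_values = fitted,
    residuals = mats$y - fitted,
    smoothing_parameters = lambda,
    edf = s$edf, df_resid = df_resid, sigma2 = sigma2,
    posterior_covariance = Vp,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    gcv_score = gcv,
    rss = rss, n = n,
    design = design, mats = mats,
    data = data, response = response), class = "ssanova_fit")
}

#' @export
print.ssanova_fit <- function(x, ...) {
  cat(sprintf("SS-ANOVA fit: n = %d, edf = %.1f, R^2 = %.1f%%, GCV = %.4g\n",
              x$n, x$edf, 100 * x$r_squared, x$gcv_score))
  cat("  lambda:", paste(names(x$smoothing_parameters),
                         sprintf("%.3g", unlist(x$smoothing_parameters)),
                         sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Proportion of response variance explained by an SS-ANOVA fit
#' @param fit An `ssanova_fit`.
#' @return `1 - RSS/TSS` on the training observations.
#' @export
model_r_squared <- function(fit) {
  stopifnot(inherits(fit, "ssanova_fit"))
  if (var(fit$data[[fit$response]]) == 0)
    stop("zero-variance response: R^2 undefined")
  fit$r_squared
}

# Build population-level design rows (subject effect zero) at new points.
# newdata must hold the smooth axes and any factor columns.
.ssanova_rows <- function(fit, newdata) {
  mats <- fit$mats; design <- fit$design
  coords <- as.matrix(newdata[design$smooth])
  cs <- sweep(sweep(coords, 2, mats$rng[1, ]), 2, mats$scl, "/")
  T_new <- .null_basis(cs, design$kernel)
  B_new <- .eta_radial(.pairwise_dist(cs, mats$knots), design$kernel) %*% mats$Z
  p <- length(fit$coefficients)
  D <- matrix(0, nrow(cs), p)
  D[, mats$idx$null] <- T_new
  if (!is.null(design$factors)) {
    for (f in design$factors) {
      lev <- mats$flevels[[f]]
      fv <- factor(newdata[[f]], levels = lev)
      M <- model.matrix(~ fv)[, -1, drop = FALSE]
      D[, mats$idx[[paste0("factor_", f)]]] <- M
    }
  }
  if (design$interaction && !is.null(design$factors)) {
    f <- design$factors[1]
    lev <- mats$flevels[[f]]
    fv <- factor(newdata[[f]], levels = lev)
    for (l in lev[-1]) {
      d_l <- as.numeric(fv == l)
      nm <- paste0("ilin_", l)
      if (!is.null(mats$idx[[nm]]))
        D[, mats$idx[[nm]]] <- d_l * T_new[, -1, drop = FALSE]
      D[, mats$idx[[paste0("ismooth_", l)]]] <- d_l * B_new
    }
  }
  D[, mats$idx$smooth] <- B_new
  D
}

#' Predict population-level values from an SS-ANOVA fit
#'
#' Evaluates the fitted surface (subject random effects set to zero) at new
#' points, optionally with pointwise Bayesian standard errors.
#'
#' @param object An `ssanova_fit`.
#' @param newdata Data.frame with the smooth axes and factor columns.
#' @param se.fit Also return pointwise posterior standard errors.
#' @param ... Unused.
#' @return A vector of predictions, or a list with `fit` and `se.fit`.
#' @export
predict.ssanova_fit <- function(object, newdata, se.fit = FALSE, ...) {
  D <- .ssanova_rows(object, newdata)
  est <- as.vector(D %*% object$coefficients)
  if (!se.fit) return(est)
  se <- sqrt(pmax(0, rowSums((D %*% object$posterior_covariance) * D)))
  list(fit = est, se.fit = se)
}

#' Pairwise group contrast with Bayesian confidence intervals
#'
#' Evaluates the difference between two groups' fitted curves (1D) or
#' surfaces (2D) on an evaluation grid, with pointwise 95% Bayesian
#' confidence intervals from the posterior covariance of the difference
#' functional, and the mean difference over the grid with the interval of
#' the averaged functional. Significance is declared when the mean
#' difference's interval excludes zero. Other nominal factors are held at
#' their reference level (they cancel in the difference), and subject
#' effects cancel by construction.
#'
#' @param fit An `ssanova_fit` with a grouping factor.
#' @param level_a,level_b Factor levels to contrast (difference = a - b).
#' @param grid Optional data.frame of evaluation points on the smooth axes;
#'   defaults to the unique axis locations of the training data.
#' @param level Confidence level.
#' @return An object of class `ssanova_contrast`: `grid`, `difference`,
#'   `ci_lower`, `ci_upper`, `mean_difference`, `mean_ci` and `significant`.
#' @export
contrast_difference <- function(fit, level_a, level_b, grid = NULL,
                                level = 0.95) {
  stopifnot(inherits(fit, "ssanova_fit"))
  design <- fit$design
  if (is.null(design$factors)) stop("fit has no grouping factor to contrast")
  f <- design$factors[1]
  lev <- fit$mats$flevels[[f]]
  if (!all(c(level_a, level_b) %in% lev))
    stop("both contrast levels must be levels of the fitted grouping factor")
  if (is.null(grid)) {
    grid <- unique(fit$data[design$smooth])
    grid <- grid[do.call(order, grid), , drop = FALSE]
    rownames(grid) <- NULL
  }
  base <- grid
  for (other in setdiff(design$factors, f))
    base[[other]] <- fit$mats$flevels[[other]][1]
  nda <- base; nda[[f]] <- factor(level_a, levels = lev)
  ndb <- base; ndb[[f]] <- factor(level_b, levels = lev)
  D <- .ssanova_rows(fit, nda) - .ssanova_rows(fit, ndb)
  est <- as.vector(D %*% fit$coefficients)
  Vp <- fit$posterior_covariance
  se <- sqrt(pmax(0, rowSums((D %*% Vp) * D)))
  q <- qt(1 - (1 - level) / 2, fit$df_resid)
  dm <- colMeans(D)
  m_est <- sum(dm * fit$coefficients)
  m_se <- sqrt(max(0, as.numeric(t(dm) %*% Vp %*% dm)))
  m_ci <- m_est + c(-1, 1) * q * m_se
  structure(list(
    grid = grid, difference = est,
    ci_lower = est - q * se, ci_upper = est + q * se,
    mean_difference = m_est, mean_ci = m_ci, mean_se = m_se,
    levels = c(level_a, level_b), level = level,
    significant = (m_ci[1] > 0 || m_ci[2] < 0)), class = "ssanova_contrast")
}

#' @export
print.ssanova_contrast <- function(x, ...) {
  cat(sprintf("Contrast %s - %s: mean difference %.2f (%.0f%% CI %.2f to %.2f)%s\n",
              x$levels[1], x$levels[2], x$mean_difference, 100 * x$level,
              x$mean_ci[1], x$mean_ci[2],
              if (x$significant) " *" else ""))
  invisible(x)
}
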