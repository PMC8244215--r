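#' Used/available composition table
#'
#' The matched-stratum design of a point selection function: each stratum
#' pairs one used row (the habitat composition at a GPS fix) with one or
#' more available rows (the distance-weighted composition of reachable
#' habitat around the fix). Compositions are per-class proportions
#' summing to 1.
#'
#' @param rows data.frame with columns `stratum`, `role`
#'   (`"used"`/`"available"`), `x`, `y`, `weight`, plus one column per
#'   land-cover class.
#' @param classes character vector of class column names.
#' @return a `used_available_table`.
#' @export
used_available_table <- function(rows, classes) {
  stopifnot(is.data.frame(rows), all(classes %in% names(rows)))
  need <- c("stratum", "role", "x", "y", "weight")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  if (!all(rows$role %in% c("used", "available")))
    stop("role must be 'used' or 'available'")
  per <- table(rows$stratum, rows$role)
  if (any(per[, "used"] != 1L) || any(per[, "available"] < 1L))
    stop("each stratum needs exactly one used row and >= 1 available rows")
  if (any(rows$weight <= 0)) stop("weights must be positive")
  sums <- rowSums(rows[classes])
  if (any(abs(sums - 1) > 1e-6))
    stop("compositions must sum to 1 within 1e-6")
  structure(list(rows = rows, classes = classes),
            class = "used_available_table")
}

#' @export
print.used_available_table <- function(x, ...) {
  cat(sprintf("used_available_table: %d strata, %d rows, classes: %s\n",
              length(unique(x$rows$stratum)), nrow(x$rows),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Composition at a used fix
#'
#' Mean per-class proportion over the fix's cell and its eight
#' neighbours (3x3 window, clipped at borders and skipping nodata),
#' renormalised to sum 1 — a buffer against GPS positional error.
#'
#' @param fix one-row data.frame (or list) with `x`, `y`.
#' @param stack a `landcover_stack`.
#' @return named numeric composition, or `NULL` with a warning when the
#'   whole window is nodata.
#' @export
extract_used_composition <- function(fix, stack) {
  stopifnot(inherits(stack, "landcover_stack"))
  ref <- stack$layers[[1]]
  d <- dim(ref$values)
  cell <- xy_cell(ref, fix$x, fix$y)
  if (is.na(cell)) stop("fix outside raster extent")
  row <- (cell - 1L) %% d[1] + 1L
  col <- (cell - 1L) %/% d[1] + 1L
  rows <- max(1L, row - 1L):min(d[1], row + 1L)
  cols <- max(1L, col - 1L):min(d[2], col + 1L)
  comp <- vapply(stack$classes, function(cl) {
    w <- stack$layers[[cl]]$values[rows, cols]
    mean(w, na.rm = TRUE)
  }, numeric(1))
  if (all(is.nan(comp))) {
    warning("all-nodata window at fix; skipped")
    return(NULL)
  }
  comp / sum(comp)
}

#' Distance-weighted available composition
#'
#' Weighted mean per-class proportion over cells whose centres lie
#' within `radius` of the fix, with weights from the generalized Pareto
#' density of the centre distance (closer cells weigh more), normalised
#' to sum 1.
#'
#' @param fix one-row data.frame (or list) with `x`, `y`.
#' @param stack a `landcover_stack`.
#' @param radius availability radius in map units (> cell size).
#' @param gpd a `gpd_params` distance-weight model.
#' @return named numeric composition, or `NULL` with a warning if no
#'   valid cell falls in the disk.
#' @export
extract_available_composition <- function(fix, stack, radius, gpd) {
  stopifnot(inherits(stack, "landcover_stack"),
            inherits(gpd, "gpd_params"))
  ref <- stack$layers[[1]]
  if (radius <= ref$res) stop("'radius' must exceed the cell size")
  disk <- disk_cells(ref, fix$x, fix$y, radius)
  if (length(disk$cells) == 0L) {
    warning("no valid cells within radius of fix; skipped")
    return(NULL)
  }
  w <- gpd_density(disk$dist, gpd)
  if (sum(w) <= 0) w <- rep(1, length(w))
  comp <- vapply(stack$classes, function(cl) {
    v <- stack$layers[[cl]]$values[disk$cells]
    sum(w * v, na.rm = TRUE)
  }, numeric(1))
  comp / sum(comp)
}

# cells with centres within radius of (x, y), nodata dropped
disk_cells <- function(ref, x, y, radius) {
  d <- dim(ref$values)
  res <- ref$res
  cell <- xy_cell(ref, x, y)
  if (is.na(cell)) return(list(cells = integer(0), dist = numeric(0)))
  row <- (cell - 1L) %% d[1] + 1L
  col <- (cell - 1L) %/% d[1] + 1L
  halo <- ceiling(radius / res)
  rows <- max(1L, row - halo):min(d[1], row + halo)
  cols <- max(1L, col - halo):min(d[2], col + halo)
  cells <- as.vector(outer(rows, (cols - 1L) * d[1], `+`))
  xy <- cell_xy(ref, cells)
  dist <- sqrt((xy[, 1] - x)^2 + (xy[, 2] - y)^2)
  keep <- dist <= radius & !is.na(ref$values[cells])
  list(cells = cells[keep], dist = dist[keep])
}

#' Build a used/available table from fixes
#'
#' One stratum per fix: the used row from the 3x3 window composition and
#' either a single distance-weighted mean available row
#' (`n_available = "mean"`, the default) or `n_available` sampled
#' available cells as separate rows (weights kept for the likelihood).
#' Fixes whose window or disk is entirely nodata are skipped with a
#' warning.
#'
#' @param fixes data.frame of fixes.
#' @param stack a `landcover_stack`.
#' @param radius availability radius (map units).
#' @param gpd a `gpd_params` distance-weight model.
#' @param n_available `"mean"` or an integer count of sampled available
#'   rows per stratum.
#' @param seed seed for available-cell sampling.
#' @return a `used_available_table`.
#' @export
build_used_available_table <- function(fixes, stack, radius, gpd,
                                       n_available = "mean", seed = 1L) {
  stopifnot(inherits(stack, "landcover_stack"))
  set.seed(as.integer(seed))
  ref <- stack$layers[[1]]
  comp_mat <- sapply(stack$classes, function(cl)
    as.vector(stack$layers[[cl]]$values))
  rows <- list()
  s <- 0L
  for (i in seq_len(nrow(fixes))) {
    fix <- fixes[i, , drop = FALSE]
    used <- tryCatch(extract_used_composition(fix, stack),
                     warning = function(w) NULL)
    if (is.null(used)) next
    if (identical(n_available, "mean")) {
      avail <- tryCatch(
        extract_available_composition(fix, stack, radius, gpd),
        warning = function(w) NULL)
      if (is.null(avail)) next
      s <- s + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, role = "used", x = fix$x, y = fix$y, weight = 1,
        t(used), check.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, role = "available", x = fix$x, y = fix$y, weight = 1,
        t(avail), check.names = FALSE)
    } else {
      disk <- disk_cells(ref, fix$x, fix$y, radius)
      if (length(disk$cells) == 0L) next
      w <- gpd_density(disk$dist, gpd)
      if (sum(w) <= 0) w <- rep(1, length(w))
      pick <- sample.int(length(disk$cells), as.integer(n_available),
                         replace = TRUE, prob = w)
      s <- s + 1L
      xy <- cell_xy(ref, disk$cells[pick])
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, role = "used", x = fix$x, y = fix$y, weight = 1,
        t(used), check.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, role = "available", x = xy[, 1], y = xy[, 2],
        weight = 1 / as.integer(n_available),
        comp_mat[disk$cells[pick], , drop = FALSE], check.names = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no usable strata (all fixes skipped)")
  used_available_table(do.call(rbind, rows), classes = stack$classes)
}

#' Fit a point selection function
#'
#' Contrasts used (1) against available (0) rows on the compositional
#' predictors with the reference-class column dropped (compositions are
#' collinear; the reference class carries no coefficient). The default
#' `method = "pooled"` is a weighted binomial logistic regression via
#' `glm`; `method = "conditional"` fits the exact stratum-conditional
#' likelihood via `survival::clogit`. Complete separation is flagged and
#' refitted with a small ridge penalty (IRLS with an L2 term) so
#' coefficients stay reportable.
#'
#' @param table a `used_available_table`.
#' @param reference_class class dropped for identifiability.
#' @param method `"pooled"` (plain weighted glm) or `"conditional"`.
#' @param weights_in_likelihood use the table's row weights as prior
#'   weights in the fit (default FALSE: weights enter only through
#'   composition averaging).
#' @return a `psf_model`: list with `coef` (named), `se`, `reference`,
#'   `loglik`, `method`, `separation` flag.
#' @export
fit_psf <- function(table, reference_class,
                    method = c("pooled", "conditional"),
                    weights_in_likelihood = FALSE) {
  stopifnot(inherits(table, "used_available_table"))
  method <- match.arg(method)
  if (!reference_class %in% table$classes)
    stop("unknown reference class: ", reference_class)
  other <- setdiff(table$classes, reference_class)
  rows <- table$rows
  X <- as.matrix(rows[other])
  if (all(apply(X, 2, stats::sd) == 0))
    stop("need at least 2 classes with variation")
  y <- as.integer(rows$role == "used")
  w <- if (weights_in_likelihood) rows$weight else rep(1, nrow(rows))

  if (method == "conditional") {
    df <- data.frame(y = y, X, stratum = rows$stratum, check.names = FALSE)
    # conditional logit as a stratified Cox fit (the clogit trick)
    fml <- stats::as.formula(paste(
      "survival::Surv(rep(1, nrow(df)), y) ~",
      paste(sprintf("`%s`", other), collapse = " + "),
      "+ survival::strata(stratum)"))
    fit <- survival::coxph(fml, data = df, weights = w,
                           method = "breslow")
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    names(co) <- names(se) <- other
    return(structure(list(coef = co, se = se,
                          reference = reference_class,
                          loglik = as.numeric(stats::logLik(fit)),
                          method = method, separation = FALSE),
                     class = "psf_model"))
  }

  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", other), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df, weights = w))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  if (separation) {
    pen <- ridge_logistic(cbind(1, X), y, w, lambda = 1e-2)
    co <- pen$coef[-1]; se <- pen$se[-1]
    ll <- pen$loglik
  } else {
    co <- stats::coef(fit)[-1]
    se <- sqrt(diag(stats::vcov(fit)))[-1]
    ll <- as.numeric(stats::logLik(fit))
  }
  names(co) <- names(se) <- other
  structure(list(coef = co, se = se, reference = reference_class,
                 loglik = ll, method = method, separation = separation,
                 intercept = if (separation) pen$coef[1] else
                   stats::coef(fit)[1]),
            class = "psf_model")
}

# L2-penalised logistic regression by IRLS; first column of X is the
# (unpenalised-in-spirit, lightly penalised in practice) intercept
ridge_logistic <- function(X, y, w, lambda = 1e-2, maxit = 100L) {
  beta <- numeric(ncol(X))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    p <- stats::plogis(eta)
    wt <- w * p * (1 - p)
    H <- crossprod(X, X * wt) + diag(lambda, ncol(X))
    gr <- crossprod(X, w * (y - p)) - lambda * beta
    step <- solve(H, gr)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < 1e-10) break
  }
  p <- stats::plogis(as.vector(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(coef = beta,
       se = sqrt(diag(solve(crossprod(X, X * (w * p * (1 - p))) +
                              diag(lambda, ncol(X))))),
       loglik = sum(w * (y * log(p) + (1 - y) * log(1 - p))))
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("psf_model (%s, reference = %s)%s\n", x$method, x$reference,
              if (x$separation) " [separation: ridge fallback]" else ""))
  print(data.frame(class = names(x$coef), estimate = unname(x$coef),
                   se = unname(x$se)), row.names = FALSE)
  invisible(x)
}

#' Table-2-shaped coefficient export
#'
#' @param model a `psf_model`.
#' @param path optional CSV path.
#' @return data.frame with `class`, `estimate`, `se` (the reference
#'   class appears with NA estimate).
#' @export
psf_coefficients <- function(model, path = NULL) {
  out <- rbind(
    data.frame(class = names(model$coef), estimate = unname(model$coef),
               se = unname(model$se)),
    data.frame(class = model$reference, estimate = NA_real_,
               se = NA_real_))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Cross-validated AUC of a PSF
#'
#' Folds are assigned per stratum (strata stay intact). Ordinary CV uses
#' seeded random fold labels; spatial CV clusters stratum coordinates
#' with k-means into `k` blocks. Out-of-fold linear predictors are
#' pooled and scored as used-versus-available AUC. Folds whose training
#' data lack both roles are skipped with a warning.
#'
#' @param table a `used_available_table`.
#' @param k number of folds (>= 2; default 10).
#' @param spatial use k-means spatial blocks instead of random folds.
#' @param seed integer seed.
#' @param reference_class passed to [fit_psf()].
#' @param method passed to [fit_psf()] (pooled only is scored).
#' @return AUC in [0, 1].
#' @export
crossvalidate_psf <- function(table, k = 10L, spatial = FALSE, seed = 1L,
                              reference_class = table$classes[1],
                              method = "pooled") {
  stopifnot(inherits(table, "used_available_table"), k >= 2L)
  set.seed(as.integer(seed))
  rows <- table$rows
  strata <- sort(unique(rows$stratum))
  if (spatial) {
    cent <- do.call(rbind, lapply(strata, function(s) {
      r <- rows[rows$stratum == s & rows$role == "used", , drop = FALSE]
      c(r$x[1], r$y[1])
    }))
    km <- stats::kmeans(cent, centers = min(k, nrow(unique(cent))),
                        nstart = 5)
    fold <- km$cluster
  } else {
    fold <- sample(rep_len(seq_len(k), length(strata)))
  }
  names(fold) <- strata
  other <- setdiff(table$classes, reference_class)
  scores <- numeric(0); truth <- integer(0)
  for (f in sort(unique(fold))) {
    test_s <- strata[fold == f]
    tr <- rows[!rows$stratum %in% test_s, , drop = FALSE]
    te <- rows[rows$stratum %in% test_s, , drop = FALSE]
    if (length(unique(tr$role)) < 2L || nrow(te) == 0L) {
      warning("fold ", f, " skipped: single-role training data")
      next
    }
    sub <- used_available_table(tr, table$classes)
    m <- fit_psf(sub, reference_class, method = method)
    lp <- as.matrix(te[other]) %*% m$coef
    scores <- c(scores, as.vector(lp))
    truth <- c(truth, as.integer(te$role == "used"))
  }
  if (length(unique(truth)) < 2L) stop("no scorable folds")
  as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                 direction = "<")))
}

#' Predict a conductance surface from a PSF
#'
#' Per-cell inverse-logit of the coefficient-weighted class proportions
#' (reference class contributing zero): the predicted selection
#' probability used directly as matrix permeability. Nodata propagates.
#'
#' @param model a `psf_model`.
#' @param stack a `landcover_stack` whose classes all appear in the
#'   model (reference included).
#' @return a `raster2d` of conductance in (0, 1).
#' @export
predict_conductance <- function(model, stack) {
  stopifnot(inherits(model, "psf_model"), inherits(stack, "landcover_stack"))
  known <- c(names(model$coef), model$reference)
  if (!all(stack$classes %in% known))
    stop("stack contains classes unseen by the model: ",
         paste(setdiff(stack$classes, known), collapse = ", "))
  g <- stack$layers[[1]]
  lp <- 0 * g$values
  for (cl in setdiff(stack$classes, model$reference))
    lp <- lp + model$coef[[cl]] * stack$layers[[cl]]$values
  raster2d(stats::plogis(lp), res = g$res, xll = g$xll, yll = g$yll)
}
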