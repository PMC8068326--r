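#' Search domain for the mapping constants and wavelet
#'
#' The box searched by [bayes_optimize()]: `a, b, c` in `[0, 0.1]`, `d` in
#' `[0.001, 1]`, and the categorical wavelet choice among the four
#' supported families. Bounds may be narrowed but not widened.
#'
#' @param a,b,c,d Length-2 numeric intervals.
#' @param wavelet Character subset of [supported_wavelets()].
#' @return An object of class `"search_domain"`.
#' @export
search_domain <- function(a = range(0, 0.1), b = range(0, 0.1),
                          c = range(0, 0.1), d = range(0.001, 1),
                          wavelet = supported_wavelets()) {
  box <- list(a = a, b = b, c = c, d = d)
  for (nm in names(box)) {
    v <- box[[nm]]
    if (length(v) != 2L || !all(is.finite(v)) || v[1] >= v[2]) {
      stop("domain for ", nm, " must be a finite interval c(lo, hi)",
           call. = FALSE)
    }
  }
  if (!all(wavelet %in% supported_wavelets()) || length(wavelet) < 1L) {
    stop("wavelet domain must be a non-empty subset of the supported names",
         call. = FALSE)
  }
  structure(c(box, list(wavelet = wavelet)), class = "search_domain")
}

.matern52 <- function(r, ell) {
  s <- sqrt(5) * r / ell
  (1 + s + s^2 / 3) * exp(-s)
}

# fit a zero-mean GP with Matern-5/2 kernel on unit-box inputs; the
# lengthscale is picked from a small grid by marginal likelihood
.gp_fit <- function(X, y, noise = 1e-6) {
  mu <- mean(y)
  sc <- stats::sd(y)
  if (!is.finite(sc) || sc < 1e-12) sc <- 1
  ys <- (y - mu) / sc
  n <- length(ys)
  D <- as.matrix(stats::dist(X))
  best <- NULL
  for (ell in c(0.1, 0.2, 0.35, 0.5, 0.75, 1, 1.5)) {
    K <- .matern52(D, ell) + diag(noise + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
    if (is.null(best) || ll > best$ll) {
      best <- list(ell = ell, L = L, alpha = alpha, ll = ll)
    }
  }
  if (is.null(best)) stop("GP fit failed", call. = FALSE)
  list(X = X, mu = mu, sc = sc, ell = best$ell, L = best$L,
       alpha = best$alpha, ymax_std = max(ys), noise = noise)
}

.gp_predict <- function(gp, Xnew) {
  d <- vapply(seq_len(nrow(gp$X)), function(i) {
    sqrt(colSums((t(Xnew) - gp$X[i, ])^2))
  }, numeric(nrow(Xnew)))
  Ks <- .matern52(matrix(d, nrow = nrow(Xnew)), gp$ell)
  mean_std <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var_std <- pmax(1 + gp$noise - colSums(v^2), 1e-12)
  list(mean = mean_std, sd = sqrt(var_std))
}

# expected improvement over the best standardized observation
.gp_ei <- function(gp, Xnew, xi = 0.01) {
  p <- .gp_predict(gp, Xnew)
  z <- (p$mean - gp$ymax_std - xi) / p$sd
  (p$mean - gp$ymax_std - xi) * stats::pnorm(z) + p$sd * stats::dnorm(z)
}

.domain_box <- function(domain) {
  rbind(a = domain$a, b = domain$b, c = domain$c, d = domain$d)
}

.to_unit <- function(x, box) (x - box[, 1]) / (box[, 2] - box[, 1])
.from_unit <- function(u, box) box[, 1] + u * (box[, 2] - box[, 1])

#' Bayesian optimization of the coefficient-mapping constants
#'
#' Maximizes a user-supplied objective over the mapping constants and the
#' categorical wavelet choice. Phase 1 draws `n_random` seeded uniform
#' samples from the domain; phase 2 runs `n_bayes` steps of Gaussian-
#' process surrogate modelling (Matern-5/2 kernel, expected-improvement
#' acquisition maximized by multi-start local search over the box). One
#' surrogate is maintained per wavelet and each proposal goes to the
#' wavelet with the best expected improvement; a wavelet with fewer than
#' two successful evaluations is explored at a random point first.
#'
#' Iterations where the objective raises an error or returns a non-finite
#' value are recorded with value `NA` and skipped by the surrogate; the
#' run aborts if all of phase 1 fails.
#'
#' The random phase draws, per iteration, `a, b, c, d` by four `runif`
#' calls in that order followed by one `sample` call for the wavelet, so
#' that with `n_bayes = 0` the tuner is exactly a seeded random search.
#'
#' @param objective Function taking a `"mapping_params"` and returning a
#'   finite scalar to maximize (the grading pipeline's objective is the
#'   fold-mean micro-AUC; see [objective_from_pipeline()]).
#' @param domain A `"search_domain"`.
#' @param n_random Number of random-exploration steps (>= 1; 25 in the
#'   reference protocol).
#' @param n_bayes Number of Bayesian steps (20 in the reference protocol).
#' @param seed Integer seed; the full trace is reproducible given the seed.
#' @return An object of class `"bo_trace"`: data frame with columns
#'   `iteration`, `phase`, `a`, `b`, `c`, `d`, `wavelet`, `value`, `best`
#'   (running maximum), with the seed and domain stored as attributes and
#'   the best parameters as attribute `"best_params"`.
#' @export
bayes_optimize <- function(objective, domain = search_domain(),
                           n_random = 25L, n_bayes = 20L, seed = 1L) {
  stopifnot(inherits(domain, "search_domain"), n_random >= 1L, n_bayes >= 0L)
  rng <- .seeded_rng(seed)
  box <- .domain_box(domain)
  wavelets <- domain$wavelet
  n_total <- n_random + n_bayes
  tr <- data.frame(iteration = seq_len(n_total),
                   phase = rep(c("random", "bayes"), c(n_random, n_bayes)),
                   a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                   wavelet = NA_character_, value = NA_real_, best = NA_real_)

  eval_point <- function(i, vals, wv) {
    params <- mapping_params(vals[1], vals[2], vals[3], vals[4], wv)
    y <- tryCatch({
      out <- objective(params)
      if (!is.numeric(out) || length(out) != 1L || !is.finite(out)) NA_real_
      else as.numeric(out)
    }, error = function(e) NA_real_)
    tr[i, c("a", "b", "c", "d")] <<- as.list(vals)
    tr$wavelet[i] <<- wv
    tr$value[i] <<- y
    finite <- tr$value[seq_len(i)]
    tr$best[i] <<- if (all(is.na(finite))) NA_real_ else max(finite, na.rm = TRUE)
  }

  for (i in seq_len(n_random)) {
    vals <- c(rng$runif(1, box["a", 1], box["a", 2]),
              rng$runif(1, box["b", 1], box["b", 2]),
              rng$runif(1, box["c", 1], box["c", 2]),
              rng$runif(1, box["d", 1], box["d", 2]))
    wv <- wavelets[rng$sample_int(length(wavelets), 1L)]
    eval_point(i, vals, wv)
  }
  if (all(is.na(tr$value[seq_len(n_random)]))) {
    stop("all random-exploration evaluations failed; cannot start surrogate",
         call. = FALSE)
  }

  for (i in seq_len(n_bayes) + n_random) {
    done <- tr[seq_len(i - 1L), ]
    proposals <- lapply(wavelets, function(wv) {
      obs <- done[done$wavelet == wv & !is.na(done$value), , drop = FALSE]
      u_cand <- matrix(rng$runif(4L * 128L), ncol = 4L)
      if (nrow(obs) < 2L) {
        return(list(ei = Inf, u = u_cand[1L, ], wavelet = wv))
      }
      U <- .to_unit(t(as.matrix(obs[, c("a", "b", "c", "d")])), box)
      gp <- .gp_fit(t(U), obs$value)
      ei <- .gp_ei(gp, u_cand)
      u0 <- u_cand[which.max(ei), ]
      opt <- tryCatch(
        stats::optim(u0, function(u) -.gp_ei(gp, matrix(u, 1L)),
                     method = "L-BFGS-B", lower = rep(0, 4), upper = rep(1, 4)),
        error = function(e) list(par = u0, value = -max(ei)))
      list(ei = -opt$value, u = opt$par, wavelet = wv)
    })
    pick <- proposals[[which.max(vapply(proposals, `[[`, numeric(1), "ei"))]]
    vals <- .from_unit(pick$u, box)
    eval_point(i, vals, pick$wavelet)
  }

  ibest <- which.max(ifelse(is.na(tr$value), -Inf, tr$value))
  attr(tr, "seed") <- as.integer(seed)
  attr(tr, "domain") <- domain
  attr(tr, "best_params") <- mapping_params(tr$a[ibest], tr$b[ibest],
                                            tr$c[ibest], tr$d[ibest],
                                            tr$wavelet[ibest])
  class(tr) <- c("bo_trace", "data.frame")
  tr
}

#' Persist a tuning trace as JSON
#'
#' Writes the full iteration history with seed and domain so a tuning run
#' can be audited and replayed exactly.
#'
#' @param trace A `"bo_trace"` from [bayes_optimize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bo_trace <- function(trace, path) {
  stopifnot(inherits(trace, "bo_trace"))
  dom <- attr(trace, "domain")
  obj <- list(seed = attr(trace, "seed"),
              domain = dom[c("a", "b", "c", "d", "wavelet")],
              iterations = as.data.frame(trace),
              best = unclass(attr(trace, "best_params")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Pipeline objective: fold-mean micro-AUC under enhancement
#'
#' Builds the closure the tuner maximizes in the grading pipeline: given
#' mapping constants, enhance every image, run the augment/train/evaluate
#' cross-validation cycle with the supplied model, and return the fold-mean
#' micro-averaged AUC.
#'
#' @param dataset A `"labeled_dataset"` of original samples.
#' @param model A model contract (see [reference_classifier()]).
#' @param folds A `"fold_assignment"` over `dataset`.
#' @return Function `mapping_params -> numeric` in `[0, 1]`.
#' @export
objective_from_pipeline <- function(dataset, model, folds) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(folds, "fold_assignment"))
  function(params) {
    report <- run_classification_cv(dataset, model, params = params,
                                    k = folds$k, seed = folds$seed,
                                    folds = folds)
    unname(report$mean[report$metric == "auc_micro"])
  }
}
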