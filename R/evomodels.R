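# --- model-implied mean/covariance construction ---------------------------
#
# All five models imply a multivariate Gaussian over vec(Y) (column-major:
# trait blocks of length n).  fit_evo_model maximizes the exact Gaussian
# likelihood with the mean parameters profiled out by GLS; no pruning
# shortcuts are taken, which keeps every model on the same dense code path
# that the tests compare against independent oracles.

# robust (1 - exp(-c s)) / c with the c -> 0 limit s
ou_int <- function(c, s) ifelse(abs(c * s) < 1e-12, s, -expm1(-c * s) / c)

# Shared-path covariance structure under EB: integral of exp(b t) over the
# shared root path.
eb_structure <- function(C, b) {
  if (abs(b) < 1e-12) return(C)
  (exp(b * C) - 1) / b
}

# Per-regime shared-time matrices S_k for multi-rate BM.
bmm_structures <- function(tree, painting) {
  rt <- regime_times_to_nodes(painting)
  M <- mrca_matrix(tree)
  n <- length(tree$tip.label)
  lapply(painting$regimes, function(rg) {
    S <- matrix(rt[as.vector(M), rg], n, n,
                dimnames = dimnames(M))
    S
  })
}

# OU covariance and regime weight matrices for diagonal pull alpha.
ou_cov <- function(tree, R, alpha, C = vcv_matrix(tree)) {
  tdep <- diag(C)
  n <- nrow(C); m <- nrow(R)
  V <- matrix(NA_real_, n * m, n * m)
  Ti <- matrix(tdep, n, n)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    ca <- alpha[a]; cb <- alpha[b]
    blk <- R[a, b] * exp(-ca * (Ti - C) - cb * (t(Ti) - C)) *
      ou_int(ca + cb, C)
    V[(a - 1) * n + seq_len(n), (b - 1) * n + seq_len(n)] <- blk
  }
  (V + t(V)) / 2
}

# OU mean weight array W[i, k, a]: contribution of regime-k optimum to the
# expectation of trait a at tip i; the root state is set to the optimum of
# the root regime so weights sum to 1 per (i, a).
ou_weights <- function(tree, painting, alpha,
                       segs = node_path_segments(painting)) {
  n <- length(tree$tip.label)
  K <- length(painting$regimes)
  m <- length(alpha)
  tdep <- node_depths(tree)
  W <- array(0, c(n, K, m))
  root_regime <- {
    first_edge <- preorder_edges(tree)[1]
    match(names(painting$maps[[first_edge]])[1], painting$regimes)
  }
  for (i in seq_len(n)) {
    s <- segs[[i]]
    ti <- tdep[i]
    for (a in seq_len(m)) {
      al <- alpha[a]
      contr <- exp(-al * (ti - s[, 2])) - exp(-al * (ti - s[, 1]))
      for (r in seq_len(nrow(s)))
        W[i, s[r, 3], a] <- W[i, s[r, 3], a] + contr[r]
      W[i, root_regime, a] <- W[i, root_regime, a] + exp(-al * ti)
    }
  }
  W
}

# Mean design matrix (nm x p_mean) for each model.
mean_design <- function(model, tree, m, painting = NULL, alpha = NULL,
                        segs = NULL) {
  n <- length(tree$tip.label)
  if (model %in% c("BM", "BMM", "EB", "OU1")) {
    return(diag(m) %x% matrix(1, n, 1))
  }
  # OUM: one optimum vector per regime
  K <- length(painting$regimes)
  if (is.null(segs)) segs <- node_path_segments(painting)
  W <- ou_weights(tree, painting, alpha, segs)
  D <- matrix(0, n * m, K * m)
  for (a in seq_len(m)) for (k in seq_len(K))
    D[(a - 1) * n + seq_len(n), (k - 1) * m + a] <- W[, k, a]
  D
}

# Profile (GLS) mean and resulting log-likelihood for a given covariance.
gls_profile_loglik <- function(y, V, D) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  Li_y <- backsolve(ch, y, transpose = TRUE)
  Li_D <- backsolve(ch, D, transpose = TRUE)
  XtX <- crossprod(Li_D)
  beta <- tryCatch(solve(XtX, crossprod(Li_D, Li_y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(list(logL = -Inf))
  r <- Li_y - Li_D %*% beta
  logL <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                    sum(r^2))
  list(logL = as.numeric(logL), beta = as.vector(beta))
}

# chol-vector <-> PD matrix parameterization (log-diagonal, free off-diag).
chol_to_mat <- function(theta, m) {
  U <- matrix(0, m, m)
  U[upper.tri(U, diag = TRUE)] <- theta
  diag(U) <- exp(diag(U))
  crossprod(U)
}
mat_to_chol <- function(R) {
  U <- chol(R)
  diag(U) <- log(diag(U))
  U[upper.tri(U, diag = TRUE)]
}

# Analytic ML for models whose covariance is kron(R, C0): GLS mean, ML rate.
kron_bm_ml <- function(Y, C0) {
  n <- nrow(Y); m <- ncol(Y)
  Cinv <- solve(C0)
  a <- gls_mean(Y, Cinv)
  Yc <- sweep(Y, 2, a)
  R <- crossprod(Yc, Cinv %*% Yc) / n
  R <- (R + t(R)) / 2
  ldR <- tryCatch(logdet_pd(R), error = function(e) NA_real_)
  logL <- if (is.na(ldR)) -Inf else
    -0.5 * (n * m * log(2 * pi) + m * logdet_pd(C0) + n * ldR + n * m)
  list(mu = a, R = R, logL = logL)
}

#' Fit a multivariate evolutionary model to tip data
#'
#' Maximum-likelihood fit of one of five Gaussian models of multivariate
#' trait evolution on a time-calibrated (possibly non-ultrametric) tree:
#' single-rate Brownian motion (`BM`), regime-dependent multi-rate Brownian
#' motion (`BMM`), Ornstein-Uhlenbeck with a single optimum (`OU1`) or with
#' per-regime optima (`OUM`, diagonal pull matrix), and early burst (`EB`,
#' exponentially decaying rate). `BMM`/`OUM` require a regime painting; when
#' a list of stochastic paintings is supplied the model is fitted on each
#' and the median-logL fit is returned with the dispersion recorded.
#'
#' @param model one of `"BM"`, `"BMM"`, `"OU1"`, `"OUM"`, `"EB"`.
#' @param tree `phylo` with branch lengths.
#' @param Y n x m matrix of trait values (retained ordination scores), rows
#'   named by taxon.
#' @param painting a [regime_painting()] or a list of them (for `BMM`/`OUM`).
#' @param n_starts number of seeded optimizer starts (first start is a
#'   moment-based initialization, the rest jitter it).
#' @param init optional named list of warm-start parameters (`R`, `R_list`,
#'   `alpha`, `b`).
#' @param seed integer seed controlling start jitter.
#' @return object of class `evo_model_fit` with the fitted parameters,
#'   `logL`, `n_params`, `AIC`, `AICc`, and optimizer diagnostics.
#' @export
fit_evo_model <- function(model = c("BM", "BMM", "OU1", "OUM", "EB"),
                          tree, Y, painting = NULL, n_starts = 5,
                          init = NULL, seed = 1) {
  model <- match.arg(model)
  Y <- align_to_tips(Y, tree)
  n <- nrow(Y); m <- ncol(Y)
  if (model %in% c("BMM", "OUM")) {
    if (is.null(painting)) stop(model, " requires a regime painting")
    if (inherits(painting, "regime_painting")) painting <- list(painting)
    if (length(painting) > 1L) {
      fits <- lapply(painting, function(p)
        fit_evo_model(model, tree, Y, p, n_starts = n_starts, init = init,
                      seed = seed))
      lls <- vapply(fits, `[[`, numeric(1), "logL")
      med <- order(lls)[ceiling(length(lls) / 2)]
      out <- fits[[med]]
      out$logL_dispersion <- stats::sd(lls)
      out$logL_all_maps <- lls
      return(out)
    }
    painting <- painting[[1]]
  }

  y <- as.vector(Y)
  C <- vcv_matrix(tree)
  bm <- kron_bm_ml(Y, C)
  n_rate <- m * (m + 1) / 2

  fit <- switch(model,
    BM = {
      list(logL = bm$logL, params = list(R = bm$R, mu = bm$mu),
         n_params = n_rate + m, diag = list(method = "closed form"))
    },
    EB = {
      Tmax <- max(diag(C))
      prof <- function(b) kron_bm_ml(Y, eb_structure(C, b))$logL
      opt <- stats::optimize(prof, c(-20 / Tmax, 0), maximum = TRUE,
                             tol = 1e-9)
      b <- if (prof(0) >= opt$objective) 0 else opt$maximum
      sol <- kron_bm_ml(Y, eb_structure(C, b))
      list(logL = sol$logL,
           params = list(R = sol$R, mu = sol$mu, b = b),
           n_params = n_rate + m + 1, diag = list(method = "profiled 1-D"))
    },
    BMM = {
      S <- bmm_structures(tree, painting)
      D <- mean_design("BMM", tree, m)
      negll <- function(th) {
        R1 <- chol_to_mat(th[1:n_rate], m)
        R2 <- chol_to_mat(th[n_rate + 1:n_rate], m)
        V <- (R1 %x% S[[1]]) + (R2 %x% S[[2]])
        -gls_profile_loglik(y, V, D)$logL
      }
      th0 <- if (!is.null(init$R_list))
        c(mat_to_chol(init$R_list[[1]]), mat_to_chol(init$R_list[[2]]))
      else rep(mat_to_chol(bm$R + diag(1e-10, m)), 2)
      best <- multistart_optim(negll, th0, n_starts, seed,
                               warm = !is.null(init$R_list) && n_starts == 1)
      R1 <- chol_to_mat(best$par[1:n_rate], m)
      R2 <- chol_to_mat(best$par[n_rate + 1:n_rate], m)
      V <- (R1 %x% S[[1]]) + (R2 %x% S[[2]])
      sol <- gls_profile_loglik(y, V, D)
      Rl <- stats::setNames(list(R1, R2), painting$regimes)
      list(logL = sol$logL,
           params = list(R_list = Rl, mu = sol$beta),
           n_params = 2 * n_rate + m, diag = best$diag)
    },
    OU1 = {
      D <- mean_design("OU1", tree, m)
      Tmax <- max(diag(C))
      negll <- function(th) {
        R <- chol_to_mat(th[1:n_rate], m)
        alpha <- exp(th[n_rate + 1:m])
        V <- ou_cov(tree, R, alpha, C)
        -gls_profile_loglik(y, V, D)$logL
      }
      th0 <- c(if (!is.null(init$R)) mat_to_chol(init$R)
               else mat_to_chol(bm$R + diag(1e-10, m)),
               if (!is.null(init$alpha)) log(init$alpha)
               else rep(log(log(2) / Tmax), m))
      best <- multistart_optim(negll, th0, n_starts, seed,
                               warm = !is.null(init$R) && n_starts == 1)
      R <- chol_to_mat(best$par[1:n_rate], m)
      alpha <- exp(best$par[n_rate + 1:m])
      sol <- gls_profile_loglik(y, ou_cov(tree, R, alpha, C), D)
      list(logL = sol$logL,
           params = list(R = R, alpha = alpha, theta = sol$beta),
           n_params = n_rate + 2 * m, diag = best$diag)
    },
    OUM = {
      Tmax <- max(diag(C))
      K <- length(painting$regimes)
      segs <- node_path_segments(painting)
      negll <- function(th) {
        R <- chol_to_mat(th[1:n_rate], m)
        alpha <- exp(th[n_rate + 1:m])
        V <- ou_cov(tree, R, alpha, C)
        D <- mean_design("OUM", tree, m, painting, alpha, segs)
        -gls_profile_loglik(y, V, D)$logL
      }
      th0 <- c(if (!is.null(init$R)) mat_to_chol(init$R)
               else mat_to_chol(bm$R + diag(1e-10, m)),
               if (!is.null(init$alpha)) log(init$alpha)
               else rep(log(log(2) / Tmax), m))
      best <- multistart_optim(negll, th0, n_starts, seed,
                               warm = !is.null(init$R) && n_starts == 1)
      R <- chol_to_mat(best$par[1:n_rate], m)
      alpha <- exp(best$par[n_rate + 1:m])
      D <- mean_design("OUM", tree, m, painting, alpha, segs)
      sol <- gls_profile_loglik(y, ou_cov(tree, R, alpha, C), D)
      theta <- matrix(sol$beta, m, K,
                      dimnames = list(colnames(Y), painting$regimes))
      list(logL = sol$logL,
           params = list(R = R, alpha = alpha, theta = theta),
           n_params = n_rate + m + K * m, diag = best$diag)
    })

  if (!is.finite(fit$logL))
    stop("fit_evo_model(", model, "): optimization did not reach a finite ",
         "likelihood")
  aic <- 2 * fit$n_params - 2 * fit$logL
  nobs <- n * m
  aicc <- if (nobs - fit$n_params - 1 > 0)
    aic + 2 * fit$n_params * (fit$n_params + 1) / (nobs - fit$n_params - 1)
  else Inf
  structure(list(model = model, logL = fit$logL, n_params = fit$n_params,
                 AIC = aic, AICc = aicc, params = fit$params,
                 painting = painting, n = n, m = m, seed = seed,
                 data_signature = data_signature(Y),
                 optimizer = fit$diag),
            class = "evo_model_fit")
}

data_signature <- function(Y)
  paste(nrow(Y), ncol(Y), format(sum(Y^2), digits = 15),
        format(sum(Y), digits = 15))

multistart_optim <- function(negll, th0, n_starts, seed, warm = FALSE) {
  if (warm) {
    # warm restart near an optimum (bootstrap refits): a single
    # quasi-Newton polish is sufficient and much cheaper
    res <- tryCatch(
      stats::optim(th0, negll, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value)) {
      res$diag <- list(method = "warm BFGS", starts = 1L,
                       failed_starts = 0L, value = res$value,
                       convergence = res$convergence)
      return(res)
    }
  }
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    if (s == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.25)
  }))
  best <- NULL
  fails <- 0L
  for (th in starts) {
    res <- tryCatch(
      stats::optim(th, negll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res)) {
      res <- tryCatch(
        stats::optim(res$par, negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) res)
    }
    if (is.null(res)) { fails <- fails + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  best$diag <- list(method = "Nelder-Mead + BFGS", starts = n_starts,
                    failed_starts = fails, value = best$value,
                    convergence = best$convergence)
  best
}

#' @export
print.evo_model_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.3f, k = %d, AIC = %.3f, AICc = %.3f\n",
              x$model, x$logL, x$n_params, x$AIC, x$AICc))
  if (!is.null(x$AICw)) cat(sprintf("  AICw = %.3f\n", x$AICw))
  if (!is.null(x$params$R))
    cat("  rate diag:", paste(signif(diag(x$params$R), 4), collapse = ", "),
        "\n")
  if (!is.null(x$params$R_list))
    for (rg in names(x$params$R_list))
      cat("  rate diag [", rg, "]: ",
          paste(signif(diag(x$params$R_list[[rg]]), 4), collapse = ", "),
          "\n", sep = "")
  if (!is.null(x$params$alpha))
    cat("  alpha:", paste(signif(x$params$alpha, 4), collapse = ", "), "\n")
  if (!is.null(x$params$b)) cat("  EB exponent b:", signif(x$params$b, 4),
                                "\n")
  invisible(x)
}

#' @export
logLik.evo_model_fit <- function(object, ...)
  structure(object$logL, df = object$n_params, class = "logLik")

#' Akaike weights for a set of fitted models
#'
#' @param fits list of `evo_model_fit` objects fitted to identical data.
#' @param criterion `"AIC"` (default) or `"AICc"`.
#' @return the list with an `AICw` element added to each fit, and an
#'   attribute `table` holding a model-comparison data frame.
#' @export
aic_weights <- function(fits, criterion = c("AIC", "AICc")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 2) stop("need at least two fits")
  sigs <- vapply(fits, `[[`, character(1), "data_signature")
  if (length(unique(sigs)) != 1L)
    stop("fits were not computed on identical data")
  ic <- vapply(fits, `[[`, numeric(1), criterion)
  d <- ic - min(ic)
  w <- exp(-d / 2) / sum(exp(-d / 2))
  for (i in seq_along(fits)) fits[[i]]$AICw <- w[i]
  nm <- names(fits) %||% vapply(fits, `[[`, character(1), "model")
  attr(fits, "table") <- data.frame(
    model = nm,
    logL = vapply(fits, `[[`, numeric(1), "logL"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    AICc = vapply(fits, `[[`, numeric(1), "AICc"),
    AICw = w, row.names = NULL)
  fits
}

#' Simulate tip data from a fitted (or specified) evolutionary model
#'
#' Exact Gaussian draw from the model-implied mean and covariance on the
#' tree (no time discretization).
#'
#' @param fit an `evo_model_fit`, or a list with elements `model` and the
#'   parameters (`R` or `R_list`, `mu`/`theta`, `alpha`, `b`).
#' @param tree `phylo`.
#' @param painting regime painting (required for `BMM`/`OUM`).
#' @param seed integer seed.
#' @param n_sim number of datasets.
#' @return an n x m matrix (or a list of them when `n_sim > 1`), rows named
#'   by taxon.
#' @export
simulate_from_model <- function(fit, tree, painting = NULL, seed = 1,
                                n_sim = 1) {
  model <- fit$model
  p <- if (inherits(fit, "evo_model_fit")) fit$params else fit
  if (model %in% c("BMM", "OUM") && is.null(painting))
    painting <- fit$painting
  n <- length(tree$tip.label)
  C <- vcv_matrix(tree)
  m <- if (!is.null(p[["R"]])) nrow(as.matrix(p[["R"]])) else nrow(p[["R_list"]][[1]])
  if (model == "BM") {
    V <- as.matrix(p[["R"]]) %x% C
    mu <- rep(p[["mu"]], each = n)
  } else if (model == "EB") {
    V <- as.matrix(p[["R"]]) %x% eb_structure(C, p[["b"]])
    mu <- rep(p[["mu"]], each = n)
  } else if (model == "BMM") {
    S <- bmm_structures(tree, painting)
    V <- Reduce(`+`, lapply(seq_along(S), function(k)
      as.matrix(p[["R_list"]][[k]]) %x% S[[k]]))
    mu <- rep(p[["mu"]], each = n)
  } else if (model == "OU1") {
    V <- ou_cov(tree, as.matrix(p[["R"]]), p[["alpha"]])
    mu <- rep(p[["theta"]], each = n)
  } else if (model == "OUM") {
    V <- ou_cov(tree, as.matrix(p[["R"]]), p[["alpha"]])
    D <- mean_design("OUM", tree, m, painting, p[["alpha"]])
    mu <- as.vector(D %*% as.vector(p[["theta"]]))
  } else stop("unknown model ", model)
  L <- chol_psd(V)
  out <- with_seed(seed, lapply(seq_len(n_sim), function(s) {
    yv <- mu + as.vector(t(L) %*% stats::rnorm(n * m))
    matrix(yv, n, m, dimnames = list(tree$tip.label, NULL))
  }))
  if (n_sim == 1) out[[1]] else out
}

#' Parametric-bootstrap adequacy of a fitted model
#'
#' Simulates datasets under the fitted model, refits the same model to
#' each, and builds percentile confidence intervals for the diagonal
#' parameters (rate-matrix diagonals, plus pull and burst parameters where
#' present). The model is judged adequate when every observed diagonal
#' parameter falls inside its interval.
#'
#' @param fit converged `evo_model_fit`.
#' @param tree `phylo` used for the fit.
#' @param n_sim number of bootstrap datasets (default 500).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return object of class `adequacy_result`.
#' @export
adequacy_bootstrap <- function(fit, tree, n_sim = 500, seed = 1,
                               level = 0.95) {
  obs <- diag_params(fit)
  sims <- simulate_from_model(fit, tree, painting = fit$painting,
                              seed = seed, n_sim = n_sim)
  init <- fit$params
  boot <- matrix(NA_real_, n_sim, length(obs),
                 dimnames = list(NULL, names(obs)))
  failures <- 0L
  for (s in seq_len(n_sim)) {
    rf <- tryCatch(
      fit_evo_model(fit$model, tree, sims[[s]], painting = fit$painting,
                    n_starts = 1, init = init, seed = seed + s),
      error = function(e) NULL)
    if (is.null(rf)) { failures <- failures + 1L; next }
    boot[s, ] <- diag_params(rf)
  }
  if (failures > 0.1 * n_sim)
    warning(failures, " of ", n_sim, " bootstrap refits failed")
  a <- (1 - level) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  inside <- obs >= ci[1, ] & obs <= ci[2, ]
  structure(list(observed = obs, lower = ci[1, ], upper = ci[2, ],
                 inside = inside, adequate = all(inside), n_sim = n_sim,
                 failures = failures, seed = seed, model = fit$model),
            class = "adequacy_result")
}

diag_params <- function(fit) {
  p <- fit$params
  out <- numeric(0)
  if (!is.null(p[["R"]])) out <- c(out, stats::setNames(
    diag(as.matrix(p[["R"]])), paste0("sigma2_", seq_len(fit$m))))
  if (!is.null(p[["R_list"]]))
    for (rg in names(p[["R_list"]]))
      out <- c(out, stats::setNames(diag(as.matrix(p[["R_list"]][[rg]])),
                                    paste0("sigma2_", rg, "_",
                                           seq_len(fit$m))))
  if (!is.null(p[["alpha"]])) out <- c(out, stats::setNames(
    p[["alpha"]], paste0("alpha_", seq_len(fit$m))))
  if (!is.null(p[["b"]])) out <- c(out, b = p[["b"]])
  out
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat("Parametric-bootstrap adequacy of the", x$model, "model (",
      x$n_sim, "simulations, seed", x$seed, ")\n")
  tab <- data.frame(observed = x$observed, lower = x$lower, upper = x$upper,
                    inside = x$inside)
  print(round(tab[1:3], 5))
  cat("  verdict:", if (x$adequate) "adequate" else "NOT adequate",
      sprintf("(%d/%d parameters inside)\n", sum(x$inside),
              length(x$inside)))
  invisible(x)
}
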