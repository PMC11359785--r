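# Marginal maximum-likelihood machinery for the reference mixed-effects
# model: Gauss-Hermite nodes by Golub-Welsch, per-study adaptive quadrature
# over the scalar random effect on logit(F), and a restarted quasi-Newton
# optimizer with asymptotic (delta-method) confidence intervals.

#' Gauss-Hermite nodes and weights
#'
#' Physicists' convention: `sum(w * f(x))` approximates
#' `integral exp(-x^2) f(x) dx`. Computed by eigendecomposition of the
#' Jacobi matrix (Golub-Welsch).
#'
#' @param n Number of nodes (>= 1).
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}

# log p(y | eta) for one study arm: proportional residual error about the
# predicted means. Returns -Inf for non-finite or non-positive predictions.
study_loglik_eta <- function(params, design, y, eta_f) {
  mu <- predict_means(params, design, eta_f)
  if (any(!is.finite(mu)) || any(mu <= 0) || params$sigma_prop <= 0) {
    return(-Inf)
  }
  sum(stats::dnorm(y, mean = mu, sd = params$sigma_prop * mu, log = TRUE))
}

# studies are grouped by study_id: arms of the same trial share one eta;
# arms without an id are treated as singleton studies
group_datasets <- function(datasets) {
  ids <- vapply(datasets, function(d) d$design$study_id, character(1))
  anon <- is.na(ids)
  ids[anon] <- paste0(".anon", which(anon))
  split(datasets, factor(ids, levels = unique(ids)))
}

# does any arm of the group depend on eta (i.e., is oral)?
group_uses_eta <- function(group) {
  any(vapply(group, function(d) d$design$route == "oral", logical(1)))
}

group_loglik_eta <- function(params, group, eta_f) {
  sum(vapply(group, function(d) {
    study_loglik_eta(params, d$design, d$conc, eta_f)
  }, numeric(1)))
}

# Per-arm cache exploiting linearity of the oral solution in F: the typical
# prediction is computed once and rescaled by F(eta)/F(0) per quadrature
# node, which is exact for a linear kinetic system.
arm_cache <- function(params, arm) {
  d <- arm$design
  mu0 <- predict_means(params, d, 0)
  f0 <- if (d$route == "oral") {
    if (d$efv) params$f_oral_efv else params$f_oral
  } else NA_real_
  list(mu0 = mu0, y = arm$conc, oral = d$route == "oral",
       logit_f0 = if (is.na(f0)) NA_real_ else stats::qlogis(f0), f0 = f0)
}

cached_loglik_eta <- function(cache, sigma, eta_f) {
  total <- 0
  for (a in cache) {
    mu <- a$mu0
    if (a$oral && eta_f != 0) {
      mu <- mu * (stats::plogis(a$logit_f0 + eta_f) / a$f0)
    }
    if (any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
    total <- total + sum(stats::dnorm(a$y, mu, sigma * mu, log = TRUE))
  }
  total
}

#' Marginal log-likelihood of the reference mixed-effects model
#'
#' Integrates the scalar study-level random effect on logit(F) out of the
#' likelihood, per study, by adaptive Gauss-Hermite quadrature (default;
#' nodes recentred at the conditional mode and rescaled by the conditional
#' curvature) or by brute-force trapezoidal integration on a wide grid
#' (cross-check). Studies without an oral arm do not depend on the random
#' effect and contribute their conditional likelihood directly.
#'
#' @param params A [mem_params()].
#' @param datasets List of `list(design = study_design, conc = numeric)`.
#' @param method `"agq"` or `"trapezoid"`.
#' @param nodes Number of quadrature nodes for AGQ (>= 9 recommended).
#' @param grid_points,grid_width Trapezoid grid resolution and half-width
#'   in units of `omega_f`.
#' @return Marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(params, datasets, method = c("agq", "trapezoid"),
                            nodes = 9, grid_points = 2001, grid_width = 10) {
  method <- match.arg(method)
  stopifnot(inherits(params, "mem_params"))
  groups <- group_datasets(datasets)
  if (params$sigma_prop <= 0) return(-Inf)
  total <- 0
  for (group in groups) {
    cache <- lapply(group, function(a) arm_cache(params, a))
    if (params$omega_f < 1e-8 || !group_uses_eta(group)) {
      total <- total + cached_loglik_eta(cache, params$sigma_prop, 0)
      next
    }
    g <- function(eta) {
      cached_loglik_eta(cache, params$sigma_prop, eta) +
        stats::dnorm(eta, 0, params$omega_f, log = TRUE)
    }
    if (method == "agq") {
      total <- total + agq_log_integral(g, params$omega_f, nodes)
    } else {
      etas <- seq(-grid_width * params$omega_f, grid_width * params$omega_f,
                  length.out = grid_points)
      lg <- vapply(etas, g, numeric(1))
      m <- max(lg)
      total <- total + m +
        log(pracma_trapz(etas, exp(lg - m)))
    }
  }
  total
}

# trapezoid rule (kept dependency-free)
pracma_trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# log of integral exp(g(eta)) d eta by adaptive GH: mode by 1-d
# optimization, scale from the numeric curvature at the mode
agq_log_integral <- function(g, omega, nodes) {
  opt <- stats::optimize(g, interval = c(-8 * omega, 8 * omega),
                         maximum = TRUE, tol = 1e-8)
  mode <- opt$maximum
  h <- max(1e-5, 1e-4 * omega)
  curv <- (g(mode + h) - 2 * opt$objective + g(mode - h)) / h^2
  scale <- if (is.finite(curv) && curv < 0) 1 / sqrt(-curv) else omega
  gh <- gauss_hermite(nodes)
  z <- mode + sqrt(2) * scale * gh$nodes
  lg <- vapply(z, g, numeric(1)) + gh$nodes^2 + log(gh$weights) +
    log(sqrt(2) * scale)
  m <- max(lg)
  m + log(sum(exp(lg - m)))
}

# natural <-> unconstrained transforms for the estimated parameters
mem_par_names <- c("cl", "cl_efv", "vss_per_kg", "q_inter", "ka",
                   "f_oral", "f_oral_efv", "omega_f", "sigma_prop")

mem_transform <- function(values, names) {
  logit <- names %in% c("f_oral", "f_oral_efv")
  out <- numeric(length(values))
  out[logit] <- stats::qlogis(values[logit])
  out[!logit] <- log(values[!logit])
  out
}

mem_untransform <- function(theta, names) {
  logit <- names %in% c("f_oral", "f_oral_efv")
  out <- numeric(length(theta))
  out[logit] <- stats::plogis(theta[logit])
  out[!logit] <- exp(theta[!logit])
  out
}

set_params <- function(params, names, values) {
  for (i in seq_along(names)) params[[names[i]]] <- values[i]
  params
}

#' Fit the reference mixed-effects model by marginal maximum likelihood
#'
#' Maximizes [marginal_loglik()] over the named parameters (log scale for
#' positive quantities, logit for bioavailabilities) with `n_restarts`
#' seeded jittered starts around `init`, keeping the best optimum. The
#' identifiability precondition mirrors the design of the pooled analysis:
#' at least two studies, and at least one IV or implant arm, without which
#' oral F cannot be separated from clearance.
#'
#' @param datasets List of `list(design, conc)` pairs (>= 2 studies).
#' @param init A [mem_params()] of initial values (the printed estimates
#'   are the natural choice).
#' @param estimate Names of parameters to estimate (default all of
#'   clearances, volume, Q, ka, bioavailabilities, omega_f, sigma_prop).
#' @param n_restarts Number of jittered restarts (>= 1).
#' @param jitter_sd SD of the transformed-scale jitter.
#' @param seed Seed for the restart jitter.
#' @param nodes Quadrature nodes for AGQ.
#' @return Object of class `mem_fit`: `params` (fitted [mem_params()]),
#'   `estimates` (data frame with estimate, SE, 95% CI per parameter),
#'   `loglik`, `convergence` (0 = clean), and `init_loglik`.
#' @export
fit_mem <- function(datasets, init = mem_params(),
                    estimate = mem_par_names,
                    n_restarts = 3, jitter_sd = 0.2, seed = 1, nodes = 9) {
  stopifnot(length(datasets) >= 2, all(estimate %in% mem_par_names))
  routes <- vapply(datasets, function(d) d$design$route, character(1))
  if (!any(routes %in% c("iv", "implant"))) {
    stop(paste("fit_mem(): no IV or implant arm in the data;",
               "parameter 'f_oral' is not identifiable from oral arms alone"))
  }
  has_efv <- any(vapply(datasets, function(d) d$design$efv, logical(1)))
  if (!has_efv) {
    estimate <- setdiff(estimate, c("cl_efv", "f_oral_efv"))
  }

  nat0 <- unlist(init[estimate])
  theta0 <- mem_transform(nat0, estimate)
  negll <- function(theta) {
    p <- set_params(init, estimate, mem_untransform(theta, estimate))
    ll <- tryCatch(marginal_loglik(p, datasets, nodes = nodes),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  init_ll <- -negll(theta0)
  set.seed(seed)
  starts <- c(list(theta0), lapply(seq_len(max(0, n_restarts - 1)), function(i) {
    theta0 + stats::rnorm(length(theta0), 0, jitter_sd)
  }))
  best <- NULL
  for (s in starts) {
    opt <- try(stats::nlminb(s, negll,
                             control = list(iter.max = 500, eval.max = 1000)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("fit_mem(): all optimizer starts failed")

  theta_hat <- best$par
  fitted <- set_params(init, estimate, mem_untransform(theta_hat, estimate))

  # asymptotic SEs from the numeric Hessian; delta method back to the
  # natural scale (non-PD Hessian -> NA SEs with the parameter named)
  H <- try(stats::optimHess(theta_hat, negll), silent = TRUE)
  se_nat <- rep(NA_real_, length(estimate))
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      se_t <- sqrt(diag(V))
      nat <- mem_untransform(theta_hat, estimate)
      deriv <- ifelse(estimate %in% c("f_oral", "f_oral_efv"),
                      nat * (1 - nat), nat)
      se_nat <- se_t * deriv
    } else {
      warning("fit_mem(): information matrix not positive definite; ",
              "flat direction involves '",
              estimate[which.max(if (inherits(V, "try-error"))
                -diag(H) else -diag(as.matrix(V)))],
              "'; standard errors not available")
    }
  }
  nat <- mem_untransform(theta_hat, estimate)
  est <- data.frame(parameter = estimate, estimate = nat, se = se_nat,
                    lower95 = nat - 1.96 * se_nat,
                    upper95 = nat + 1.96 * se_nat)
  structure(list(params = fitted, estimates = est,
                 loglik = -best$objective, init_loglik = init_ll,
                 convergence = best$convergence,
                 message = best$message),
            class = "mem_fit")
}

#' @export
print.mem_fit <- function(x, ...) {
  cat(sprintf("<mem_fit> marginal log-likelihood %.4f (convergence %d)\n",
              x$loglik, x$convergence))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read / write pooled mean-concentration datasets as CSV
#'
#' Column layout: `study_id, route, dose_mg, time_h, mean_conc_pg_ml,
#' efv_flag`. Each (study_id, route, efv_flag) combination becomes one arm;
#' repeated oral dose times are encoded in an optional `dose_times_h`
#' column as a `;`-separated list.
#'
#' @param path CSV file path.
#' @return For the reader: list of `list(design, conc)`.
#' @export
read_mem_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "route", "dose_mg", "time_h", "mean_conc_pg_ml",
            "efv_flag")
  stopifnot(all(need %in% names(df)))
  keys <- unique(df[, c("study_id", "route", "dose_mg", "efv_flag")])
  lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$study_id == k$study_id & df$route == k$route &
                df$dose_mg == k$dose_mg & df$efv_flag == k$efv_flag, ]
    sub <- sub[order(sub$time_h), ]
    dt <- if ("dose_times_h" %in% names(sub) && nzchar(sub$dose_times_h[1])) {
      as.numeric(strsplit(as.character(sub$dose_times_h[1]), ";")[[1]])
    } else 0
    list(design = study_design(route = k$route, dose_mg = k$dose_mg,
                               sampling_times_h = sub$time_h,
                               dose_times_h = dt,
                               efv = as.logical(k$efv_flag),
                               study_id = as.character(k$study_id)),
         conc = sub$mean_conc_pg_ml)
  })
}

#' @rdname read_mem_csv
#' @param datasets List of `list(design, conc)` pairs to serialize.
#' @export
write_mem_csv <- function(datasets, path) {
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(study_id = d$design$study_id,
               route = d$design$route,
               dose_mg = d$design$dose_mg,
               time_h = d$design$sampling_times_h,
               mean_conc_pg_ml = d$conc,
               efv_flag = d$design$efv,
               dose_times_h = paste(d$design$dose_times_h, collapse = ";"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
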