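#' Pooled-SD Cohen's d between two groups
#'
#' `d = (mean2 - mean1) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#' By the sign convention used throughout, group 1 is the control group and
#' group 2 the patient group, so positive `d` means higher in patients.
#'
#' @param mean1,sd1,n1 control-group summary statistics.
#' @param mean2,sd2,n2 patient-group summary statistics.
#' @return Cohen's d.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp <= 0) stop("zero pooled variance: effect size undefined")
  (mean2 - mean1) / sp
}

#' Topographic permutation test (TANOVA)
#'
#' Nonparametric randomization test for a topographic difference between
#' two groups of subject mean maps. Each map is normalized to unit GFP; the
#' test statistic is the GFP of the difference between the two group-mean
#' normalized maps (global map dissimilarity), and the permutation
#' distribution is obtained by shuffling subjects' group labels.
#' `p = (1 + #{permuted >= observed}) / (1 + n_perm)`.
#'
#' @param maps_group1,maps_group2 matrices `n_subjects x n_channels` of
#'   average-referenced subject mean maps (>= 2 rows each).
#' @param n_perm number of permutations (default 4999; < 99 rejected).
#' @param seed integer seed.
#' @return list with `p`, `statistic`, `n_perm`.
#' @export
tanova <- function(maps_group1, maps_group2, n_perm = 4999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  n1 <- nrow(maps_group1); n2 <- nrow(maps_group2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  # canonical within-group row order makes p invariant to how subjects are
  # listed inside each group (given the seed)
  canon <- function(m) m[do.call(order, as.data.frame(m)), , drop = FALSE]
  M <- normalize_map(rbind(canon(maps_group1), canon(maps_group2)))
  n <- n1 + n2
  stat_for <- function(w) sqrt(rowMeans((w %*% M)^2))
  w_obs <- matrix(c(rep(1 / n1, n1), rep(-1 / n2, n2)), nrow = 1)
  observed <- stat_for(w_obs)
  rng <- local_rng(seed)
  perms <- rng$eval(function() {
    t(replicate(n_perm, sample.int(n)))
  })
  W <- matrix(-1 / n2, n_perm, n)
  for (r in seq_len(n_perm)) W[r, perms[r, 1:n1]] <- 1 / n1
  perm_stats <- stat_for(W)
  list(p = (1 + sum(perm_stats >= observed)) / (1 + n_perm),
       statistic = as.numeric(observed), n_perm = n_perm)
}

#' Electrode-wise two-sample t-tests on normalized absolute voltage
#'
#' Normalizes each subject map to unit GFP, takes the absolute voltage per
#' electrode, and computes pooled-variance two-sample t-tests per
#' electrode with two-sided p-values. Electrodes with zero pooled variance
#' are flagged and recorded with `t = 0`, `p = 1`.
#'
#' @param maps_group1,maps_group2 matrices `n_subjects x n_channels`.
#' @return data.frame `electrode`, `t`, `p`, `flagged`.
#' @export
electrodewise_t <- function(maps_group1, maps_group2) {
  a1 <- abs(normalize_map(maps_group1))
  a2 <- abs(normalize_map(maps_group2))
  n1 <- nrow(a1); n2 <- nrow(a2)
  m1 <- colMeans(a1); m2 <- colMeans(a2)
  v1 <- apply(a1, 2, stats::var); v2 <- apply(a2, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  flagged <- se <= .Machine$double.eps
  tval <- ifelse(flagged, 0, (m1 - m2) / se)
  pval <- ifelse(flagged, 1, 2 * stats::pt(-abs(tval), df = n1 + n2 - 2))
  data.frame(electrode = seq_along(m1), t = tval, p = pval, flagged = flagged)
}

#' Per-class group contrasts from a linear mixed-effects model
#'
#' Fits `feature ~ class * group + age + sex + (1 | subject)` by maximum
#' likelihood and reports, for every microstate class, the group effect
#' (patient minus control, i.e. the group main effect plus the class-specific
#' interaction), its standard error, Wald z, and two-sided p.
#'
#' @param feature_table data.frame from [feature_table()] with columns
#'   `subject`, `group`, `age`, `sex`, `label`, and the feature columns.
#' @param feature `"mean_duration"` or `"occurrence"`.
#' @param reml fit by REML instead of ML (default `FALSE`).
#' @return data.frame `label`, `estimate`, `se`, `z`, `p`; attribute
#'   `"singular"` flags a singular fit.
#' @export
lmm_contrasts <- function(feature_table,
                          feature = c("mean_duration", "occurrence"),
                          reml = FALSE) {
  feature <- match.arg(feature)
  col <- c(mean_duration = "mean_duration_ms",
           occurrence = "occurrence_per_s")[[feature]]
  d <- feature_table
  d$value <- d[[col]]
  d$class_f <- factor(d$label)
  d$group_f <- factor(d$group, levels = c("control", "patient"))
  d$sex_f <- factor(d$sex)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (nlevels(droplevels(d$class_f)) < 2) {
    # single class degenerates to a plain linear model
    fit <- stats::lm(value ~ group_f + age + sex_f, data = d)
    est <- stats::coef(fit)[["group_fpatient"]]
    se <- sqrt(stats::vcov(fit)["group_fpatient", "group_fpatient"])
    z <- est / se
    return(structure(data.frame(label = levels(droplevels(d$class_f)),
                                estimate = est, se = se, z = z,
                                p = 2 * stats::pnorm(-abs(z))),
                     singular = FALSE))
  }
  fit <- lme4::lmer(value ~ class_f * group_f + age + sex_f + (1 | subject),
                    data = d, REML = reml)
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  classes <- levels(d$class_f)
  out <- lapply(classes, function(cl) {
    L <- stats::setNames(numeric(length(beta)), names(beta))
    L["group_fpatient"] <- 1
    inter <- paste0("class_f", cl, ":group_fpatient")
    if (inter %in% names(beta)) L[inter] <- 1
    est <- sum(L * beta)
    se <- sqrt(as.numeric(t(L) %*% V %*% L))
    z <- est / se
    data.frame(label = cl, estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  })
  structure(do.call(rbind, out), singular = lme4::isSingular(fit))
}

# --- Dirichlet regression (common parameterization) -----------------------

#' Dirichlet log-likelihood
#'
#' `sum_j [ lgamma(sum_c alpha_jc) - sum_c lgamma(alpha_jc)
#'          + sum_c (alpha_jc - 1) log y_jc ]`.
#'
#' @param alpha matrix `n x k` of positive concentration parameters.
#' @param y matrix `n x k` of simplex observations (strictly interior).
#' @return scalar log-likelihood.
#' @export
dirichlet_loglik <- function(alpha, y) {
  stopifnot(all(dim(alpha) == dim(y)), all(alpha > 0), all(y > 0), all(y < 1))
  sum(lgamma(rowSums(alpha)) - rowSums(lgamma(alpha)) +
        rowSums((alpha - 1) * log(y)))
}

# Draws from Dirichlet(alpha) rows via gamma variates.
rdirichlet <- function(n, alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, n, length(alpha), byrow = TRUE)
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha))
  g / rowSums(g)
}

#' Dirichlet regression of compositional outcomes on covariates
#'
#' Common parameterization: `alpha_jc = exp(x_j' beta_c)`, one coefficient
#' vector per class, fitted by maximum likelihood (BFGS with analytic
#' gradient). Wald z and two-sided p per coefficient come from the inverse
#' observed information at the optimum.
#'
#' @param y matrix `n x k` of compositions. Rows are renormalized to sum 1;
#'   boundary zeros are nudged by 1e-6 and renormalized (the Dirichlet
#'   density is undefined on the simplex boundary).
#' @param x design matrix `n x p` (include an intercept column).
#' @param maxit optimizer iteration cap (default 500).
#' @return list of class `ms_dirichlet_fit`: `coefficients` (`p x k`),
#'   `se`, `z`, `p` (same shape), `alpha` (fitted, `n x k`), `loglik`,
#'   `loglik_start`, `converged`, `grad_norm`, `vcov`.
#' @export
dirichlet_regression <- function(y, x, maxit = 500L) {
  y <- as.matrix(y); x <- as.matrix(x)
  stopifnot(nrow(y) == nrow(x))
  y <- y / rowSums(y)
  if (any(y <= 0)) {
    y <- y + 1e-6
    y <- y / rowSums(y)
  }
  n <- nrow(y); k <- ncol(y); p <- ncol(x)
  logy <- log(y)
  nll <- function(b) {
    beta <- matrix(b, p, k)
    alpha <- exp(x %*% beta)
    -(sum(lgamma(rowSums(alpha))) - sum(lgamma(alpha)) +
        sum((alpha - 1) * logy))
  }
  ngr <- function(b) {
    beta <- matrix(b, p, k)
    alpha <- exp(x %*% beta)
    core <- alpha * (digamma(rowSums(alpha)) - digamma(alpha) + logy)
    -as.numeric(crossprod(x, core))
  }
  # moment-based start: common precision, class means
  m <- colMeans(y); v <- pmax(apply(y, 2, stats::var), 1e-8)
  s0 <- max(2, stats::median(m * (1 - m) / v - 1))
  b0 <- matrix(0, p, k)
  b0[1, ] <- log(m * s0)
  ll_start <- -nll(as.numeric(b0))
  opt <- stats::optim(as.numeric(b0), nll, ngr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12),
                      hessian = TRUE)
  grad_norm <- sqrt(sum(ngr(opt$par)^2))
  if (opt$convergence != 0) {
    warning("Dirichlet regression did not converge (code ", opt$convergence,
            "); gradient norm ", signif(grad_norm, 3))
  }
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("observed information singular; standard errors unavailable")
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  beta <- matrix(opt$par, p, k,
                 dimnames = list(colnames(x), colnames(y)))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, k, dimnames = dimnames(beta))
  z <- beta / se
  structure(list(
    coefficients = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
    alpha = exp(x %*% beta), loglik = -opt$value, loglik_start = ll_start,
    converged = opt$convergence == 0, grad_norm = grad_norm, vcov = V
  ), class = "ms_dirichlet_fit")
}

#' Family-wise error threshold for the tested group effects
#'
#' Three dynamic features are tested per class, but the coverage contrasts
#' are not counted as independent tests (coverage is deducible from mean
#' duration and occurrence), so the cutoff is `0.05 / (2 k_star)`.
#'
#' @param k_star number of microstate classes (>= 1).
#' @return list with `cutoff` and `n_effects` (`3 k_star`, for the record).
#' @export
fwer_threshold <- function(k_star) {
  stopifnot(k_star >= 1)
  list(cutoff = 0.05 / (2 * k_star), n_effects = 3L * as.integer(k_star))
}
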