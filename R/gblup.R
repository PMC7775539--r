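#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum_j p_j (1 - p_j)) where Z holds allele doses centered
#' by twice the allele frequency. Frequencies are computed from the supplied
#' matrix (training and testing animals together); missing doses are
#' mean-imputed first; monomorphic columns are excluded from numerator and
#' denominator with a message.
#'
#' @param geno dose matrix (0/1/2, NA missing) for all animals involved.
#' @return symmetric relationship matrix with sample ids as dimnames;
#'   attribute `"n_snps_used"` records the column count after exclusions.
#' @export
compute_grm <- function(geno) {
  if (nrow(geno) < 2) stopf("GRM needs at least 2 samples")
  g <- impute_mean(geno)
  p <- colMeans(g) / 2
  mono <- p <= 0 | p >= 1 | apply(g, 2, var) == 0
  if (any(mono)) {
    message(sprintf("compute_grm: excluded %d monomorphic SNP(s)", sum(mono)))
    g <- g[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (!ncol(g)) stopf("no polymorphic SNPs left for the GRM")
  Z <- sweep(g, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  G <- (G + t(G)) / 2
  attr(G, "n_snps_used") <- ncol(g)
  G
}

#' Pedigree numerator relationship matrix
#'
#' Expected additive relationships from the pedigree via the tabular
#' method. Used mainly as the G = A limit to check GBLUP against classic
#' pedigree BLUP on small examples.
#'
#' @param pedigree data frame with id, sire, dam.
#' @return the A matrix with ids as dimnames.
#' @export
pedigree_nrm <- function(pedigree) {
  gen <- assign_generations(pedigree)
  ord <- order(gen[pedigree$id])
  ids <- pedigree$id[ord]
  sire <- pedigree$sire[ord]
  dam <- pedigree$dam[ord]
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- match(sire[i], ids)
    d <- match(dam[i], ids)
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(s)) a <- a + 0.5 * A[j, s]
      if (!is.na(d)) a <- a + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- a
    }
  }
  A[pedigree$id, pedigree$id]
}

check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stopf("relationship matrix is not positive semidefinite (min eigenvalue %.3g); consider diagonal bending (adding a small constant to the diagonal)",
          min(ev))
  invisible(ev)
}

# REML log-likelihood pieces in the eigenbasis of K (X = intercept only).
# Returns quadratic forms and traces needed by EM / gradient / deviance.
reml_parts <- function(sg, se, d, yt, xt) {
  v <- sg * d + se
  xvx <- sum(xt^2 / v)
  w <- yt / v - (xt / v) * (sum(xt * yt / v) / xvx)   # P y in eigenbasis
  tr_pk <- sum(d / v) - sum(xt^2 * d / v^2) / xvx
  tr_p <- sum(1 / v) - sum(xt^2 / v^2) / xvx
  list(w = w, tr_pk = tr_pk, tr_p = tr_p,
       ypkpy = sum(d * w^2), yppy = sum(w^2), ypy = sum(yt * w),
       logdet_v = sum(log(v)), logdet_xvx = log(xvx))
}

reml_deviance <- function(parts) {
  parts$logdet_v + parts$logdet_xvx + parts$ypy
}

#' Estimate additive and residual variance components
#'
#' Fits y = 1 mu + g + e with g ~ N(0, K sigma2_g), e ~ N(0, I sigma2_e).
#' `method = "reml"` runs EM-REML in the eigenbasis of K (iterating until
#' the REML gradient norm drops below `tol` or `max_iter` iterations,
#' estimates clamped at zero), started from a coarse profile-likelihood scan
#' over heritability. `method = "gibbs"` runs a single-site Gibbs sampler in
#' the same eigenbasis with scaled-inverse-chi-squared variance priors
#' (weakly informative defaults: nu0 = 4, scale = var(y)/2) and flat priors
#' on the mean, with long-chain defaults, and returns
#' posterior means of the retained samples.
#'
#' @param y numeric response (pre-adjusted trait).
#' @param K relationship matrix aligned with y.
#' @param method `"reml"` (default) or `"gibbs"`.
#' @param tol REML gradient-norm convergence tolerance.
#' @param max_iter maximum EM iterations (default 500).
#' @param n_iter,burnin,thin Gibbs chain settings (defaults 250000, 25000,
#'   10).
#' @param seed Gibbs RNG seed.
#' @return object of class `varcomp`: sigma2_g, sigma2_e, h2, method,
#'   convergence details (REML: iterations, gradient, deviance history;
#'   Gibbs: chain settings and retained-sample count).
#' @export
estimate_varcomp <- function(y, K, method = c("reml", "gibbs"),
                             tol = 1e-6, max_iter = 500,
                             n_iter = 250000, burnin = 25000, thin = 10,
                             seed = 1) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n)
  check_psd(K)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- as.numeric(crossprod(eg$vectors, y))
  xt <- as.numeric(crossprod(eg$vectors, rep(1, n)))
  vy <- var(y)
  if (vy < 1e-12) stopf("response has no variance")

  if (method == "reml") {
    # profile scan over h2 for a good EM start
    cand_h2 <- seq(0.02, 0.98, by = 0.04)
    dev <- vapply(cand_h2, function(h) {
      reml_deviance(reml_parts(h * vy, (1 - h) * vy, d, yt, xt))
    }, 0)
    h0 <- cand_h2[which.min(dev)]
    sg <- h0 * vy; se <- (1 - h0) * vy
    history <- numeric(0)
    grad <- c(Inf, Inf)
    it <- 0
    floor_v <- 1e-10 * vy
    while (it < max_iter) {
      it <- it + 1
      parts <- reml_parts(sg, se, d, yt, xt)
      history <- c(history, reml_deviance(parts))
      grad <- -0.5 * c(parts$tr_pk - parts$ypkpy, parts$tr_p - parts$yppy)
      if (sqrt(sum(grad^2)) < tol) break
      sg <- max(sg + (sg^2 / n) * (parts$ypkpy - parts$tr_pk), floor_v)
      se <- max(se + (se^2 / n) * (parts$yppy - parts$tr_p), floor_v)
    }
    sg_out <- if (sg <= floor_v) 0 else sg
    out <- list(sigma2_g = sg_out, sigma2_e = se,
                h2 = sg_out / (sg_out + se), method = "EM-REML",
                iterations = it, gradient = grad,
                converged = sqrt(sum(grad^2)) < tol,
                deviance_history = history)
  } else {
    set.seed(seed)
    keep <- d > 1e-10 * max(d)
    q <- sum(keep)
    dk <- d[keep]
    nu0 <- 4; S0 <- vy / 2
    sg <- se <- vy / 2
    mu <- mean(y)
    gam <- numeric(q)
    xx <- sum(xt^2)
    n_saved <- floor((n_iter - burnin) / thin)
    saved <- matrix(NA_real_, n_saved, 2)
    si <- 0L
    for (s in seq_len(n_iter)) {
      prec <- 1 / se + 1 / (sg * dk)
      mn <- ((yt[keep] - mu * xt[keep]) / se) / prec
      gam <- mn + rnorm(q) / sqrt(prec)
      mu_mean <- sum(xt * (yt - replace(numeric(n), which(keep), gam))) / xx
      mu <- rnorm(1, mu_mean, sqrt(se / xx))
      ee <- yt - mu * xt
      ee[keep] <- ee[keep] - gam
      sse <- sum(ee^2)
      se <- (nu0 * S0 + sse) / rchisq(1, nu0 + n)
      ssg <- sum(gam^2 / dk)
      sg <- (nu0 * S0 + ssg) / rchisq(1, nu0 + q)
      if (s > burnin && (s - burnin) %% thin == 0) {
        si <- si + 1L
        saved[si, ] <- c(sg, se)
      }
    }
    saved <- saved[seq_len(si), , drop = FALSE]
    out <- list(sigma2_g = mean(saved[, 1]), sigma2_e = mean(saved[, 2]),
                h2 = mean(saved[, 1] / rowSums(saved)), method = "Gibbs",
                chain = c(n_iter = n_iter, burnin = burnin, thin = thin),
                n_samples = nrow(saved))
  }
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("Variance components (%s)\n", x$method))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, h2 = %.3f\n",
              x$sigma2_g, x$sigma2_e, x$h2))
  if (x$method == "EM-REML")
    cat(sprintf("  %d iterations, gradient norm %.2g (%s)\n", x$iterations,
                sqrt(sum(x$gradient^2)),
                if (x$converged) "converged" else "cap reached"))
  else
    cat(sprintf("  chain %d / burn-in %d / thin %d (%d samples)\n",
                x$chain["n_iter"], x$chain["burnin"], x$chain["thin"],
                x$n_samples))
  invisible(x)
}

#' Genomic BLUP
#'
#' Solves the mixed-model equations for y = 1 mu + g + e over all animals in
#' the relationship matrix, with phenotypes observed on the training animals
#' only; breeding values of the remaining animals are predicted through
#' their genomic relationships. Variance components are estimated on the
#' training records by [estimate_varcomp()] unless supplied.
#'
#' @param y named numeric vector of training phenotypes.
#' @param K relationship matrix over all animals (training and testing).
#' @param vc optional `varcomp` object (or list with sigma2_g, sigma2_e).
#' @param ... passed to [estimate_varcomp()] when `vc` is NULL.
#' @return object of class `gblup`: intercept `mu`, named breeding values
#'   `g` for every animal in K, the variance components, and bookkeeping.
#' @export
gblup <- function(y, K, vc = NULL, ...) {
  if (is.null(names(y))) stopf("y must be named by animal id")
  all_ids <- rownames(K)
  if (is.null(all_ids)) stopf("K needs sample ids as dimnames")
  if (!all(names(y) %in% all_ids))
    stopf("training ids absent from K: %s",
          paste(utils::head(setdiff(names(y), all_ids), 5), collapse = ", "))
  train <- names(y)
  if (is.null(vc))
    vc <- estimate_varcomp(as.numeric(y), K[train, train], ...)
  sg <- vc$sigma2_g; se <- vc$sigma2_e
  n_all <- length(all_ids); n_tr <- length(train)
  if (sg < 1e-12 * max(se, 1e-300)) {
    g <- setNames(rep(0, n_all), all_ids)
    fit <- list(mu = mean(y), g = g, vc = vc, train_ids = train,
                n_all = n_all, call = match.call())
    class(fit) <- "gblup"
    return(fit)
  }
  # invert the relationship matrix; a rank-deficient K (few markers, close
  # relatives) is bent on its eigenvalue floor
  ev <- eigen(K, symmetric = TRUE)
  lam <- ev$values
  floor_ev <- 1e-8 * max(lam)
  if (min(lam) < floor_ev) {
    message(sprintf("gblup: relationship matrix near-singular (min eigenvalue %.3g); bending to %.3g",
                    min(lam), floor_ev))
    lam <- pmax(lam, floor_ev)
  }
  Kinv <- ev$vectors %*% (t(ev$vectors) / lam)
  W <- matrix(0, n_tr, n_all, dimnames = list(train, all_ids))
  W[cbind(seq_len(n_tr), match(train, all_ids))] <- 1
  lambda <- se / sg
  C <- rbind(cbind(n_tr, t(colSums(W))),
             cbind(colSums(W), crossprod(W) + lambda * Kinv))
  rhs <- c(sum(y), as.numeric(crossprod(W, y)))
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    message("gblup: singular MME coefficient matrix; adding 1e-8 ridge")
    tryCatch(solve(C + diag(1e-8, nrow(C)), rhs),
             error = function(e2) stopf("mixed-model equations are singular"))
  })
  fit <- list(mu = sol[1], g = setNames(sol[-1], all_ids), vc = vc,
              train_ids = train, n_all = n_all, call = match.call())
  class(fit) <- "gblup"
  fit
}

#' @export
print.gblup <- function(x, ...) {
  cat("GBLUP fit\n")
  cat(sprintf("  %d training records, %d animals in the relationship matrix\n",
              length(x$train_ids), x$n_all))
  cat(sprintf("  mu = %.4g; h2 used = %.3f (%s)\n", x$mu, x$vc$h2,
              x$vc$method %||% "supplied"))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  print(object)
  cat(sprintf("  breeding values: mean %.3g, SD %.3g\n",
              mean(object$g), sd(object$g)))
  invisible(object)
}

#' @export
coef.gblup <- function(object, ...) c("(Intercept)" = object$mu, object$g)

#' Predict phenotypes for animals in a GBLUP fit
#'
#' @param object a [gblup()] fit.
#' @param ids animal ids to predict (default: every non-training animal).
#' @param ... unused.
#' @return named numeric vector mu + g_hat.
#' @export
predict.gblup <- function(object, ids = NULL, ...) {
  ids <- ids %||% setdiff(names(object$g), object$train_ids)
  missing <- setdiff(ids, names(object$g))
  if (length(missing))
    stopf("ids absent from the fit: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  object$mu + object$g[ids]
}

#' @export
fitted.gblup <- function(object, ...) {
  object$mu + object$g[object$train_ids]
}
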